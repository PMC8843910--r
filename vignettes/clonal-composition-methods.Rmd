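---
title: "Clonal composition from BAF and log2R: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal composition from BAF and log2R: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecomp)
```

## The mixture model

A tumor sample is modelled as diploid normal cells mixed with aberrant
clones. If a clone present in a fraction $\rho$ of cells carries a segment
at $N$ total copies with $m$ copies of the minor allele, the segment's
sample-average copy number is $c = 2(1-\rho) + N\rho$, its expected log2
ratio is $\log_2(c/2)$, and its expected B-allele frequency at
germline-heterozygous sites is $b = ((1-\rho) + m\rho)/c$. Because allele
labels on an array are arbitrary, all computation uses the folded value
$\min(b, 1-b) \in [0, 0.5]$: 0.5 is heterozygous, 0 is complete loss of
heterozygosity (LOH).

The model's central assumptions are that (i) each segment's aberration is
attributable to a single clone, so segments sharing an aberrant-cell
percentage (%AC $= 100\rho$) belong to the same clone; (ii) the normal-cell
compartment is diploid and heterozygous at the probes used; and (iii) clones
are not nested on the same locus. The clonal composition (CC) number is the
count of distinct %AC values among qualifying aberrant segments — it
estimates the number of clones *with copy-number changes*, not the total
number of clones.

Only zero-minor-allele states (NOMA $= 0$) qualify for the CC count. Gains
are excluded because the BAF displacement of a gain depends on how many
copies were gained, which is not constant across segments; losses have no
such ambiguity. By default both hemizygous loss ($N = 1$) and copy-neutral
LOH ($N = 2$) qualify; the set is configurable (`qualifying_n_set`) because
one could read the qualifying state narrowly as copy-neutral LOH only.
Homozygous deletion ($N = m = 0$) is enumerable in fitting but can never
qualify: its folded BAF is identically 0.5 and carries no LOH signal.

## Segment fitting

`fit_segment()` enumerates hypotheses on a grid — $N \in \{0..4\}$,
$m \in \{0..\lfloor N/2 \rfloor\}$, $\rho$ in steps of 0.01 — and minimizes

$$w_b\,(b_{obs} - \hat b)^2 + w_r\,(r_{obs} - \hat r)^2,
  \qquad w_b = 1,\; w_r = 0.25 .$$

Whether the original estimation programs fit BAF alone, log2R alone, or
jointly is not publicly specified, so the weights are exposed rather than
guessed; the defaults make BAF the primary signal (it is the better-behaved
of the two on molecular-inversion-probe arrays) while log2R disambiguates
$N$ — copy-neutral LOH and hemizygous loss can produce the same folded BAF
but differ in log2R. Ties are broken toward smaller $N$, then smaller $m$,
then smaller $\rho$, so results are reproducible bit for bit; an exhaustive
brute-force oracle in the test suite confirms the argmin on seeded random
inputs.

A segment *qualifies* for the CC count when its best fit has $m = 0$, $N$ in
the qualifying set, residuals within the curve gates
($\varepsilon_b = 0.025$ BAF units, $\varepsilon_r = 0.10$ log2R units) and
$\rho \ge 0.05$. The gates reflect typical segment-level noise: a
500-probe segment with per-probe noise $\sigma_b = 0.04$ has a median-based
folded-BAF standard error near 0.005, so the gates sit several standard
errors out while still rejecting points far from every curve. The floor
$\rho \ge 0.05$ prevents noise-level "clones".

## Screening, clustering, and the undetermined status

Segments enter the analysis when they have at least 50 probes and show
either folded BAF $< 0.45$ or $|$log2R$| > 0.10$. The 0.45 floor also
absorbs the small downward bias of median-folded BAF near 0.5 (folding noise
around 0.5 can only push values down; at $\sigma_b = 0.04$ the median of
folded probe values for a diploid segment sits near 0.473).

Qualifying segments are clustered in two stages:

1. **Stage 1** — single-linkage clustering in (folded BAF, log2R) with
   per-axis tolerances (0.02, 0.08): segments "with the same log2R and BAF"
   join a cluster. Single linkage with fixed tolerances is deterministic and
   needs no cluster-count choice.
2. **Stage 2** — stage-1 clusters whose probe-weighted %AC differ by at most
   `merge_delta_ac` = 5 percentage points are combined (one-dimensional
   chain merging on sorted %AC). This is what joins, say, a hemizygous loss
   and a copy-neutral LOH carried by the same clone: different curves, same
   %AC. The merging tolerance has no published value; 5 points was chosen
   once as commensurate with the %AC estimation error of well-powered
   segments and is monotone by construction (a larger tolerance can only
   reduce the CC number). Cluster %AC is probe-weighted so large segments
   carry more evidence.

CC equals the number of merged clusters; CC $= 0$ (no qualifying aberration)
is the homogeneous, mono-CC reading. An alternative "subclone" count
(clusters minus one) is available behind `count_mode = "subclones"` but is
not the default, since the CC-number definition counts distinct %AC values.

A sample is **undetermined** when at least one segment demands an LOH
explanation (folded BAF below the aberrance floor with enough probes) but no
segment lies on any qualifying curve — the "did not plot onto the fitting
curve" case. If only some LOH segments are off-curve they are dropped with a
warning and CC is computed from the rest; whether real failed cases had
partial or no fits is not documented, and this is the more conservative
reading (a partly interpretable sample still yields an estimate).
Undetermined samples are excluded from all group statistics, mirroring a
cohort analyzed as 36 minus 2.

## The synthetic cohort

`simulate_cohort()` emulates the study design end to end, with every
parameter fixed in one spec and a single seed:

* **Arms** — 8 mono-CC samples (diploid segments only), 26 poly-CC samples
  (1–3 clones, fractions drawn from [0.2, 0.9] with pairwise gaps above
  twice the merging tolerance so truth is well defined; each clone carries
  1–3 hemizygous-loss or copy-neutral-LOH events), and 2 undetermined
  samples whose LOH-like segments (folded BAF near 0.15 with log2R near
  +0.8) are jointly inconsistent with every NOMA $= 0$ curve. The enforced
  clone separation can be disabled (`min_rho_gap = 0`) for a harder regime.
* **Probes** — each segment draws 100–2000 probes; 25% are
  germline-heterozygous. Het probes get the model-expected unfolded BAF with
  a random per-SNP allele phase (folding happens only at summarization,
  reproducing the mirror-band geometry of real arrays); homozygous probes
  sit near 0 or 1. Per-probe Gaussian noise defaults to $\sigma_r = 0.25$
  and $\sigma_b = 0.04$, typical of molecular-inversion-probe arrays.
* **Clinical table** — recurrence-free survival is exponential with the
  group median (rate $\ln 2 / \text{median}$): 7.0 months for poly-CC, and
  60 months for mono-CC as a stand-in for a median "not reached" inside the
  60-month administrative censoring window. The exponential is the minimal
  model specified by a median alone. The two undetermined patients draw from
  the mono model (in the emulated design they were recurrence-free). Binary
  covariates (age ≥ 70, PIVKA-II ≥ 40, tumor size ≥ 4 cm) are Bernoulli with
  group-dependent prevalences.

What the generator does **not** emulate: real karyotypes and genome
coordinates (segments live on synthetic chromosomes), GC waves and spatial
autocorrelation of probe noise, segmentation error (segments are given, not
inferred), nested subclones on one locus (cross-clone overlapping events are
rejected outright), whole-genome doubling, and any dependence between
covariates. Passing recovery tests on this generator therefore demonstrates
correctness of the estimation machinery under the stated noise model, not
performance on real arrays, where segmentation quality and purity are the
dominant error sources.

## Numerical and statistical choices

* The $\rho$ grid is $\{0.01, \dots, 1.00\}$; zero-copy rows
  ($N = 0, \rho = 1$) are dropped. Forward/inverse BAF maps round-trip to
  $10^{-10}$; balanced states ($N = 2m$) are non-invertible by construction
  and raise an error rather than returning a pseudo-value.
* The two-sided Fisher exact test sums hypergeometric point probabilities at
  most that of the observed table (relative tie tolerance $10^{-7}$) — the
  probability-ordering convention used by mainstream statistics software,
  verified in the test suite against ten published 2×2 tables. Tables with
  an empty margin return $p = 1$ with a warning. Per-variable p-values are
  reported unadjusted, as such studies print them.
* Mann–Whitney U uses midranks; the p-value is exact by enumeration for
  $n_1 + n_2 \le 12$ and a tie-corrected, continuity-corrected normal
  approximation otherwise.
* Kaplan–Meier treats censored observations tied with an event time as still
  at risk (events first); the median is the smallest event time with
  $S \le 0.5$ (with a $10^{-9}$ tolerance against floating-point products),
  and "not reached" is returned as `NA`, the survival-software convention.
* The log-rank statistic is the usual one-degree-of-freedom
  $(\sum O - E)^2 / \sum V$ with hypergeometric variances. At the study's
  size (8 vs 26) the chi-square approximation is slightly anticonservative
  when nearly all observations are events; the test suite's size check
  therefore evaluates the null where both arms follow the mono arm's
  distribution (about half the observations censored at 60 months), the
  natural no-group-effect null for this design.
* All randomness flows through one seed; identical (spec, seed) pairs give
  byte-identical files, and the resolved configuration is written next to
  every stage's outputs.

## Problem sizes in the test suite

The suite checks model-core properties on dense grids and 1000 seeded random
fits; CC recovery on 200 seeded one-sample cohorts (300–800 probes per
segment) at zero and at default noise; distributional properties of the
generator at $n = 5000$; log-rank power over 500 and size over 1000
replicates of the 8/26 design; and end-to-end determinism on a 10-sample
cohort. These sizes keep the full suite under a minute while leaving the
Monte-Carlo assertions comfortably away from their thresholds.

## Limitations

The CC number counts copy-number-defined clones only; tumors diversifying
through point mutations alone are invisible to it. The model assumes a pure
two-compartment mixture per segment and does not estimate global tumor
purity or ploidy (no ASCAT-style joint fit); a genome-doubled tumor would
need a wider `hypothesis_n_range` and a reconsidered qualifying set. The
undetermined rule is one consistent reading of "did not plot onto the
fitting curve". Segment calls are taken as given: segmentation error
propagates directly into screening and fitting.
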
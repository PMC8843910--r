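# clonecomp

Clonal composition estimation from allele-specific copy number segments.

Tumors are mixtures: a fraction of normal cells plus one or more aberrant
clones carrying copy-number events. On a SNP array each genomic segment is
summarized by two signals — the **folded B-allele frequency** (BAF, folded to
`[0, 0.5]`; 0.5 means heterozygous, 0 means complete loss of heterozygosity)
and the **log2 intensity ratio** (log2R; 0 means two copies on average).
`clonecomp` estimates how many *copy-number-defined clones* a tumor contains
(its **clonal composition number**, CC) and classifies tumors as **mono-CC**
(CC = 0, homogeneous) or **poly-CC** (CC ≥ 1, heterogeneous), a distinction
associated with early recurrence risk in resected hepatocellular carcinoma.

## The model

A segment carried at `N` total copies, `m` of them the minor allele, by an
aberrant clone present in a cell fraction `ρ` (%AC = 100·ρ) has

```
c(ρ, N)    = 2 (1 − ρ) + N ρ                     sample-average copy number
log2R      = log2( c / 2 )
folded BAF = min(b, 1 − b),  b = ((1 − ρ) + m ρ) / c
```

As ρ sweeps (0, 1] each state `(N, m)` traces a *fitting curve* in
(folded BAF, log2R) space. Only states with **zero minor alleles in the
aberrant cells** (`m = 0`, i.e. NOMA = 0: hemizygous loss `N = 1` and
copy-neutral LOH `N = 2`) are used for the CC number, because their BAF
response to ρ is strong and unambiguous. Each aberrant segment is fitted by
enumerating `(N, m, ρ)` on a grid and minimizing the weighted squared
residual in both coordinates; qualifying segments are clustered by %AC
(single linkage in (BAF, log2R), then merging of clusters within 5 %AC
points), and **CC = the number of distinct %AC clusters**. A sample whose
LOH-like segments fit no curve is **undetermined** and excluded from group
statistics.

Downstream, the package provides the cohort statistics such a study reports —
two-sided Fisher exact test (probability-ordering convention), Mann–Whitney
U, Kaplan–Meier product-limit curves with median survival, and the log-rank
test — implemented from first principles, plus a seeded synthetic-cohort
generator (probe-level BAF/log2R with known clone structure, exponential
group-dependent recurrence times) so the whole pipeline is testable without
array data.

## Worked example

Four segments of one tumor, two clones (72% and 31% of cells), noiseless:

```r
library(clonecomp)
seg <- data.frame(sample_id = "HCC_017",
                  chrom = c("chr4", "chr8", "chr13", "chr17"),
                  start = 0L, end = 2000000L, n_probes = 800L, n_het = 200L,
                  log2r = c(expected_log2r(0.72, 1), 0,
                            expected_log2r(0.31, 1), 0.01),
                  folded_baf = c(expected_folded_baf(0.72, 1, 0),
                                 expected_folded_baf(0.72, 2, 0),
                                 expected_folded_baf(0.31, 1, 0), 0.5))
call_sample(seg)
#> Sample HCC_017: status estimated, CC number 2 (poly-CC)
#>   clone clusters (%AC): 72.0, 31.0
```

The hemizygous loss on chr4 and the copy-neutral LOH on chr8 land on
different fitting curves but share %AC 72 — one clone; chr13 is a second
clone at %AC 31; the diploid chr17 is screened out. A single segment fit:

```r
fit_segment(1/3, log2(0.75))
#> Segment fit: N = 1, m = 0, rho = 0.50 (%AC 50)
#>   expected (BAF 0.3333, log2R -0.4150); residuals (0.0000, 0.0000)
#>   aberrant: TRUE; qualifies for CC: TRUE
```

A full synthetic study (36 samples: 8 mono, 26 poly, 2 undetermined by
construction), through the three pipeline stages:

```r
cfg <- read_run_config()          # package defaults, seed 42
cc_simulate(cfg, "run")           # segments.tsv, patients.tsv
cc_call(cfg, "run/segments.tsv", "run")
#> called 36 samples: 8 mono-CC, 26 poly-CC, 2 undetermined
cc_stats(cfg, "run/cc_results.tsv", "run/patients.tsv", "run")
#> 2 undetermined sample(s) excluded from group statistics
#> median RFS: mono 27.18, poly 6.72; log-rank p = 0.0051
```

The poly-CC arm's median recurrence-free survival (6.72 months here) sits
near its configured 7.0-month exponential median; the mono arm, drawn with a
60-month median inside a 60-month follow-up window, recurs late or not at
all. The same three stages are available from a shell via
`inst/cli/clonecomp simulate|call|stats --config <yaml>`.

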
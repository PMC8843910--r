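# clonecomp run configuration — every key is optional; the values below are
# the package defaults and are used verbatim when a key is omitted.

model:
  hypothesis_n_range: [0, 1, 2, 3, 4]   # total copies N enumerated in aberrant cells
  qualifying_n_set: [1, 2]              # NOMA=0 states that may contribute to CC
  rho_grid_step: 0.01                   # %AC grid resolution (fraction)
  rho_min: 0.05                         # smallest aberrant-cell fraction accepted
  gate_eps_baf: 0.025                   # curve gate on |observed - fitted| folded BAF
  gate_eps_log2r: 0.10                  # curve gate on |observed - fitted| log2R
  weight_baf: 1.0                       # fit weight of squared BAF residual
  weight_log2r: 0.25                    # fit weight of squared log2R residual
  aberrance_baf_floor: 0.45             # screen: folded BAF below this is aberrant
  aberrance_log2r_band: 0.10            # screen: |log2R| above this is aberrant
  min_probes: 50                        # screen: minimum probes per segment
  merge_delta_ac: 5.0                   # clusters within this %AC are one clone
  stage1_tol_baf: 0.02                  # stage-1 single-linkage tolerance, BAF axis
  stage1_tol_log2r: 0.08                # stage-1 single-linkage tolerance, log2R axis
  count_mode: clusters                  # "clusters" or "subclones" (clusters - 1)

cohort:
  n_mono: 8                             # samples with no qualifying aberration
  n_poly: 26                            # samples with 1-3 clones
  n_undetermined: 2                     # samples with off-curve LOH-like segments
  seed: 42                              # governs all randomness
  n_normal_segments: 4                  # diploid background segments per sample
  probes_per_segment: [100, 2000]       # probe count drawn uniformly per segment
  het_fraction: 0.25                    # germline-heterozygous probe fraction
  clone_range: [1, 3]                   # clones per poly sample
  rho_range: [0.2, 0.9]                 # clone fractions drawn from this range
  min_rho_gap: 0.10                     # enforced separation between clone fractions
  survival:
    median_rfs_poly: 7.0                # months (exponential median)
    median_rfs_mono: 60.0               # months; encodes "not reached" in the window
    admin_censor: 60.0                  # administrative censoring, months
  noise:
    sigma_log2r_probe: 0.25             # per-probe log2R s.d.
    sigma_baf_probe: 0.04               # per-probe BAF s.d.
  covariates:                           # binary covariate prevalences per group
    age_ge_70:   {mono: 0.625, poly: 0.577}
    pivka_ge_40: {mono: 0.25,  poly: 0.72}
    size_ge_4:   {mono: 0.375, poly: 0.577}

write_probes: false                     # also write per-probe TSV from cc_simulate()
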
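# cpgc — correlation-purged Granger causality for resting-state brain networks

`cpgc` implements directed (effective) connectivity analysis of
resting-state fMRI ROI time series for two-group clinical studies, of the
kind used to compare amnesic mild-cognitive-impairment patients with
matched controls across four resting-state networks (default-mode,
hippocampal-cortical memory, dorsal-attention, fronto-parietal control; a
33-ROI coordinate table ships with the package).

The core statistic is **correlation-purged Granger causality (CPGC)**.
With standardized ROI series `X(t)`, the modified multivariate
autoregressive model

    X(t) = A(0) X(t) + A(1) X(t-1) + ... + A(p) X(t-p) + E(t)

includes an instantaneous coefficient matrix `A(0)` whose diagonal is
structurally zero: each series loads on the zero-lag values of the *other*
series, so instantaneous cross-correlation is absorbed by `A(0)` instead of
leaking into the lagged coefficients. Directed causal strength from ROI j
to ROI i is the sum of squared lagged coefficients,
`CPGC_ij = Σ_n a_ij(n)²`. Inference is fully empirical:

* **within groups** — per-subject phase-randomized surrogates (magnitude
  spectrum kept, phases randomized independently per series) give an
  empirical null per directed path; add-one empirical p-values are combined
  across subjects with Fisher's method (`-2 Σ log p ~ χ²_2m`) at p < 0.01,
  and significant pairs are classified uni-/bi-directional;
* **between groups** — per-path one-way ANOVA with a gray-matter atrophy
  covariate, masked by the within-group significant sets (increased =
  patient > control ∩ within-patient; decreased = control > patient ∩
  within-control);
* **behavior** — Pearson correlation of surviving paths with MMSE / CVLT /
  CDT scores; motion QC via framewise displacement (50 mm rotational
  arc-length conversion).

A synthetic-cohort generator with known planted causal structure
(`make_ground_truth()`, `simulate_cohort()`) provides the validation bed:
two groups × 16 subjects × 229 frames at TR 2 s by default, with optional
hemodynamic blurring, drift/global components, motion traces, tissue
nuisance series, atrophy covariates and behavior coupling.

## Worked example

```r
library(cpgc)

rois <- load_roi_table(cpgc_roi_table())   # 33 ROIs, 4 networks
table(rois$network)
#  DAN  DMN FPCN HCMN
#    6   12    9    6

gt <- make_ground_truth("one-edge", k = 6, edge_strength = 0.4,
                        behavior = list(measure = "MMSE", r = 0.6))
cohort <- simulate_cohort(gt, cohort_config(n_per_group = 16, hrf = FALSE),
                          seed = 42)
an <- analyze_cohort(cohort, n_surrogates = 500, band = NULL)
an
# cohort analysis (order 5, 500 surrogates)
#   within-patient significant paths: 2
#   within-control significant paths: 1
#   increased (patient > control, masked): 1
#   decreased (control > patient, masked): 1
an$diff$increased_edges
#   source target        F            p
# 1  node1  node2 94.29598 1.279452e-10
```

The planted patient-only edge node1 → node2 is the single masked increased
path: its within-patient Fisher-combined p is below 0.01 and the
covariate-adjusted group contrast gives F = 94.3 (p ≈ 1e-10) with
patient > control. `an$behavior` holds the Pearson correlations of the
surviving paths with the (coupled) MMSE score in patients, and
`framewise_displacement()` summarizes each subject's fabricated motion
trace (`mean FD 0.116 mm` for the first subject here).

A thin command-line wrapper over the same functions is in
`inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --scenario one-edge --seed 1 --out-dir out`);
`cpgc_defaults()` is the single source of every numeric default (band
0.01–0.08 Hz, order 5, 10,000 surrogates, α = 0.01, 12 mm ROI spheres,
50 mm head radius, TR 2 s, 229 frames).

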
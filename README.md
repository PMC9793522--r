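# methylRF

Random-forest comparative analysis of DNA methylome risk groups in
neuroblastoma.

Neuroblastoma risk stratification uses INSS stage, *MYCN* amplification and
age at diagnosis, but these clinical markers misplace part of the
intermediate-risk spectrum. This package implements an analysis workflow
over Illumina 450K-style beta-value matrices (β = M / (M + U + 100)) for
researchers who want to ask whether DNA methylation recovers — and
refines — the clinical grouping:

* **Risk-group classification.** Samples are assigned to classes
  A (*MYCN*-amplified), B (stage 4), C (stage 4S), D (stages 1–3) and
  classified by repeated hold-out random forests (stratified 70/30 splits,
  balanced class weights, optional chi2/ANOVA-F select-percentile
  prefilter fitted on training folds only), reported as per-class
  precision/recall/f1 mean ± SD.
* **Subgroup discovery.** Per-sample prediction tallies across replicates
  define each sample's modal predicted class; group-D samples modally
  predicted as B become subgroup **D1**, those predicted as D become
  **D2**. Group B is split at age 1.5 years into B1/B2.
* **Feature-group power.** Annotation-defined probe groups (enhancers,
  CGI promoters, DMRs, ...) are scored by f1 against size-matched random
  baselines and the ANOVA-F select-percentile ranking; the obs/sim f1
  ratio is correlated with per-group beta variance (permutation p).
* **Single-probe statistics.** For each probe, the threshold r0 minimizing
  the weighted two-partition Gini impurity
  `(n_u/n)(1 − Σ_k q_{k,u}²) + (n_l/n)(1 − Σ_k q_{k,l}²)`,
  the per-class side fractions p_{k,u}, p_{k,l} at r0, and the CMS_k call:
  a probe isolates class k at threshold θ when p of class k on one side and
  of every other class on the opposite side are all ≥ θ. Impurity-decrease
  importance is averaged over repeated forests; top-N probes are summarized
  per gene and in ±100 kb locus views.
* **Survival screening.** Per-probe Δβ contrasts, log-rank tests on the
  per-probe mean-β split with Benjamini–Hochberg control (LRFDR), joint
  Δβ/LRFDR filtering, an RMS profile-distance permutation test against a
  reference group, Fisher tests on subgroup composition, and Kaplan–Meier
  comparisons.
* **Synthetic cohort generator.** A 450K-like simulator whose defaults
  emulate the pooled four-source cohort (493 samples, latent B-like D1
  subgroup inside group D, enhancer-enriched group-A hypomethylation,
  low-variance CGI-promoter probes, exponential event-free survival with
  censoring), so the entire workflow is testable without patient data.

The methods vignette (`vignettes/methylome-risk-groups.Rmd`) documents the
model, the design decisions and the generator's scope.

## Worked example

The `analysis/` directory holds the workflow as numbered scripts
(simulate → classify → feature groups → CMS/importance → survival), each a
thin driver over the package functions, writing tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify.R
```

prints, for the default synthetic cohort:

```
  class precision_mean precision_sd recall_mean recall_sd f1_mean  f1_sd
1     A          1.000       0.0000       1.000    0.0000   1.000 0.0000
2     B          0.882       0.0224       1.000    0.0000   0.937 0.0126
3     C          1.000       0.0000       1.000    0.0000   1.000 0.0000
4     D          1.000       0.0000       0.602    0.0849   0.748 0.0664

group D relabeling: 33 D1 (modal B), 49 D2 (modal D), 0 other
agreement with planted subgroups: 1.000
```

Groups A and B classify strongly while group D's recall is pulled down by
exactly the samples planted to methylate like group B — which the modal
relabeling then recovers as D1. The survival stage
(`Rscript analysis/05_survival.R`) closes the loop:

```
probes with |delta beta|(D1-D2) > 0.3: 100 (100 higher in D1)
RMS distance to B1: D1 0.0140 vs D2 0.3504 (permutation p = 0.001)
pairwise log-rank p-values:
  group1 group2        p
1      B     D1 7.35e-02
2      B     D2 7.43e-26
3     D1     D2 1.12e-14
```

The D1/D2 contrast is one-sidedly hypermethylated in D1, D1's methylation
profile sits next to the young stage-4 group B1, and the two discovered
subgroups have sharply different event-free survival — D1 is statistically
indistinguishable from high-risk B.

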
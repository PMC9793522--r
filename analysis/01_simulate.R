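#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 450K-like cohort all later stages analyse.
#
# The default configuration emulates the pooled four-source neuroblastoma
# cohort: 493 samples (A = 110 MYCN-amplified, B = 246 stage 4, C = 55
# stage 4S, D = 82 stages 1-3), 2000 probes, a latent B-like subgroup D1
# making up 40% of group D, enhancer-enriched group-A hypomethylation, and
# low-variance CGI-promoter probes.

library(methylRF)

out_dir <- "results/cohort"
cohort <- generate_cohort(sim_config(seed = 20260921 %% 10000))
write_cohort(cohort, out_dir)

cat("cohort written to", out_dir, "\n")
cat(sprintf("  %d probes x %d samples\n", nrow(cohort$beta), ncol(cohort$beta)))
print(table(cohort$truth$samples$true_group))
cat("latent subgroups inside group D:\n")
print(table(cohort$truth$samples$true_subgroup[
  cohort$truth$samples$true_group == "D"]))
cat(sprintf("censored fraction: %.2f\n", mean(!cohort$metadata$efs_event)))
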
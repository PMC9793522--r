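#!/usr/bin/env Rscript
# Stage 5: what separates D1 from D2, and does it matter for survival?
# Delta-beta contrast, per-probe log-rank screen with BH control (LRFDR),
# the joint filter, the profile-distance permutation test against the young
# stage-4 group B1, composition Fisher tests, and Kaplan-Meier comparisons.

library(methylRF)

beta <- read_beta_matrix("results/cohort/beta.tsv")
meta <- read_metadata("results/cohort/metadata.csv")
groups <- read.csv("results/groups.csv", stringsAsFactors = FALSE)

prof <- delta_beta(beta, groups, "D1", "D2")
write.csv(prof, "results/deltabeta.csv", row.names = FALSE)
sel <- filter_probes(prof, 0.3)
cat(sprintf("probes with |delta beta|(D1-D2) > 0.3: %d (%d higher in D1)\n",
            length(sel), sum(prof$delta[prof$probe_id %in% sel] > 0)))

screen <- logrank_screen(beta, meta)
write.csv(screen, "results/lrfdr.csv", row.names = FALSE)
joint <- joint_filter(prof, screen, delta_threshold = 0.3,
                      fdr_threshold = 0.01)
writeLines(joint, "results/joint_probes.txt")
cat(sprintf("probes passing both |delta beta| > 0.3 and LRFDR < 0.01: %d\n",
            length(joint)))

dist <- profile_distance_test(beta, groups, "B1", "D1", "D2", sel,
                              n_permutations = 999, seed = 5)
cat(sprintf("RMS distance to B1: D1 %.4f vs D2 %.4f (permutation p = %.4g)\n",
            dist$d1, dist$d2, dist$p))

# subgroup composition: INSS stage 3 and age < 1.5 years in D1 vs D2
stage <- meta$inss_stage[match(groups$sample_id, meta$sample_id)]
age <- meta$age_years[match(groups$sample_id, meta$sample_id)]
for (feat in c("stage3", "young")) {
  flag <- if (feat == "stage3") stage == "3" else age < 1.5
  tab <- rbind(D1 = c(sum(flag & groups$subgroup %in% "D1"),
                      sum(!flag & groups$subgroup %in% "D1")),
               D2 = c(sum(flag & groups$subgroup %in% "D2"),
                      sum(!flag & groups$subgroup %in% "D2")))
  ft <- fisher_composition(tab)
  cat(sprintf("%s composition D1 %d/%d vs D2 %d/%d: Fisher p = %.4g\n",
              feat, tab[1, 1], sum(tab[1, ]), tab[2, 1], sum(tab[2, ]),
              ft$p))
}

grouping <- setNames(
  ifelse(groups$subgroup %in% c("D1", "D2"), groups$subgroup,
         ifelse(groups$group == "B", "B", NA_character_)),
  groups$sample_id)
km <- km_compare(meta, grouping[!is.na(grouping)])
write.csv(km$pairwise, "results/km_pvalues.csv", row.names = FALSE)
cat("\nmedian event-free survival (days):\n")
print(km$median_survival)
cat("pairwise log-rank p-values:\n")
print(km$pairwise, digits = 3)
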
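#!/usr/bin/env Rscript
# Stage 4: single-probe classification power. Optimal Gini splits and CMS
# calls at theta = 0.8, impurity-decrease importance averaged over repeated
# forests (chi2 top-10% prefilter, as for the headline scores), the
# top-probe gene summary, the CMS-along-rank profile, and a locus view of
# the most probe-rich top gene.

library(methylRF)

beta <- read_beta_matrix("results/cohort/beta.tsv")
manifest <- read_manifest("results/cohort/manifest.csv")
groups <- read.csv("results/groups.csv", stringsAsFactors = FALSE)

splits <- suppressWarnings(find_split_all(beta, groups))
write.csv(splits, "results/splits.csv", row.names = FALSE)
calls <- cms_call_all(splits, theta = 0.8)
write.csv(calls, "results/calls.csv", row.names = FALSE)
cat("CMS calls at theta = 0.8:\n")
print(table(calls$class[calls$call == "cms"],
            calls$side[calls$call == "cms"]))

imp <- aggregate_importance(
  beta, groups,
  rf_config(n_trees = 500, prefilter = prefilter_chi2(10), seed = 4),
  R = 50)
write.csv(imp, "results/importance.csv", row.names = FALSE)

top <- top_probes_to_genes(imp, manifest, N = 200)
cat(sprintf("\ntop 200 importance probes fall on %d genes\n", top$n_genes))
print(head(top$genes[, c("gene", "n_probes")], 10))
write.csv(top$genes, "results/top_genes.csv", row.names = FALSE)

prof <- rank_cms_profile(imp, calls, n_bins = 10)
write.csv(prof, "results/rank_cms_profile.csv", row.names = FALSE)
cat("\nCMS proportion in the top importance bin (the 'L-shape' head):\n")
print(prof[prof$bin == 1, c("class", "n_cms", "n_u", "n_l", "proportion")])

anchor_gene <- top$genes$gene[1]
lv <- locus_view(manifest, beta, groups, anchor_gene,
                 calls = calls, top_probes = top$top_probes)
write.table(lv, "results/locus_view.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nlocus view of %s: %d probes within 100 kb, %d with CMS calls\n",
            anchor_gene, nrow(lv), sum(!is.na(lv$cms_class))))
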
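# Shared fixtures and independent oracles, built in code at test time.

tiny_cohort <- function(seed = 1, ...) {
  args <- list(n_per_group = c(A = 20, B = 40, C = 10, D = 30),
               n_probes = 300, seed = seed)
  args[names(list(...))] <- list(...)
  generate_cohort(do.call(sim_config, args))
}

risk_groups_of <- function(cohort) {
  assign_age_subgroup(assign_risk_group(cohort$metadata), cohort$metadata)
}

truth_groups_of <- function(cohort) {
  tr <- cohort$truth$samples
  data.frame(sample_id = tr$sample_id, group = tr$true_group,
             subgroup = ifelse(tr$true_subgroup %in% c("D1", "D2"),
                               tr$true_subgroup, NA_character_),
             stringsAsFactors = FALSE)
}

# brute-force weighted two-partition Gini scan: plain double loop, kept
# deliberately independent of find_split()'s vectorized path
brute_force_split <- function(beta_probe, y) {
  y <- factor(y)
  vals <- sort(unique(beta_probe))
  cands <- (vals[-1] + vals[-length(vals)]) / 2
  n <- length(beta_probe)
  best_r <- NA_real_
  best_imp <- Inf
  for (r in cands) {
    up <- beta_probe > r
    imp <- 0
    for (side in list(up, !up)) {
      ns <- sum(side)
      q <- table(y[side]) / ns
      imp <- imp + (ns / n) * (1 - sum(q^2))
    }
    if (imp < best_imp - 1e-12) {   # ties keep the earlier (smaller) r
      best_imp <- imp
      best_r <- r
    }
  }
  list(r0 = best_r, impurity = best_imp)
}

# literal Benjamini-Hochberg step-up: sort, multiply, cumulative-min, unsort
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

mini_annotation <- function() {
  ann <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                    stringsAsFactors = FALSE)
  ann$refgene_group <- list("1stExon", "TSS200", character(0))
  ann$cgi_relation <- c("", "Island", "")
  ann$enhancer_450k <- c(FALSE, FALSE, FALSE)
  ann$phantom5_enhancer <- c(FALSE, FALSE, FALSE)
  ann$dmr_class <- c("", "", "")
  ann$dnase <- c(FALSE, FALSE, FALSE)
  ann$tfbs <- c(FALSE, FALSE, FALSE)
  ann$open_chromatin <- c(FALSE, FALSE, FALSE)
  ann$snp_flag <- c(FALSE, FALSE, FALSE)
  ann$chromosome <- c("chr1", "chr1", "chr1")
  ann$position <- c(100L, 200L, 300L)
  ann$gene_symbols <- list("G1", "G1", "G2")
  ann
}

# printed worked-example side fractions for probe cg12343591
worked_example_fractions <- function() {
  data.frame(class = c("A", "B", "C", "D"),
             p_u = c(0.163, 0.918, 0.982, 0.927),
             p_l = c(0.836, 0.082, 0.018, 0.073),
             stringsAsFactors = FALSE)
}
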
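make_separable <- function(n_per_class = 10, seed = 71) {
  set.seed(seed)
  n <- 2 * n_per_class
  beta <- matrix(c(runif(n_per_class, 0.05, 0.2),
                   runif(n_per_class, 0.8, 0.95)), 1, n,
                 dimnames = list("cg1", paste0("s", 1:n)))
  groups <- data.frame(sample_id = colnames(beta),
                       group = rep(c("A", "B"), each = n_per_class),
                       subgroup = NA_character_, stringsAsFactors = FALSE)
  list(beta = beta, groups = groups)
}

test_that("perfectly separated classes score 1.0 in every replicate", {
  d <- make_separable()
  res <- repeated_holdout_classify(
    d$beta, d$groups, rf_config(n_replicates = 10, n_trees = 50, seed = 72))
  expect_true(all(res$replicate_precision == 1))
  expect_true(all(res$replicate_recall == 1))
  # at 10 replicates a sample may never be drawn into a test fold
  tp <- suppressWarnings(per_sample_tp_rate(res))
  expect_true(all(tp$tp_rate[tp$times_in_test > 0] == 1))
})

test_that("stored scores are consistent with stored confusion matrices", {
  co <- tiny_cohort(seed = 73)
  g <- risk_groups_of(co)
  res <- repeated_holdout_classify(
    co$beta, g, rf_config(n_replicates = 8, n_trees = 100, seed = 74))
  for (r in seq_len(8)) {
    cm <- res$confusion[, , r]
    # confusion rows sum to the replicate's per-class test counts
    expect_true(all(rowSums(cm) > 0))
    recall <- diag(cm) / rowSums(cm)
    expect_equal(unname(recall), unname(res$replicate_recall[r, ]))
  }
  expect_equal(colMeans(res$replicate_recall), res$scores$recall_mean,
               ignore_attr = TRUE)
  # fixed seed reproduces the whole result
  res2 <- repeated_holdout_classify(
    co$beta, g, rf_config(n_replicates = 8, n_trees = 100, seed = 74))
  expect_identical(res$scores, res2$scores)
  expect_identical(res$per_sample, res2$per_sample)
})

test_that("single-sample classes are rejected", {
  d <- make_separable(n_per_class = 5)
  d$groups$group[1] <- "C"
  expect_error(repeated_holdout_classify(d$beta, d$groups, rf_config()),
               "stratif")
})

test_that("per-sample tallies give TP rates and modal classes with ties flagged", {
  fake <- structure(list(
    per_sample = data.frame(sample_id = c("s1", "s2", "s3"),
                            true_group = c("A", "B", "D"),
                            times_in_test = c(10L, 10L, 0L),
                            times_correct = c(7L, 10L, 0L),
                            A = c(10L, 0L, 0L), B = c(2L, 5L, 0L),
                            C = c(0L, 0L, 0L), D = c(0L, 5L, 0L),
                            stringsAsFactors = FALSE),
    classes = c("A", "B", "C", "D")), class = "rf_result")
  expect_warning(tp <- per_sample_tp_rate(fake), "never")
  expect_equal(tp$tp_rate, c(0.7, 1.0, NA))
  modal <- most_assigned_class(fake)
  expect_equal(modal$modal_class, c("A", "B", NA))
  # counts {B:5, D:5}: tie broken towards B in fixed class order, flagged
  expect_equal(modal$tie, c(FALSE, TRUE, FALSE))
})

test_that("relabeling partitions group D by modal class", {
  groups <- data.frame(sample_id = paste0("s", 1:5),
                       group = c("D", "D", "D", "B", "A"),
                       subgroup = NA_character_, stringsAsFactors = FALSE)
  modal <- data.frame(sample_id = paste0("s", 1:5),
                      modal_class = c("B", "D", "C", "B", "A"),
                      stringsAsFactors = FALSE)
  out <- relabel_subgroups(modal, groups)
  expect_equal(out$subgroup, c("D1", "D2", NA, NA, NA))
})

test_that("prefilter scoring uses training samples only", {
  co <- tiny_cohort(seed = 81)
  y <- factor(co$truth$samples$true_group)
  train <- colnames(co$beta)[1:60]
  sel <- methylRF:::apply_prefilter(co$beta, train, y[1:60], prefilter_chi2(10))
  # corrupting test-fold values must not change training-fold selection
  tampered <- co$beta
  test_cols <- setdiff(colnames(co$beta), train)
  tampered["cg0000001", test_cols] <- rep(c(0.01, 0.99),
                                          length.out = length(test_cols))
  sel2 <- methylRF:::apply_prefilter(tampered, train, y[1:60], prefilter_chi2(10))
  expect_identical(sel, sel2)
})

test_that("balanced class weights protect the minority class", {
  set.seed(91)
  n_maj <- 90; n_min <- 10
  beta <- matrix(runif(20 * (n_maj + n_min), 0.4, 0.6), 20,
                 dimnames = list(paste0("cg", 1:20), paste0("s", 1:(n_maj + n_min))))
  shift <- c(rep(0, n_maj), rep(0.25, n_min))
  beta[1:6, ] <- pmin(sweep(beta[1:6, ], 2, shift, "+"), 1)
  groups <- data.frame(sample_id = colnames(beta),
                       group = rep(c("A", "B"), c(n_maj, n_min)),
                       subgroup = NA_character_, stringsAsFactors = FALSE)
  res <- repeated_holdout_classify(
    beta, groups, rf_config(n_replicates = 30, n_trees = 200, seed = 92))
  rec <- setNames(res$scores$recall_mean, res$scores$class)
  expect_lt(abs(rec[["A"]] - rec[["B"]]), 0.15)
})

test_that("cross-source table compares sources and degenerates to 1x1", {
  co <- tiny_cohort(seed = 95, n_probes = 200,
                    n_per_group = c(A = 40, B = 60, C = 16, D = 40),
                    n_sources = 2)
  g <- risk_groups_of(co)
  src <- setNames(co$metadata$source, co$metadata$sample_id)
  tab <- cross_source_classify(co$beta, g, src,
                               rf_config(n_replicates = 10, n_trees = 100,
                                         seed = 96))
  expect_equal(dim(tab), c(2, 2))
  # identical planted signal in every round-robin source: off-diagonal
  # performance close to within-source hold-out
  expect_lt(abs(mean(tab[upper.tri(tab) | lower.tri(tab)]) - mean(diag(tab))),
            0.1)
  one <- cross_source_classify(co$beta, g,
                               setNames(rep("S1", ncol(co$beta)),
                                        colnames(co$beta)),
                               rf_config(n_replicates = 5, n_trees = 100,
                                         seed = 97))
  expect_equal(dim(one), c(1, 1))
})
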
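test_that("delta-beta contrasts group means and is antisymmetric", {
  beta <- matrix(c(0.9, 0.2, 0.2, 0.9), 2, 2,
                 dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  groups <- data.frame(sample_id = c("s1", "s2"), group = c("X", "Y"),
                       subgroup = NA_character_, stringsAsFactors = FALSE)
  d <- delta_beta(beta, groups, "X", "Y")
  expect_equal(d$delta, c(0.7, -0.7))
  expect_equal(d$abs_delta, c(0.7, 0.7))
  d_rev <- delta_beta(beta, groups, "Y", "X")
  expect_equal(d$delta, -d_rev$delta)
  # identical groups: all zero
  same <- delta_beta(beta, groups, "X", "X")
  expect_true(all(same$delta == 0))
  expect_error(delta_beta(beta, groups, "X", "Z"), "no samples")
  # subgroup labels resolve too
  groups$subgroup <- c("D1", "D2"); groups$group <- c("D", "D")
  expect_equal(delta_beta(beta, groups, "D1", "D2")$delta, c(0.7, -0.7))
})

test_that("delta filtering uses a strict threshold with range checks", {
  prof <- data.frame(probe_id = c("a", "b", "c"),
                     delta = c(0.31, -0.3, 0.05),
                     abs_delta = c(0.31, 0.3, 0.05), stringsAsFactors = FALSE)
  expect_equal(filter_probes(prof, 0.3), "a")
  expect_setequal(filter_probes(prof, 0), c("a", "b", "c"))
  expect_equal(length(filter_probes(prof, 1)), 0)
  expect_error(filter_probes(prof, 1.5), "\\[0, 1\\]")
})

test_that("BH adjustment equals the literal step-up oracle", {
  # worked arithmetic example: all adjusted values collapse to 0.04
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(161)
  for (i in 1:200) {
    p <- runif(sample(2:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p))
  }
})

test_that("log-rank screen detects a planted prognostic probe", {
  set.seed(171)
  n <- 200
  beta <- matrix(runif(20 * n), 20, n,
                 dimnames = list(paste0("cg", 1:20), paste0("s", 1:n)))
  risk <- beta[5, ] >= mean(beta[5, ])         # probe 5 drives hazard (HR 3)
  time <- rexp(n, rate = ifelse(risk, 0.003, 0.001))
  meta <- data.frame(sample_id = colnames(beta),
                     efs_time_days = time, efs_event = TRUE,
                     stringsAsFactors = FALSE)
  scr <- logrank_screen(beta, meta)
  expect_equal(scr$probe_id, rownames(beta))
  expect_lt(scr$fdr[5], 0.01)
  # BH is monotone: ordering by p never reverses the ordering by FDR
  ord <- order(scr$p)
  expect_true(all(diff(scr$fdr[ord]) >= -1e-12))
  # survival-package cross-check on the planted probe
  sd <- survival::survdiff(survival::Surv(time, rep(1, n)) ~ risk)
  expect_equal(scr$p[5], stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
})

test_that("joint filter intersects the two strict criteria", {
  prof <- data.frame(probe_id = c("a", "b", "c", "d"),
                     delta = c(0.4, 0.4, 0.1, 0.35),
                     abs_delta = c(0.4, 0.4, 0.1, 0.35),
                     stringsAsFactors = FALSE)
  scr <- data.frame(probe_id = c("a", "b", "c", "d"),
                    p = c(0.001, 0.5, 0.001, 0.002),
                    fdr = c(0.004, 0.6, 0.004, 0.008),
                    stringsAsFactors = FALSE)
  expect_setequal(joint_filter(prof, scr, 0.3, 0.01), c("a", "d"))
  expect_setequal(joint_filter(prof, scr, 0.3, 0.01),
                  intersect(filter_probes(prof, 0.3),
                            scr$probe_id[scr$fdr < 0.01]))
  expect_equal(length(joint_filter(prof, scr, 1, 0.01)), 0)
  expect_error(joint_filter(prof, scr[1:3, ], 0.3, 0.01), "different probes")
})

test_that("profile distance test measures RMS closeness to the reference", {
  co <- tiny_cohort(seed = 181, n_probes = 100)
  g <- truth_groups_of(co)
  g$subgroup[g$group == "B"] <- "B1"
  # a single probe: RMS distance reduces to |delta beta| on that probe
  pr <- rownames(co$beta)[1]
  out <- profile_distance_test(co$beta, g, "B1", "D1", "D2", pr,
                               n_permutations = 19, seed = 182)
  d1_direct <- abs(delta_beta(co$beta, g, "B1", "D1")$delta[1])
  expect_equal(out$d1, d1_direct)
  expect_gte(out$p, 1 / 20)
  # D1 shares B's signature: closer to B than D2 is, significantly
  sig <- co$truth$probes$probe_id[co$truth$probes$d1_shared]
  out2 <- profile_distance_test(co$beta, g, "B1", "D1", "D2", sig,
                                n_permutations = 199, seed = 183)
  expect_lt(out2$d1, out2$d2)
  expect_lte(out2$p, 0.01)
  expect_error(profile_distance_test(co$beta, g, "B1", "D1", "D2", pr,
                                     n_permutations = 0), "n_permutations")
})

test_that("Fisher composition test reproduces exact-test arithmetic", {
  # hypergeometric closed form for a perfectly diagonal table
  out <- fisher_composition(matrix(c(10, 0, 0, 10), 2))
  expect_equal(out$p, 2 / choose(20, 10), tolerance = 1e-9)
  # identical rows carry no association
  expect_equal(fisher_composition(matrix(c(5, 5, 5, 5), 2))$p, 1.0)
  # invariance to transposition
  tab <- matrix(c(16, 19, 9, 22), 2, byrow = TRUE)
  expect_equal(fisher_composition(tab)$p, fisher_composition(t(tab))$p)
  expect_error(fisher_composition(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
  expect_error(fisher_composition(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("Kaplan-Meier comparison orders hazards and handles edge groups", {
  set.seed(191)
  n <- 100
  meta <- data.frame(
    sample_id = paste0("s", 1:(2 * n)),
    efs_time_days = c(rexp(n, 0.01), rexp(n, 0.001)),
    efs_event = TRUE, stringsAsFactors = FALSE)
  grouping <- setNames(rep(c("hi", "lo"), each = n), meta$sample_id)
  km <- km_compare(meta, grouping)
  expect_lt(km$median_survival[["hi"]], km$median_survival[["lo"]])
  expect_lt(km$pairwise$p, 0.001)
  # identical survival data in both groups: no difference
  meta2 <- meta
  meta2$efs_time_days <- rep(meta$efs_time_days[1:n], 2)
  km2 <- km_compare(meta2, grouping)
  expect_gt(km2$pairwise$p, 0.9)
  # an all-censored group yields a flat curve at 1
  meta3 <- data.frame(sample_id = paste0("s", 1:20),
                      efs_time_days = rexp(20, 0.01),
                      efs_event = FALSE, stringsAsFactors = FALSE)
  km3 <- km_compare(meta3, setNames(rep("only", 20), meta3$sample_id))
  expect_true(all(km3$fit$surv == 1))
})
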
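test_that("side fractions count class samples above and below r", {
  b <- c(s1 = 0.2, s2 = 0.8, s3 = 0.9, s4 = 0.95)
  y <- c("A", "A", "B", "B")
  fr <- side_fractions(b, y, 0.5)
  expect_equal(fr$p_u[fr$class == "A"], 0.5)
  expect_equal(fr$p_l[fr$class == "A"], 0.5)
  expect_equal(fr$p_u[fr$class == "B"], 1.0)
  expect_equal(fr$p_l[fr$class == "B"], 0.0)
  # pairs always sum to one
  expect_equal(fr$p_u + fr$p_l, c(1, 1))
  expect_error(side_fractions(b, y, 1.5), "\\[0, 1\\]")
})

test_that("optimal split finds the perfect-separation midpoint", {
  b <- c(s1 = 0.1, s2 = 0.2, s3 = 0.8, s4 = 0.9)
  fs <- find_split(b, c("A", "A", "B", "B"))
  expect_equal(fs$r0, 0.5)
  expect_equal(fs$impurity, 0)
  expect_error(find_split(rep(0.5, 4), c("A", "A", "B", "B")), "unsplittable")
  expect_warning(find_split(b, rep("A", 4)), "one class")
})

test_that("vectorized split scan equals the brute-force Gini oracle", {
  set.seed(121)
  for (i in 1:60) {
    n <- sample(6:50, 1)
    b <- round(runif(n), sample(c(1, 2, 3), 1))  # induce ties in beta
    if (length(unique(b)) < 2) next
    names(b) <- paste0("s", seq_len(n))
    y <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    got <- find_split(b, y)
    want <- brute_force_split(b, y)
    expect_equal(got$r0, want$r0)
    expect_equal(got$impurity, want$impurity)
  }
})

test_that("CMS calls follow the isolation rule and are monotone in theta", {
  fr <- worked_example_fractions()
  # the printed worked-example fractions: class A is isolated low at 0.8
  call08 <- cms_call(fr, theta = 0.8)
  expect_equal(call08$call, "cms")
  expect_equal(call08$class, "A")
  expect_equal(call08$side, "l")
  expect_equal(cms_call(fr, theta = 0.9)$call, "none")
  expect_error(cms_call(fr, theta = 0.5), "theta")
  # perfect isolation is called at any theta
  perfect <- data.frame(class = c("A", "B", "C", "D"),
                        p_u = c(1, 0, 0, 0), p_l = c(0, 1, 1, 1))
  expect_equal(cms_call(perfect, theta = 1)$side, "u")
  # monotone: a call at theta persists at every smaller theta > 0.5
  set.seed(122)
  for (i in 1:50) {
    pu <- runif(4)
    tab <- data.frame(class = c("A", "B", "C", "D"), p_u = pu, p_l = 1 - pu)
    thetas <- sort(runif(5, 0.51, 1))
    calls <- lapply(thetas, function(th) cms_call(tab, th))
    for (j in seq_along(thetas)[-1]) {
      if (calls[[j]]$call == "cms") {
        expect_equal(calls[[j - 1]]$call, "cms")
        expect_equal(calls[[j - 1]]$class, calls[[j]]$class)
        expect_equal(calls[[j - 1]]$side, calls[[j]]$side)
      }
    }
  }
})

test_that("CMS direction is consistent with class mean separation", {
  co <- tiny_cohort(seed = 131, n_probes = 200, noise_concentration = 150)
  g <- risk_groups_of(co)
  splits <- suppressWarnings(find_split_all(co$beta, g))
  calls <- cms_call_all(splits, theta = 0.8)
  hit <- calls[calls$call == "cms", ]
  expect_gt(nrow(hit), 0)
  y <- g$group[match(colnames(co$beta), g$sample_id)]
  for (i in seq_len(nrow(hit))) {
    b <- co$beta[hit$probe_id[i], ]
    mk <- tapply(b, y, mean)
    k <- hit$class[i]
    if (hit$side[i] == "u") {
      expect_true(mk[[k]] > max(mk[names(mk) != k]))
    } else {
      expect_true(mk[[k]] < min(mk[names(mk) != k]))
    }
  }
})

test_that("importance aggregation ranks a planted separator first", {
  d <- local({
    set.seed(141)
    n <- 40
    beta <- matrix(runif(30 * n, 0.3, 0.7), 30,
                   dimnames = list(paste0("cg", sprintf("%02d", 1:30)),
                                   paste0("s", 1:n)))
    beta[7, ] <- c(runif(20, 0.05, 0.2), runif(20, 0.8, 0.95))
    beta[9, ] <- 0.5                     # constant probe
    groups <- data.frame(sample_id = colnames(beta),
                         group = rep(c("A", "B"), each = 20),
                         subgroup = NA_character_, stringsAsFactors = FALSE)
    list(beta = beta, groups = groups)
  })
  imp <- aggregate_importance(d$beta, d$groups,
                              rf_config(n_trees = 100, seed = 142), R = 20)
  expect_equal(imp$probe_id[imp$rank == 1], "cg07")
  expect_equal(imp$importance[imp$probe_id == "cg09"], 0)
  imp2 <- aggregate_importance(d$beta, d$groups,
                               rf_config(n_trees = 100, seed = 142), R = 20)
  expect_identical(imp, imp2)
  expect_error(aggregate_importance(d$beta, d$groups, rf_config(), R = 0), "R")
})

test_that("top-probe gene summaries count and clamp correctly", {
  ann <- mini_annotation()
  imp <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                    importance = c(3, 2, 1), rank = 1:3,
                    stringsAsFactors = FALSE)
  out <- top_probes_to_genes(imp, ann, N = 3)
  expect_equal(out$n_genes, 2)
  expect_equal(out$genes$gene[1], "G1")
  expect_equal(out$genes$n_probes[1], 2)
  expect_warning(out2 <- top_probes_to_genes(imp, ann, N = 10), "clamped")
  expect_equal(out2$n_genes, 2)
  top1 <- top_probes_to_genes(imp, ann, N = 1)
  expect_equal(top1$genes$gene, "G1")
})

test_that("rank profile bins CMS calls along the importance ranking", {
  imp <- data.frame(probe_id = paste0("cg", 1:10), importance = 10:1,
                    rank = 1:10, stringsAsFactors = FALSE)
  calls <- data.frame(probe_id = paste0("cg", 1:10),
                      call = c(rep("cms", 3), rep("none", 7)),
                      class = c("A", "A", "B", rep(NA, 7)),
                      side = c("u", "l", "u", rep(NA, 7)),
                      theta = 0.8, stringsAsFactors = FALSE)
  prof <- rank_cms_profile(imp, calls, n_bins = 1)
  expect_equal(prof$proportion[prof$class == "A"], 0.2)
  expect_equal(prof$n_u[prof$class == "A"], 1)
  expect_equal(prof$n_l[prof$class == "A"], 1)
  two <- rank_cms_profile(imp, calls, n_bins = 2)
  expect_equal(two$n_cms[two$bin == 2], c(0, 0))
  expect_error(rank_cms_profile(imp, calls, n_bins = 0), "n_bins")
  none <- calls; none$call <- "none"; none$class <- NA; none$side <- NA
  prof0 <- rank_cms_profile(imp, none, n_bins = 2)
  expect_true(all(prof0$n_cms == 0))
})

test_that("locus view reports ordered probes around a gene anchor", {
  co <- tiny_cohort(seed = 151, n_probes = 90)
  g <- risk_groups_of(co)
  gene <- co$manifest$gene_symbols[[1]][1]
  lv <- locus_view(co$manifest, co$beta, g, gene)
  expect_true(all(diff(lv$position) >= 0))
  expect_true(all(c("A", "B", "C", "D") %in% names(lv)))
  # window 0 keeps only probes at the anchor position
  lv0 <- locus_view(co$manifest, co$beta, g, gene, window_bp = 0)
  expect_true(all(lv0$position == lv0$position[1]))
  expect_error(locus_view(co$manifest, co$beta, g, "NOSUCHGENE"), "not found")
})
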
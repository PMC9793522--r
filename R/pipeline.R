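#' Pipeline configuration
#'
#' Bundles the stage parameters for [run_pipeline()]. Either `sim` is a
#' [sim_config()] (synthetic mode) or all three input `paths` must point to
#' existing files. The global `seed` is expanded to per-stage seeds by fixed
#' offsets so any stage can be rerun in isolation and reproduce its output.
#'
#' @param sim [sim_config()] for synthetic mode, or `NULL` to read inputs.
#' @param beta_path,manifest_path,metadata_path input files (non-simulate
#'   mode).
#' @param rf [rf_config()] for the classification stage.
#' @param feature_rf [rf_config()] for the (cheaper) feature-group stage.
#' @param feature_n_draws random-baseline draws per probe-group size.
#' @param run_features logical; the feature-group stage is the most
#'   expensive and can be skipped.
#' @param theta CMS isolation threshold.
#' @param importance_R forests averaged for importance.
#' @param top_n top-importance probes summarized at gene level.
#' @param delta_threshold,fdr_threshold joint probe-filter thresholds.
#' @param n_permutations permutations for the profile-distance test.
#' @param seed global integer seed.
#' @param out_dir output directory for the report bundle.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            beta_path = NULL, manifest_path = NULL,
                            metadata_path = NULL,
                            rf = rf_config(),
                            feature_rf = rf_config(n_replicates = 5,
                                                   n_trees = 200),
                            feature_n_draws = 5,
                            run_features = TRUE,
                            theta = 0.8,
                            importance_R = 50,
                            top_n = 500,
                            delta_threshold = 0.3,
                            fdr_threshold = 0.01,
                            n_permutations = 999,
                            seed = 1,
                            out_dir = "results/pipeline") {
  if (is.null(sim)) {
    for (p in c(beta_path, manifest_path, metadata_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input file not found: ", if (is.null(p)) "(unset path)" else p)
      }
    }
  }
  structure(list(sim = sim, beta_path = beta_path,
                 manifest_path = manifest_path, metadata_path = metadata_path,
                 rf = rf, feature_rf = feature_rf,
                 feature_n_draws = feature_n_draws,
                 run_features = run_features, theta = theta,
                 importance_R = importance_R, top_n = top_n,
                 delta_threshold = delta_threshold,
                 fdr_threshold = fdr_threshold,
                 n_permutations = n_permutations, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full comparative-methylome analysis
#'
#' Sequences the stages on one cohort: data (simulate or read), risk-group
#' assignment, repeated hold-out classification with D1/D2 relabeling and
#' B1/B2 age split, feature-group scoring with the variance correlation,
#' split statistics / CMS calls / importance aggregation, and the
#' delta-beta + log-rank survival screen with the distance permutation test
#' and composition Fisher tests. Writes per-stage CSVs and a JSON summary
#' under `config$out_dir`; identical seeds give identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly (also written as `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = config$seed)

  cohort <- stage("data", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed + 100
      generate_cohort(sim)
    } else {
      list(beta = read_beta_matrix(config$beta_path),
           manifest = read_manifest(config$manifest_path),
           metadata = read_metadata(config$metadata_path),
           truth = NULL)
    }
  })
  beta <- impute_beta(cohort$beta)
  groups <- assign_risk_group(cohort$metadata)
  groups <- assign_age_subgroup(groups, cohort$metadata)
  summary$n_samples <- ncol(beta)
  summary$n_probes <- nrow(beta)
  summary$group_sizes <- as.list(table(groups$group))

  cls <- stage("classify", {
    rf <- config$rf
    rf$seed <- config$seed + 200
    res <- repeated_holdout_classify(beta, groups, rf)
    modal <- most_assigned_class(res)
    relabeled <- relabel_subgroups(modal, groups)
    utils::write.csv(res$scores, file.path(config$out_dir, "scores.csv"),
                     row.names = FALSE)
    ps <- merge(per_sample_tp_rate(res), modal, by = "sample_id")
    ps$subgroup <- relabeled$subgroup[match(ps$sample_id,
                                            relabeled$sample_id)]
    utils::write.csv(ps, file.path(config$out_dir, "per_sample.csv"),
                     row.names = FALSE)
    list(res = res, groups = relabeled)
  })
  groups <- cls$groups
  cls <- cls$res
  summary$f1 <- as.list(stats::setNames(cls$scores$f1_mean, cls$scores$class))
  summary$n_D1 <- sum(groups$subgroup == "D1", na.rm = TRUE)
  summary$n_D2 <- sum(groups$subgroup == "D2", na.rm = TRUE)

  if (config$run_features) {
    feats <- stage("features", {
      pg <- define_probe_groups(cohort$manifest)
      set.seed(config$seed + 300)
      sc <- feature_group_scores(beta, groups, pg, config$feature_rf,
                                 target_classes = c("A", "B"),
                                 n_draws = config$feature_n_draws)
      utils::write.csv(sc, file.path(config$out_dir, "features.csv"),
                       row.names = FALSE)
      sc
    })
    corr <- stage("features", {
      sa <- feats[feats$target_class == "A", ]
      variance_ratio_correlation(sa$beta_variance, sa$obs_sim_ratio,
                                 n_permutations = 9999,
                                 seed = config$seed + 301)
    })
    summary$variance_ratio_r_A <- corr$r
    summary$variance_ratio_p_A <- corr$p
  }

  cms <- stage("cms", {
    splits <- suppressWarnings(find_split_all(beta, groups))
    calls <- cms_call_all(splits, config$theta)
    rf <- config$rf
    rf$seed <- config$seed + 400
    if (is.null(rf$prefilter)) rf$prefilter <- prefilter_chi2(10)
    imp <- aggregate_importance(beta, groups, rf, R = config$importance_R)
    top <- top_probes_to_genes(imp, cohort$manifest, N = config$top_n)
    utils::write.csv(splits, file.path(config$out_dir, "splits.csv"),
                     row.names = FALSE)
    utils::write.csv(calls, file.path(config$out_dir, "calls.csv"),
                     row.names = FALSE)
    utils::write.csv(imp, file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
    list(splits = splits, calls = calls, importance = imp, top = top)
  })
  summary$n_cms_calls <- sum(cms$calls$call == "cms")
  summary$n_top_genes <- cms$top$n_genes

  surv <- stage("survival", {
    prof <- delta_beta(beta, groups, "D1", "D2")
    screen <- logrank_screen(beta, cohort$metadata)
    joint <- joint_filter(prof, screen, config$delta_threshold,
                          config$fdr_threshold)
    utils::write.csv(prof, file.path(config$out_dir, "deltabeta.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(config$out_dir, "lrfdr.csv"),
                     row.names = FALSE)
    writeLines(joint, file.path(config$out_dir, "joint_probes.txt"))
    sel <- filter_probes(prof, config$delta_threshold)
    dist <- if (length(sel) > 0 && any(groups$subgroup == "B1", na.rm = TRUE)) {
      profile_distance_test(beta, groups, "B1", "D1", "D2", sel,
                            n_permutations = config$n_permutations,
                            seed = config$seed + 500)
    } else NULL
    grouping <- stats::setNames(
      ifelse(!is.na(groups$subgroup) & groups$subgroup %in% c("D1", "D2"),
             groups$subgroup,
             ifelse(groups$group == "B", "B", NA_character_)),
      groups$sample_id)
    km <- km_compare(cohort$metadata, grouping[!is.na(grouping)])
    utils::write.csv(km$pairwise, file.path(config$out_dir, "km_pvalues.csv"),
                     row.names = FALSE)
    list(profile = prof, screen = screen, joint = joint, dist = dist, km = km)
  })
  summary$n_delta_probes <- length(filter_probes(surv$profile,
                                                 config$delta_threshold))
  summary$n_joint_probes <- length(surv$joint)
  if (!is.null(surv$dist)) {
    summary$distance_B1_D1 <- surv$dist$d1
    summary$distance_B1_D2 <- surv$dist$d2
    summary$distance_p <- surv$dist$p
  }
  summary$km_p_D1_vs_D2 <-
    surv$km$pairwise$p[surv$km$pairwise$group1 == "D1" &
                         surv$km$pairwise$group2 == "D2"]

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
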
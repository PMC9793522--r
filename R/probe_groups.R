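#' Annotation-defined probe groups
#'
#' Builds the named probe groups used for feature-group power analysis, from
#' the manifest annotation:
#' Promoter (any of TSS1500/TSS200/1stExon), TSS (TSS1500/TSS200),
#' CGI ("Island"), the composites CGI_promoter and CGI_TSS200,
#' pha5enha (Phantom5 enhancers), 450Kenha (450K enhancer flag),
#' DMR/RDMR/CDMR (tokens of the DMR column), DNase, TFBS, OpenChr and SNP.
#' Groups may overlap; empty groups are kept (with a warning) so callers can
#' exclude them from scoring.
#'
#' @param ann annotation data frame from [read_manifest()].
#' @return named list of probe-id character vectors.
#' @export
define_probe_groups <- function(ann) {
  has_token <- function(tokens) {
    vapply(ann$refgene_group, function(g) any(g %in% tokens), logical(1))
  }
  promoter <- has_token(c("TSS1500", "TSS200", "1stExon"))
  tss <- has_token(c("TSS1500", "TSS200"))
  tss200 <- has_token("TSS200")
  cgi <- ann$cgi_relation == "Island"
  groups <- list(
    Promoter = promoter,
    TSS = tss,
    CGI = cgi,
    CGI_promoter = cgi & promoter,
    CGI_TSS200 = cgi & tss200,
    pha5enha = ann$phantom5_enhancer,
    `450Kenha` = ann$enhancer_450k,
    DMR = ann$dmr_class == "DMR",
    RDMR = ann$dmr_class == "RDMR",
    CDMR = ann$dmr_class == "CDMR",
    DNase = ann$dnase,
    TFBS = ann$tfbs,
    OpenChr = ann$open_chromatin,
    SNP = ann$snp_flag)
  out <- lapply(groups, function(m) ann$probe_id[m])
  empty <- names(out)[lengths(out) == 0]
  if (length(empty) > 0) {
    warning("empty probe group(s): ", paste(empty, collapse = ", "))
  }
  out
}

#' Mean f1 of one class using only a probe subset
#'
#' Repeated hold-out random forest restricted to `probe_set`; returns the
#' mean f1 for `target_class` over replicates.
#'
#' @param beta probes x samples matrix.
#' @param groups risk-group data frame.
#' @param probe_set character vector of probe ids.
#' @param config an [rf_config()].
#' @param target_class class whose f1 is reported (e.g. "A").
#' @return scalar mean f1.
#' @export
evaluate_feature_group <- function(beta, groups, probe_set, config, target_class) {
  probe_set <- intersect(probe_set, rownames(beta))
  if (length(probe_set) == 0) {
    stop("probe_set has no probes in the beta matrix")
  }
  res <- repeated_holdout_classify(beta[probe_set, , drop = FALSE], groups, config)
  res$scores$f1_mean[res$scores$class == target_class]
}

#' Random-subsample f1 baseline ("sim" curve)
#'
#' Mean target-class f1 over `n_draws` uniformly sampled probe subsets of
#' size `n_probes` (sampling without replacement within a draw).
#'
#' @inheritParams evaluate_feature_group
#' @param n_probes subset size.
#' @param n_draws number of random subsets (>= 1).
#' @param seed optional seed for the draws.
#' @return scalar mean f1 across draws.
#' @export
random_subsample_baseline <- function(beta, groups, n_probes, n_draws = 20,
                                      config = rf_config(), target_class = "A",
                                      seed = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (n_probes > nrow(beta)) stop("n_probes exceeds the probe universe")
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    subset <- sample(rownames(beta), n_probes)
    cfg <- config
    cfg$seed <- NULL                             # keep one RNG stream
    evaluate_feature_group(beta, groups, subset, cfg, target_class)
  }, numeric(1))
  mean(draws)
}

#' Select-percentile f1 baseline (ANOVA-F ranking)
#'
#' Target-class f1 when, inside every training fold, the `n_probes` probes
#' with the largest one-way ANOVA F statistic are selected (ranking is
#' fitted on training folds only, so the baseline does not leak test data).
#'
#' @inheritParams random_subsample_baseline
#' @return scalar mean f1.
#' @export
select_percentile_baseline <- function(beta, groups, n_probes,
                                       config = rf_config(), target_class = "A") {
  if (n_probes > nrow(beta)) stop("n_probes exceeds the probe universe")
  cfg <- config
  cfg$prefilter <- prefilter_anova(100 * n_probes / nrow(beta))
  res <- repeated_holdout_classify(beta, groups, cfg)
  res$scores$f1_mean[res$scores$class == target_class]
}

#' Score annotation probe groups against size-matched random baselines
#'
#' For each probe group: the observed target-class f1, the mean f1 of
#' size-matched random probe subsets, their ratio (obs/sim), and the mean
#' per-probe beta variance within the group. Empty groups are skipped.
#'
#' @inheritParams evaluate_feature_group
#' @param probe_groups named list from [define_probe_groups()].
#' @param target_classes classes to score (default A and B).
#' @param n_draws random subsets per group size.
#' @param seed optional seed.
#' @return data frame, one row per (group, target class): `group`,
#'   `target_class`, `n_probes`, `f1_obs`, `f1_rand`, `obs_sim_ratio`,
#'   `beta_variance`.
#' @export
feature_group_scores <- function(beta, groups, probe_groups,
                                 config = rf_config(),
                                 target_classes = c("A", "B"),
                                 n_draws = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probe_groups <- Filter(function(p) length(intersect(p, rownames(beta))) > 0,
                         probe_groups)
  rows <- list()
  for (gname in names(probe_groups)) {
    members <- intersect(probe_groups[[gname]], rownames(beta))
    v <- mean(apply(beta[members, , drop = FALSE], 1, stats::var))
    for (tc in target_classes) {
      cfg <- config; cfg$seed <- NULL
      f1_obs <- evaluate_feature_group(beta, groups, members, cfg, tc)
      f1_rand <- random_subsample_baseline(beta, groups, length(members),
                                           n_draws, cfg, tc)
      rows[[length(rows) + 1]] <- data.frame(
        group = gname, target_class = tc, n_probes = length(members),
        f1_obs = f1_obs, f1_rand = f1_rand,
        obs_sim_ratio = if (f1_rand > 0) f1_obs / f1_rand else NA_real_,
        beta_variance = v, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Correlation between probe-group variance and obs/sim f1 ratio
#'
#' Pearson correlation between the mean beta variance of each probe group
#' and its obs/sim f1 ratio, with a permutation p-value: the ratio vector is
#' shuffled `n_permutations` times and p = (b + 1) / (B + 1) where b counts
#' permutations with |r_perm| >= |r_obs| (so p is never exactly 0).
#'
#' @param beta_variance,obs_sim_ratio numeric vectors over probe groups.
#' @param n_permutations number of shuffles (default 9999).
#' @param seed optional seed.
#' @return list with `r`, `p`, `n_permutations`.
#' @export
variance_ratio_correlation <- function(beta_variance, obs_sim_ratio,
                                       n_permutations = 9999, seed = NULL) {
  ok <- is.finite(beta_variance) & is.finite(obs_sim_ratio)
  x <- beta_variance[ok]; y <- obs_sim_ratio[ok]
  if (length(x) < 3) stop("need at least 3 groups with finite scores")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in an input vector")
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(x, y)
  b <- sum(vapply(seq_len(n_permutations), function(i) {
    abs(stats::cor(x, sample(y))) >= abs(r_obs)
  }, logical(1)))
  list(r = r_obs, p = (b + 1) / (n_permutations + 1),
       n_permutations = n_permutations)
}
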
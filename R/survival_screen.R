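#' Per-probe delta-beta between two sample groups
#'
#' Signed difference of group mean beta-values (first minus second), per
#' probe, ignoring missing values. Labels may be parent groups (A/B/C/D) or
#' subgroups (D1/D2/B1/B2).
#'
#' @param beta probes x samples matrix.
#' @param groups risk-group data frame (with `subgroup` filled where used).
#' @param g1,g2 group or subgroup labels to contrast.
#' @return data frame `probe_id`, `delta` (mean g1 - mean g2), `abs_delta`.
#' @export
delta_beta <- function(beta, groups, g1, g2) {
  s1 <- group_members(groups, g1)
  s2 <- group_members(groups, g2)
  s1 <- intersect(s1, colnames(beta))
  s2 <- intersect(s2, colnames(beta))
  if (length(s1) == 0) stop("no samples in group: ", g1)
  if (length(s2) == 0) stop("no samples in group: ", g2)
  d <- rowMeans(beta[, s1, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, s2, drop = FALSE], na.rm = TRUE)
  data.frame(probe_id = rownames(beta), delta = as.numeric(d),
             abs_delta = abs(as.numeric(d)), row.names = NULL,
             stringsAsFactors = FALSE)
}

group_members <- function(groups, label) {
  groups$sample_id[(!is.na(groups$group) & groups$group == label) |
                     (!is.na(groups$subgroup) & groups$subgroup == label)]
}

#' Filter probes by absolute delta-beta
#'
#' @param profile data frame from [delta_beta()].
#' @param delta_threshold threshold in \[0, 1\]; strict `>`.
#' @return character vector of probe ids with `|delta| >` threshold.
#' @export
filter_probes <- function(profile, delta_threshold = 0.3) {
  if (delta_threshold < 0 || delta_threshold > 1) {
    stop("delta_threshold must lie in [0, 1]")
  }
  profile$probe_id[profile$abs_delta > delta_threshold]
}

#' Per-probe log-rank survival screen with BH correction
#'
#' For each probe, samples are split at the probe's mean beta-value
#' (>= mean vs < mean) and the two groups are compared by the log-rank test
#' on event-free survival; p-values are Benjamini-Hochberg adjusted across
#' all screened probes (LRFDR). Probes whose split leaves one side empty get
#' a missing p-value and are excluded from the adjustment.
#'
#' @param beta probes x samples matrix.
#' @param metadata data frame with `sample_id`, `efs_time_days`,
#'   `efs_event`; samples with missing survival are dropped.
#' @return data frame `probe_id`, `p`, `fdr`.
#' @export
logrank_screen <- function(beta, metadata) {
  m <- metadata[match(colnames(beta), metadata$sample_id), ]
  keep <- !is.na(m$efs_time_days) & !is.na(m$efs_event)
  if (sum(keep) < 2) stop("need at least two samples with survival data")
  beta <- beta[, keep, drop = FALSE]
  time <- m$efs_time_days[keep]
  event <- as.integer(m$efs_event[keep])
  p <- rep(NA_real_, nrow(beta))
  n_degenerate <- 0L
  for (i in seq_len(nrow(beta))) {
    b <- beta[i, ]
    high <- b >= mean(b, na.rm = TRUE)
    if (all(high, na.rm = TRUE) || !any(high, na.rm = TRUE)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    sd <- survival::survdiff(survival::Surv(time, event) ~ high)
    p[i] <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  if (n_degenerate > 0) {
    warning(n_degenerate, " probe(s) left one split side empty; p is NA")
  }
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(probe_id = rownames(beta), p = p, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Joint delta-beta / LRFDR probe filter
#'
#' Intersection of the probes with `|delta-beta|` strictly above
#' `delta_threshold` and LRFDR strictly below `fdr_threshold`.
#'
#' @param profile data frame from [delta_beta()].
#' @param screen data frame from [logrank_screen()].
#' @param delta_threshold,fdr_threshold strict thresholds.
#' @return character vector of probe ids.
#' @export
joint_filter <- function(profile, screen, delta_threshold = 0.3,
                         fdr_threshold = 0.01) {
  if (!setequal(profile$probe_id, screen$probe_id)) {
    stop("delta-beta profile and survival screen cover different probes")
  }
  by_delta <- filter_probes(profile, delta_threshold)
  by_fdr <- screen$probe_id[!is.na(screen$fdr) & screen$fdr < fdr_threshold]
  intersect(by_delta, by_fdr)
}

#' Permutation test of methylation-profile distance to a reference group
#'
#' Measures which of two subgroups is closer to a reference group over a
#' probe set, using the root-mean-square of per-probe mean differences
#' (RMS keeps the distance on the beta scale regardless of probe count).
#' The statistic is d(ref, sub2) - d(ref, sub1); the null shuffles the
#' sub1/sub2 membership labels (reference fixed) and
#' p = (b + 1) / (B + 1) counts permuted statistics >= the observed one, so
#' p is never exactly zero. The Monte-Carlo standard error of p is reported.
#'
#' @param beta probes x samples matrix.
#' @param groups risk-group data frame.
#' @param ref_group reference label (e.g. "B1").
#' @param sub1,sub2 subgroup labels to compare (e.g. "D1", "D2").
#' @param probe_set probe ids over which distances are computed.
#' @param n_permutations number of label shuffles (>= 1).
#' @param seed optional seed.
#' @return list `d1`, `d2`, `statistic`, `p`, `p_se`, `n_permutations`.
#' @export
profile_distance_test <- function(beta, groups, ref_group, sub1, sub2,
                                  probe_set, n_permutations = 999,
                                  seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  probe_set <- intersect(probe_set, rownames(beta))
  if (length(probe_set) == 0) stop("probe_set is empty")
  ref <- intersect(group_members(groups, ref_group), colnames(beta))
  s1 <- intersect(group_members(groups, sub1), colnames(beta))
  s2 <- intersect(group_members(groups, sub2), colnames(beta))
  if (length(ref) == 0 || length(s1) == 0 || length(s2) == 0) {
    stop("reference and both subgroups must be non-empty")
  }
  sub <- beta[probe_set, , drop = FALSE]
  ref_mean <- rowMeans(sub[, ref, drop = FALSE])
  rms <- function(cols) sqrt(mean((ref_mean - rowMeans(sub[, cols, drop = FALSE]))^2))
  d1 <- rms(s1)
  d2 <- rms(s2)
  stat_obs <- d2 - d1
  if (!is.null(seed)) set.seed(seed)
  pool <- c(s1, s2)
  n1 <- length(s1)
  b <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- sample(pool)
    if (rms(perm[-seq_len(n1)]) - rms(perm[seq_len(n1)]) >= stat_obs) b <- b + 1L
  }
  p <- (b + 1) / (n_permutations + 1)
  list(d1 = d1, d2 = d2, statistic = stat_obs, p = p,
       p_se = sqrt(p * (1 - p) / n_permutations),
       n_permutations = n_permutations)
}

#' Fisher's exact test on a 2x2 subgroup-composition table
#'
#' Two-sided exact test (hypergeometric-probability summation, the
#' [stats::fisher.test] convention) with the conditional odds-ratio
#' estimate.
#'
#' @param counts 2x2 matrix of non-negative integer counts; all row and
#'   column margins must be positive.
#' @return list `odds_ratio`, `p`.
#' @export
fisher_composition <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be a 2x2 matrix of non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all table margins must be positive")
  }
  ft <- stats::fisher.test(counts)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Kaplan-Meier comparison of sample groupings
#'
#' Kaplan-Meier event-free-survival estimates per group (event = death of
#' disease, progression or relapse) and pairwise log-rank p-values.
#'
#' @param metadata data frame with `sample_id`, `efs_time_days`, `efs_event`.
#' @param grouping named character vector: group label per sample id.
#' @return list `fit` ([survival::survfit] object), `median_survival`
#'   (named vector, days), `pairwise` (data frame `group1`, `group2`, `p`).
#' @export
km_compare <- function(metadata, grouping) {
  m <- metadata[match(names(grouping), metadata$sample_id), ]
  keep <- !is.na(m$efs_time_days) & !is.na(m$efs_event) & !is.na(grouping)
  time <- m$efs_time_days[keep]
  event <- as.integer(m$efs_event[keep])
  g <- factor(grouping[keep])
  if (nlevels(g) < 1 || any(table(g) == 0)) stop("empty grouping")
  for (k in levels(g)) {
    if (all(is.na(time[g == k]))) stop("group with no survival data: ", k)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  med <- summary(fit)$table
  med_surv <- if (is.matrix(med)) {
    stats::setNames(med[, "median"], sub("^g=", "", rownames(med)))
  } else {
    stats::setNames(med["median"], levels(g))
  }
  if (nlevels(g) < 2) {
    return(list(fit = fit, median_survival = med_surv,
                pairwise = data.frame(group1 = character(0),
                                      group2 = character(0),
                                      p = numeric(0))))
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- g %in% pr
    sd <- survival::survdiff(survival::Surv(time[sel], event[sel]) ~
                               droplevels(g[sel]))
    data.frame(group1 = pr[1], group2 = pr[2],
               p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  list(fit = fit, median_survival = med_surv, pairwise = pairwise)
}
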
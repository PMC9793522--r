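#' Random-forest run configuration
#'
#' Desk-scale defaults (100 replicates, 500 trees) keep repeated hold-out
#' runs fast; the reference setting used for the headline cohort analysis is
#' 1000 replicates, 10,000 trees, max depth 4, with a chi2-style
#' select-percentile prefilter keeping the top 10% of probes — reachable via
#' `rf_config(n_replicates = 1000, n_trees = 10000, prefilter = prefilter_chi2(10))`.
#'
#' @param train_fraction fraction of samples in each training split.
#' @param n_replicates number of hold-out replicates.
#' @param n_trees trees per forest.
#' @param max_depth maximum tree depth (0 = unlimited).
#' @param prefilter `NULL`/"none", or a list from [prefilter_chi2()] /
#'   [prefilter_anova()]; fitted on training folds only.
#' @param seed integer seed making splits, probe selection and forests
#'   reproducible; `NULL` uses the current RNG state.
#' @return an `rf_config` list.
#' @export
rf_config <- function(train_fraction = 0.7, n_replicates = 100,
                      n_trees = 500, max_depth = 4,
                      prefilter = NULL, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.character(prefilter) && identical(prefilter, "none")) prefilter <- NULL
  structure(list(train_fraction = train_fraction, n_replicates = n_replicates,
                 n_trees = n_trees, max_depth = max_depth,
                 prefilter = prefilter, seed = seed),
            class = "rf_config")
}

#' Select-percentile probe prefilters
#'
#' `prefilter_chi2` scores probes by a chi-square-style statistic on the
#' non-negative beta-values (class-wise feature sums against expectation
#' under class-independence); `prefilter_anova` scores by the one-way
#' ANOVA F statistic across classes. Either keeps the top `percentile`% of
#' probes, always fitted on the training fold only.
#'
#' @param percentile percentage of probes to keep (0 < percentile <= 100).
#' @return a prefilter description list.
#' @export
prefilter_chi2 <- function(percentile = 10) {
  stopifnot(percentile > 0, percentile <= 100)
  list(method = "chi2", percentile = percentile)
}

#' @rdname prefilter_chi2
#' @export
prefilter_anova <- function(percentile = 10) {
  stopifnot(percentile > 0, percentile <= 100)
  list(method = "anova", percentile = percentile)
}

#' Per-probe class-association scores
#'
#' @param X samples x probes numeric matrix.
#' @param y factor of class labels.
#' @return numeric score per probe (higher = more class-associated).
#' @export
chi2_scores <- function(X, y) {
  if (any(X < 0)) stop("chi2 scoring requires non-negative features")
  y <- factor(y)
  ind <- stats::model.matrix(~ y - 1)            # samples x classes
  observed <- t(ind) %*% X                        # classes x probes
  class_prob <- colSums(ind) / nrow(X)
  expected <- outer(class_prob, colSums(X))
  colSums((observed - expected)^2 / expected)
}

#' @rdname chi2_scores
#' @export
anova_f_scores <- function(X, y) {
  y <- factor(y)
  n <- nrow(X)
  k <- nlevels(y)
  cnt <- as.vector(table(y))
  gm <- rowsum(X, y) / cnt                        # class means, classes x probes
  overall <- colMeans(X)
  ss_between <- colSums(cnt * (sweep(gm, 2, overall))^2)
  ss_total <- colSums(sweep(X, 2, overall)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (n - k)
  f <- ms_between / ms_within
  f[!is.finite(f)] <- 0
  f
}

apply_prefilter <- function(beta, train_ids, y_train, prefilter) {
  if (is.null(prefilter)) return(rownames(beta))
  X <- t(beta[, train_ids, drop = FALSE])
  sc <- switch(prefilter$method,
               chi2 = chi2_scores(X, y_train),
               anova = anova_f_scores(X, y_train),
               stop("unknown prefilter method: ", prefilter$method))
  keep <- max(1L, round(length(sc) * prefilter$percentile / 100))
  rownames(beta)[order(sc, decreasing = TRUE)[seq_len(keep)]]
}

stratified_split <- function(y, train_fraction) {
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- round(length(idx) * train_fraction)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # >=1 in each fold
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

replicate_scores <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = prec, recall = rec, f1 = f1)
}

#' Repeated hold-out random-forest classification
#'
#' For each replicate: a stratified train/test split, an optional
#' select-percentile probe prefilter fitted on the training fold only, a
#' balanced-class-weight random forest, and test-set predictions. Per-class
#' precision/recall/f1 are aggregated as mean and standard deviation over
#' replicates, and each sample's test-set appearances and predicted classes
#' are tallied for the per-sample TP-rate and most-assigned-class summaries.
#'
#' @param beta probes x samples beta matrix (no missing values; see
#'   [impute_beta()]).
#' @param groups risk-group data frame from [assign_risk_group()].
#' @param config an [rf_config()].
#' @return an `rf_result` list: `scores` (per-class mean +/- sd), `confusion`
#'   (classes x classes x replicates, rows = true class), `per_sample`
#'   (times in test, times correct, per-class prediction counts),
#'   `replicate_precision` / `replicate_recall` / `replicate_f1`
#'   (replicates x classes), `classes`, `config`.
#' @export
repeated_holdout_classify <- function(beta, groups, config = rf_config()) {
  validate_beta_matrix(beta)
  if (anyNA(beta)) beta <- impute_beta(beta)
  y <- factor(groups$group[match(colnames(beta), groups$sample_id)])
  if (anyNA(y)) stop("every sample in the beta matrix needs a group label")
  if (nlevels(y) < 2) stop("need at least two classes")
  if (any(table(y) < 2)) {
    stop("class with a single sample cannot be stratified: ",
         paste(names(which(table(y) < 2)), collapse = ", "))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  classes <- levels(y)
  K <- length(classes)
  R <- config$n_replicates
  conf <- array(0L, dim = c(K, K, R), dimnames = list(classes, classes, NULL))
  prec <- rec <- f1 <- matrix(NA_real_, R, K, dimnames = list(NULL, classes))
  n_samp <- ncol(beta)
  times_in_test <- times_correct <- integer(n_samp)
  pred_counts <- matrix(0L, n_samp, K,
                        dimnames = list(colnames(beta), classes))
  for (r in seq_len(R)) {
    tr <- stratified_split(y, config$train_fraction)
    te <- setdiff(seq_len(n_samp), tr)
    sel <- apply_prefilter(beta, colnames(beta)[tr], y[tr], config$prefilter)
    fit <- fit_forest(beta[sel, tr, drop = FALSE], y[tr], config)
    pred <- predict_forest(fit, beta[sel, te, drop = FALSE], classes)
    cm <- table(factor(y[te], levels = classes),
                factor(pred, levels = classes))
    conf[, , r] <- cm
    sc <- replicate_scores(cm)
    prec[r, ] <- sc$precision; rec[r, ] <- sc$recall; f1[r, ] <- sc$f1
    times_in_test[te] <- times_in_test[te] + 1L
    times_correct[te] <- times_correct[te] + as.integer(pred == y[te])
    pred_counts[cbind(te, match(pred, classes))] <-
      pred_counts[cbind(te, match(pred, classes))] + 1L
  }
  scores <- data.frame(
    class = classes,
    precision_mean = colMeans(prec), precision_sd = apply(prec, 2, stats::sd),
    recall_mean = colMeans(rec), recall_sd = apply(rec, 2, stats::sd),
    f1_mean = colMeans(f1), f1_sd = apply(f1, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  per_sample <- data.frame(sample_id = colnames(beta), true_group = as.character(y),
                           times_in_test = times_in_test,
                           times_correct = times_correct,
                           stringsAsFactors = FALSE)
  per_sample <- cbind(per_sample, as.data.frame(pred_counts))
  structure(list(scores = scores, confusion = conf, per_sample = per_sample,
                 replicate_precision = prec, replicate_recall = rec,
                 replicate_f1 = f1, classes = classes, config = config),
            class = "rf_result")
}

fit_forest <- function(beta_train, y_train, config) {
  freq <- table(y_train)
  cw <- as.numeric(sum(freq) / (length(freq) * freq))  # "balanced" weighting
  names(cw) <- names(freq)
  ranger::ranger(x = t(beta_train), y = y_train,
                 num.trees = config$n_trees, max.depth = config$max_depth,
                 class.weights = cw[levels(y_train)],
                 seed = sample.int(.Machine$integer.max, 1),
                 num.threads = 1)
}

predict_forest <- function(fit, beta_test, classes) {
  as.character(stats::predict(fit, data = t(beta_test),
                              num.threads = 1)$predictions)
}

#' Per-sample true-positive rate over replicates
#'
#' @param result an `rf_result`.
#' @return data frame `sample_id`, `times_in_test`, `tp_rate` (`NA` with a
#'   warning for samples never drawn into a test fold).
#' @export
per_sample_tp_rate <- function(result) {
  ps <- result$per_sample
  never <- ps$times_in_test == 0
  if (any(never)) {
    warning(sum(never), " sample(s) never appeared in a test fold; TP rate is NA")
  }
  data.frame(sample_id = ps$sample_id,
             times_in_test = ps$times_in_test,
             tp_rate = ifelse(never, NA_real_,
                              ps$times_correct / pmax(ps$times_in_test, 1L)),
             stringsAsFactors = FALSE)
}

#' Most-assigned (modal) predicted class per sample
#'
#' Arg-max of the per-sample predicted-class counts; ties are broken towards
#' the first class in A < B < C < D order and flagged.
#'
#' @param result an `rf_result`.
#' @return data frame `sample_id`, `true_group`, `modal_class`, `tie`.
#' @export
most_assigned_class <- function(result) {
  counts <- as.matrix(result$per_sample[, result$classes, drop = FALSE])
  best <- apply(counts, 1, which.max)             # first max = fixed class order
  tie <- apply(counts, 1, function(x) sum(x == max(x)) > 1) &
    rowSums(counts) > 0
  modal <- result$classes[best]
  modal[rowSums(counts) == 0] <- NA_character_
  data.frame(sample_id = result$per_sample$sample_id,
             true_group = result$per_sample$true_group,
             modal_class = modal, tie = tie, stringsAsFactors = FALSE)
}

#' Relabel group-D samples into D1/D2 subgroups
#'
#' D1 = group-D samples whose modal predicted class is B (methylation
#' resembles the high-risk stage-4 group); D2 = modally predicted as D;
#' samples modally predicted as A or C stay unassigned.
#'
#' @param modal data frame from [most_assigned_class()].
#' @param groups risk-group data frame.
#' @return `groups` with `subgroup` set to "D1"/"D2" for group-D samples.
#' @export
relabel_subgroups <- function(modal, groups) {
  m <- modal$modal_class[match(groups$sample_id, modal$sample_id)]
  in_d <- groups$group == "D"
  if (anyNA(m[in_d])) {
    warning(sum(is.na(m[in_d])),
            " group-D sample(s) have no modal class and stay unassigned")
  }
  groups$subgroup[in_d & !is.na(m) & m == "B"] <- "D1"
  groups$subgroup[in_d & !is.na(m) & m == "D"] <- "D2"
  groups
}

#' Cross-source classification score table
#'
#' Fits a forest on all samples of each source and evaluates on every other
#' source; the diagonal holds the within-source repeated hold-out score.
#' Sources whose samples span fewer than two classes are skipped with a
#' warning.
#'
#' @param beta probes x samples matrix.
#' @param groups risk-group data frame.
#' @param sources named character vector (or data frame column) of source
#'   labels per sample, aligned by sample_id.
#' @param config an [rf_config()].
#' @return matrix of macro-averaged f1 scores, train sources as rows.
#' @export
cross_source_classify <- function(beta, groups, sources, config = rf_config()) {
  validate_beta_matrix(beta)
  src <- sources[match(colnames(beta), names(sources))]
  if (anyNA(src)) stop("every sample needs a source label")
  y <- factor(groups$group[match(colnames(beta), groups$sample_id)])
  labs <- sort(unique(src))
  usable <- vapply(labs, function(s) {
    tab <- table(droplevels(y[src == s]))
    length(tab) >= 2 && all(tab >= 2)
  }, logical(1))
  if (any(!usable)) {
    warning("skipping source(s) with fewer than two usable classes: ",
            paste(labs[!usable], collapse = ", "))
    labs <- labs[usable]
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(train = labs, test = labs))
  classes <- levels(y)
  for (s_tr in labs) {
    tr <- which(src == s_tr)
    for (s_te in labs) {
      if (s_te == s_tr) {
        sub_cfg <- config
        sub_cfg$seed <- NULL                     # RNG stream already positioned
        res <- repeated_holdout_classify(
          beta[, tr, drop = FALSE],
          groups[groups$sample_id %in% colnames(beta)[tr], ], sub_cfg)
        out[s_tr, s_te] <- mean(res$scores$f1_mean, na.rm = TRUE)
      } else {
        te <- which(src == s_te)
        sel <- apply_prefilter(beta, colnames(beta)[tr], y[tr], config$prefilter)
        fit <- fit_forest(beta[sel, tr, drop = FALSE], droplevels(y[tr]), config)
        pred <- predict_forest(fit, beta[sel, te, drop = FALSE], classes)
        cm <- table(factor(y[te], levels = classes),
                    factor(pred, levels = classes))
        present <- classes %in% unique(as.character(y[te]))
        out[s_tr, s_te] <- mean(replicate_scores(cm)$f1[present])
      }
    }
  }
  out
}
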
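#' Per-class side fractions at a beta threshold
#'
#' For a threshold r on the beta scale, p_u(k) is the fraction of class-k
#' samples with beta strictly above r and p_l(k) = 1 - p_u(k) the fraction
#' below. These side fractions are the ingredients of the CMS call: a probe
#' isolates class k when k sits almost entirely on one side of r and every
#' other class on the opposite side.
#'
#' @param beta_probe named numeric vector of beta-values, one per sample.
#' @param groups risk-group data frame (or factor/character vector aligned
#'   with `beta_probe`).
#' @param r threshold in \[0, 1\].
#' @return data frame `class`, `p_u`, `p_l`.
#' @export
side_fractions <- function(beta_probe, groups, r) {
  if (r < 0 || r > 1) stop("threshold r must lie in [0, 1]")
  y <- group_labels(beta_probe, groups)
  if (any(table(y) < 1)) stop("each class needs at least one sample")
  up <- tapply(beta_probe > r, y, mean)
  data.frame(class = names(up), p_u = as.numeric(up),
             p_l = 1 - as.numeric(up), row.names = NULL,
             stringsAsFactors = FALSE)
}

group_labels <- function(beta_probe, groups) {
  if (is.data.frame(groups)) {
    y <- groups$group[match(names(beta_probe), groups$sample_id)]
    if (anyNA(y)) stop("every sample needs a group label")
    factor(y)
  } else {
    factor(groups)
  }
}

#' Optimal Gini split of a single probe
#'
#' Scans every candidate threshold (the midpoints between consecutive sorted
#' distinct beta-values) and returns the one minimizing the weighted
#' two-partition Gini impurity
#' \deqn{(n_u/n)(1 - \sum_k q_{k,u}^2) + (n_l/n)(1 - \sum_k q_{k,l}^2)}
#' where \eqn{q_{k,\cdot}} are the class proportions within each partition.
#' Ties in impurity are broken towards the smaller threshold. "Upper" means
#' strictly above the threshold; with midpoint candidates no observation can
#' tie with a threshold.
#'
#' @inheritParams side_fractions
#' @return list with `r0`, `impurity`, and `fractions` (the
#'   [side_fractions()] table at `r0`).
#' @export
find_split <- function(beta_probe, groups) {
  y <- group_labels(beta_probe, groups)
  vals <- sort(unique(beta_probe))
  if (length(vals) < 2) stop("unsplittable: probe has a single distinct value")
  if (nlevels(droplevels(y)) < 2) {
    warning("all samples in one class; every split has zero impurity")
  }
  candidates <- (vals[-1] + vals[-length(vals)]) / 2
  n <- length(beta_probe)
  ord <- order(beta_probe)
  y_ord <- y[ord]
  ## cumulative class counts below each distinct-value boundary
  cls_ind <- outer(y_ord, levels(y), "==") * 1L
  cum <- apply(cls_ind, 2, cumsum)
  boundary <- cumsum(as.vector(table(factor(beta_probe[ord], levels = vals))))
  boundary <- boundary[-length(boundary)]        # one boundary per candidate
  low <- cum[boundary, , drop = FALSE]           # counts below each candidate
  tot <- matrix(colSums(cls_ind), nrow(low), ncol(low), byrow = TRUE)
  upp <- tot - low
  n_l <- rowSums(low); n_u <- n - n_l
  gini_l <- 1 - rowSums((low / n_l)^2)
  gini_u <- 1 - rowSums((upp / n_u)^2)
  impurity <- (n_l / n) * gini_l + (n_u / n) * gini_u
  # ties (within float tolerance) break towards the smaller threshold
  best <- which(impurity <= min(impurity) + 1e-12)[1]
  r0 <- candidates[best]
  list(r0 = r0, impurity = impurity[best],
       fractions = side_fractions(beta_probe, groups, r0))
}

#' Split statistics for every probe in a matrix
#'
#' Applies [find_split()] probe-wise; constant probes get an `NA` row and a
#' warning.
#'
#' @param beta probes x samples matrix.
#' @param groups risk-group data frame.
#' @return data frame `probe_id`, `r0`, `impurity`, and one `p_<k>_u` /
#'   `p_<k>_l` column pair per class.
#' @export
find_split_all <- function(beta, groups) {
  y <- factor(groups$group[match(colnames(beta), groups$sample_id)])
  classes <- levels(y)
  rows <- vector("list", nrow(beta))
  n_const <- 0L
  for (i in seq_len(nrow(beta))) {
    b <- beta[i, ]
    names(b) <- colnames(beta)
    if (length(unique(b)) < 2) {
      n_const <- n_const + 1L
      frac <- rep(NA_real_, 2 * length(classes))
      rows[[i]] <- c(NA_real_, NA_real_, frac)
      next
    }
    fs <- find_split(b, y)
    fr <- fs$fractions[match(classes, fs$fractions$class), ]
    rows[[i]] <- c(fs$r0, fs$impurity, rbind(fr$p_u, fr$p_l))
  }
  if (n_const > 0) warning(n_const, " constant probe(s) are unsplittable (NA)")
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("r0", "impurity",
                  as.vector(rbind(paste0("p_", classes, "_u"),
                                  paste0("p_", classes, "_l"))))
  cbind(data.frame(probe_id = rownames(beta), stringsAsFactors = FALSE), out)
}

#' Classifying-methylation-site (CMS) call at threshold theta
#'
#' A probe is called CMS for class k on side u when at the optimal split at
#' least a fraction theta of class-k samples lie above r0 while at least
#' theta of every other class lies below (and symmetrically for side l).
#' If more than one (class, side) qualifies the probe is flagged ambiguous
#' and gets no call.
#'
#' @param fractions side-fraction table from [side_fractions()] /
#'   [find_split()].
#' @param theta isolation threshold in (0.5, 1\].
#' @return list `call` ("none", "ambiguous", or "cms"), `class`, `side`
#'   ("u"/"l"), `theta`.
#' @export
cms_call <- function(fractions, theta = 0.8) {
  if (theta <= 0.5 || theta > 1) {
    stop("theta must lie in (0.5, 1]: the isolation rule degenerates otherwise")
  }
  k <- fractions$class
  hits <- list()
  for (i in seq_along(k)) {
    others <- setdiff(seq_along(k), i)
    if (fractions$p_u[i] >= theta && all(fractions$p_l[others] >= theta)) {
      hits[[length(hits) + 1]] <- c(k[i], "u")
    }
    if (fractions$p_l[i] >= theta && all(fractions$p_u[others] >= theta)) {
      hits[[length(hits) + 1]] <- c(k[i], "l")
    }
  }
  if (length(hits) == 0) {
    return(list(call = "none", class = NA_character_, side = NA_character_,
                theta = theta))
  }
  if (length(hits) > 1) {
    return(list(call = "ambiguous", class = NA_character_,
                side = NA_character_, theta = theta))
  }
  list(call = "cms", class = hits[[1]][1], side = hits[[1]][2], theta = theta)
}

#' CMS calls for a table of split statistics
#'
#' @param splits data frame from [find_split_all()].
#' @param theta isolation threshold.
#' @return data frame `probe_id`, `call`, `class`, `side`, `theta`.
#' @export
cms_call_all <- function(splits, theta = 0.8) {
  classes <- sub("^p_(.*)_u$", "\\1",
                 grep("^p_.*_u$", names(splits), value = TRUE))
  out <- data.frame(probe_id = splits$probe_id, call = "none",
                    class = NA_character_, side = NA_character_,
                    theta = theta, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(splits))) {
    pu <- as.numeric(splits[i, paste0("p_", classes, "_u")])
    if (anyNA(pu)) next
    fr <- data.frame(class = classes, p_u = pu, p_l = 1 - pu,
                     stringsAsFactors = FALSE)
    cc <- cms_call(fr, theta)
    out$call[i] <- cc$call
    out$class[i] <- cc$class
    out$side[i] <- cc$side
  }
  out
}

#' Aggregate random-forest probe importance over replicates
#'
#' Fits `R` forests, each on a fresh stratified training split after the
#' (training-fold-only) prefilter, and averages the per-probe mean
#' impurity-decrease importance; probes never passing the prefilter score 0.
#' Ranks are dense over all probes, ties broken by probe id.
#'
#' @param beta probes x samples matrix.
#' @param groups risk-group data frame.
#' @param config an [rf_config()] (its `n_replicates` is ignored in favour
#'   of `R`); the reference setting uses the chi2 top-10% prefilter.
#' @param R number of forests to average (>= 1).
#' @return data frame `probe_id`, `importance`, `rank`.
#' @export
aggregate_importance <- function(beta, groups, config = rf_config(), R = 100) {
  if (R < 1) stop("R must be >= 1")
  validate_beta_matrix(beta)
  y <- factor(groups$group[match(colnames(beta), groups$sample_id)])
  if (!is.null(config$seed)) set.seed(config$seed)
  total <- stats::setNames(numeric(nrow(beta)), rownames(beta))
  for (r in seq_len(R)) {
    tr <- stratified_split(y, config$train_fraction)
    sel <- apply_prefilter(beta, colnames(beta)[tr], y[tr], config$prefilter)
    freq <- table(y[tr])
    cw <- as.numeric(sum(freq) / (length(freq) * freq))
    names(cw) <- names(freq)
    fit <- ranger::ranger(x = t(beta[sel, tr, drop = FALSE]), y = y[tr],
                          num.trees = config$n_trees,
                          max.depth = config$max_depth,
                          class.weights = cw[levels(y)],
                          importance = "impurity",
                          seed = sample.int(.Machine$integer.max, 1),
                          num.threads = 1)
    total[sel] <- total[sel] + fit$variable.importance[sel]
  }
  imp <- total / R
  ord <- order(-imp, names(imp))
  rank <- integer(length(imp))
  rank[ord] <- seq_along(imp)
  data.frame(probe_id = names(imp), importance = as.numeric(imp),
             rank = rank, row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize the top-N importance probes at gene level
#'
#' @param importance data frame from [aggregate_importance()].
#' @param ann annotation data frame.
#' @param N number of top-ranked probes to keep (clamped to the probe count
#'   with a warning).
#' @return list: `top_probes` (probe ids in rank order), `genes` (data frame
#'   `gene`, `n_probes`, `probes`), `n_genes`.
#' @export
top_probes_to_genes <- function(importance, ann, N = 10000) {
  if (N > nrow(importance)) {
    warning("N exceeds probe count; clamped to ", nrow(importance))
    N <- nrow(importance)
  }
  top <- importance$probe_id[order(importance$rank)][seq_len(N)]
  idx <- match(top, ann$probe_id)
  genes <- ann$gene_symbols[idx]
  pairs <- data.frame(
    probe_id = rep(top, lengths(genes)),
    gene = unlist(genes),
    stringsAsFactors = FALSE)
  per_gene <- if (nrow(pairs) > 0) {
    agg <- stats::aggregate(probe_id ~ gene, pairs,
                            FUN = function(p) paste(p, collapse = ";"))
    cnt <- stats::aggregate(probe_id ~ gene, pairs, FUN = length)
    out <- data.frame(gene = agg$gene, n_probes = cnt$probe_id,
                      probes = agg$probe_id, stringsAsFactors = FALSE)
    out[order(-out$n_probes, out$gene), ]
  } else {
    data.frame(gene = character(0), n_probes = integer(0),
               probes = character(0))
  }
  list(top_probes = top, genes = per_gene, n_genes = nrow(per_gene))
}

#' CMS composition along the importance ranking
#'
#' Bins probes by importance rank and reports, per bin and class, the count
#' and proportion of CMS calls (total and split by side).
#'
#' @param importance data frame from [aggregate_importance()].
#' @param calls data frame from [cms_call_all()].
#' @param n_bins number of rank bins (>= 1).
#' @return data frame `bin`, `class`, `n_probes`, `n_cms`, `n_u`, `n_l`,
#'   `proportion`.
#' @export
rank_cms_profile <- function(importance, calls, n_bins = 10) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  merged <- merge(importance, calls, by = "probe_id")
  merged <- merged[order(merged$rank), ]
  bin <- ceiling(merged$rank / (nrow(merged) / n_bins))
  bin <- pmin(bin, n_bins)
  classes <- sort(unique(stats::na.omit(calls$class)))
  if (length(classes) == 0) classes <- character(0)
  rows <- list()
  for (b in seq_len(n_bins)) {
    in_bin <- bin == b
    for (k in classes) {
      is_k <- in_bin & merged$call == "cms" & !is.na(merged$class) &
        merged$class == k
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, class = k, n_probes = sum(in_bin), n_cms = sum(is_k),
        n_u = sum(is_k & merged$side == "u"),
        n_l = sum(is_k & merged$side == "l"),
        proportion = if (sum(in_bin) > 0) sum(is_k) / sum(in_bin) else 0,
        stringsAsFactors = FALSE)
    }
    if (length(classes) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, class = NA_character_, n_probes = sum(in_bin), n_cms = 0L,
        n_u = 0L, n_l = 0L, proportion = 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Locus view: probes around a gene's TSS
#'
#' Reports every probe within `window_bp` of the gene's anchor position (the
#' first TSS-annotated probe of the gene, falling back to its most upstream
#' probe), ordered by genomic position, with annotation, CMS call, top-N
#' membership and per-group mean beta.
#'
#' @param ann annotation data frame.
#' @param beta probes x samples matrix.
#' @param groups risk-group data frame.
#' @param gene gene symbol to anchor on.
#' @param window_bp half-window in bp (default 100 kb, a conservative bound
#'   for enhancer-promoter regulation distance).
#' @param calls optional CMS call table from [cms_call_all()].
#' @param top_probes optional character vector of top-importance probe ids.
#' @return data frame, one row per probe in the window.
#' @export
locus_view <- function(ann, beta, groups, gene, window_bp = 100000,
                       calls = NULL, top_probes = NULL) {
  in_gene <- vapply(ann$gene_symbols, function(g) gene %in% g, logical(1))
  if (!any(in_gene)) stop("gene not found in annotation: ", gene)
  gene_rows <- which(in_gene)
  is_tss <- vapply(ann$refgene_group[gene_rows],
                   function(g) any(g %in% c("TSS200", "TSS1500")), logical(1))
  anchor_row <- if (any(is_tss)) {
    gene_rows[is_tss][which.min(ann$position[gene_rows[is_tss]])]
  } else {
    gene_rows[which.min(ann$position[gene_rows])]
  }
  chrom <- ann$chromosome[anchor_row]
  anchor <- ann$position[anchor_row]
  win <- which(ann$chromosome == chrom &
                 !is.na(ann$position) &
                 abs(ann$position - anchor) <= window_bp)
  win <- win[order(ann$position[win])]
  ids <- ann$probe_id[win]
  y <- factor(groups$group[match(colnames(beta), groups$sample_id)])
  present <- ids %in% rownames(beta)
  gmeans <- matrix(NA_real_, length(ids), nlevels(y),
                   dimnames = list(ids, levels(y)))
  if (any(present)) {
    sub <- beta[ids[present], , drop = FALSE]
    for (k in levels(y)) {
      gmeans[present, k] <- rowMeans(sub[, y == k, drop = FALSE])
    }
  }
  out <- data.frame(
    probe_id = ids,
    position = ann$position[win],
    refgene_group = vapply(ann$refgene_group[win], paste, character(1),
                           collapse = ";"),
    cgi_relation = ann$cgi_relation[win],
    enhancer_450k = ann$enhancer_450k[win],
    phantom5_enhancer = ann$phantom5_enhancer[win],
    stringsAsFactors = FALSE)
  if (!is.null(calls)) {
    m <- match(ids, calls$probe_id)
    out$cms_class <- calls$class[m]
    out$cms_side <- calls$side[m]
  }
  out$top_n <- if (!is.null(top_probes)) ids %in% top_probes else NA
  cbind(out, as.data.frame(gmeans))
}
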
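#' Compute methylation beta-values from signal intensities
#'
#' The methylation fraction of a probe is computed from the methylated (M)
#' and unmethylated (U) channel intensities as \eqn{\beta = M / (M + U + 100)}.
#' The +100 offset regularises low-intensity probes, so the value always lies
#' in \[0, 1).
#'
#' @param M numeric vector of methylated signal intensities (>= 0).
#' @param U numeric vector of unmethylated signal intensities (>= 0),
#'   recycled against `M`.
#' @return numeric vector of beta-values in \[0, 1).
#' @examples
#' compute_beta(300, 100)  # 0.6
#' @export
compute_beta <- function(M, U) {
  if (!is.numeric(M) || !is.numeric(U)) {
    stop("M and U must be numeric")
  }
  if (any(!is.finite(M)) || any(!is.finite(U)) || any(M < 0) || any(U < 0)) {
    stop("signal intensities must be finite and non-negative")
  }
  M / (M + U + 100)
}

#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with probes as rows and samples as
#' columns, row/column names as identifiers, and all non-missing entries in
#' \[0, 1\]. This checks those invariants and returns the matrix invisibly.
#'
#' @param beta numeric matrix, probes x samples.
#' @return `beta`, invisibly.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("beta must be a numeric matrix (probes x samples)")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta must have probe row names and sample column names")
  }
  if (anyDuplicated(rownames(beta))) {
    stop("duplicate probe_id: ", rownames(beta)[duplicated(rownames(beta))][1])
  }
  if (anyDuplicated(colnames(beta))) {
    stop("duplicate sample_id: ", colnames(beta)[duplicated(colnames(beta))][1])
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta out of [0,1] at probe '%s', sample '%s'",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  }
  invisible(beta)
}

#' Read / write a beta-value matrix as TSV
#'
#' The on-disk format is a tab-separated table whose first column is
#' `probe_id` and whose remaining columns are sample IDs; values are
#' methylation fractions in \[0, 1\] (empty cells = missing). `read_beta_matrix`
#' validates ranges and ID uniqueness; the pair round-trips to within float
#' formatting (15 significant digits).
#'
#' @param path file path of the TSV.
#' @return `read_beta_matrix`: numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "probe_id") {
    stop("beta TSV must have a first column named 'probe_id'")
  }
  beta <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- as.character(df$probe_id)
  validate_beta_matrix(beta)
  beta
}

#' @rdname read_beta_matrix
#' @param beta numeric matrix to write.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  df <- data.frame(probe_id = rownames(beta),
                   signif(beta, 15),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# multi-valued manifest cells are ";"-separated token lists
split_tokens <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(t) t[nzchar(t)])
}

manifest_cols <- c("probe_id", "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island",
                   "450k_Enhancer", "Phantom5_Enhancers", "DMR",
                   "DNase_Hypersensitivity_NAME", "TFBS_NAME",
                   "OpenChromatin_NAME", "SNP_ID",
                   "chromosome", "position", "gene_symbols")

#' Read an EPIC-manifest-style probe annotation table
#'
#' Parses the CSV columns named as in the Illumina manifest into typed
#' per-probe records. Multi-valued cells (`UCSC_RefGene_Group`,
#' `gene_symbols`) hold ";"-separated tokens; flag columns
#' (`450k_Enhancer`, `Phantom5_Enhancers`) parse "TRUE"/"FALSE"/empty; the
#' NAME columns (`DNase_Hypersensitivity_NAME`, `TFBS_NAME`,
#' `OpenChromatin_NAME`) and `SNP_ID` count as set when non-empty.
#'
#' @param path CSV file path.
#' @return data frame with one row per probe: `probe_id`, `refgene_group`
#'   (list of tokens), `cgi_relation`, `enhancer_450k`, `phantom5_enhancer`,
#'   `dmr_class`, `dnase`, `tfbs`, `open_chromatin`, `snp_flag`,
#'   `chromosome`, `position`, `gene_symbols` (list of tokens).
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(manifest_cols, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!nzchar(df$probe_id)) || anyNA(df$probe_id)) {
    stop("manifest has rows with missing probe_id")
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id in manifest: ",
         df$probe_id[duplicated(df$probe_id)][1])
  }
  flag <- function(x) !is.na(x) & toupper(x) == "TRUE"
  nonempty <- function(x) !is.na(x) & nzchar(x)
  ann <- data.frame(probe_id = df$probe_id, stringsAsFactors = FALSE)
  ann$refgene_group <- split_tokens(df$UCSC_RefGene_Group)
  ann$cgi_relation <- ifelse(is.na(df$Relation_to_UCSC_CpG_Island), "",
                             df$Relation_to_UCSC_CpG_Island)
  ann$enhancer_450k <- flag(df$`450k_Enhancer`)
  ann$phantom5_enhancer <- flag(df$Phantom5_Enhancers)
  ann$dmr_class <- ifelse(is.na(df$DMR), "", df$DMR)
  ann$dnase <- nonempty(df$DNase_Hypersensitivity_NAME)
  ann$tfbs <- nonempty(df$TFBS_NAME)
  ann$open_chromatin <- nonempty(df$OpenChromatin_NAME)
  ann$snp_flag <- flag(df$SNP_ID) | (nonempty(df$SNP_ID) &
                                       toupper(df$SNP_ID) != "FALSE")
  ann$chromosome <- ifelse(is.na(df$chromosome), "", df$chromosome)
  ann$position <- suppressWarnings(as.integer(df$position))
  if (any(!is.na(ann$position) & ann$position < 1)) {
    stop("manifest positions must be 1-based (>= 1)")
  }
  ann$gene_symbols <- split_tokens(df$gene_symbols)
  ann
}

metadata_cols <- c("sample_id", "inss_stage", "mycn_amplified", "age_years",
                   "efs_time_days", "efs_event", "source")

#' Read sample clinical metadata
#'
#' Expects columns `sample_id`, `inss_stage` (1/2/3/4/4S), `mycn_amplified`
#' (TRUE/FALSE), `age_years`, `efs_time_days`, `efs_event` (TRUE = death of
#' disease, progression or relapse), `source`. Survival fields may be empty
#' (censoring status unknown / not collected).
#'
#' @param path CSV file path.
#' @return data frame of typed sample records.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(metadata_cols, names(df))
  if (length(missing) > 0) {
    stop("metadata is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  df$sample_id <- as.character(df$sample_id)
  df$inss_stage <- as.character(df$inss_stage)
  bad <- setdiff(unique(df$inss_stage), c("1", "2", "3", "4", "4S"))
  if (length(bad) > 0) {
    stop("unknown INSS stage token(s): ", paste(bad, collapse = ", "))
  }
  df$mycn_amplified <- as.logical(df$mycn_amplified)
  df$age_years <- as.numeric(df$age_years)
  if (any(!is.na(df$age_years) & df$age_years < 0)) {
    stop("age_years must be non-negative")
  }
  df$efs_time_days <- as.numeric(df$efs_time_days)
  if (any(!is.na(df$efs_time_days) & df$efs_time_days < 0)) {
    stop("efs_time_days must be non-negative")
  }
  df$efs_event <- as.logical(df$efs_event)
  df$source <- as.character(df$source)
  df
}

#' Mean-impute missing beta-values per probe
#'
#' Replaces each missing entry by its probe's mean over observed samples,
#' as done before model fitting. Probes with no observed value at all are an
#' error.
#'
#' @param beta probes x samples matrix.
#' @return matrix of same shape with no missing values.
#' @export
impute_beta <- function(beta) {
  validate_beta_matrix(beta)
  miss <- which(is.na(beta), arr.ind = TRUE)
  if (nrow(miss) == 0) return(beta)
  means <- rowMeans(beta, na.rm = TRUE)
  if (any(is.nan(means[unique(miss[, 1])]))) {
    stop("probe with all values missing cannot be imputed")
  }
  message(sprintf("imputed %d missing beta value(s) by per-probe mean",
                  nrow(miss)))
  beta[miss] <- means[miss[, 1]]
  beta
}

#' Principal-component embedding of samples
#'
#' Thin wrapper around [stats::prcomp] on the sample x probe orientation,
#' centering probes; missing values are mean-imputed per probe first.
#'
#' @param beta probes x samples matrix.
#' @param n_components number of components to return (>= 1).
#' @return matrix of sample scores (samples x n_components).
#' @export
pca_embed <- function(beta, n_components = 2) {
  if (n_components < 1) stop("n_components must be >= 1")
  beta <- impute_beta(beta)
  n_components <- min(n_components, nrow(beta), ncol(beta))
  pc <- stats::prcomp(t(beta), center = TRUE, scale. = FALSE)
  pc$x[, seq_len(n_components), drop = FALSE]
}
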
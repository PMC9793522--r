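#' Configuration for the synthetic 450K-like cohort generator
#'
#' Defaults emulate the four-cohort neuroblastoma methylome the analyses
#' assume: 493 samples in groups A/B/C/D (110/246/55/82), a latent subgroup
#' D1 inside group D whose methylation resembles group B, enhancer-enriched
#' hypomethylation signal for group A, low-variance CpG-island promoter
#' probes, an age-at-diagnosis covariate, and exponentially distributed
#' event-free-survival times with independent censoring.
#'
#' @param n_per_group named integer vector of sample counts for groups
#'   A, B, C, D.
#' @param n_probes total probe count (desk scale default 2000).
#' @param frac_informative fraction of probes carrying an effect, per
#'   signature-bearing group (A, B, C; group D is the baseline methylome,
#'   distinguishable only by lacking the other signatures).
#' @param effect_size mean beta shift of informative probes (in (0,1)).
#' @param noise_concentration precision of the beta-distributed noise around
#'   each probe's group mean (variance = mu(1-mu)/(c+1)).
#' @param frac_D1 fraction of group D belonging to the latent subgroup D1.
#' @param d1_effect_overlap fraction of B-informative probes that D1 shares.
#' @param d1_direction_ratio fraction of the shared probes shifted hyper
#'   (towards B) in D1; the remainder shift hypo.
#' @param enhancer_frac,cgi_promoter_frac annotation composition fractions.
#' @param cgi_promoter_variance_scale multiplier < 1 shrinking CGI-promoter
#'   probe variance (applied as concentration / scale).
#' @param hazard_per_group named event hazards (1/day) for A, B, C, D1, D2.
#' @param censor_rate probability a sample's survival time is censored.
#' @param age_rule named P(age < 1.5y) per subgroup A, B, C, D1, D2.
#' @param n_sources number of cohort source labels, assigned round-robin.
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(A = 110, B = 246, C = 55, D = 82),
                       n_probes = 2000,
                       frac_informative = 0.05,
                       effect_size = 0.35,
                       noise_concentration = 50,
                       frac_D1 = 0.4,
                       d1_effect_overlap = 1.0,
                       d1_direction_ratio = 1.0,
                       enhancer_frac = 0.15,
                       cgi_promoter_frac = 0.25,
                       cgi_promoter_variance_scale = 0.25,
                       hazard_per_group = c(A = 8e-4, B = 6e-4, C = 1e-4,
                                            D1 = 4e-4, D2 = 5e-5),
                       censor_rate = 0.3,
                       age_rule = c(A = 0.2, B = 0.3, C = 0.6,
                                    D1 = 0.26, D2 = 0.97),
                       n_sources = 4,
                       seed = NULL) {
  cfg <- list(n_per_group = n_per_group, n_probes = n_probes,
              frac_informative = frac_informative, effect_size = effect_size,
              noise_concentration = noise_concentration, frac_D1 = frac_D1,
              d1_effect_overlap = d1_effect_overlap,
              d1_direction_ratio = d1_direction_ratio,
              enhancer_frac = enhancer_frac,
              cgi_promoter_frac = cgi_promoter_frac,
              cgi_promoter_variance_scale = cgi_promoter_variance_scale,
              hazard_per_group = hazard_per_group, censor_rate = censor_rate,
              age_rule = age_rule, n_sources = n_sources, seed = seed)
  fracs <- c(frac_informative, frac_D1, d1_effect_overlap, d1_direction_ratio,
             enhancer_frac, cgi_promoter_frac, censor_rate, age_rule)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (enhancer_frac + cgi_promoter_frac > 1) {
    stop("enhancer_frac + cgi_promoter_frac must not exceed 1")
  }
  if (n_probes < 1) stop("n_probes must be >= 1")
  if (any(n_per_group < 1)) stop("each group needs at least one sample")
  if (!all(c("A", "B", "C", "D") %in% names(n_per_group))) {
    stop("n_per_group must name groups A, B, C, D")
  }
  if (any(hazard_per_group <= 0)) stop("hazards must be positive")
  if (!all(c("A", "B", "C", "D1", "D2") %in% names(hazard_per_group))) {
    stop("hazard_per_group must name A, B, C, D1, D2")
  }
  if (effect_size < 0 || effect_size >= 0.9) {
    stop("effect_size must lie in [0, 0.9)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic 450K-like cohort
#'
#' Draws a probes x samples beta matrix with planted group structure, an
#' EPIC-style probe annotation table, clinical metadata and the ground truth.
#'
#' Construction: each probe gets a baseline mean; `frac_informative` of the
#' probes per signature-bearing group (A, B, C) shift that group's mean by
#' the effect size. Group A's informative probes are preferentially placed
#' on 450K-enhancer probes with hypomethylation direction; group B's are
#' hypermethylated. Group D is the baseline methylome with no signature of
#' its own, except that the latent D1 samples carry a `d1_effect_overlap`
#' share of group B's hyper signature — the "looks clinically low-risk but
#' methylates like stage 4" structure the subgroup-discovery analysis is
#' designed to find, and the reason the D1-D2 contrast is one-sidedly
#' hypermethylated in D1. Per-sample beta-values
#' are beta-distributed around the group mean; CGI-promoter probes have their
#' variance shrunk. Survival is exponential per subgroup hazard with
#' independent censoring; ages are drawn from the per-subgroup
#' under-1.5-year probabilities.
#'
#' @param config a [sim_config()] list.
#' @return list with elements `beta` (matrix), `manifest` (annotation data
#'   frame as from [read_manifest()]), `metadata` (data frame as from
#'   [read_metadata()]), `truth` (list: `samples` with true group/subgroup,
#'   `probes` with informative-for flags and directions), and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  P <- config$n_probes
  n <- config$n_per_group[c("A", "B", "C", "D")]
  N <- sum(n)
  delta <- config$effect_size

  probe_ids <- sprintf("cg%07d", seq_len(P))
  sample_ids <- sprintf("S%04d", seq_len(N))
  group <- rep(c("A", "B", "C", "D"), times = n)

  ## latent subgroups: D splits into D1 (B-like) and D2
  subgroup <- group
  d_idx <- which(group == "D")
  n_d1 <- round(config$frac_D1 * length(d_idx))
  d1_idx <- sample(d_idx, n_d1)
  subgroup[d1_idx] <- "D1"
  subgroup[setdiff(d_idx, d1_idx)] <- "D2"

  ## annotation: probe category, gene/position layout
  cat_probe <- sample(c("cgi_promoter", "enhancer", "other"), P, replace = TRUE,
                      prob = c(config$cgi_promoter_frac, config$enhancer_frac,
                               1 - config$cgi_promoter_frac - config$enhancer_frac))
  probes_per_gene <- 15
  gene_idx <- ceiling(seq_len(P) / probes_per_gene)
  gene <- sprintf("GENE%04d", gene_idx)
  chrom <- paste0("chr", ((gene_idx - 1) %% 22) + 1)
  gene_within_chr <- ceiling(gene_idx / 22)
  position <- gene_within_chr * 1000000L + ((seq_len(P) - 1L) %% probes_per_gene) * 2000L

  refgene <- character(P)
  cgi <- character(P)
  is_cgi_prom <- cat_probe == "cgi_promoter"
  is_enh <- cat_probe == "enhancer"
  refgene[is_cgi_prom] <- sample(c("TSS200", "TSS200;1stExon"),
                                 sum(is_cgi_prom), replace = TRUE)
  cgi[is_cgi_prom] <- "Island"
  cgi[is_enh] <- sample(c("", "N_Shore"), sum(is_enh), replace = TRUE,
                        prob = c(0.7, 0.3))
  oth <- which(cat_probe == "other")
  refgene[oth] <- sample(c("Body", "TSS1500", "5'UTR", "3'UTR", ""),
                         length(oth), replace = TRUE,
                         prob = c(0.35, 0.15, 0.1, 0.1, 0.3))
  cgi[oth] <- sample(c("", "N_Shore", "S_Shelf", "Island"),
                     length(oth), replace = TRUE,
                     prob = c(0.55, 0.2, 0.15, 0.1))
  manifest <- data.frame(probe_id = probe_ids, stringsAsFactors = FALSE)
  manifest$refgene_group <- split_tokens(refgene)
  manifest$cgi_relation <- cgi
  manifest$enhancer_450k <- is_enh
  manifest$phantom5_enhancer <- is_enh & stats::runif(P) < 0.4
  manifest$dmr_class <- sample(c("", "DMR", "RDMR", "CDMR"), P, replace = TRUE,
                               prob = c(0.85, 0.05, 0.05, 0.05))
  manifest$dnase <- stats::runif(P) < 0.2
  manifest$tfbs <- stats::runif(P) < 0.25
  manifest$open_chromatin <- stats::runif(P) < 0.15
  manifest$snp_flag <- stats::runif(P) < 0.05
  manifest$chromosome <- chrom
  manifest$position <- as.integer(position)
  manifest$gene_symbols <- as.list(gene)

  ## informative probes: disjoint across groups, never on CGI-promoter
  ## probes. Group D carries no signature of its own: the localized-tumour
  ## methylome is the baseline state, distinguishable only by lacking the
  ## A/B/C signatures, so the D1-D2 difference is purely D1's hyper shift.
  n_inf <- round(config$frac_informative * P)
  pool_enh <- which(is_enh)
  pool_other <- which(!is_cgi_prom & !is_enh)
  take <- function(pool, k) if (k > 0) sample(pool, min(k, length(pool))) else integer(0)
  n_enh_a <- round(0.8 * n_inf)                # enhancer-enriched group-A signal
  inf_A <- c(take(pool_enh, n_enh_a),
             take(pool_other, n_inf - min(n_enh_a, length(pool_enh))))
  avail <- setdiff(c(pool_enh, pool_other), inf_A)
  inf_B <- take(avail, n_inf); avail <- setdiff(avail, inf_B)
  inf_C <- take(avail, n_inf)

  dir_A <- rep(-1, length(inf_A))              # group-A enhancer hypomethylation
  dir_B <- rep(+1, length(inf_B))              # poor-prognosis hypermethylation
  dir_C <- sample(c(-1, 1), length(inf_C), replace = TRUE)

  ## D1 shares a subset of B's signature (hyper towards B)
  n_shared <- round(config$d1_effect_overlap * length(inf_B))
  shared_pos <- if (n_shared > 0) sample(seq_along(inf_B), n_shared) else integer(0)
  inf_D1 <- inf_B[shared_pos]
  dir_D1 <- ifelse(stats::runif(length(inf_D1)) < config$d1_direction_ratio, 1, -1)

  ## baselines: informative probes keep mu and mu +/- delta inside (0.05, 0.95)
  mu0 <- numeric(P)
  comp <- sample(3, P, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu0[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 8)
  mu0[comp == 2] <- stats::rbeta(sum(comp == 2), 8, 2)
  mu0[comp == 3] <- stats::rbeta(sum(comp == 3), 2, 2)
  mu0 <- pmin(pmax(mu0, 0.05), 0.95)
  inf_all <- list(A = inf_A, B = inf_B, C = inf_C)
  dir_all <- list(A = dir_A, B = dir_B, C = dir_C)
  for (g in names(inf_all)) {
    idx <- inf_all[[g]]; d <- dir_all[[g]]
    hyper <- idx[d > 0]; hypo <- idx[d < 0]
    mu0[hyper] <- stats::runif(length(hyper), 0.05, 0.95 - delta)
    mu0[hypo] <- stats::runif(length(hypo), 0.05 + delta, 0.95)
  }

  ## group means, then latent-subgroup overrides
  mu <- matrix(mu0, nrow = P, ncol = N)
  for (g in names(inf_all)) {
    cols <- which(group == g)
    mu[inf_all[[g]], cols] <- mu0[inf_all[[g]]] + dir_all[[g]] * delta
  }
  d1_cols <- which(subgroup == "D1")
  if (length(inf_D1) > 0 && length(d1_cols) > 0) {
    mu[inf_D1, d1_cols] <- mu0[inf_D1] + dir_D1 * delta
  }
  mu <- pmin(pmax(mu, 0.02), 0.98)

  conc <- rep(config$noise_concentration, P)
  conc[is_cgi_prom] <- config$noise_concentration / config$cgi_promoter_variance_scale
  beta <- matrix(stats::rbeta(P * N, mu * conc, (1 - mu) * conc), nrow = P, ncol = N)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(probe_ids, sample_ids)

  ## clinical covariates consistent with the group definitions
  stage <- character(N)
  stage[group == "A"] <- sample(c("2", "3", "4"), sum(group == "A"),
                                replace = TRUE, prob = c(0.15, 0.25, 0.6))
  stage[group == "B"] <- "4"
  stage[group == "C"] <- "4S"
  stage[group == "D"] <- sample(c("1", "2", "3"), sum(group == "D"),
                                replace = TRUE, prob = c(0.4, 0.25, 0.35))
  p_young <- config$age_rule[subgroup]
  young <- stats::runif(N) < p_young
  age <- ifelse(young, stats::runif(N, 0, 1.5), stats::runif(N, 1.5, 12))

  ev_time <- stats::rexp(N, rate = config$hazard_per_group[subgroup])
  censored <- stats::runif(N) < config$censor_rate
  obs_time <- ifelse(censored, stats::runif(N, 0, ev_time), ev_time)

  metadata <- data.frame(
    sample_id = sample_ids, inss_stage = stage,
    mycn_amplified = group == "A", age_years = round(age, 3),
    efs_time_days = round(obs_time, 1), efs_event = !censored,
    source = paste0("SRC", ((seq_len(N) - 1) %% config$n_sources) + 1),
    stringsAsFactors = FALSE)

  informative_for <- rep("", P)
  direction <- rep("", P)
  for (g in names(inf_all)) {
    informative_for[inf_all[[g]]] <- g
    direction[inf_all[[g]]] <- ifelse(dir_all[[g]] > 0, "hyper", "hypo")
  }
  d1_shared <- logical(P); d1_shared[inf_D1] <- TRUE
  d1_dir <- rep("", P); d1_dir[inf_D1] <- ifelse(dir_D1 > 0, "hyper", "hypo")
  truth <- list(
    samples = data.frame(sample_id = sample_ids, true_group = group,
                         true_subgroup = subgroup, stringsAsFactors = FALSE),
    probes = data.frame(probe_id = probe_ids, informative_for = informative_for,
                        direction = direction, d1_shared = d1_shared,
                        d1_direction = d1_dir, stringsAsFactors = FALSE))

  list(beta = beta, manifest = manifest, metadata = metadata,
       truth = truth, config = config)
}

#' Write a synthetic cohort to disk as plain-text fixtures
#'
#' Emits `beta.tsv`, `manifest.csv` (Illumina-style column names, re-readable
#' by [read_manifest()]), `metadata.csv`, `truth.csv` and `probe_truth.csv`
#' into `dir`.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  ann <- cohort$manifest
  join <- function(l) vapply(l, paste, character(1), collapse = ";")
  raw <- data.frame(
    probe_id = ann$probe_id,
    UCSC_RefGene_Group = join(ann$refgene_group),
    Relation_to_UCSC_CpG_Island = ann$cgi_relation,
    `450k_Enhancer` = ifelse(ann$enhancer_450k, "TRUE", ""),
    Phantom5_Enhancers = ifelse(ann$phantom5_enhancer, "TRUE", ""),
    DMR = ann$dmr_class,
    DNase_Hypersensitivity_NAME = ifelse(ann$dnase, "DNASE", ""),
    TFBS_NAME = ifelse(ann$tfbs, "TFBS", ""),
    OpenChromatin_NAME = ifelse(ann$open_chromatin, "OPEN", ""),
    SNP_ID = ifelse(ann$snp_flag, "TRUE", ""),
    chromosome = ann$chromosome,
    position = ann$position,
    gene_symbols = join(ann$gene_symbols),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(raw, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth$samples, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth$probes, file.path(dir, "probe_truth.csv"), row.names = FALSE)
  invisible(dir)
}
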
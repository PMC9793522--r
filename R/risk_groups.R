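#' Assign clinical risk groups from stage and MYCN status
#'
#' The four-class scheme used throughout the analysis:
#' \describe{
#'   \item{A}{MYCN-amplified tumours, any INSS stage (amplification takes
#'     precedence over stage).}
#'   \item{B}{INSS stage 4 without MYCN amplification.}
#'   \item{C}{INSS stage 4S without amplification.}
#'   \item{D}{INSS stages 1, 2 and 3 without amplification.}
#' }
#' In `five_class` mode stage 3 is split out of D into its own class `S3`.
#'
#' @param meta data frame as returned by [read_metadata()] (needs
#'   `sample_id`, `inss_stage`, `mycn_amplified`).
#' @param mode `"four_class"` (default) or `"five_class"`.
#' @return data frame with columns `sample_id`, `group`, `subgroup`
#'   (initially `NA`).
#' @export
assign_risk_group <- function(meta, mode = c("four_class", "five_class")) {
  mode <- match.arg(mode)
  stage <- as.character(meta$inss_stage)
  bad <- setdiff(unique(stage), c("1", "2", "3", "4", "4S"))
  if (length(bad) > 0 || anyNA(stage)) {
    stop("unknown or missing INSS stage token(s): ",
         paste(c(bad, if (anyNA(stage)) "NA"), collapse = ", "))
  }
  if (anyNA(meta$mycn_amplified)) {
    stop("mycn_amplified must be present for all samples")
  }
  group <- ifelse(meta$mycn_amplified, "A",
           ifelse(stage == "4", "B",
           ifelse(stage == "4S", "C", "D")))
  if (mode == "five_class") {
    group[group == "D" & stage == "3"] <- "S3"
  }
  data.frame(sample_id = meta$sample_id, group = group,
             subgroup = NA_character_, stringsAsFactors = FALSE)
}

#' Split group B by age at diagnosis
#'
#' Defines B1 as group-B samples diagnosed strictly under
#' `threshold_years` (default 1.5 years, the standard neuroblastoma
#' prognostic cut-off) and B2 as the remaining group-B samples. Samples
#' outside group B are untouched; B samples with missing age are left
#' unsubgrouped with a warning.
#'
#' @param groups risk-group data frame from [assign_risk_group()].
#' @param meta metadata data frame with `age_years`.
#' @param threshold_years age cut-off in years (strict `<`).
#' @return `groups` with `subgroup` filled with "B1"/"B2" for group B.
#' @export
assign_age_subgroup <- function(groups, meta, threshold_years = 1.5) {
  age <- meta$age_years[match(groups$sample_id, meta$sample_id)]
  in_b <- groups$group == "B"
  no_age <- in_b & is.na(age)
  if (any(no_age)) {
    warning(sum(no_age), " group-B sample(s) lack age and were left unsubgrouped")
  }
  groups$subgroup[in_b & !is.na(age) & age < threshold_years] <- "B1"
  groups$subgroup[in_b & !is.na(age) & age >= threshold_years] <- "B2"
  groups
}
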
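# Identification-quality filters, log transform, and the valid-value /
# stage-specific quantification filter.

#' Apply identification-quality filters
#'
#' Retains protein groups that are not reverse (decoy) hits, not contaminants,
#' not identified only by a modification site, and that reach the stringent
#' identification criterion: at least `min_razor_unique` razor+unique peptides
#' of which at least `min_unique` are unique. Defaults (2 and 1) give the
#' high-confidence quantification set; `min_razor_unique = 1, min_unique = 0`
#' reproduces the permissive one-peptide identification list.
#'
#' @param protein_groups Tibble from [read_protein_groups()].
#' @param min_razor_unique Minimum "Razor + unique peptides" count.
#' @param min_unique Minimum "Unique peptides" count.
#' @return The input tibble restricted to retained rows, order preserved.
#' @export
apply_quality_filters <- function(protein_groups, min_razor_unique = 2,
                                  min_unique = 1) {
  protein_groups |>
    filter(
      !.data$flag_reverse, !.data$flag_contaminant, !.data$flag_site_only,
      .data$razor_unique_peptides >= min_razor_unique,
      .data$unique_peptides >= min_unique
    )
}

#' Log2-transform raw LFQ intensities
#'
#' Nonzero intensities become log2 values; a raw intensity of 0 is the
#' missing-value sentinel and becomes `NA`. Negative intensities are an
#' error.
#'
#' @param protein_groups Tibble with raw intensity columns named by sample id.
#' @param design Sample design.
#' @return Tibble with `protein_id` and one log2-intensity column per sample
#'   (`NA` = missing).
#' @export
log2_transform <- function(protein_groups, design) {
  check_design(design)
  m <- intensity_matrix(protein_groups, design)
  if (any(m < 0, na.rm = TRUE)) {
    lfq_abort("Raw intensities must be >= 0.", "lfq_value_error")
  }
  m[m == 0] <- NA_real_
  m <- log2(m)
  bind_cols(tibble(protein_id = protein_groups$protein_id), as_tibble(m))
}

#' Count valid values per condition
#'
#' A "valid value" is a non-missing log2 intensity, i.e. a raw LFQ intensity
#' different from 0.
#'
#' @param log_intensities Tibble from [log2_transform()].
#' @param design Sample design.
#' @return Tibble with `protein_id`, one `valid_<condition>` count column per
#'   condition, and `n_valid`, the row total.
#' @export
missingness_pattern <- function(log_intensities, design) {
  check_design(design)
  miss_cols <- setdiff(names(log_intensities), "protein_id")
  if (!setequal(miss_cols, design$sample_id)) {
    lfq_abort("Sample columns do not match the design.", "lfq_design_error")
  }
  conds <- design_conditions(design)
  out <- tibble(protein_id = log_intensities$protein_id)
  for (cond in conds) {
    sids <- design$sample_id[design$condition == cond]
    m <- as.matrix(log_intensities[, sids, drop = FALSE])
    out[[paste0("valid_", cond)]] <- as.integer(rowSums(!is.na(m)))
  }
  out$n_valid <- out[[paste0("valid_", conds[1])]] +
    out[[paste0("valid_", conds[2])]]
  out
}

#' Valid-value filter with stage-specific detection
#'
#' Retains proteins quantifiable for the two-condition comparison: those with
#' valid LFQ values in at least `min_valid` of all samples, plus those with
#' valid values in every replicate of one condition and none of the other
#' (the 3:0 / 0:3 presence/absence patterns with three replicates). The
#' latter are flagged stage-specific for the condition in which they were
#' detected.
#'
#' @param log_intensities Tibble from [log2_transform()] (quality filters
#'   already applied).
#' @param design Sample design.
#' @param min_valid Minimum total valid values for the general rule
#'   (default 4 of 6).
#' @return A "quant set": the missingness-pattern tibble restricted to
#'   retained proteins, with a `stage_specific` column that is `"none"` or
#'   the condition label of exclusive detection.
#' @export
filter_for_quantification <- function(log_intensities, design, min_valid = 4) {
  pat <- missingness_pattern(log_intensities, design)
  conds <- design_conditions(design)
  n_rep <- table(design$condition)[conds]
  v1 <- pat[[paste0("valid_", conds[1])]]
  v2 <- pat[[paste0("valid_", conds[2])]]
  spec1 <- v1 == n_rep[[1]] & v2 == 0L
  spec2 <- v2 == n_rep[[2]] & v1 == 0L
  pat$stage_specific <- dplyr::case_when(
    spec1 ~ conds[1], spec2 ~ conds[2], .default = "none"
  )
  pat[pat$n_valid >= min_valid | spec1 | spec2, , drop = FALSE]
}
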
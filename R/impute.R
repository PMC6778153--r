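# Two-branch missing-value imputation on the log2 scale.
#
# Branch A (sporadic missingness, 1-2 cells missing in total): per-sample
# downshifted normal draws, the standard treatment for intensity-dependent
# (MNAR) dropout - missing values are most likely low-abundance, so fills are
# centred `downshift` observed-SDs below the sample mean with spread `width`
# observed-SDs.
#
# Branch B (condition-absent proteins, the 3:0 / 0:3 patterns): a single
# deterministic fill, the average minimum log-intensity across runs.

#' Per-sample summary statistics of observed log2 intensities
#'
#' Mean, sample SD (n-1 denominator) and minimum of the observed (non-missing)
#' log2 intensities of each sample column. These parameterize both imputation
#' branches.
#'
#' @param log_intensities Tibble from [log2_transform()].
#' @param design Sample design.
#' @return Tibble with `sample_id`, `n_obs`, `mean`, `sd`, `min`.
#' @export
compute_sample_stats <- function(log_intensities, design) {
  check_design(design)
  m <- as.matrix(log_intensities[, sample_cols(design), drop = FALSE])
  stats <- tibble(
    sample_id = design$sample_id,
    n_obs = unname(as.integer(colSums(!is.na(m)))),
    mean  = unname(apply(m, 2, mean, na.rm = TRUE)),
    sd    = unname(apply(m, 2, sd, na.rm = TRUE)),
    min   = unname(suppressWarnings(apply(m, 2, min, na.rm = TRUE)))
  )
  if (any(stats$n_obs < 2L)) {
    lfq_abort(
      paste0("Sample(s) with fewer than 2 observed values: ",
             paste(stats$sample_id[stats$n_obs < 2L], collapse = ", ")),
      "lfq_stats_error"
    )
  }
  if (any(stats$sd == 0)) {
    warn(paste0("Sample(s) with zero SD of observed values: ",
                paste(stats$sample_id[stats$sd == 0], collapse = ", ")))
  }
  stats
}

# Branch routing for the retained proteins: "complete", "downshift" (branch
# A), or "minfill" (branch B). The valid-value filter guarantees every
# retained incomplete protein fits exactly one branch.
impute_routing <- function(quant_set, design) {
  n_samples <- nrow(design)
  n_missing <- n_samples - quant_set$n_valid
  branch <- dplyr::case_when(
    quant_set$stage_specific != "none" ~ "minfill",
    n_missing == 0L ~ "complete",
    n_missing <= 2L ~ "downshift",
    .default = NA_character_
  )
  if (anyNA(branch)) {
    lfq_abort("Retained protein with >2 missing cells that is not condition-absent; was the valid-value filter applied?",
              "lfq_impute_error")
  }
  tibble(protein_id = quant_set$protein_id, branch = branch)
}

#' Impute sporadically missing cells from a downshifted normal (branch A)
#'
#' For proteins with exactly one or two missing cells in total (and not
#' condition-absent), each missing cell in sample *s* is filled with an
#' independent draw from
#' `Normal(mean_s - downshift * sd_s, (width * sd_s)^2)`, where `mean_s` and
#' `sd_s` are that sample's observed-value statistics. Cells are filled in
#' (protein, sample) lexicographic order so the result is reproducible under a
#' fixed seed regardless of row order.
#'
#' @param log_intensities Tibble from [log2_transform()], restricted to the
#'   quant set.
#' @param quant_set Tibble from [filter_for_quantification()].
#' @param design Sample design.
#' @param width,downshift Multiples of the per-sample observed SD
#'   (defaults 0.3 and 1.8).
#' @param seed Optional integer seed for reproducible draws.
#' @return The log-intensity tibble with branch-A cells filled.
#' @export
impute_downshifted <- function(log_intensities, quant_set, design,
                               width = 0.3, downshift = 1.8, seed = NULL) {
  stopifnot(width > 0, downshift >= 0)
  stats <- compute_sample_stats(log_intensities, design)
  routing <- impute_routing(quant_set, design)
  targets <- routing$protein_id[routing$branch == "downshift"]

  m <- intensity_matrix(log_intensities, design)
  cells <- which(is.na(m) & rownames(m) %in% targets, arr.ind = TRUE)
  if (nrow(cells) > 0L) {
    ord <- order(rownames(m)[cells[, 1]], colnames(m)[cells[, 2]])
    cells <- cells[ord, , drop = FALSE]
    mu <- stats$mean[cells[, 2]] - downshift * stats$sd[cells[, 2]]
    sig <- width * stats$sd[cells[, 2]]
    m[cells] <- with_seed_or_not(seed, rnorm(nrow(cells), mu, sig))
  }
  log_intensities[, sample_cols(design)] <- as_tibble(m)
  log_intensities
}

#' Impute condition-absent proteins with the average minimum (branch B)
#'
#' Proteins detected in every replicate of one condition and none of the other
#' have all their missing cells set to one deterministic value: the mean over
#' runs of each run's minimum observed log2 intensity. With
#' `min_fill = "per_condition"` the mean is taken over the runs of the
#' condition in which the protein is missing instead of over all runs.
#'
#' @inheritParams impute_downshifted
#' @param min_fill `"global"` (default; mean of all per-sample minima) or
#'   `"per_condition"`.
#' @return The log-intensity tibble with branch-B cells filled.
#' @export
impute_condition_absent <- function(log_intensities, quant_set, design,
                                    min_fill = c("global", "per_condition")) {
  min_fill <- match.arg(min_fill)
  stats <- compute_sample_stats(log_intensities, design)
  routing <- impute_routing(quant_set, design)
  spec <- quant_set[routing$branch == "minfill", , drop = FALSE]
  if (nrow(spec) == 0L) return(log_intensities)

  m <- intensity_matrix(log_intensities, design)
  global_fill <- mean(stats$min)
  for (i in seq_len(nrow(spec))) {
    pid <- spec$protein_id[i]
    fill <- if (min_fill == "global") {
      global_fill
    } else {
      absent_cond <- setdiff(design_conditions(design), spec$stage_specific[i])
      mean(stats$min[design$condition == absent_cond])
    }
    row <- which(rownames(m) == pid)
    m[row, is.na(m[row, ])] <- fill
  }
  log_intensities[, sample_cols(design)] <- as_tibble(m)
  log_intensities
}

#' Impute all missing values of the quant set
#'
#' Routes every retained protein to exactly one branch - complete (no
#' missing cells, untouched), downshifted-normal (1-2 sporadic missing cells),
#' or average-minimum fill (condition-absent) - and fills all missing cells.
#' Observed cells are never modified.
#'
#' @inheritParams impute_downshifted
#' @inheritParams impute_condition_absent
#' @return A complete log-intensity tibble (no `NA` cells) restricted to the
#'   quant set, with attribute `"routing"`: a tibble `protein_id`, `branch`.
#' @export
impute_lfq <- function(log_intensities, quant_set, design,
                       width = 0.3, downshift = 1.8,
                       min_fill = c("global", "per_condition"), seed = NULL) {
  min_fill <- match.arg(min_fill)
  log_intensities <- log_intensities |>
    semi_join(quant_set, by = "protein_id")
  routing <- impute_routing(quant_set, design)

  out <- log_intensities |>
    impute_downshifted(quant_set, design, width = width,
                       downshift = downshift, seed = seed) |>
    impute_condition_absent(quant_set, design, min_fill = min_fill)
  if (anyNA(out[, sample_cols(design)])) {
    lfq_abort("Imputation left missing cells; this should be unreachable.",
              "lfq_impute_error")
  }
  attr(out, "routing") <- routing
  out
}

#' Branch routing of an imputed table
#'
#' @param imputed Result of [impute_lfq()].
#' @return Tibble `protein_id`, `branch` (complete / downshift / minfill).
#' @export
imputation_routing <- function(imputed) attr(imputed, "routing")
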
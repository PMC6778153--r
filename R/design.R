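#' Build a two-condition sample design
#'
#' Describes which LFQ sample belongs to which biological condition. The
#' default mirrors a two-stage fruit ripening comparison: mature green (MG30)
#' versus red ripe (R45), three biological replicates each. Every log2 ratio
#' computed downstream is `mean(condition 2) - mean(condition 1)` in the order
#' the conditions are given here, so with the defaults a positive ratio means
#' higher abundance in R45.
#'
#' @param conditions Character vector of exactly two condition labels; the
#'   second is the numerator of all fold changes.
#' @param replicates Number of biological replicates per condition (>= 2).
#' @return A tibble with columns `sample_id` (`"<condition>_<replicate>"`),
#'   `condition` and `replicate`.
#' @examples
#' sample_design()
#' sample_design(c("ctrl", "treated"), replicates = 4)
#' @export
sample_design <- function(conditions = c("MG30", "R45"), replicates = 3) {
  stopifnot(length(conditions) == 2L, !anyDuplicated(conditions),
            replicates >= 2)
  design <- tibble(
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), times = 2L),
    sample_id = paste(.data$condition, .data$replicate, sep = "_")
  )
  check_design(design[, c("sample_id", "condition", "replicate")])
}

#' Read a sample design file
#'
#' A tab-separated file with columns `sample_id`, `condition`, `replicate`.
#' Sample-to-condition mapping is always taken from this explicit table and
#' never inferred from intensity column names.
#'
#' @param path Path to the design TSV.
#' @return A design tibble, validated as in [sample_design()].
#' @export
read_design <- function(path) {
  design <- readr::read_tsv(path, show_col_types = FALSE,
                            progress = FALSE)
  check_design(as_tibble(design))
}
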
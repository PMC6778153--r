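# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on the class.
lfq_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "lfqpipe_error"), ...)
}

# Intensity columns of a protein-groups / log-intensity tibble are exactly the
# design's sample ids, in design order.
sample_cols <- function(design) design$sample_id

# The two condition labels, in order of first appearance in the design.
# All log2 ratios in the package are mean(condition 2) - mean(condition 1),
# i.e. the second condition is the numerator on the raw scale.
design_conditions <- function(design) unique(design$condition)

check_design <- function(design) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "condition", "replicate") %in% names(design))) {
    lfq_abort(
      "`design` must have columns sample_id, condition and replicate.",
      "lfq_design_error"
    )
  }
  if (anyDuplicated(design$sample_id)) {
    lfq_abort("Duplicated sample_id in design.", "lfq_design_error")
  }
  conds <- design_conditions(design)
  if (length(conds) != 2L) {
    lfq_abort("The design must contain exactly two conditions.",
              "lfq_design_error")
  }
  n_rep <- table(design$condition)
  if (any(n_rep < 2L)) {
    lfq_abort("Each condition needs at least two replicates.",
              "lfq_design_error")
  }
  invisible(design)
}

# Extract the intensity matrix (proteins x samples) from a tibble whose
# sample columns are named by sample_id. Rows keep protein_id as rownames
# purely for internal bookkeeping.
intensity_matrix <- function(tbl, design) {
  m <- as.matrix(tbl[, sample_cols(design), drop = FALSE])
  rownames(m) <- tbl$protein_id
  m
}

# Run `code` under a fixed seed when one is given, leaving the global RNG
# untouched; with seed = NULL the global stream is used (and advanced).
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
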
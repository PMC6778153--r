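# Relative abundance ratios, two-sample tests, FDR adjustment and the
# five-category abundance classification.

group_matrices <- function(imputed, design) {
  conds <- design_conditions(design)
  m <- intensity_matrix(imputed, design)
  list(
    g1 = m[, design$sample_id[design$condition == conds[1]], drop = FALSE],
    g2 = m[, design$sample_id[design$condition == conds[2]], drop = FALSE]
  )
}

#' Relative abundance ratios on the log2 scale
#'
#' The difference in average log2 intensity between the second and the first
#' design condition (with the default design, R45 minus MG30, i.e.
#' log2(R45/MG30)), computed on complete rows - imputed values included.
#'
#' @param imputed Complete log-intensity tibble from [impute_lfq()].
#' @param design Sample design.
#' @return Tibble `protein_id`, `log2_ratio`.
#' @export
log2_ratio <- function(imputed, design) {
  check_design(design)
  g <- group_matrices(imputed, design)
  tibble(protein_id = imputed$protein_id,
         log2_ratio = unname(rowMeans(g$g2) - rowMeans(g$g1)))
}

#' Row-wise two-sample t tests
#'
#' Two-sided Student (pooled variance, `n1 + n2 - 2` df) or Welch
#' (Satterthwaite df) t test of each protein's log2 intensities between the
#' two conditions. Degenerate rows follow a fixed contract: zero variance in
#' both groups with equal means gives `t = 0, p = 1`; zero variance with
#' unequal means gives `p = 0` (infinite t) with a warning.
#'
#' @param imputed Complete log-intensity tibble.
#' @param design Sample design.
#' @param flavor `"student"` (default) or `"welch"`.
#' @return Tibble `protein_id`, `t_stat`, `df`, `p_value`. The sign of
#'   `t_stat` matches the sign of the log2 ratio.
#' @export
two_sample_test <- function(imputed, design, flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  check_design(design)
  g <- group_matrices(imputed, design)
  n1 <- ncol(g$g1); n2 <- ncol(g$g2)
  if (n1 < 2L || n2 < 2L) {
    lfq_abort("Each group needs >= 2 values.", "lfq_stats_error")
  }
  d  <- rowMeans(g$g2) - rowMeans(g$g1)
  v1 <- apply(g$g1, 1, var)
  v2 <- apply(g$g2, 1, var)

  if (flavor == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se  <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df  <- rep(n1 + n2 - 2, length(d))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se  <- sqrt(se2)
    df  <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }

  t_stat <- d / se
  zero_se <- se == 0
  t_stat[zero_se & d == 0] <- 0
  t_stat[zero_se & d != 0] <- sign(d[zero_se & d != 0]) * Inf
  df[zero_se] <- n1 + n2 - 2
  if (any(zero_se & d != 0)) {
    warn("Zero within-group variance with unequal means; p set to 0.")
  }
  p <- 2 * pt(-abs(t_stat), df)
  p[zero_se & d == 0] <- 1

  tibble(protein_id = imputed$protein_id, t_stat = unname(t_stat),
         df = unname(df), p_value = unname(p))
}

#' Adjust p-values for multiple testing
#'
#' `"bh"` is Benjamini-Hochberg step-up (monotone by construction).
#' `"permutation"` estimates q-values from a condition-label permutation null
#' of the t statistics pooled across proteins: for every observed `|t|`, the
#' q-value is the mean number of null statistics at least as extreme divided
#' by the number of observed statistics at least as extreme, with step-up
#' monotonicity enforced. All distinct balanced relabelings are used (10 for
#' a 3 vs 3 design).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"permutation"`.
#' @param imputed,design Required for `method = "permutation"`: the complete
#'   log-intensity table and design on which the observed statistics were
#'   computed.
#' @param flavor Test flavor used for the permutation statistics.
#' @return Numeric vector of q-values, same length and order as `p_values`.
#' @export
adjust_fdr <- function(p_values, method = c("bh", "permutation"),
                       imputed = NULL, design = NULL,
                       flavor = "student") {
  method <- match.arg(method)
  if (length(p_values) == 0L) return(numeric())
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    lfq_abort("p-values must lie in [0, 1].", "lfq_stats_error")
  }
  if (method == "bh") return(p.adjust(p_values, method = "BH"))
  if (is.null(imputed) || is.null(design)) {
    lfq_abort("Permutation FDR needs `imputed` and `design`.",
              "lfq_stats_error")
  }
  permutation_fdr(imputed, design, flavor = flavor)
}

# Distinct balanced relabelings of the design's samples (complement-equivalent
# splits collapsed; the observed labeling is included, the SAM convention).
balanced_relabelings <- function(design) {
  conds <- design_conditions(design)
  idx1 <- which(design$condition == conds[1])
  n1 <- length(idx1)
  all_idx <- seq_len(nrow(design))
  splits <- utils::combn(all_idx, n1, simplify = FALSE)
  keep <- vapply(splits, function(s) s[1] == 1L, logical(1))
  splits[keep]
}

permutation_fdr <- function(imputed, design, flavor = "student") {
  obs <- abs(two_sample_test(imputed, design, flavor)$t_stat)
  splits <- balanced_relabelings(design)
  conds <- design_conditions(design)
  null_t <- unlist(lapply(splits, function(s) {
    perm_design <- design
    perm_design$condition <- ifelse(seq_len(nrow(design)) %in% s,
                                    conds[1], conds[2])
    abs(two_sample_test(imputed, perm_design, flavor)$t_stat)
  }))
  n_perm <- length(splits)

  ord <- order(obs, decreasing = TRUE)
  sorted <- obs[ord]
  # counts of statistics >= each sorted observed value
  r_obs  <- seq_along(sorted)
  e_null <- (length(null_t) - findInterval(sorted, sort(null_t))) / n_perm
  q_sorted <- pmin(1, e_null / r_obs)
  # enforce monotonicity: q non-increasing in |t|
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(length(obs))
  q[ord] <- q_sorted
  q
}

#' Classify proteins into abundance categories
#'
#' The five-category scheme of the two-stage comparison, plus the sixth
#' "putatively-invariant" label kept distinct for transparency:
#' condition-absent proteins are `<condition>-specific` regardless of the
#' test; otherwise a protein is `<condition>-enriched` when its |log2 ratio|
#' reaches `logfc_cut` *and* its FDR-adjusted q is below `fdr_cut`;
#' `invariant` when |log2 ratio| <= `logfc_cut` (the closed interval wins at
#' exactly the cutoff); and `putatively-invariant` when the fold change is
#' large but the q-value fails the cut.
#'
#' @param log2_ratio Numeric vector of log2 ratios (condition 2 over 1).
#' @param q_value Numeric vector of FDR-adjusted p-values.
#' @param stage_specific Character vector: `"none"` or a condition label.
#' @param design Sample design (supplies the condition labels).
#' @param logfc_cut Absolute log2-ratio cutoff (default 0.58, the printed
#'   two-decimal rounding of log2(1.5)).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return Factor with levels `<cond1>-specific`, `<cond1>-enriched`,
#'   `invariant`, `putatively-invariant`, `<cond2>-enriched`,
#'   `<cond2>-specific`.
#' @export
classify_abundance <- function(log2_ratio, q_value, stage_specific, design,
                               logfc_cut = 0.58, fdr_cut = 0.05) {
  stopifnot(logfc_cut > 0, fdr_cut > 0, fdr_cut < 1)
  conds <- design_conditions(design)
  lev <- c(paste0(conds[1], "-specific"), paste0(conds[1], "-enriched"),
           "invariant", "putatively-invariant",
           paste0(conds[2], "-enriched"), paste0(conds[2], "-specific"))
  out <- dplyr::case_when(
    stage_specific == conds[1] ~ lev[1],
    stage_specific == conds[2] ~ lev[6],
    abs(log2_ratio) <= logfc_cut ~ "invariant",
    log2_ratio <= -logfc_cut & q_value < fdr_cut ~ lev[2],
    log2_ratio >=  logfc_cut & q_value < fdr_cut ~ lev[5],
    .default = "putatively-invariant"
  )
  factor(out, levels = lev)
}

#' Differential abundance analysis of the quant set
#'
#' Composes ratio computation, row-wise testing, FDR adjustment and
#' classification into one call. Condition-absent (stage-specific) proteins
#' carry their presence/absence category regardless of the test outcome but
#' still receive a ratio/t/p/q computed on the imputed values.
#'
#' @param imputed Complete log-intensity tibble from [impute_lfq()].
#' @param quant_set Tibble from [filter_for_quantification()].
#' @param design Sample design.
#' @param test `"student"` or `"welch"`.
#' @param fdr_method `"bh"` or `"permutation"`.
#' @param logfc_cut,fdr_cut Classification thresholds.
#' @return A tibble of class `lfq_differential`: `protein_id`, `log2_ratio`,
#'   `t_stat`, `df`, `p_value`, `q_value`, `valid_*` counts,
#'   `stage_specific`, `category`.
#' @export
run_differential <- function(imputed, quant_set, design,
                             test = c("student", "welch"),
                             fdr_method = c("bh", "permutation"),
                             logfc_cut = 0.58, fdr_cut = 0.05) {
  test <- match.arg(test)
  fdr_method <- match.arg(fdr_method)
  res <- log2_ratio(imputed, design) |>
    inner_join(two_sample_test(imputed, design, test), by = "protein_id") |>
    mutate(q_value = adjust_fdr(.data$p_value, fdr_method,
                                imputed = imputed, design = design,
                                flavor = test)) |>
    inner_join(quant_set, by = "protein_id") |>
    mutate(category = classify_abundance(
      .data$log2_ratio, .data$q_value, .data$stage_specific, design,
      logfc_cut = logfc_cut, fdr_cut = fdr_cut
    ))
  structure(res,
            class = c("lfq_differential", class(res)),
            design = design,
            thresholds = list(logfc_cut = logfc_cut, fdr_cut = fdr_cut),
            test = test, fdr_method = fdr_method)
}

#' Proteins counted as differential
#'
#' The enriched categories plus the stage-specific proteins (which the
#' two-stage comparison counts within its differential total).
#'
#' @param differential An `lfq_differential` tibble.
#' @return Character vector of protein ids.
#' @export
differential_proteins <- function(differential) {
  differential$protein_id[grepl("-enriched$|-specific$",
                                differential$category)]
}

#' @exportS3Method generics::tidy
tidy.lfq_differential <- function(x, ...) {
  class(x) <- setdiff(class(x), "lfq_differential")
  attr(x, "design") <- attr(x, "thresholds") <- NULL
  attr(x, "test") <- attr(x, "fdr_method") <- NULL
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.lfq_differential <- function(x, ...) {
  counts <- table(x$category)
  out <- tibble(
    n_proteins = nrow(x),
    n_differential = length(differential_proteins(x)),
    n_stage_specific = sum(x$stage_specific != "none")
  )
  bind_cols(out, as_tibble(as.list(counts)))
}
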
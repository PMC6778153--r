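# Transcript-protein fold-change correlation, globally and per functional
# class.

#' Transcript log2 fold change from RPM values
#'
#' `log2((rpm_to + pseudocount) / (rpm_from + pseudocount))`, vectorized. With
#' `pseudocount = 0`, genes with zero RPM at both stages are undefined and
#' return `NA` with a warning (they are dropped from correlations).
#'
#' @param rpm_from,rpm_to Non-negative RPM vectors (denominator / numerator
#'   stage; with the default design, MG30 and R45).
#' @param pseudocount Non-negative RPM offset added to both stages
#'   (default 1).
#' @return Numeric vector of log2 ratios.
#' @export
transcript_log2fc <- function(rpm_from, rpm_to, pseudocount = 1) {
  stopifnot(all(rpm_from >= 0), all(rpm_to >= 0), pseudocount >= 0)
  num <- rpm_to + pseudocount
  den <- rpm_from + pseudocount
  undef <- num == 0 & den == 0
  if (any(undef)) {
    warn(paste0(sum(undef),
                " gene(s) with zero RPM at both stages and no pseudocount; ",
                "log2 ratio undefined, returned NA."))
  }
  out <- rep(NA_real_, length(num))
  out[!undef] <- log2(num[!undef] / den[!undef])
  out
}

#' Pearson correlation with its t-based test
#'
#' Product-moment correlation and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` df (the classical
#' `cor.test` procedure).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, both with positive
#'   variance.
#' @return Tibble with `r`, `p_value`, `n`, `slope` (regression slope of `y`
#'   on `x`).
#' @export
pearson_with_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    lfq_abort("Need at least 3 complete pairs for a correlation test.",
              "lfq_cor_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    lfq_abort("Correlation undefined: one variable has zero variance.",
              "lfq_cor_error")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         slope = unname(ct$estimate) * sd(y) / sd(x))
}

#' Correlate protein and transcript log2 fold changes by functional class
#'
#' Pairs each quantified protein with its transcript via the annotation's
#' `gene_id`, computes the transcript log2 ratio from RPM, and reports the
#' Pearson correlation of protein versus transcript log2(R45/MG30) globally
#' and within every functional class with at least `min_n` paired points.
#' Proteins without a gene id or without transcript data are dropped with a
#' message; duplicate proteins mapping to one gene each contribute their own
#' point. Condition-absent proteins participate with their imputation-derived
#' protein ratio.
#'
#' @param protein_fc Tibble with `protein_id` and `log2_ratio` (e.g. an
#'   [run_differential()] result).
#' @param transcripts Tibble from [read_transcript_table()].
#' @param annotation Annotation tibble (supplies `gene_id` and
#'   `functional_class`).
#' @param design Sample design (fixes the ratio direction).
#' @param pseudocount RPM pseudocount for [transcript_log2fc()].
#' @param min_n Minimum paired points for a per-class correlation.
#' @return A tibble of class `lfq_correlation` with one row per scope
#'   (`"global"` first, then each class): `scope`, `n`, `r`, `p_value`,
#'   `slope`, `significant` (p < 0.05). The paired points are attached as
#'   attribute `"points"` for plotting.
#' @export
correlate_by_class <- function(protein_fc, transcripts, annotation,
                               design = sample_design(), pseudocount = 1,
                               min_n = 3) {
  check_design(design)
  conds <- design_conditions(design)
  rpm_from <- paste0("rpm_", conds[1])
  rpm_to   <- paste0("rpm_", conds[2])

  pts <- as_tibble(protein_fc)[, c("protein_id", "log2_ratio")] |>
    inner_join(annotation_for(annotation, protein_fc$protein_id)[,
               c("protein_id", "gene_id", "functional_class")],
               by = "protein_id") |>
    filter(!is.na(.data$gene_id)) |>
    inner_join(transcripts, by = "gene_id") |>
    mutate(mrna_log2_ratio = transcript_log2fc(.data[[rpm_from]],
                                               .data[[rpm_to]],
                                               pseudocount)) |>
    filter(!is.na(.data$mrna_log2_ratio))
  n_dropped <- nrow(protein_fc) - nrow(pts)
  if (n_dropped > 0L) {
    inform(paste0(n_dropped, " protein(s) without a paired transcript dropped."))
  }
  if (nrow(pts) == 0L) {
    lfq_abort("No protein could be paired with a transcript.",
              "lfq_cor_error")
  }

  one_scope <- function(df, scope) {
    bind_cols(tibble(scope = scope),
              pearson_with_test(df$mrna_log2_ratio, df$log2_ratio))
  }
  res <- one_scope(pts, "global")
  classes <- sort(unique(pts$functional_class[!is.na(pts$functional_class)]))
  for (cl in classes) {
    sub <- pts[!is.na(pts$functional_class) & pts$functional_class == cl, ]
    if (nrow(sub) >= max(3L, min_n) &&
        sd(sub$mrna_log2_ratio) > 0 && sd(sub$log2_ratio) > 0) {
      res <- bind_rows(res, one_scope(sub, cl))
    }
  }
  res$significant <- res$p_value < 0.05
  structure(res, class = c("lfq_correlation", class(res)), points = pts)
}

#' Paired points behind a correlation result
#'
#' @param correlation An `lfq_correlation` tibble.
#' @return Tibble of paired protein/transcript log2 ratios with class labels.
#' @export
correlation_points <- function(correlation) attr(correlation, "points")

#' @exportS3Method generics::tidy
tidy.lfq_correlation <- function(x, ...) {
  class(x) <- setdiff(class(x), "lfq_correlation")
  attr(x, "points") <- NULL
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.lfq_correlation <- function(x, ...) {
  tibble(n_scopes = nrow(x),
         global_r = x$r[x$scope == "global"],
         global_p = x$p_value[x$scope == "global"],
         n_points = x$n[x$scope == "global"])
}
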
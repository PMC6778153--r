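# GO-term over-representation of a protein set against a background proteome.
# Annotations are used exactly as given (no ontology-graph propagation; an
# ancestor closure, if wanted, must be precomputed upstream).

#' Build the 2x2 contingency table for one GO term
#'
#' @param query_set Character vector of query protein ids (a subset of the
#'   background).
#' @param background_set Character vector of background protein ids.
#' @param term A GO term id.
#' @param annotation Annotation tibble from [read_annotation_table()].
#' @return 2x2 integer matrix: rows in-query / out-of-query, columns
#'   annotated / not-annotated; margins sum to the background size.
#' @export
build_contingency <- function(query_set, background_set, term, annotation) {
  offenders <- setdiff(query_set, background_set)
  if (length(offenders) > 0L) {
    lfq_abort(paste0("Query proteins not in background: ",
                     paste(head(offenders, 5), collapse = ", ")),
              "lfq_enrich_error")
  }
  ann <- annotation_for(annotation, background_set)
  has_term <- vapply(ann$go_terms, function(g) term %in% g, logical(1))
  annotated <- background_set[has_term]
  q_ann <- sum(query_set %in% annotated)
  matrix(
    c(q_ann, length(query_set) - q_ann,
      length(annotated) - q_ann,
      length(background_set) - length(query_set) - (length(annotated) - q_ann)),
    nrow = 2,
    dimnames = list(c("query", "rest"), c("annotated", "not_annotated"))
  )
}

#' One-sided over-representation p-value
#'
#' The upper hypergeometric tail `P(X >= observed)` - the one-sided
#' (greater) Fisher exact test of the 2x2 table; `alternative = "two.sided"`
#' gives the two-sided Fisher p instead.
#'
#' @param counts 2x2 matrix from [build_contingency()].
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A p-value.
#' @export
over_representation_p <- function(counts, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(counts), all(dim(counts) == 2L), all(counts >= 0))
  if (alternative == "two.sided") {
    return(stats::fisher.test(counts, alternative = "two.sided")$p.value)
  }
  obs <- counts[1, 1]
  K <- counts[1, 1] + counts[2, 1]   # background annotated
  N <- sum(counts)                   # background size
  n <- counts[1, 1] + counts[1, 2]   # query size
  phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO-term over-representation analysis
#'
#' Tests every term with at least one background annotation for
#' over-representation in the query set, reports observed and expected
#' counts, fold enrichment (observed over the count expected from the
#' background annotation frequency), raw and corrected p-values, and flags
#' terms with corrected p below `significance`.
#'
#' @inheritParams build_contingency
#' @param correction `"bh"` (default) or `"bonferroni"`, applied across all
#'   tested terms.
#' @param significance Corrected-p cutoff for the `significant` flag.
#' @return A tibble of class `lfq_enrichment`, sorted by q then p, with
#'   columns `term_id`, `observed`, `expected`, `fold_enrichment`, `p_value`,
#'   `q_value`, `background_annotated`, `background_size`, `query_size`,
#'   `significant`.
#' @export
enrich <- function(query_set, background_set, annotation,
                   correction = c("bh", "bonferroni"), significance = 0.05) {
  correction <- match.arg(correction)
  if (length(query_set) == 0L || length(background_set) == 0L) {
    lfq_abort("Query and background must be non-empty.", "lfq_enrich_error")
  }
  offenders <- setdiff(query_set, background_set)
  if (length(offenders) > 0L) {
    lfq_abort(paste0("Query proteins not in background: ",
                     paste(head(offenders, 5), collapse = ", ")),
              "lfq_enrich_error")
  }

  ann <- annotation_for(annotation, background_set)
  long <- tibble(protein_id = rep(ann$protein_id, lengths(ann$go_terms)),
                 term_id = unlist(ann$go_terms))
  if (nrow(long) == 0L) {
    lfq_abort("No background protein carries any GO annotation.",
              "lfq_enrich_error")
  }
  N <- length(background_set)
  n <- length(query_set)
  per_term <- long |>
    group_by(.data$term_id) |>
    summarise(background_annotated = dplyr::n_distinct(.data$protein_id),
              observed = sum(unique(.data$protein_id) %in% query_set),
              .groups = "drop") |>
    mutate(
      background_size = N,
      query_size = n,
      expected = n * .data$background_annotated / N,
      fold_enrichment = ifelse(.data$expected > 0,
                               .data$observed / .data$expected, NA_real_),
      p_value = phyper(.data$observed - 1, .data$background_annotated,
                       N - .data$background_annotated, n, lower.tail = FALSE),
      q_value = p.adjust(.data$p_value,
                         method = if (correction == "bh") "BH" else "bonferroni"),
      significant = .data$q_value < significance
    ) |>
    arrange(.data$q_value, .data$p_value) |>
    select("term_id", "observed", "expected", "fold_enrichment",
           "p_value", "q_value", "background_annotated", "background_size",
           "query_size", "significant")
  structure(per_term, class = c("lfq_enrichment", class(per_term)),
            correction = correction, significance = significance)
}

#' @exportS3Method generics::tidy
tidy.lfq_enrichment <- function(x, ...) {
  class(x) <- setdiff(class(x), "lfq_enrichment")
  attr(x, "correction") <- attr(x, "significance") <- NULL
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.lfq_enrichment <- function(x, ...) {
  tibble(n_terms_tested = nrow(x),
         n_significant = sum(x$significant),
         correction = attr(x, "correction"),
         significance = attr(x, "significance"))
}
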
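# End-to-end orchestration: quality filter -> log transform -> valid-value
# filter -> impute -> ratio/test/FDR -> classify -> enrich -> correlate,
# with conserved stage bookkeeping and a machine-readable summary.

#' Run the full LFQ differential-abundance pipeline
#'
#' Executes every stage in the order of the underlying analysis and writes
#' the per-stage result tables plus a `summary.json` run summary to
#' `out_dir`. All randomness (the downshifted-normal imputation draws) flows
#' from `seed`, so a fixed configuration and seed give byte-identical output
#' files.
#'
#' @param protein_groups Path to a proteinGroups TSV, or a tibble already in
#'   [read_protein_groups()] shape.
#' @param design Path to a design TSV or a design tibble.
#' @param annotation Path to an annotation TSV or an annotation tibble.
#' @param transcripts Path to a transcript TSV or a transcript tibble;
#'   `NULL` disables the correlation stage.
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param min_razor_unique,min_unique Identification-quality thresholds.
#' @param min_valid Valid-value threshold (default 4 of 6).
#' @param width,downshift,min_fill Imputation parameters, see [impute_lfq()].
#' @param test,fdr_method,logfc_cut,fdr_cut Differential-stage parameters,
#'   see [run_differential()].
#' @param correction,significance Enrichment parameters, see [enrich()].
#' @param pseudocount RPM pseudocount for the correlation stage.
#' @param seed Integer seed for the imputation draws.
#' @return A list of class `lfq_run` with elements `summary` (named counts),
#'   `differential`, `enrichment` (or `NULL` when no protein is
#'   differential), `correlation` (or `NULL` when disabled), `routing` and
#'   `manifest` (files written).
#' @export
run_lfq_pipeline <- function(protein_groups, design, annotation,
                             transcripts = NULL, out_dir = NULL,
                             min_razor_unique = 2, min_unique = 1,
                             min_valid = 4,
                             width = 0.3, downshift = 1.8,
                             min_fill = "global",
                             test = "student", fdr_method = "bh",
                             logfc_cut = 0.58, fdr_cut = 0.05,
                             correction = "bh", significance = 0.05,
                             pseudocount = 1, seed = 1) {
  # resolve inputs up front so a missing file fails before any work
  for (stage in c("protein_groups", "annotation", "transcripts", "design")) {
    val <- get(stage)
    if (is.character(val) && !file.exists(val)) {
      lfq_abort(paste0("Stage '", stage_name_for(stage),
                       "': input file not found: ", val),
                "lfq_config_error")
    }
  }
  design <- if (is.character(design)) read_design(design) else check_design(design)
  pg <- if (is.character(protein_groups)) {
    read_protein_groups(protein_groups, design)
  } else {
    protein_groups
  }
  annotation <- if (is.character(annotation)) {
    read_annotation_table(annotation)
  } else {
    annotation
  }
  transcripts <- if (is.character(transcripts)) {
    read_transcript_table(transcripts, design)
  } else {
    transcripts
  }

  n_read <- nrow(pg)
  quality <- apply_quality_filters(pg, min_razor_unique, min_unique)
  log_tbl <- log2_transform(quality, design)
  quant <- filter_for_quantification(log_tbl, design, min_valid = min_valid)
  imputed <- impute_lfq(log_tbl, quant, design, width = width,
                        downshift = downshift, min_fill = min_fill,
                        seed = seed)
  differential <- run_differential(imputed, quant, design, test = test,
                                   fdr_method = fdr_method,
                                   logfc_cut = logfc_cut, fdr_cut = fdr_cut)

  query <- differential_proteins(differential)
  enrichment <- if (length(query) > 0L) {
    enrich(query, differential$protein_id, annotation,
           correction = correction, significance = significance)
  } else {
    inform("No differential protein; enrichment stage skipped.")
    NULL
  }

  correlation <- if (!is.null(transcripts)) {
    correlate_by_class(differential, transcripts, annotation,
                       design = design, pseudocount = pseudocount)
  } else {
    NULL
  }

  cat_counts <- as.list(table(differential$category))
  summary <- c(
    list(
      n_read = n_read,
      n_removed_quality = n_read - nrow(quality),
      n_after_quality = nrow(quality),
      n_removed_valid_value = nrow(quality) - nrow(quant),
      n_quantified = nrow(quant),
      n_stage_specific = sum(quant$stage_specific != "none"),
      n_differential = length(query),
      n_enriched_terms = if (is.null(enrichment)) 0L else sum(enrichment$significant),
      global_r = if (is.null(correlation)) NA_real_ else correlation$r[correlation$scope == "global"],
      parameters = list(
        min_razor_unique = min_razor_unique, min_unique = min_unique,
        min_valid = min_valid, width = width, downshift = downshift,
        min_fill = min_fill, test = test, fdr_method = fdr_method,
        logfc_cut = logfc_cut, fdr_cut = fdr_cut, correction = correction,
        significance = significance, pseudocount = pseudocount, seed = seed
      )
    ),
    list(categories = cat_counts)
  )

  manifest <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- write_stage_outputs(out_dir, differential, enrichment,
                                    correlation, imputed, summary)
  }
  structure(list(summary = summary, differential = differential,
                 enrichment = enrichment, correlation = correlation,
                 routing = imputation_routing(imputed), manifest = manifest),
            class = "lfq_run")
}

stage_name_for <- function(input) {
  switch(input, transcripts = "correlation", protein_groups = "read", input)
}

write_stage_outputs <- function(out_dir, differential, enrichment,
                                correlation, imputed, summary) {
  paths <- character()
  add <- function(paths, name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    c(paths, p)
  }
  paths <- add(paths, "differential.tsv",
               function(p) write_results(tidy(differential), p))
  if (!is.null(enrichment)) {
    paths <- add(paths, "enrichment.tsv",
                 function(p) write_results(tidy(enrichment), p))
  }
  if (!is.null(correlation)) {
    paths <- add(paths, "correlation.tsv",
                 function(p) write_results(tidy(correlation), p))
  }
  paths <- add(paths, "imputation_routing.tsv",
               function(p) write_results(imputation_routing(imputed), p))
  paths <- add(paths, "summary.json", function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  paths
}

#' @export
print.lfq_run <- function(x, ...) {
  s <- x$summary
  cat("LFQ pipeline run\n")
  cat("  proteins read:            ", s$n_read, "\n")
  cat("  after quality filters:    ", s$n_after_quality, "\n")
  cat("  quantified (valid-value): ", s$n_quantified, "\n")
  cat("  stage-specific:           ", s$n_stage_specific, "\n")
  cat("  differential:             ", s$n_differential, "\n")
  cat("  enriched GO terms:        ", s$n_enriched_terms, "\n")
  if (!is.na(s$global_r)) {
    cat("  global mRNA-protein r:    ", round(s$global_r, 3), "\n")
  }
  cat("  categories:\n")
  for (nm in names(s$categories)) {
    cat("    ", format(nm, width = 24), s$categories[[nm]], "\n")
  }
  invisible(x)
}
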
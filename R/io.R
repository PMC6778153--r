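# Readers/writers for the tabular formats the pipeline touches. The
# proteinGroups dialect follows MaxQuant's column naming; only the columns the
# analysis needs are interpreted, everything else is ignored (logged once).

.pg_flag_cols <- c(
  flag_reverse     = "Reverse",
  flag_contaminant = "Potential contaminant",
  flag_site_only   = "Only identified by site"
)

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the per-protein-group output of a MaxQuant-style search into a tidy
#' table: one row per protein group with identification metadata and one raw
#' LFQ intensity column per design sample. An LFQ intensity of 0 is the
#' missing-value sentinel (a protein not quantified in that run); negative
#' intensities are rejected.
#'
#' Required columns: `Protein IDs`, `Razor + unique peptides`,
#' `Unique peptides`, and one `LFQ intensity <sample_id>` per design sample.
#' The flag columns `Reverse`, `Potential contaminant` and
#' `Only identified by site` mark positives with `"+"`; absent flag columns
#' default to all-false with a warning. Unrecognized columns are ignored.
#'
#' @param path Path to the tab-separated proteinGroups file.
#' @param design Sample design from [sample_design()] or [read_design()].
#' @return A tibble with columns `protein_id`, `description`,
#'   `razor_unique_peptides`, `unique_peptides`, `flag_reverse`,
#'   `flag_contaminant`, `flag_site_only`, then one numeric column per
#'   `design$sample_id` holding raw LFQ intensities.
#' @export
read_protein_groups <- function(path, design) {
  check_design(design)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  if (!"Protein IDs" %in% names(raw)) {
    lfq_abort("proteinGroups file lacks a 'Protein IDs' column.",
              "lfq_parse_error")
  }

  lfq_cols <- paste("LFQ intensity", design$sample_id)
  missing_lfq <- design$sample_id[!lfq_cols %in% names(raw)]
  if (length(missing_lfq) > 0L) {
    lfq_abort(
      paste0("proteinGroups file lacks LFQ intensity column(s) for sample(s): ",
             paste(missing_lfq, collapse = ", ")),
      "lfq_config_error"
    )
  }

  parse_count <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_integer_, nrow(raw)))
    suppressWarnings(as.integer(raw[[col]]))
  }

  out <- tibble(
    protein_id  = raw[["Protein IDs"]],
    description = if ("Protein names" %in% names(raw)) {
      raw[["Protein names"]]
    } else {
      rep(NA_character_, nrow(raw))
    },
    razor_unique_peptides = parse_count("Razor + unique peptides"),
    unique_peptides       = parse_count("Unique peptides")
  )
  if (anyDuplicated(out$protein_id)) {
    lfq_abort("Duplicated protein ids in proteinGroups file.",
              "lfq_parse_error")
  }

  absent_flags <- character()
  for (nm in names(.pg_flag_cols)) {
    col <- .pg_flag_cols[[nm]]
    if (col %in% names(raw)) {
      out[[nm]] <- raw[[col]] == "+"
    } else {
      out[[nm]] <- FALSE
      absent_flags <- c(absent_flags, col)
    }
  }
  if (length(absent_flags) > 0L) {
    warn(paste0("Flag column(s) absent, defaulting to all-false: ",
                paste(absent_flags, collapse = ", ")))
  }

  for (i in seq_along(design$sample_id)) {
    vals <- suppressWarnings(as.numeric(raw[[lfq_cols[i]]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      lfq_abort(
        paste0("Non-numeric LFQ intensity in column '", lfq_cols[i],
               "', data row ", bad[1L], "."),
        "lfq_parse_error"
      )
    }
    if (any(vals < 0)) {
      lfq_abort(
        paste0("Negative LFQ intensity in column '", lfq_cols[i],
               "'; intensities must be >= 0 (0 encodes missing)."),
        "lfq_parse_error"
      )
    }
    out[[design$sample_id[i]]] <- vals
  }

  extra <- setdiff(names(raw),
                   c("Protein IDs", "Protein names", "Razor + unique peptides",
                     "Unique peptides", unname(.pg_flag_cols), lfq_cols))
  if (length(extra) > 0L) {
    inform(paste0("Ignoring ", length(extra), " unrecognized column(s)."))
  }
  out
}

#' Read a protein annotation table
#'
#' Tab-separated with columns `protein_id`, `go_terms` (delimiter-separated
#' list of GO identifiers), `functional_class` (one label per protein out of a
#' closed set; the reference analysis uses fourteen manually compiled classes)
#' and optionally `gene_id` (the transcript/unigene used for mRNA pairing).
#' Duplicate rows for one protein merge their GO sets; their class labels must
#' agree.
#'
#' @param path Path to the annotation TSV.
#' @param go_delim Delimiter separating GO terms within the cell.
#' @return A tibble with columns `protein_id`, `go_terms` (list column of
#'   character vectors), `functional_class` and `gene_id`.
#' @export
read_annotation_table <- function(path, go_delim = ";") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"protein_id" %in% names(raw)) {
    lfq_abort("Annotation file lacks a 'protein_id' column.",
              "lfq_parse_error")
  }
  raw$go_terms <- if ("go_terms" %in% names(raw)) raw$go_terms else NA_character_
  raw$functional_class <-
    if ("functional_class" %in% names(raw)) raw$functional_class else NA_character_
  raw$gene_id <- if ("gene_id" %in% names(raw)) raw$gene_id else NA_character_

  split_go <- function(x) {
    if (length(x) == 0L) return(character())
    terms <- as.character(unlist(strsplit(x[!is.na(x)], go_delim,
                                          fixed = TRUE)))
    sort(unique(terms[nzchar(terms)]))
  }
  pick_one <- function(x, what, id) {
    vals <- unique(x[!is.na(x)])
    if (length(vals) > 1L) {
      lfq_abort(
        paste0("Conflicting ", what, " for protein ", id, ": ",
               paste(vals, collapse = " / ")),
        "lfq_annotation_error"
      )
    }
    if (length(vals) == 0L) NA_character_ else vals
  }

  raw |>
    group_by(.data$protein_id) |>
    summarise(
      go_terms = list(split_go(.data$go_terms)),
      functional_class = pick_one(.data$functional_class, "functional class",
                                  first(.data$protein_id)),
      gene_id = pick_one(.data$gene_id, "gene id", first(.data$protein_id)),
      .groups = "drop"
    )
}

#' Look up the annotation of proteins, absent proteins getting empty sets
#'
#' @param annotation Tibble from [read_annotation_table()].
#' @param protein_ids Character vector of proteins to look up.
#' @return Annotation tibble with one row per requested protein, in order;
#'   proteins absent from the table get an empty GO set and `NA` class/gene.
#' @export
annotation_for <- function(annotation, protein_ids) {
  out <- tibble(protein_id = protein_ids) |>
    left_join(annotation, by = "protein_id")
  out$go_terms <- lapply(out$go_terms, function(x) if (is.null(x)) character() else x)
  out
}

#' Read a transcript abundance table
#'
#' Tab-separated with columns `gene_id` and one `rpm_<condition>` column per
#' design condition holding normalized reads-per-million (RPM), emulating
#' expression-atlas exports. RPM values must be finite and non-negative.
#'
#' @param path Path to the transcript TSV.
#' @param design Sample design; used to check that both conditions have an
#'   RPM column.
#' @return Tibble with columns `gene_id`, `rpm_<cond1>`, `rpm_<cond2>`.
#' @export
read_transcript_table <- function(path, design = sample_design()) {
  check_design(design)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  rpm_cols <- paste0("rpm_", design_conditions(design))
  miss <- setdiff(c("gene_id", rpm_cols), names(raw))
  if (length(miss) > 0L) {
    lfq_abort(paste0("Transcript file lacks column(s): ",
                     paste(miss, collapse = ", ")), "lfq_parse_error")
  }
  for (col in rpm_cols) {
    v <- raw[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      lfq_abort(paste0("Column '", col,
                       "' must be finite non-negative RPM values."),
                "lfq_parse_error")
    }
  }
  as_tibble(raw[, c("gene_id", rpm_cols)])
}

#' Write a results table to TSV
#'
#' Writes any of the pipeline's result tibbles (classification, enrichment,
#' correlation, ...) as UTF-8 tab-separated text with a stable column order
#' and full float precision, so that a write/read round trip preserves text
#' columns exactly and numerics to at least six significant digits. List
#' columns (GO term sets) are collapsed with `";"`.
#'
#' @param rows A tibble of results; an empty tibble writes a header-only file.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  out <- as_tibble(rows)
  is_list <- vapply(out, is.list, logical(1))
  for (col in names(out)[is_list]) {
    out[[col]] <- vapply(out[[col]], paste, character(1), collapse = ";")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A tibble with column types guessed by the reader.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
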
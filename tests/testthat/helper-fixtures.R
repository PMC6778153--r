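# Fixtures built in code: tiny protein-groups tibbles and on-disk TSVs in the
# MaxQuant dialect.

default_design <- sample_design()

# A protein-groups tibble in the reader's output shape, from a matrix of raw
# intensities (rows = proteins).
make_pg <- function(raw, ids = sprintf("P%03d", seq_len(nrow(raw))),
                    design = default_design,
                    razor = 5L, unique = 3L) {
  colnames(raw) <- design$sample_id
  dplyr::bind_cols(
    tibble::tibble(
      protein_id = ids, description = ids,
      razor_unique_peptides = rep_len(razor, nrow(raw)),
      unique_peptides = rep_len(unique, nrow(raw)),
      flag_reverse = FALSE, flag_contaminant = FALSE, flag_site_only = FALSE
    ),
    tibble::as_tibble(raw)
  )
}

# Write a proteinGroups-dialect TSV; `rows` is a list of named cell values,
# columns taken from the union of names.
write_pg_file <- function(df, path = withr::local_tempfile(fileext = ".txt",
                                                           .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

pg_dialect_header <- function(design = default_design) {
  c("Protein IDs", "Protein names", "Razor + unique peptides",
    "Unique peptides", "Reverse", "Potential contaminant",
    "Only identified by site", paste("LFQ intensity", design$sample_id))
}

# A minimal two-row proteinGroups file on disk.
write_tiny_pg <- function(design = default_design, drop_cols = character(),
                          env = parent.frame()) {
  df <- tibble::tibble(
    `Protein IDs` = c("P001", "P002"),
    `Protein names` = c("alpha", "beta"),
    `Razor + unique peptides` = c(5L, 2L),
    `Unique peptides` = c(3L, 1L),
    Reverse = c("", "+"),
    `Potential contaminant` = c("", ""),
    `Only identified by site` = c("", "")
  )
  for (sid in design$sample_id) {
    df[[paste("LFQ intensity", sid)]] <- c(1024, 0)
  }
  df <- df[, setdiff(names(df), drop_cols)]
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = env)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Complete (no missing) log-intensity tibble from per-group replicate values.
make_log_tbl <- function(values_by_protein, design = default_design) {
  m <- do.call(rbind, values_by_protein)
  colnames(m) <- design$sample_id
  dplyr::bind_cols(
    tibble::tibble(protein_id = sprintf("P%03d", seq_along(values_by_protein))),
    tibble::as_tibble(m)
  )
}

# Annotation tibble in the reader's output shape.
make_annotation <- function(protein_ids, go = NULL, class = NA_character_,
                            gene = NA_character_) {
  tibble::tibble(
    protein_id = protein_ids,
    go_terms = if (is.null(go)) replicate(length(protein_ids), character(),
                                          simplify = FALSE) else go,
    functional_class = rep_len(class, length(protein_ids)),
    gene_id = rep_len(gene, length(protein_ids))
  )
}
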
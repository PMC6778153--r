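# Synthetic two-condition LFQ data with known ground truth: log-normal
# intensities, intensity-dependent (MNAR) dropout, planted log2 fold changes,
# forced condition-absent proteins, planted GO enrichment, and transcripts
# with class-specific correlation to the protein fold changes.

.default_classes <- c(
  "C compound and sugar metabolism", "Cell wall metabolism",
  "Amino acid metabolism", "Lipid metabolism", "Secondary metabolism",
  "Hormone biosynthesis", "Protein synthesis", "Protein degradation",
  "Protein folding", "Transport", "Vesicular trafficking",
  "Stress and defense", "Energy and photosynthesis", "Other"
)

.default_class_r <- c(0.63, 0.40, 0.35, 0.80, 0.88, 0.80, -0.04, 0.20,
                      0.30, 0.45, 0.25, 0.30, 0.50, 0.52)

#' Configuration of the synthetic LFQ study
#'
#' Defaults emulate the two-stage microsomal study design: two conditions
#' with three biological replicates, roughly 10% of proteins differential
#' (true |log2 fold change| between 0.58 and 3), about 4% fully
#' stage-specific, log-normal baseline abundances (log2 mean 25, SD 2),
#' replicate noise SD 0.25 on the log2 scale, logistic intensity-dependent
#' dropout tuned to a realistic overall missingness of a few percent, fourteen
#' functional classes with heterogeneous transcript-protein correlation
#' targets, and transcript fold changes with a wider dynamic range than the
#' protein ones (attenuation slope 0.6 of protein on transcript).
#'
#' @param n_proteins Number of genuine protein groups.
#' @param frac_differential Fraction with a planted nonzero fold change
#'   (stage-specific proteins included).
#' @param frac_stage_specific Fraction forced condition-absent (must not
#'   exceed `frac_differential`).
#' @param log2fc_range Interval for planted |log2 FC| (signs random).
#' @param baseline_mean,baseline_sd Log2-intensity baseline distribution.
#' @param replicate_sd Replicate noise SD, log2 units.
#' @param dropout_midpoint,dropout_steepness Logistic MNAR dropout parameters
#'   on the log2 scale (probability 0.5 at the midpoint, decreasing with
#'   intensity).
#' @param n_classes Number of functional classes.
#' @param class_names Class labels (recycled/truncated to `n_classes`).
#' @param class_target_r Per-class target Pearson correlation between planted
#'   protein and transcript log2 fold changes.
#' @param mrna_dynamic_range_slope Attenuation of protein relative to
#'   transcript fold changes: transcript FCs are drawn with SD equal to the
#'   protein-FC SD divided by this slope.
#' @param n_go_terms,n_enriched_go Total GO vocabulary size and number of
#'   terms planted as over-represented among differential proteins.
#' @param n_contaminants,n_reverse,n_site_only,n_low_evidence Extra decoy
#'   rows exercising the identification-quality filters.
#' @param rpm_mean_log2,rpm_sd_log2 Log2 distribution of baseline transcript
#'   RPM.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `lfq_sim_config`.
#' @export
sim_config <- function(n_proteins = 1000,
                       frac_differential = 0.10,
                       frac_stage_specific = 0.04,
                       log2fc_range = c(0.58, 3.0),
                       baseline_mean = 25, baseline_sd = 2,
                       replicate_sd = 0.25,
                       dropout_midpoint = 19, dropout_steepness = 0.8,
                       n_classes = 14,
                       class_names = .default_classes,
                       class_target_r = .default_class_r,
                       mrna_dynamic_range_slope = 0.6,
                       n_go_terms = 30, n_enriched_go = 3,
                       n_contaminants = 5, n_reverse = 5,
                       n_site_only = 3, n_low_evidence = 5,
                       rpm_mean_log2 = 7, rpm_sd_log2 = 1.5,
                       seed = 1) {
  if (frac_differential < 0 || frac_differential > 1 ||
      frac_stage_specific < 0 || frac_stage_specific > 1) {
    lfq_abort("Fractions must lie in [0, 1].", "lfq_sim_error")
  }
  if (frac_stage_specific > frac_differential) {
    lfq_abort("frac_stage_specific cannot exceed frac_differential.",
              "lfq_sim_error")
  }
  stopifnot(replicate_sd > 0, baseline_sd > 0, mrna_dynamic_range_slope > 0,
            length(log2fc_range) == 2L, log2fc_range[1] <= log2fc_range[2])
  class_names <- rep_len(class_names, n_classes)
  class_target_r <- rep_len(class_target_r, n_classes)
  if (any(abs(class_target_r) > 1)) {
    lfq_abort("class_target_r must lie in [-1, 1].", "lfq_sim_error")
  }
  structure(
    list(n_proteins = n_proteins, frac_differential = frac_differential,
         frac_stage_specific = frac_stage_specific,
         log2fc_range = log2fc_range, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, replicate_sd = replicate_sd,
         dropout_midpoint = dropout_midpoint,
         dropout_steepness = dropout_steepness,
         n_classes = n_classes, class_names = class_names,
         class_target_r = class_target_r,
         mrna_dynamic_range_slope = mrna_dynamic_range_slope,
         n_go_terms = n_go_terms, n_enriched_go = n_enriched_go,
         n_contaminants = n_contaminants, n_reverse = n_reverse,
         n_site_only = n_site_only, n_low_evidence = n_low_evidence,
         rpm_mean_log2 = rpm_mean_log2, rpm_sd_log2 = rpm_sd_log2,
         seed = seed),
    class = "lfq_sim_config"
  )
}

#' Intensity-dependent dropout probability
#'
#' Logistic in the (true, pre-dropout) log2 intensity:
#' `1 / (1 + exp(steepness * (x - midpoint)))` - monotone decreasing, 0.5 at
#' the midpoint, so low-abundance proteins drop out preferentially (the MNAR
#' regime that motivates downshifted imputation).
#'
#' @param log2_intensity Numeric vector of log2 intensities.
#' @param midpoint,steepness Logistic parameters.
#' @return Dropout probabilities in (0, 1).
#' @export
dropout_probability <- function(log2_intensity, midpoint = 19,
                                steepness = 0.8) {
  stopifnot(all(is.finite(log2_intensity)))
  1 / (1 + exp(steepness * (log2_intensity - midpoint)))
}

#' Simulate a complete synthetic LFQ study
#'
#' Generates a proteinGroups-dialect table (with decoy/contaminant rows to
#' exercise the quality filters), a functional/GO annotation table, a
#' transcript RPM table, and a ground-truth table, all consistent with the
#' configured study design. Deterministic under the configured seed.
#'
#' @param config An [sim_config()] list.
#' @param design Sample design (two conditions; defaults to MG30/R45 x 3).
#' @return A list of class `lfq_sim` with elements `protein_groups` (same
#'   shape as [read_protein_groups()] output), `annotation`, `transcripts`,
#'   `truth` (per genuine protein: true log2 FC, category, class, gene id,
#'   transcript log2 FC), `enriched_terms`, `design`, `config`.
#' @export
simulate_lfq <- function(config = sim_config(), design = sample_design()) {
  stopifnot(inherits(config, "lfq_sim_config"))
  check_design(design)
  withr::with_seed(config$seed, simulate_lfq_impl(config, design))
}

simulate_lfq_impl <- function(config, design) {
  n <- config$n_proteins
  conds <- design_conditions(design)
  n_rep <- as.vector(table(design$condition)[conds])

  pid <- sprintf("P%05d", seq_len(n))
  gid <- sprintf("G%05d", seq_len(n))
  fclass <- rep_len(config$class_names, n)

  n_diff <- round(n * config$frac_differential)
  n_spec <- round(n * config$frac_stage_specific)
  is_diff <- seq_len(n) <= n_diff
  is_spec <- seq_len(n) <= n_spec

  fc <- numeric(n)
  if (n_diff > 0) {
    fc[is_diff] <- sample(c(-1, 1), n_diff, replace = TRUE) *
      runif(n_diff, config$log2fc_range[1], config$log2fc_range[2])
  }
  # condition-absent proteins get a large planted effect; its sign fixes the
  # condition of exclusive detection
  if (n_spec > 0) {
    fc[is_spec] <- sign(fc[is_spec]) * config$log2fc_range[2]
  }
  spec_cond <- ifelse(is_spec, ifelse(fc > 0, conds[2], conds[1]), "none")

  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  mu1 <- baseline - fc / 2
  mu2 <- baseline + fc / 2

  log2_true <- cbind(
    matrix(rep(mu1, n_rep[1]), n, n_rep[1]),
    matrix(rep(mu2, n_rep[2]), n, n_rep[2])
  ) + matrix(rnorm(n * sum(n_rep), 0, config$replicate_sd), n, sum(n_rep))
  colnames(log2_true) <- design$sample_id

  drop_p <- dropout_probability(log2_true, config$dropout_midpoint,
                                config$dropout_steepness)
  dropped <- matrix(rbinom(length(drop_p), 1, drop_p) == 1L,
                    n, ncol(log2_true))
  # forced complete dropout in the absent condition of specific proteins
  for (k in 1:2) {
    cols <- design$sample_id[design$condition == conds[k]]
    dropped[spec_cond == conds[3 - k], colnames(log2_true) %in% cols] <- TRUE
  }
  raw <- 2^log2_true
  raw[dropped] <- 0

  razor <- 2L + stats::rpois(n, 4)
  uniq  <- pmin(razor, 1L + stats::rpois(n, 2))
  pg <- bind_cols(
    tibble(protein_id = pid,
           description = paste("synthetic protein", pid),
           razor_unique_peptides = razor,
           unique_peptides = uniq,
           flag_reverse = FALSE, flag_contaminant = FALSE,
           flag_site_only = FALSE),
    as_tibble(raw)
  )
  pg <- bind_rows(pg, decoy_rows(config, design))

  # transcripts: per class, bivariate-normal construction so that the
  # correlation of planted protein and transcript FCs hits the class target
  mrna_fc <- numeric(n)
  for (k in seq_len(config$n_classes)) {
    members <- which(fclass == config$class_names[k])
    if (length(members) == 0L) next
    p <- fc[members]
    r <- config$class_target_r[k]
    sd_p <- sd(p)
    if (length(members) < 3L || is.na(sd_p) || sd_p == 0) {
      mrna_fc[members] <- rnorm(length(members), 0, 0.5)
      next
    }
    # noise orthogonalized against the protein FCs so the realized sample
    # correlation equals the class target exactly
    sd_t <- sd_p / config$mrna_dynamic_range_slope
    z <- (p - mean(p)) / sd_p
    e <- rnorm(length(members))
    e <- e - mean(e) - z * sum(e * z) / sum(z * z)
    e <- if (sd(e) > 0) e / sd(e) else e
    mrna_fc[members] <- sd_t * (r * z + sqrt(1 - r^2) * e)
  }
  rpm_from <- 2^rnorm(n, config$rpm_mean_log2, config$rpm_sd_log2)
  rpm_to <- rpm_from * 2^mrna_fc
  transcripts <- tibble(gene_id = gid)
  transcripts[[paste0("rpm_", conds[1])]] <- rpm_from
  transcripts[[paste0("rpm_", conds[2])]] <- rpm_to

  # GO vocabulary with planted over-represented terms among the differential
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  enriched_terms <- head(terms, config$n_enriched_go)
  background_terms <- setdiff(terms, enriched_terms)
  go_sets <- vector("list", n)
  for (i in seq_len(n)) {
    base <- background_terms[runif(length(background_terms)) < 0.08]
    extra <- if (is_diff[i]) {
      enriched_terms[runif(length(enriched_terms)) < 0.5]
    } else {
      enriched_terms[runif(length(enriched_terms)) < 0.05]
    }
    go_sets[[i]] <- sort(c(base, extra))
  }
  annotation <- tibble(protein_id = pid, go_terms = go_sets,
                       functional_class = fclass, gene_id = gid)

  true_category <- dplyr::case_when(
    spec_cond != "none" ~ paste0(spec_cond, "-specific"),
    is_diff & fc > 0 ~ paste0(conds[2], "-enriched"),
    is_diff & fc < 0 ~ paste0(conds[1], "-enriched"),
    .default = "invariant"
  )
  truth <- tibble(protein_id = pid, gene_id = gid,
                  functional_class = fclass,
                  true_log2fc = fc, true_mrna_log2fc = mrna_fc,
                  is_differential = is_diff, is_stage_specific = is_spec,
                  stage = spec_cond, true_category = true_category)

  structure(
    list(protein_groups = pg, annotation = annotation,
         transcripts = transcripts, truth = truth,
         enriched_terms = enriched_terms, design = design, config = config),
    class = "lfq_sim"
  )
}

# Reverse/contaminant/site-only/low-evidence rows; all carry intensities so
# that only the flags/peptide counts remove them.
decoy_rows <- function(config, design) {
  kinds <- c(rep("REV", config$n_reverse),
             rep("CON", config$n_contaminants),
             rep("SITE", config$n_site_only),
             rep("LOWEV", config$n_low_evidence))
  if (length(kinds) == 0L) return(NULL)
  ids <- paste0(kinds, "_", stats::ave(seq_along(kinds), kinds, FUN = seq_along))
  m <- matrix(2^rnorm(length(kinds) * nrow(design), config$baseline_mean,
                      config$baseline_sd),
              length(kinds), nrow(design))
  colnames(m) <- design$sample_id
  bind_cols(
    tibble(protein_id = ids,
           description = paste("synthetic decoy", ids),
           razor_unique_peptides = ifelse(kinds == "LOWEV", 1L, 5L),
           unique_peptides = ifelse(kinds == "LOWEV", 0L, 3L),
           flag_reverse = kinds == "REV",
           flag_contaminant = kinds == "CON",
           flag_site_only = kinds == "SITE"),
    as_tibble(m)
  )
}

#' Simulate a null study (no planted effects)
#'
#' The same generator with `frac_differential = 0` and
#' `frac_stage_specific = 0`; every protein's true category is invariant, so
#' any significant call downstream is a false discovery. Used for FDR
#' calibration.
#'
#' @param config Base [sim_config()]; its differential fractions are zeroed.
#' @param design Sample design.
#' @return An `lfq_sim` list.
#' @export
simulate_null <- function(config = sim_config(), design = sample_design()) {
  config$frac_differential <- 0
  config$frac_stage_specific <- 0
  simulate_lfq(config, design)
}

#' Write a simulated study to disk in the pipeline's file formats
#'
#' Produces `proteinGroups.txt` (MaxQuant-dialect TSV), `annotation.tsv`,
#' `transcripts.tsv`, `design.tsv` and `truth.tsv` under `dir`; the first
#' four parse with the package's readers.
#'
#' @param sim An `lfq_sim` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lfq_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "lfq_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pg <- sim$protein_groups
  out <- tibble(
    `Protein IDs` = pg$protein_id,
    `Protein names` = pg$description,
    `Razor + unique peptides` = pg$razor_unique_peptides,
    `Unique peptides` = pg$unique_peptides,
    Reverse = ifelse(pg$flag_reverse, "+", ""),
    `Potential contaminant` = ifelse(pg$flag_contaminant, "+", ""),
    `Only identified by site` = ifelse(pg$flag_site_only, "+", "")
  )
  for (sid in sim$design$sample_id) {
    out[[paste("LFQ intensity", sid)]] <- pg[[sid]]
  }
  readr::write_tsv(out, file.path(dir, "proteinGroups.txt"), progress = FALSE)
  write_results(sim$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(sim$transcripts, file.path(dir, "transcripts.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$design, file.path(dir, "design.tsv"), progress = FALSE)
  write_results(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
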
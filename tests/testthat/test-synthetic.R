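test_that("dropout probability is logistic, symmetric and monotone", {
  expect_equal(dropout_probability(19, midpoint = 19), 0.5)
  expect_lt(dropout_probability(40, midpoint = 19), 1e-6)
  grid <- dropout_probability(seq(10, 30, by = 0.5), midpoint = 19)
  expect_true(all(diff(grid) < 0))
})

test_that("the generator is deterministic under a seed and seed-sensitive", {
  a <- simulate_lfq(sim_config(n_proteins = 80, seed = 42))
  b <- simulate_lfq(sim_config(n_proteins = 80, seed = 42))
  c <- simulate_lfq(sim_config(n_proteins = 80, seed = 43))
  expect_identical(a$protein_groups, b$protein_groups)
  expect_identical(a$transcripts, b$transcripts)
  expect_false(identical(a$protein_groups, c$protein_groups))
})

test_that("generated tables are internally consistent with the truth", {
  cfg <- sim_config(n_proteins = 300, seed = 6)
  sim <- simulate_lfq(cfg)

  # truth covers every genuine protein; decoys are extra rows
  expect_equal(nrow(sim$truth), 300)
  expect_true(all(sim$truth$protein_id %in% sim$protein_groups$protein_id))
  expect_equal(nrow(sim$protein_groups),
               300 + cfg$n_reverse + cfg$n_contaminants + cfg$n_site_only +
                 cfg$n_low_evidence)

  # stage-specific proteins have zero intensity in the whole absent condition
  spec <- sim$truth[sim$truth$is_stage_specific, ]
  for (i in seq_len(nrow(spec))) {
    absent <- setdiff(c("MG30", "R45"), spec$stage[i])
    cols <- sim$design$sample_id[sim$design$condition == absent]
    row <- sim$protein_groups[sim$protein_groups$protein_id ==
                                spec$protein_id[i], ]
    expect_true(all(row[, cols] == 0))
  }

  # categories consistent with planted fold changes
  expect_true(all(sim$truth$true_category[sim$truth$true_log2fc == 0] ==
                    "invariant"))
  up <- sim$truth$true_log2fc > 0 & sim$truth$is_differential &
    !sim$truth$is_stage_specific
  expect_true(all(sim$truth$true_category[up] == "R45-enriched"))
})

test_that("a null configuration plants nothing", {
  sim <- simulate_null(sim_config(n_proteins = 150, seed = 10))
  expect_true(all(sim$truth$true_category == "invariant"))
  expect_true(all(sim$truth$true_log2fc == 0))
})

test_that("marginal missingness increases with the dropout midpoint", {
  rates <- vapply(c(15, 18, 21), function(mid) {
    sim <- simulate_lfq(sim_config(n_proteins = 400, dropout_midpoint = mid,
                                   frac_differential = 0,
                                   frac_stage_specific = 0, seed = 13))
    m <- as.matrix(sim$protein_groups[, sim$design$sample_id])
    mean(m == 0)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("planted per-class correlations converge to their targets", {
  targets <- c(0.9, 0.5, 0.0, -0.1)
  cfg <- sim_config(n_proteins = 2000, n_classes = 4,
                    class_names = paste("class", 1:4),
                    class_target_r = targets, frac_differential = 0.3,
                    frac_stage_specific = 0, seed = 77)
  sim <- simulate_lfq(cfg)
  realized <- vapply(seq_along(targets), function(k) {
    idx <- sim$truth$functional_class == cfg$class_names[k]
    cor(sim$truth$true_log2fc[idx], sim$truth$true_mrna_log2fc[idx])
  }, numeric(1))
  expect_true(all(abs(realized - targets) < 0.05))
})

test_that("null p-values from the pipeline t-test are uniform", {
  sim <- simulate_null(sim_config(n_proteins = 2000, seed = 19))
  pg <- apply_quality_filters(sim$protein_groups)
  lt <- log2_transform(pg, sim$design)
  quant <- filter_for_quantification(lt, sim$design)
  # restrict to complete rows so no imputation artefact enters
  complete <- quant$protein_id[quant$n_valid == 6]
  lt_c <- lt[lt$protein_id %in% complete, ]
  p <- two_sample_test(lt_c, sim$design)$p_value
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("with tiny noise and large effects the pipeline recovers the truth", {
  cfg <- sim_config(n_proteins = 600, replicate_sd = 0.1,
                    log2fc_range = c(2, 2), seed = 33)
  sim <- simulate_lfq(cfg)
  run <- suppressMessages(
    run_lfq_pipeline(sim$protein_groups, sim$design, sim$annotation,
                     sim$transcripts, seed = 33)
  )
  joined <- dplyr::inner_join(tidy(run$differential), sim$truth,
                              by = "protein_id")
  # compare on the five-category grouping, where a failed-FDR large ratio is
  # reported as invariant
  five <- function(x) ifelse(x == "putatively-invariant", "invariant", x)
  agreement <- mean(five(as.character(joined$category)) ==
                      five(joined$true_category))
  expect_gte(agreement, 0.99)

  # the planted GO terms surface as enriched
  expect_true(all(sim$enriched_terms %in%
                    run$enrichment$term_id[run$enrichment$significant]))
})
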
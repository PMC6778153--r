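# Brute-force Benjamini-Hochberg step-up: q_i = min_{j >= i} p_(j) * n / j.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * n / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

test_that("log2 ratios are mean differences with the documented sign", {
  lt <- make_log_tbl(list(
    c(19, 20, 21, 20, 21, 22),   # +1: higher in R45
    c(20, 21, 22, 20, 21, 22)    # identical groups
  ))
  expect_equal(log2_ratio(lt, default_design)$log2_ratio, c(1, 0))

  # relabeling the same samples with swapped conditions negates the ratio
  design_ab <- tibble::tibble(sample_id = paste0("s", 1:6),
                              condition = rep(c("A", "B"), each = 3),
                              replicate = rep(1:3, 2))
  design_ba <- design_ab[c(4:6, 1:3), ]   # B now appears first
  lt_s <- lt
  names(lt_s) <- c("protein_id", paste0("s", 1:6))
  expect_equal(log2_ratio(lt_s, design_ab)$log2_ratio,
               -log2_ratio(lt_s, design_ba)$log2_ratio)
})

test_that("row-wise t tests match stats::t.test on random data", {
  set.seed(31)
  m <- matrix(rnorm(50 * 6, 25, 1.5), 50, 6)
  lt <- make_log_tbl(asplit(m, 1))

  for (flavor in c("student", "welch")) {
    res <- two_sample_test(lt, default_design, flavor)
    ref <- t(apply(m, 1, function(row) {
      tt <- t.test(row[4:6], row[1:3], var.equal = flavor == "student")
      c(tt$statistic, tt$p.value)
    }))
    expect_equal(res$t_stat, unname(ref[, 1]), tolerance = 1e-12)
    expect_equal(res$p_value, unname(ref[, 2]), tolerance = 1e-12)
  }
})

test_that("the textbook pooled-t example and degenerate contracts hold", {
  lt <- make_log_tbl(list(
    c(10, 11, 12, 13, 14, 15),   # MG (10,11,12) vs R (13,14,15)
    c(20, 20, 20, 20, 20, 20)    # identical, zero variance
  ))
  res <- two_sample_test(lt, default_design, "student")
  expect_equal(res$t_stat[1], 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$p_value[1], 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-10)
  expect_equal(res$t_stat[2], 0)
  expect_equal(res$p_value[2], 1)

  # zero variance with unequal means: p = 0, flagged
  lt0 <- make_log_tbl(list(c(10, 10, 10, 12, 12, 12)))
  expect_warning(res0 <- two_sample_test(lt0, default_design), "Zero")
  expect_equal(res0$p_value, 0)

  # student and welch coincide at equal group variances
  lt_eq <- make_log_tbl(list(c(10, 11, 12, 14, 15, 16)))
  s <- two_sample_test(lt_eq, default_design, "student")
  w <- two_sample_test(lt_eq, default_design, "welch")
  expect_equal(s$t_stat, w$t_stat)
  expect_equal(s$p_value, w$p_value)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))

  set.seed(7)
  max_err <- max(vapply(1:1000, function(i) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    max(abs(adjust_fdr(p) - bh_oracle(p)))
  }, numeric(1)))
  expect_lt(max_err, 1e-12)

  # step-up property: q non-decreasing in sorted-p order
  p <- runif(200)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_identical(adjust_fdr(numeric()), numeric())
})

test_that("permutation FDR is calibrated against planted effects", {
  set.seed(12)
  n <- 300
  fc <- c(rep(3, 30), rep(0, n - 30))
  m <- cbind(matrix(rnorm(n * 3, 25, 0.25), n, 3),
             matrix(rnorm(n * 3, 25 + fc, 0.25), n, 3))
  lt <- make_log_tbl(asplit(m, 1))
  p <- two_sample_test(lt, default_design)$p_value
  q <- adjust_fdr(p, "permutation", imputed = lt, design = default_design)

  expect_true(all(q >= 0 & q <= 1))
  # strong planted effects rank ahead of nulls
  expect_lt(mean(q[1:30]), mean(q[-(1:30)]))
  # monotone in |t|
  t_abs <- abs(two_sample_test(lt, default_design)$t_stat)
  expect_true(all(diff(q[order(t_abs)]) <= 1e-12))
})

test_that("classification follows the five-category rules with overrides", {
  cases <- tibble::tribble(
    ~ratio, ~q,    ~flag,   ~expected,
     0.70,  0.01, "none",  "R45-enriched",
     0.70,  0.20, "none",  "putatively-invariant",
    -0.70,  0.01, "none",  "MG30-enriched",
    -0.70,  0.20, "none",  "putatively-invariant",
     0.30,  0.001, "none", "invariant",
     0.58,  0.001, "none", "invariant",   # boundary: closed interval wins
    -0.58,  0.001, "none", "invariant",
     2.50,  0.90, "MG30",  "MG30-specific",
    -2.50,  0.001, "R45",  "R45-specific"
  )
  got <- classify_abundance(cases$ratio, cases$q, cases$flag, default_design)
  expect_equal(as.character(got), cases$expected)
})

test_that("categories partition the quant set and agree with an independent recount", {
  sim <- simulate_lfq(sim_config(n_proteins = 500, seed = 3))
  pg <- apply_quality_filters(sim$protein_groups)
  lt <- log2_transform(pg, sim$design)
  quant <- filter_for_quantification(lt, sim$design)
  imp <- impute_lfq(lt, quant, sim$design, seed = 3)
  res <- run_differential(imp, quant, sim$design)

  expect_equal(sum(table(res$category)), nrow(quant))
  # enriched labels agree with the ratio sign
  expect_true(all(res$log2_ratio[res$category == "R45-enriched"] > 0))
  expect_true(all(res$log2_ratio[res$category == "MG30-enriched"] < 0))

  # independent recount of the differential total
  recount <- sum(res$stage_specific != "none") +
    sum(res$stage_specific == "none" & abs(res$log2_ratio) >= 0.58 &
          res$q_value < 0.05)
  expect_equal(length(differential_proteins(res)), recount)

  g <- glance(res)
  expect_equal(g$n_differential, recount)
  expect_equal(g$n_proteins, nrow(quant))
})

test_that("an overwhelming planted effect is called, pure noise rarely is", {
  set.seed(21)
  n <- 200
  m <- cbind(matrix(rnorm(n * 3, 25, 0.1), n, 3),
             matrix(rnorm(n * 3, 25, 0.1), n, 3))
  m[1, 4:6] <- m[1, 4:6] + 2          # true FC +2, sigma = 0.1
  lt <- make_log_tbl(asplit(m, 1))
  quant <- filter_for_quantification(lt, default_design)
  res <- run_differential(lt, quant, default_design)
  expect_equal(as.character(res$category[1]), "R45-enriched")
  expect_lte(sum(res$category[-1] != "invariant"), 2)
})
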
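test_that("sample statistics use observed values only, n-1 SD", {
  lt <- make_log_tbl(list(
    c(20, 20, 20, 20, 20, 20),
    c(22, 21, NA, 24, 26, 28),
    c(NA, 22, 21, 26, 24, 30)
  ))
  stats <- compute_sample_stats(lt, default_design)
  expect_equal(stats$mean[1], mean(c(20, 22)))         # column MG30_1
  expect_equal(stats$sd[2], sd(c(20, 21, 22)))
  expect_equal(stats$min[1], 20)
  expect_equal(stats$n_obs, c(2L, 3L, 2L, 3L, 3L, 3L))
})

test_that("a sample with fewer than 2 observed values is fatal, zero SD warns", {
  lt <- make_log_tbl(list(c(20, 21, NA, 22, 23, 24),
                          c(25, 26, NA, 27, 28, 29)))
  expect_error(compute_sample_stats(lt, default_design), "MG30_3",
               class = "lfq_stats_error")

  lt_const <- make_log_tbl(list(c(20, 21, 22, 23, 24, 25),
                                c(20, 26, 27, 28, 29, 30)))
  expect_warning(compute_sample_stats(lt_const, default_design), "zero SD")
})

test_that("branch A fills from Normal(mean - 1.8 SD, (0.3 SD)^2) per sample", {
  # many proteins so the per-sample stats are stable, one protein missing once
  set.seed(99)
  n <- 2000
  m <- matrix(rnorm(n * 6, 25, 2), n, 6)
  m[1, 4] <- NA
  lt <- make_log_tbl(asplit(m, 1))
  quant <- filter_for_quantification(lt, default_design)
  stats <- compute_sample_stats(lt, default_design)

  draws <- vapply(1:400, function(i) {
    filled <- impute_downshifted(lt, quant, default_design, seed = i)
    filled$R45_1[1]
  }, numeric(1))
  mu_expect <- stats$mean[4] - 1.8 * stats$sd[4]
  sd_expect <- 0.3 * stats$sd[4]
  expect_lt(abs(mean(draws) - mu_expect), 0.1)
  expect_lt(abs(sd(draws) - sd_expect), 0.1)

  # observed cells are bit-identical before/after
  filled <- impute_downshifted(lt, quant, default_design, seed = 1)
  expect_identical(as.matrix(filled[-1, default_design$sample_id]),
                   as.matrix(lt[-1, default_design$sample_id]))
})

test_that("imputation is deterministic under a fixed seed", {
  set.seed(5)
  m <- matrix(rnorm(100 * 6, 25, 2), 100, 6)
  m[cbind(sample(100, 20), sample(6, 20, TRUE))] <- NA
  lt <- make_log_tbl(asplit(m, 1))
  quant <- filter_for_quantification(lt, default_design)

  a <- impute_lfq(lt, quant, default_design, seed = 123)
  b <- impute_lfq(lt, quant, default_design, seed = 123)
  c <- impute_lfq(lt, quant, default_design, seed = 124)
  expect_identical(a, b)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))

  # row order does not change the filled values (lexicographic fill order)
  perm <- sample(nrow(lt))
  d <- impute_lfq(lt[perm, ], quant, default_design, seed = 123)
  d <- d[match(a$protein_id, d$protein_id), ]
  expect_equal(as.data.frame(d), as.data.frame(a), ignore_attr = TRUE)
})

test_that("branch B fills condition-absent proteins with the average minimum", {
  lt <- make_log_tbl(list(
    c(18, 18.5, 19, 20, 20.5, 21),
    c(25, 26, 24, NA, NA, NA),     # (3,0): stage-specific MG30
    c(NA, NA, NA, 23, 22, 24),     # (0,3): stage-specific R45
    c(30, 31, 32, 33, 34, 35)
  ))
  quant <- filter_for_quantification(lt, default_design)
  filled <- impute_condition_absent(lt, quant, default_design)

  fill_value <- mean(c(18, 18.5, 19, 20, 20.5, 21))  # 19.5
  expect_equal(fill_value, 19.5)
  expect_equal(unname(unlist(filled[2, c("R45_1", "R45_2", "R45_3")])),
               rep(19.5, 3))
  expect_equal(unname(unlist(filled[3, c("MG30_1", "MG30_2", "MG30_3")])),
               rep(19.5, 3))
  expect_false(anyNA(filled[, default_design$sample_id]))

  # per-condition variant averages only the absent condition's minima
  per_cond <- impute_condition_absent(lt, quant, default_design,
                                      min_fill = "per_condition")
  expect_equal(unname(unlist(per_cond[2, c("R45_1", "R45_2", "R45_3")])),
               rep(mean(c(20, 20.5, 21)), 3))
})

test_that("branch routing partitions the quant set and fills everything", {
  lt <- make_log_tbl(list(
    c(20, 21, 22, 23, 24, 25),            # complete
    c(21, 22.5, 23, NA, 25, 26) ,         # 1 missing -> downshift
    c(22, NA, 24, NA, 26.5, 27),          # 2 missing -> downshift
    c(23, 24, 25.5, NA, NA, NA),          # (3,0) -> minfill
    c(NA, NA, NA, 26, 27.5, 28)           # (0,3) -> minfill
  ))
  quant <- filter_for_quantification(lt, default_design)
  imputed <- impute_lfq(lt, quant, default_design, seed = 2)
  routing <- imputation_routing(imputed)

  expect_equal(routing$branch,
               c("complete", "downshift", "downshift", "minfill", "minfill"))
  expect_false(anyNA(imputed[, default_design$sample_id]))
  # complete rows untouched
  expect_identical(unlist(imputed[1, default_design$sample_id]),
                   unlist(lt[1, default_design$sample_id]))
})
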
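test_that("CMC handles identical, constant and noisy waveform pairs", {
  tau <- seq(0, 1, length.out = 101)
  y <- 50 * minimum_jerk(tau)
  expect_equal(as.numeric(cmc(cbind(y, y))), 1)
  # two constants at 0 and 1: radicand 1 - (2T-1)/(T-1) < 0 -> clamped, flagged
  cst <- cmc(cbind(rep(0, 101), rep(1, 101)))
  expect_equal(as.numeric(cst), 0)
  expect_true(attr(cst, "degenerate"))
  rad <- cmc_brute(cbind(rep(0, 101), rep(1, 101)))
  expect_lt(rad, 0)   # negative radicand: waveforms less similar than pooled
  # identical constant pair: 0/0 -> flagged NaN
  nanc <- cmc(cbind(rep(2, 50), rep(2, 50)))
  expect_true(is.nan(as.numeric(nanc)))
  expect_true(attr(nanc, "degenerate"))
  # agreement with the independent brute-force implementation
  set.seed(13)
  for (k in 1:25) {
    G <- sample(2:5, 1)
    Y <- sapply(seq_len(G), function(g) y + stats::rnorm(101, 0, 0.05 * 50))
    expect_equal(as.numeric(cmc(Y)), sqrt(max(0, cmc_brute(Y))),
                 tolerance = 1e-10)
  }
  expect_error(cmc(list(1:5, 1:4)), "equal length")
})

test_that("CMC decreases with independent noise amplitude in expectation", {
  set.seed(99)
  tau <- seq(0, 1, length.out = 101)
  y <- 50 * minimum_jerk(tau)
  mean_cmc <- sapply(c(0.02, 0.1, 0.3), function(s) {
    mean(replicate(40, as.numeric(cmc(cbind(y, y + stats::rnorm(101, 0, s * 50))))))
  })
  expect_true(all(diff(mean_cmc) < 0))
})

test_that("RMSE matches hand values and satisfies the triangle inequality", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(rmse(rep(2.5, 10) + 7, rep(2.5, 10)), 7)
  expect_error(rmse(1:4, 1:5), "mismatch")
  set.seed(4)
  for (k in 1:50) {
    a <- stats::rnorm(30); b <- stats::rnorm(30); cc <- stats::rnorm(30)
    expect_lte(rmse(a, cc), rmse(a, b) + rmse(b, cc) + 1e-12)
  }
})

test_that("ROM and PTA read the normalized movement correctly", {
  mono <- make_norm_waveform(function(tau, j) 90 * minimum_jerk(tau))
  expect_equal(rom(mono, "FE"), 90)
  expect_equal(pta(mono, "FE"), 90)
  # overshoot: rises to 120 then settles at 100
  tau <- seq(0, 1, length.out = 101)
  over <- angle_waveform(matrix(100 * minimum_jerk(tau) + 20 * sin(pi * tau),
                                101, 4), normalized = TRUE)
  expect_equal(pta(over, "EFE"), 100, tolerance = 1e-9)
  expect_gt(rom(over, "EFE"), 100)
  expect_equal(rom(over, "EFE"), max(over$values[, 4]) - min(over$values[, 4]))
  const <- angle_waveform(matrix(12, 101, 4), normalized = TRUE)
  expect_equal(rom(const, "IE"), 0)
  expect_equal(pta(const, "IE"), 12)
  expect_error(rom(angle_waveform(matrix(1:8, 2, 4)), "FE"), "normalized")
})

test_that("Bland-Altman limits of agreement are mean +/- 1.96 sd", {
  ba0 <- bland_altman(1:10, 1:10)
  expect_equal(c(ba0$mean_diff, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))
  ba <- bland_altman(c(1, 2, 3), c(0, 0, 0))
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$loa_lower, 2 - 1.96, tolerance = 1e-12)
  expect_equal(ba$loa_upper, 2 + 1.96, tolerance = 1e-12)
  # Monte-Carlo: differences N(5, 2^2) -> LoA near (1.08, 8.92)
  set.seed(123)
  d <- stats::rnorm(1e4, 5, 2)
  bam <- bland_altman(d, rep(0, 1e4))
  expect_lt(abs(bam$loa_lower - 1.08), 0.1)
  expect_lt(abs(bam$loa_upper - 8.92), 0.1)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("paired comparisons gate on Shapiro-Wilk normality", {
  expect_identical(paired_comparison(1:10 + 0, 1:10 + 0)$test, "degenerate")
  set.seed(10)
  x <- stats::rnorm(13, 1, 1)
  res <- paired_comparison(x, rep(0, 13))
  expect_identical(res$test, "paired-t")
  ref <- stats::t.test(x, rep(0, 13), paired = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  # heavy-tailed differences fail normality -> Wilcoxon
  set.seed(42)
  h <- exp(stats::rnorm(20, 0, 2)); h <- h - stats::median(h)
  resw <- paired_comparison(h, rep(0, 20))
  expect_identical(resw$test, "wilcoxon")
  expect_lt(resw$shapiro_p, 0.05)
})

test_that("report assembly equals independent recomputation of its statistics", {
  set.seed(55)
  tau <- seq(0, 1, length.out = 101)
  mk_fold <- function(sid) {
    tg <- lapply(1:2, function(i)
      angle_waveform(matrix(80 * minimum_jerk(tau) + stats::rnorm(1, 0, 5),
                            101, 4), normalized = TRUE,
                     task = "t1_contralateral_shoulder"))
    inp <- lapply(tg, function(w)
      angle_waveform(w$values + 10 + matrix(stats::rnorm(404, 0, 2), 101, 4),
                     normalized = TRUE, task = w$task))
    ref <- lapply(tg, function(w)
      angle_waveform(w$values + matrix(stats::rnorm(404, 0, 1), 101, 4),
                     normalized = TRUE, task = w$task))
    structure(list(subject_id = sid, model = NULL, input = inp, target = tg,
                   refined = ref,
                   rmse_before = matrix(0, 2, 4), rmse_after = matrix(0, 2, 4)),
              class = "loocv_fold")
  }
  folds <- lapply(sprintf("S%02d", 1:5), mk_fold)
  rep <- build_report(folds)
  expect_equal(nrow(rep$table), 4)
  row <- rep$table[rep$table$channel == "FE", ]
  # recompute the refined RMSE aggregation independently
  per_subject <- sapply(folds, function(f) {
    mean(sapply(1:2, function(i)
      sqrt(mean((f$refined[[i]]$values[, "FE"] - f$target[[i]]$values[, "FE"])^2))))
  })
  expect_equal(row$rmse_refined, mean(per_subject), tolerance = 1e-10)
  # Bland-Altman bounds bracket the mean difference
  expect_true(row$pta_loa_lower <= row$pta_diff_refined &
                row$pta_diff_refined <= row$pta_loa_upper)
  # single fold, single trial: report equals that trial's statistics
  f1 <- mk_fold("S99"); f1$input <- f1$input[1]; f1$target <- f1$target[1]
  f1$refined <- f1$refined[1]
  rep1 <- build_report(list(f1))
  r1 <- rep1$table[rep1$table$channel == "FE", ]
  expect_equal(r1$rmse_refined,
               rmse(f1$refined[[1]]$values[, "FE"], f1$target[[1]]$values[, "FE"]),
               tolerance = 1e-12)
  expect_error(build_report(list()), "empty")
})
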
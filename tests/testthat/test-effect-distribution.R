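test_that("error model is the sample mean and n-1 standard deviation", {
  em <- fit_error_model(rep(166, 6))
  expect_equal(em$mean, 166)
  expect_equal(em$sd, 0)

  # two-point closed form: sd = |delta| / sqrt(2)
  em2 <- fit_error_model(c(160, 172))
  expect_equal(em2$mean, 166)
  expect_equal(em2$sd, 12 / sqrt(2))

  expect_error(fit_error_model(166), class = "epizyme_insufficient_data")
})

test_that("error model recovers Gaussian parameters from many draws", {
  x <- withr::with_seed(123, rnorm(10000, 166, 8))
  em <- fit_error_model(x)
  expect_lt(abs(em$mean - 166), 0.25)
  expect_lt(abs(em$sd - 8), 0.2)
})

test_that("reflection estimator doubles the above-mean count", {
  pan <- panel_from_means(c(rep(170, 52), rep(100, 111), rep(0, 5)))
  est <- estimate_neutral_count(pan, boot = 0)
  expect_identical(est$n_above, 52L)
  expect_identical(est$neutral_estimate, 104L)

  none_above <- panel_from_means(rep(100, 20))
  expect_identical(estimate_neutral_count(none_above, boot = 0)$neutral_estimate,
                   0L)

  # ties with the wild-type mean are "not above"
  tied <- panel_from_means(c(166, 166, 170))
  expect_identical(estimate_neutral_count(tied, boot = 0)$n_above, 1L)

  # integer determinism on arbitrary panels
  withr::with_seed(21, {
    for (i in 1:10) {
      means <- runif(40, 0, 340)
      pan_i <- panel_from_means(means)
      expect_identical(estimate_neutral_count(pan_i, boot = 0)$neutral_estimate,
                       2L * sum(means > 166))
    }
  })
})

test_that("reflection estimator is unbiased on simulated ground truth", {
  # 100 true-neutral + 60 strongly deleterious mutants
  ests <- vapply(1:60, function(s) {
    pan <- generate_panel(panel_spec(
      n_mutants = 160, neutral_fraction = 100 / 160, inactive_count = 5,
      deleterious_shape = c(2, 8), seed = s))
    estimate_neutral_count(pan, boot = 0)$neutral_estimate
  }, integer(1))
  sem <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 100), 3 * sem)
})

test_that("welch test statistics match the reference implementation", {
  # identity
  w0 <- welch_test(c(160, 172), c(160, 172))
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)

  withr::with_seed(31, {
    for (i in 1:15) {
      x <- rnorm(sample(2:10, 1), 166, 8)
      y <- rnorm(sample(2:30, 1), sample(c(120, 166), 1), 12)
      w <- welch_test(x, y)
      ref <- t.test(x, y)
      expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
    }
  })

  # equal n and equal variance: Welch reduces to the pooled Student t
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  w <- welch_test(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-12)
})

test_that("welch degenerate conventions: zero variance on both sides", {
  same <- welch_test(c(5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  diff <- welch_test(c(5, 5), c(7, 7))
  expect_equal(diff$p_value, 0)
  expect_true(diff$degenerate)
})

test_that("BH matches the brute-force step-up definition exhaustively", {
  expect_equal(benjamini_hochberg(rep(1, 8), 0.05), rep(FALSE, 8))
  expect_true(benjamini_hochberg(0.04, 0.05))
  expect_false(benjamini_hochberg(0.06, 0.05))

  p4 <- c(0.001, 0.01, 0.02, 0.9)
  expect_equal(benjamini_hochberg(p4, 0.05), brute_force_bh(p4, 0.05))

  withr::with_seed(41, {
    for (m in 1:12) {
      for (rep in 1:40) {
        p <- round(runif(m), 3)
        q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
        expect_equal(benjamini_hochberg(p, q), brute_force_bh(p, q),
                     info = sprintf("m=%d q=%.2f", m, q))
      }
    }
  })
})

test_that("BH controls FDR with valid null p-values", {
  # mixed panels with enough replication for calibrated Welch p-values
  fdp <- vapply(1:300, function(s) {
    pan <- generate_panel(panel_spec(
      n_mutants = 80, neutral_fraction = 0.75, inactive_count = 2,
      deleterious_shape = c(2, 8), n_replicates_mutant = 10, seed = s))
    cls <- classify_panel(pan)
    truth <- panel_truth(pan)
    rej <- cls$q_threshold_pass
    if (sum(rej) == 0) return(0)
    sum(rej & truth[cls$mutant_id] == 1) / sum(rej)
  }, numeric(1))
  expect_lt(mean(fdp), 0.05 + 0.01)
})

test_that("classification calls decreased / unchanged / increased correctly", {
  # every mutant duplicates the wild-type replicates -> all unchanged
  wt <- c(160, 166, 172, 170, 164)
  dat <- tibble::tibble(
    mutant_id = rep(sprintf("M%02d", 1:6), each = 5),
    replicate = rep(1:5, times = 6),
    performance = rep(wt, times = 6)
  )
  pan <- mutant_panel(dat, wt_replicates = wt)
  cls <- classify_panel(pan)
  expect_true(all(cls$category == "unchanged"))
  expect_true(all(!cls$q_threshold_pass))

  # strongly decreased mutants are detected with high power
  pan2 <- generate_panel(panel_spec(
    n_mutants = 160, neutral_fraction = 120 / 160, inactive_count = 0,
    deleterious_shape = c(200, 800), # tight around relative 0.2
    error_cv = 0.02, n_replicates_mutant = 4, seed = 77))
  cls2 <- classify_panel(pan2)
  truth2 <- panel_truth(pan2)
  low <- names(truth2)[truth2 < 0.5]
  expect_gte(sum(cls2$category[match(low, cls2$mutant_id)] == "decreased"),
             39 * length(low) / 40)

  # fully inactive mutant: decreased with relative performance 0
  pan3 <- panel_from_means(c(0, 166), wt_replicates = c(160, 166, 172))
  cls3 <- classify_panel(pan3)
  expect_equal(cls3$category[cls3$mean_perf == 0], "decreased")
  expect_equal(cls3$relative_perf[cls3$mean_perf == 0], 0)
})

test_that("large_increase flags relative performance above 1.15", {
  pan <- panel_from_means(c(166 * 1.2, 166 * 1.1, 100),
                          wt_replicates = c(160, 166, 172))
  cls <- classify_panel(pan)
  expect_equal(cls$large_increase, c(TRUE, FALSE, FALSE))
})

test_that("half-Gaussian sd of the upper tail estimates the error sd", {
  # all-neutral panel: upper-tail deviations are pure measurement error
  pan <- generate_panel(panel_spec(
    n_mutants = 400, neutral_fraction = 1, inactive_count = 0,
    n_replicates_mutant = 2, seed = 13))
  em <- fit_error_model(pan)
  est <- estimate_neutral_count(pan, em, boot = 50)
  # mutant means carry error sd/sqrt(2); expected ratio ~ 1/sqrt(2)
  expect_lt(abs(est$sd_ratio - 1 / sqrt(2)), 0.15)
  expect_lt(est$sd_ratio_lo, est$sd_ratio)
  expect_gt(est$sd_ratio_hi, est$sd_ratio)
})
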
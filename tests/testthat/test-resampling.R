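test_that("percentage_p reproduces the worked fractions", {
  expect_identical(percentage_p(c(rep(1, 991), rep(-1, 9))), 0.009)
  expect_identical(percentage_p(c(rep(1, 958), rep(-1, 42))), 0.042)
  expect_identical(percentage_p(c(rep(1, 500), rep(-1, 500))), 0.5)
  # exact zeros count against the hypothesized direction
  expect_identical(percentage_p(c(1, 0, -1)), 2 / 3)
  # complementary counting between directions (no zeros)
  withr::with_seed(20, {
    d <- rnorm(1000)
    expect_equal(percentage_p(d, "greater") +
                   percentage_p(-d, "less"), 2 * mean(d <= 0))
    expect_equal((1 - percentage_p(d, "greater")) +
                   (1 - percentage_p(d, "less")), 1)
  })
  expect_error(percentage_p(numeric(0)), "nonempty")
})

test_that("bootstrap_dmp_by_accuracy separates and reproduces", {
  tbl <- tibble::tibble(dmp = c(rep(0, 30), rep(pi, 10)),
                        correct = rep(c(TRUE, FALSE), c(30, 10)))
  b <- bootstrap_dmp_by_accuracy(tbl, n_boot = 500, seed = 1)
  expect_true(all(b$diffs == pi))
  expect_identical(b$p_percent, 0)   # below the 1/n_boot resolution
  expect_lt(b$p_sign, 1e-100)
  b2 <- bootstrap_dmp_by_accuracy(tbl, n_boot = 500, seed = 1)
  expect_identical(b$diffs, b2$diffs)
  expect_error(bootstrap_dmp_by_accuracy(
    tibble::tibble(dmp = 1:3, correct = c(TRUE, TRUE, NA)), seed = 1),
    "incorrect")
})

test_that("bootstrap_dmp_by_accuracy is calibrated under the null", {
  withr::with_seed(21, {
    rej <- vapply(1:500, function(i) {
      tbl <- tibble::tibble(dmp = runif(60, 0, pi),
                            correct = sample(rep(c(TRUE, FALSE), 30)))
      bootstrap_dmp_by_accuracy(tbl, n_boot = 200,
                                seed = i)$p_percent < 0.05
    }, logical(1))
    expect_lt(abs(mean(rej) - 0.05), 0.02)
  })
})

test_that("accuracy-by-DMP bootstrap behaves at the extremes and the null", {
  # deterministic rule: correct iff DMP below the median
  tbl <- tibble::tibble(dmp = seq(0, pi, length.out = 100),
                        correct = seq(0, pi, length.out = 100) <
                          median(seq(0, pi, length.out = 100)))
  b <- bootstrap_accuracy_by_dmp(tbl, quantile = 0.2, n_boot = 200,
                                 seed = 2)
  expect_true(all(b$diffs == 1))
  # accuracy independent of DMP: mean difference near zero
  withr::with_seed(22, {
    m <- vapply(1:300, function(i) {
      tbl0 <- tibble::tibble(dmp = runif(100, 0, pi),
                             correct = runif(100) < 0.8)
      mean(bootstrap_accuracy_by_dmp(tbl0, n_boot = 60, seed = i)$diffs)
    }, numeric(1))
    expect_lt(abs(mean(m)), 0.02)
  })
  expect_error(bootstrap_accuracy_by_dmp(
    tibble::tibble(dmp = runif(10), correct = rep(TRUE, 10)),
    quantile = 0.1, n_boot = 10, seed = 1), "fewer than 2")
})

test_that("phase-coupled accuracy is detected by both bootstraps", {
  hits <- vapply(1:20, function(s) {
    ds <- generate_dataset(quick_cfg(seed = 800 + s, n_anticipatory = 150,
                                     reset_kappa = 4,
                                     sampling_rate_hz = 100,
                                     accuracy_slope = 2))
    tr <- ds$truth$breaths[ds$truth$breaths$is_trial, ]
    tbl <- tibble::tibble(dmp = tr$dmp_true, correct = tr$correct)
    c(bootstrap_dmp_by_accuracy(tbl, n_boot = 500, seed = s)$p_percent,
      bootstrap_accuracy_by_dmp(tbl, n_boot = 500, seed = s)$p_percent)
  }, numeric(2))
  expect_gte(mean(hits[1, ] < 0.05), 0.8)
  expect_gte(mean(hits[2, ] < 0.05), 0.8)
})

test_that("surrogate_event_zmap calibrates on noise and detects bursts", {
  fs <- 100
  n <- 120 * fs
  withr::with_seed(23, {
    pow <- matrix(abs(rnorm(3 * n, 1, 0.2))^2, 3, n)
    on <- seq(10, 110, by = 5)
    z0 <- surrogate_event_zmap(pow, fs, on, window = c(-1, 3),
                               n_perm = 200, seed = 1)
    expect_lt(abs(mean(abs(z0$z) > 1.96) - 0.05), 0.02)
    # burst of power injected 0-1 s after every event in row 2
    pow2 <- pow
    for (o in on) {
      idx <- (round(o * fs) + 1):(round(o * fs) + fs)
      pow2[2, idx] <- pow2[2, idx] + 5
    }
    z1 <- surrogate_event_zmap(pow2, fs, on, window = c(-1, 3),
                               n_perm = 200, seed = 1)
    burst_cols <- z1$time_s >= 0.1 & z1$time_s <= 0.9
    expect_true(all(z1$z[2, burst_cols] > 3))
    expect_error(surrogate_event_zmap(pow, fs, on, n_perm = 0, seed = 1),
                 "n_perm")
  })
})

test_that("label_shuffle_zmap nulls, detects offsets, and checks grids", {
  withr::with_seed(24, {
    d <- c(60, 4, 30)
    a <- array(rexp(prod(d)) + 0.5, d)
    b <- array(rexp(prod(d)) + 0.5, d)
    z0 <- label_shuffle_zmap(a, b, n_perm = 300, seed = 3)
    expect_lte(mean(z0$fdr_mask), 0.05)
    # +3 dB offset: power doubled in one condition
    z1 <- label_shuffle_zmap(a * 2, b, n_perm = 300, seed = 3)
    expect_true(all(z1$fdr_mask))
    expect_gt(min(abs(z1$z)), 2)
    # identical trial-for-trial: observed difference exactly zero
    z2 <- label_shuffle_zmap(a, a, n_perm = 100, seed = 4)
    expect_true(all(z2$observed == 0))
    expect_true(all(abs(z2$z) < 3))
    expect_error(label_shuffle_zmap(a, b[, 1:2, ], n_perm = 10, seed = 1),
                 "grids")
    expect_error(label_shuffle_zmap(a[1, , , drop = FALSE], b,
                                    n_perm = 10, seed = 1), "at least 2")
  })
})

test_that("BH-FDR on null z-maps controls the false discovery rate", {
  withr::with_seed(25, {
    fdrs <- vapply(1:2000, function(i) {
      z <- matrix(rnorm(20 * 50), 20, 50)
      p <- 2 * pnorm(-abs(z))
      rej <- p.adjust(p, method = "BH") <= 0.05
      sum(rej) / max(1, sum(rej))   # all rejections are false here
    }, numeric(1))
    expect_lte(mean(fdrs), 0.05 + 0.02)
  })
})

test_that("correlate_pairs returns both coefficients with sane behavior", {
  x <- c(1, 2, 3, 4, 5)
  r <- correlate_pairs(x, 2 * x + 1)
  expect_equal(r$spearman_r, 1)
  expect_equal(r$pearson_r, 1)
  # monotone nonlinear transform: rank correlation stays 1
  r2 <- correlate_pairs(x, exp(x))
  expect_equal(r2$spearman_r, 1)
  expect_lt(r2$pearson_r, 1)
  # hand-computed rank correlation: d = (-1, 1, -1, 1),
  # rho = 1 - 6 * 4 / (4 * 15) = 0.6
  r3 <- correlate_pairs(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r3$spearman_r, 0.6, tolerance = 1e-9)
  expect_error(correlate_pairs(1:3, 1:3), "at least 4")
  expect_error(correlate_pairs(rep(1, 5), 1:5), "constant")
})

test_that("paired_tests matches hand computation and is antisymmetric", {
  b <- c(1, 1, 1)
  a <- b + c(1, 2, 3)
  r <- paired_tests(a, b)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)  # 3.4641
  expect_equal(r$df, 2)
  r2 <- paired_tests(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(paired_tests(c(1, 2, 3), c(1, 2, 3)), "Zero-variance")
})

test_that("rm_anova_2x2 matches a hand sums-of-squares oracle", {
  # all cells equal: no effects
  flat <- tidyr::expand_grid(subject = 1:4, factor_a = c("x", "y"),
                             factor_b = c("u", "v")) |>
    dplyr::mutate(value = 5)
  r0 <- rm_anova_2x2(flat)
  expect_equal(r0$F, c(0, 0, 0))
  # pure main effect of A, no interaction; subject offsets and noise
  df <- tidyr::expand_grid(subject = 1:4, factor_a = c("x", "y"),
                           factor_b = c("u", "v")) |>
    dplyr::mutate(value = ifelse(.data$factor_a == "y", 2, 0) +
                    c(0.1, 0.2, 0.3, 0.4)[.data$subject] +
                    withr::with_seed(30, rnorm(16, sd = 0.05)))
  r <- rm_anova_2x2(df)
  # independent oracle: for a 2-level within-subject factor, F equals the
  # squared paired t on the per-subject contrast, F = n * mean(d)^2 / var(d)
  wide <- tidyr::pivot_wider(df, names_from = c("factor_a", "factor_b"),
                             values_from = "value")
  dA <- rowMeans(wide[, c("y_u", "y_v")]) -
    rowMeans(wide[, c("x_u", "x_v")])
  expect_equal(r$F[r$term == "factor_a"],
               4 * mean(dA)^2 / var(dA), tolerance = 1e-8)
  dI <- (wide$y_v - wide$y_u) - (wide$x_v - wide$x_u)
  expect_equal(r$F[r$term == "factor_a:factor_b"],
               4 * mean(dI)^2 / var(dI), tolerance = 1e-8)
  expect_gt(r$F[r$term == "factor_a"], 100)
  expect_lt(r$p[r$term == "factor_a"], 0.01)
  expect_gt(r$p[r$term == "factor_a:factor_b"], 0.05)
  # permuting subject order leaves all F unchanged
  perm <- df |> dplyr::mutate(subject = c(3, 1, 4, 2)[.data$subject])
  expect_equal(rm_anova_2x2(perm)$F, r$F, tolerance = 1e-10)
  expect_error(rm_anova_2x2(df[-1, ]), "incomplete")
})

test_that("median_split_compare pairs small- vs large-DMP inhale peaks", {
  # peaks deterministically doubled for well-aligned trials
  tbl <- tidyr::expand_grid(subject = 1:5, trial = 1:20) |>
    dplyr::mutate(dmp = withr::with_seed(28, runif(dplyr::n(), 0, pi))) |>
    dplyr::mutate(inhale_peak = ifelse(.data$dmp < median(.data$dmp),
                                       2, 1))
  r <- median_split_compare(tbl)
  expect_gt(r$test$t, 3)
  expect_lt(r$test$p, 0.05)
  # subjects with < 4 trials are skipped with a warning
  tbl2 <- dplyr::bind_rows(tbl,
                           tibble::tibble(subject = 9, trial = 1:3,
                                          dmp = c(0.1, 0.2, 0.3),
                                          inhale_peak = 1))
  expect_warning(r2 <- median_split_compare(tbl2), "skipped")
  expect_false(9 %in% r2$per_subject$subject)
  # odd trial counts: the median trial is excluded
  scale3 <- c(1, 1.1, 0.9)
  odd <- tibble::tibble(subject = rep(1:3, each = 5),
                        dmp = rep(1:5, 3),
                        inhale_peak = rep(1:5, 3) *
                          rep(scale3, each = 5))
  r3 <- suppressWarnings(median_split_compare(odd))
  expect_equal(r3$per_subject$peak_small_dmp, 1.5 * scale3)
  expect_equal(r3$per_subject$peak_large_dmp, 4.5 * scale3)
})

test_that("independent inhale peaks yield a null median-split result", {
  ps <- vapply(1:20, function(s) {
    tbl <- withr::with_seed(900 + s, tibble::tibble(
      subject = rep(1:13, each = 20),
      dmp = runif(260, 0, pi),
      inhale_peak = rlnorm(260, 0, 0.2)))
    median_split_compare(tbl)$test$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("resampling results are seed-deterministic", {
  tbl <- withr::with_seed(26, tibble::tibble(dmp = runif(50, 0, pi),
                                             correct = runif(50) < 0.8))
  b1 <- bootstrap_accuracy_by_dmp(tbl, n_boot = 100, seed = 9)
  b2 <- bootstrap_accuracy_by_dmp(tbl, n_boot = 100, seed = 9)
  expect_identical(b1$diffs, b2$diffs)
  d <- c(20, 2, 10)
  a <- withr::with_seed(27, array(rexp(prod(d)) + 0.5, d))
  z1 <- label_shuffle_zmap(a, a * 1.5, n_perm = 50, seed = 11)
  z2 <- label_shuffle_zmap(a, a * 1.5, n_perm = 50, seed = 11)
  expect_identical(z1$z, z2$z)
})
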
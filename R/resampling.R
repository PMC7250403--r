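#' Percentage-based one-sided bootstrap p-value
#'
#' The fraction of bootstrap repetitions that *fail* the hypothesized
#' direction. For `direction = "greater"`, repetitions with difference
#' values less than or equal to zero count against the hypothesis (exact
#' zeros always count against). The resolution is `1/length(diffs)`; a
#' value of 0 should be read as "< 1/n".
#'
#' @param diffs Nonempty numeric vector of bootstrap difference values.
#' @param direction `"greater"` (default) or `"less"`.
#' @return The p-value (a fraction in \[0, 1\]).
#' @examples
#' percentage_p(c(rep(1, 991), rep(-1, 9)))   # 0.009
#' @export
percentage_p <- function(diffs, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!length(diffs)) abort("`diffs` must be nonempty.")
  ok <- if (direction == "greater") diffs > 0 else diffs < 0
  mean(!ok)
}

new_bootstrap_result <- function(diffs, n_boot, seed, statistic) {
  z <- mean(diffs) / stats::sd(diffs)
  nz <- sum(diffs != 0)
  p_sign <- if (nz == 0) 1 else
    stats::binom.test(sum(diffs > 0), nz)$p.value
  structure(list(diffs = diffs,
                 p_percent = percentage_p(diffs),
                 p_normal = stats::pnorm(z, lower.tail = FALSE),
                 p_sign = p_sign,
                 n_boot = n_boot, seed = seed, statistic = statistic),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  fmt_p <- function(p) {
    if (p == 0) sprintf("< %.2g", 1 / x$n_boot) else sprintf("%.4g", p)
  }
  cat(sprintf("<bootstrap_result> %s (%d repetitions, seed %d)\n",
              x$statistic, x$n_boot, x$seed))
  cat(sprintf("  mean difference %.4g; p(percentage) = %s, p(normal) = %s, p(sign) = %s\n",
              mean(x$diffs), fmt_p(x$p_percent), fmt_p(x$p_normal),
              fmt_p(x$p_sign)))
  invisible(x)
}

#' Bootstrap DMP difference between correct and incorrect trials
#'
#' Groups trials by perceptual accuracy, then on each repetition resamples
#' each group with replacement (resample size = group size) and records the
#' difference `mean(DMP incorrect) - mean(DMP correct)`, so positive values
#' support the hypothesis that correct trials are better phase-aligned.
#'
#' @param dmp_table A tibble with columns `dmp` and logical `correct`
#'   (trials with `NA` accuracy are dropped).
#' @param n_boot Number of repetitions.
#' @param seed Integer seed.
#' @return A `bootstrap_result` with the difference distribution and its
#'   percentage-based, normal-approximation and sign-test p-values.
#' @export
bootstrap_dmp_by_accuracy <- function(dmp_table, n_boot = 1000, seed) {
  stopifnot(is.data.frame(dmp_table),
            all(c("dmp", "correct") %in% names(dmp_table)))
  check_scalar(n_boot, "n_boot", lower = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  tbl <- dmp_table[!is.na(dmp_table$correct), ]
  d_cor <- tbl$dmp[tbl$correct]
  d_inc <- tbl$dmp[!tbl$correct]
  if (!length(d_cor)) abort("No correct trials with DMP values.")
  if (!length(d_inc)) abort("No incorrect trials with DMP values.")
  diffs <- withr::with_seed(as.integer(seed), {
    m_cor <- colMeans(matrix(
      d_cor[sample.int(length(d_cor), length(d_cor) * n_boot, replace = TRUE)],
      length(d_cor), n_boot))
    m_inc <- colMeans(matrix(
      d_inc[sample.int(length(d_inc), length(d_inc) * n_boot, replace = TRUE)],
      length(d_inc), n_boot))
    m_inc - m_cor
  })
  new_bootstrap_result(diffs, n_boot, as.integer(seed),
                       "DMP(incorrect) - DMP(correct)")
}

#' Bootstrap accuracy difference between well- and poorly-aligned trials
#'
#' On each repetition, resamples trials with replacement, sorts them by
#' DMP, takes the smallest `quantile` fraction as the well-aligned group
#' and the largest as the poorly-aligned group, and records the accuracy
#' difference `acc(well-aligned) - acc(poorly-aligned)`.
#'
#' @param dmp_table A tibble with columns `dmp` and logical `correct`;
#'   at least 10 labeled trials.
#' @param quantile Fraction per extreme group (default 0.20).
#' @param n_boot Number of repetitions.
#' @param seed Integer seed.
#' @return A `bootstrap_result`.
#' @export
bootstrap_accuracy_by_dmp <- function(dmp_table, quantile = 0.20,
                                      n_boot = 1000, seed) {
  stopifnot(is.data.frame(dmp_table),
            all(c("dmp", "correct") %in% names(dmp_table)))
  check_scalar(quantile, "quantile", lower = 1e-9, upper = 0.5)
  check_scalar(n_boot, "n_boot", lower = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  tbl <- dmp_table[!is.na(dmp_table$correct), ]
  n <- nrow(tbl)
  if (n < 10) abort("Need at least 10 trials with accuracy labels.")
  k <- floor(quantile * n)
  if (k < 2) abort("Quantile groups would hold fewer than 2 trials.")
  dmp <- tbl$dmp
  correct <- as.numeric(tbl$correct)
  diffs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      ord <- idx[order(dmp[idx])]
      mean(correct[ord[seq_len(k)]]) -
        mean(correct[ord[seq(n - k + 1L, n)]])
    }, numeric(1))
  })
  new_bootstrap_result(diffs, n_boot, as.integer(seed),
                       "accuracy(well-aligned) - accuracy(poorly aligned)")
}

new_surrogate_zmap <- function(observed, z, freq, time_s, n_perm, fdr_q) {
  p <- 2 * stats::pnorm(-abs(z))
  padj <- matrix(stats::p.adjust(p, method = "BH"), nrow(z), ncol(z))
  structure(list(observed = observed, z = z, p = p,
                 fdr_mask = padj <= fdr_q,
                 freq = freq, time_s = time_s,
                 n_perm = n_perm, fdr_q = fdr_q),
            class = "surrogate_zmap")
}

#' @export
print.surrogate_zmap <- function(x, ...) {
  cat(sprintf(
    "<surrogate_zmap> %d x %d bins, %d permutations; |z| max %.2f; %d bin(s) significant at FDR q = %g\n",
    nrow(x$z), ncol(x$z), x$n_perm, max(abs(x$z)), sum(x$fdr_mask), x$fdr_q))
  invisible(x)
}

#' Surrogate-event permutation z-map of event-locked power
#'
#' Tests whether event-locked power deviates from what arbitrary event
#' placement would produce. The observed statistic is the trial-averaged
#' dB power map around the true events. Each permutation shifts every
#' event independently by a uniform random amount (circular over the
#' recording, minimum shift one epoch length) and recomputes the map; the
#' z-map standardizes the observed map by the surrogate mean and SD, with
#' two-sided normal p-values and BH-FDR correction.
#'
#' @param power Matrix of instantaneous power (frequency x sample) for the
#'   full recording, e.g. squared smoothed amplitude from the filter bank.
#' @param fs Sampling rate (Hz).
#' @param onsets_s Event onset times (s).
#' @param window Epoch window (s relative to onset).
#' @param freq Frequency axis labels for the rows of `power`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param fdr_q FDR level.
#' @return A `surrogate_zmap`.
#' @export
surrogate_event_zmap <- function(power, fs, onsets_s, window = c(-1, 3),
                                 freq = NULL, n_perm = 1000, seed,
                                 fdr_q = 0.05) {
  stopifnot(is.matrix(power))
  check_scalar(n_perm, "n_perm", lower = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  n <- ncol(power)
  offs <- round(window[1] * fs):(round(window[2] * fs) - 1L)
  epoch_len <- length(offs)
  if (n <= 3L * epoch_len) {
    abort("Recording too short to admit surrogate event shifts.")
  }
  i_on <- round(onsets_s * fs) + 1L
  gather <- function(onsets_idx) {
    idx <- ((outer(onsets_idx, offs, `+`) - 1L) %% n) + 1L  # circular
    acc <- matrix(0, nrow(power), epoch_len)
    for (e in seq_len(nrow(idx))) acc <- acc + power[, idx[e, ]]
    acc / nrow(idx)
  }
  observed <- 10 * log10(gather(i_on))
  min_shift <- epoch_len
  sums <- matrix(0, nrow(power), epoch_len)
  sq <- matrix(0, nrow(power), epoch_len)
  withr::with_seed(as.integer(seed), {
    for (p_i in seq_len(n_perm)) {
      shifts <- sample.int(n - 2L * min_shift, length(i_on),
                           replace = TRUE) + min_shift
      surro <- 10 * log10(gather(((i_on + shifts - 1L) %% n) + 1L))
      sums <- sums + surro
      sq <- sq + surro^2
    }
  })
  mu <- sums / n_perm
  sdv <- sqrt(pmax(sq / n_perm - mu^2, 0) * n_perm / max(n_perm - 1, 1))
  z <- (observed - mu) / sdv
  z[!is.finite(z)] <- 0
  new_surrogate_zmap(observed, z, freq %||% seq_len(nrow(power)),
                     offs / fs, n_perm, fdr_q)
}

#' Label-shuffle permutation z-map of a power difference
#'
#' The observed statistic is the dB difference between condition-averaged
#' power maps, `10*log10(mean(A)) - 10*log10(mean(B))`. The null is built
#' by repeatedly re-partitioning the pooled epochs into groups of the
#' original sizes; z, two-sided p and a BH-FDR mask follow as in
#' [surrogate_event_zmap()].
#'
#' @param pow_a,pow_b Power epoch arrays (trial x frequency x time) on the
#'   same frequency/time grid, >= 2 epochs each.
#' @param freq,time_s Axis labels (recycled onto the result).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param fdr_q FDR level.
#' @return A `surrogate_zmap`.
#' @export
label_shuffle_zmap <- function(pow_a, pow_b, freq = NULL, time_s = NULL,
                               n_perm = 1000, seed, fdr_q = 0.05) {
  stopifnot(length(dim(pow_a)) == 3, length(dim(pow_b)) == 3)
  if (!all(dim(pow_a)[2:3] == dim(pow_b)[2:3])) {
    abort("Condition epochs are on different time/frequency grids.")
  }
  na <- dim(pow_a)[1]; nb <- dim(pow_b)[1]
  if (na < 2 || nb < 2) abort("Need at least 2 epochs per condition.")
  check_scalar(n_perm, "n_perm", lower = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  d <- dim(pow_a)[2:3]
  nb_bins <- prod(d)
  A <- matrix(pow_a, na, nb_bins)
  B <- matrix(pow_b, nb, nb_bins)
  pooled <- rbind(A, B)
  obs <- 10 * log10(colMeans(A)) - 10 * log10(colMeans(B))
  diffs <- withr::with_seed(as.integer(seed), {
    sel <- matrix(0, n_perm, na + nb)
    for (p_i in seq_len(n_perm)) {
      sel[p_i, sample.int(na + nb, na)] <- 1
    }
    ma <- (sel %*% pooled) / na
    mb <- ((1 - sel) %*% pooled) / nb
    10 * log10(ma) - 10 * log10(mb)
  })
  mu <- colMeans(diffs)
  sdv <- apply(diffs, 2, stats::sd)
  z <- (obs - mu) / sdv
  z[!is.finite(z)] <- 0
  new_surrogate_zmap(matrix(obs, d[1], d[2]), matrix(z, d[1], d[2]),
                     freq %||% seq_len(d[1]),
                     time_s %||% seq_len(d[2]), n_perm, fdr_q)
}

#' Spearman and Pearson correlation across subjects
#'
#' @param x,y Numeric vectors (paired per subject), n >= 4, no missing
#'   values. Spearman uses average ranks for ties.
#' @return A one-row tibble: `spearman_r`, `spearman_p`, `pearson_r`,
#'   `pearson_p` (two-sided).
#' @export
correlate_pairs <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 4) abort("Need at least 4 pairs.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation undefined for constant input.")
  }
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  pe <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(spearman_r = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 pearson_r = unname(pe$estimate),
                 pearson_p = pe$p.value)
}

#' Two-tailed paired t test
#'
#' @param a,b Numeric vectors of equal length (n >= 3), paired per subject.
#' @return A one-row tibble: `t`, `df`, `p`.
#' @export
paired_tests <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 3) abort("Need at least 3 pairs.")
  d <- a - b
  if (stats::sd(d) == 0) {
    abort("Zero-variance differences: paired t statistic undefined.")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value)
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-subject sums-of-squares decomposition for a complete two-factor
#' design with two levels per factor; each effect is tested against its own
#' subject-by-effect interaction with df = (1, n - 1).
#'
#' @param data Data frame with columns `subject`, `factor_a`, `factor_b`,
#'   `value`; every subject must contribute all four cells.
#' @return A tibble with rows for `factor_a`, `factor_b` and
#'   `factor_a:factor_b`: columns `term`, `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("subject", "factor_a", "factor_b", "value") %in%
                  names(data)))
  df <- data |>
    dplyr::mutate(subject = factor(.data$subject),
                  factor_a = factor(.data$factor_a),
                  factor_b = factor(.data$factor_b))
  if (nlevels(df$factor_a) != 2 || nlevels(df$factor_b) != 2) {
    abort("Both factors must have exactly 2 levels.")
  }
  n_sub <- nlevels(df$subject)
  if (n_sub < 3) abort("Need at least 3 subjects.")
  counts <- table(df$subject, df$factor_a, df$factor_b)
  if (any(counts != 1)) abort("Design incomplete: each subject needs all 4 cells exactly once.")
  fit <- stats::aov(value ~ factor_a * factor_b +
                      Error(subject / (factor_a * factor_b)), data = df)
  sm <- summary(fit)
  pull_row <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)[1]
    Fv <- tab[i, "F value"]
    pv <- tab[i, "Pr(>F)"]
    if (!is.finite(Fv) && tab[i, "Sum Sq"] < 1e-20) {
      Fv <- 0; pv <- 1    # degenerate 0/0: no effect, no error variance
    }
    tibble::tibble(term = term,
                   F = Fv, df1 = tab[i, "Df"],
                   df2 = tab[grep("Residuals", rownames(tab)), "Df"],
                   p = pv)
  }
  dplyr::bind_rows(
    pull_row("Error: subject:factor_a", "factor_a"),
    pull_row("Error: subject:factor_b", "factor_b"),
    pull_row("Error: subject:factor_a:factor_b", "factor_a:factor_b"))
}

#' Median-split comparison of inhale peaks by phase alignment
#'
#' Within each subject, trials are split at the median DMP into
#' well-aligned (small DMP) and poorly aligned (large DMP) halves (the
#' median trial is excluded for odd counts), and the mean inhale peak of
#' each half is computed. A group-level two-tailed paired t test compares
#' the halves across subjects. Subjects with fewer than 4 usable trials
#' are skipped with a warning.
#'
#' @param dmp_table Tibble with columns `subject`, `dmp`, `inhale_peak`.
#' @return A list with `per_subject` (tibble: `subject`, `peak_small_dmp`,
#'   `peak_large_dmp`, `n_trials`) and `test` (paired t tibble).
#' @export
median_split_compare <- function(dmp_table) {
  stopifnot(is.data.frame(dmp_table),
            all(c("subject", "dmp", "inhale_peak") %in% names(dmp_table)))
  per <- dmp_table |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 4) {
        warn(sprintf("Subject %s has %d trial(s) (< 4); skipped.",
                     as.character(key$subject[1]), nrow(g)))
        return(NULL)
      }
      ord <- order(g$dmp)
      n <- nrow(g)
      half <- n %/% 2
      lo <- ord[seq_len(half)]
      hi <- ord[seq(n - half + 1L, n)]
      tibble::tibble(subject = key$subject[1],
                     peak_small_dmp = mean(g$inhale_peak[lo]),
                     peak_large_dmp = mean(g$inhale_peak[hi]),
                     n_trials = n)
    }) |>
    dplyr::bind_rows()
  if (nrow(per) < 3) abort("Fewer than 3 subjects usable for the paired test.")
  list(per_subject = per,
       test = paired_tests(per$peak_small_dmp, per$peak_large_dmp))
}
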
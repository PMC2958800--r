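#' Fit the wild-type measurement error model
#'
#' Repeated assays of the wild-type enzyme define the Gaussian measurement
#' error of the performance statistic; mutants whose deviation from the
#' wild-type mean is explicable by this error are candidates for the
#' "no effect" class.
#'
#' @param x Numeric vector of wild-type replicate performances, or a
#'   `mutant_panel` (whose wild-type replicates are used).
#' @return An `error_model` with fields `mean`, `sd` (n-1 denominator) and
#'   `n`.
#' @examples
#' fit_error_model(c(160, 172))
#' @export
fit_error_model <- function(x) {
  if (inherits(x, "mutant_panel")) x <- wt_replicates(x)
  x <- as.numeric(x)
  if (length(x) < 2) {
    abort("need at least 2 wild-type replicates to fit the error model",
          class = "epizyme_insufficient_data")
  }
  structure(list(mean = mean(x), sd = sd(x), n = length(x)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model> mean =", format(x$mean, digits = 6),
      " sd =", format(x$sd, digits = 6), sprintf(" (n = %d)\n", x$n))
  invisible(x)
}

#' @method tidy error_model
#' @export
tidy.error_model <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, n = x$n)
}

#' Half-Gaussian reflection estimate of the neutral count
#'
#' If measurement error is symmetric, mutants with no true effect land above
#' the wild-type mean half the time. Doubling the count of mutants measured
#' above the wild-type mean therefore estimates the size of the whole
#' no-effect class. The above-mean deviations are additionally fitted as a
#' half-Gaussian (MLE sd = root mean square deviation) for comparison with
#' the wild-type error sd; similarity of the two supports the reflection
#' logic. Ties with the wild-type mean count as "not above".
#'
#' @param panel A `mutant_panel`.
#' @param error_model Optional [fit_error_model()] result; fitted from the
#'   panel's wild-type replicates when omitted.
#' @param boot Number of bootstrap resamples for the sd-ratio interval
#'   (0 skips the interval).
#' @return A one-row tibble: `n_mutants`, `n_above`, `neutral_estimate`
#'   (= 2 * `n_above`), `half_gaussian_sd`, `error_sd`, `sd_ratio` and the
#'   bootstrap interval `sd_ratio_lo`, `sd_ratio_hi`.
#' @export
estimate_neutral_count <- function(panel, error_model = NULL, boot = 200) {
  error_model <- error_model %||% fit_error_model(panel)
  means <- panel_means(panel)
  dev <- means$mean_perf - error_model$mean
  n_above <- sum(dev > 0)
  upper <- dev[dev > 0]
  half_sd <- if (length(upper) > 0) sqrt(mean(upper^2)) else NA_real_
  ratio <- half_sd / error_model$sd
  lo <- hi <- NA_real_
  if (boot > 0 && length(upper) > 1 && is.finite(ratio)) {
    bs <- vapply(seq_len(boot), function(i) {
      sqrt(mean(sample(upper, replace = TRUE)^2)) / error_model$sd
    }, numeric(1))
    qs <- quantile(bs, c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble(n_mutants = nrow(means), n_above = n_above,
         neutral_estimate = 2L * n_above,
         half_gaussian_sd = half_sd, error_sd = error_model$sd,
         sd_ratio = ratio, sd_ratio_lo = lo, sd_ratio_hi = hi)
}

# per-mutant replicate summaries, in first-appearance order
panel_means <- function(panel) {
  as_tibble(panel) |>
    mutate(.ord = match(.data$mutant_id, unique(.data$mutant_id))) |>
    group_by(.data$mutant_id, .data$.ord) |>
    summarise(mean_perf = mean(.data$performance),
              var_perf = var(.data$performance),
              n_rep = n(), .groups = "drop") |>
    arrange(.data$.ord) |>
    select(!".ord")
}

# vectorised Welch machinery shared by welch_test and classify_panel.
# Degenerate convention: both variances zero -> p = 1 when means agree,
# p = 0 when they differ (flagged via degenerate column).
welch_stats <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  degen <- se2 == 0
  t <- ifelse(degen, ifelse(m1 == m2, 0, Inf * sign(m1 - m2)),
              (m1 - m2) / sqrt(se2))
  df <- ifelse(degen, NA_real_,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(degen, ifelse(m1 == m2, 1, 0), 2 * pt(-abs(t), df))
  tibble(t = t, df = df, p_value = p, degenerate = degen)
}

#' Welch two-sample t test
#'
#' Two-sided t test for unequal variances and unequal replication, with
#' fractional Satterthwaite degrees of freedom (no integer rounding). When
#' both samples have zero variance the p-value is 1 if the means agree and
#' 0 otherwise (flagged as `degenerate`).
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return A one-row tibble: `t`, `df`, `p_value`, `degenerate`.
#' @examples
#' welch_test(c(160, 172), c(160, 172))
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("need at least 2 replicates on each side",
          class = "epizyme_insufficient_data")
  }
  welch_stats(mean(x), var(x), length(x), mean(y), var(y), length(y))
}

#' Benjamini-Hochberg step-up rejections
#'
#' Standard step-up rule at false discovery rate `q`: with ordered p-values
#' p(1) <= ... <= p(m), find the largest k with p(k) <= k q / m and reject
#' every hypothesis with p <= p(k).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q Target false discovery rate in (0, 1).
#' @return Logical rejection vector in the original order.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1), q > 0, q < 1)
  p.adjust(p_values, method = "BH") <= q
}

#' Classify mutants as decreased, unchanged or increased
#'
#' Per-mutant Welch tests against the wild-type replicates, combined with
#' Benjamini-Hochberg control at `config$fdr_q`. Rejected mutants are called
#' `decreased` or `increased` by the sign of the mean difference; the rest
#' `unchanged`. Mutants whose relative performance exceeds 1.15 are flagged
#' `large_increase`.
#'
#' @param panel A `mutant_panel` with >= 2 wild-type replicates and >= 2
#'   replicates per mutant.
#' @param config A [run_config()]; only `fdr_q` is used.
#' @return An `effect_classification` tibble, one row per mutant:
#'   `mutant_id`, `mean_perf`, `relative_perf`, `t`, `p_value`,
#'   `q_threshold_pass`, `category`, `large_increase`. [glance()] returns
#'   the category counts together with the reflection neutral estimate.
#' @export
classify_panel <- function(panel, config = run_config()) {
  wt <- wt_replicates(panel)
  if (length(wt) < 2) {
    abort("panel has fewer than 2 wild-type replicates",
          class = "epizyme_insufficient_data")
  }
  means <- panel_means(panel)
  if (any(means$n_rep < 2)) {
    abort(sprintf("mutant %s has fewer than 2 replicates",
                  means$mutant_id[which(means$n_rep < 2)[1]]),
          class = "epizyme_insufficient_data")
  }
  ws <- welch_stats(means$mean_perf, means$var_perf, means$n_rep,
                    mean(wt), var(wt), length(wt))
  rej <- benjamini_hochberg(ws$p_value, config$fdr_q)
  out <- means |>
    mutate(relative_perf = .data$mean_perf / mean(wt),
           t = ws$t, p_value = ws$p_value,
           q_threshold_pass = rej,
           category = dplyr::case_when(
             rej & .data$mean_perf < mean(wt) ~ "decreased",
             rej & .data$mean_perf > mean(wt) ~ "increased",
             .default = "unchanged"
           ),
           large_increase = .data$relative_perf > 1.15) |>
    select(!dplyr::any_of(c("var_perf", "n_rep")))
  class(out) <- c("effect_classification", class(out))
  attr(out, "fdr_q") <- config$fdr_q
  attr(out, "wt_mean") <- mean(wt)
  out
}

#' @method glance effect_classification
#' @export
glance.effect_classification <- function(x, ...) {
  tibble(
    n_mutants = nrow(x),
    n_decreased = sum(x$category == "decreased"),
    n_unchanged = sum(x$category == "unchanged"),
    n_increased = sum(x$category == "increased"),
    n_above_wt_mean = sum(x$mean_perf > attr(x, "wt_mean")),
    neutral_estimate = 2L * sum(x$mean_perf > attr(x, "wt_mean")),
    fdr_q = attr(x, "fdr_q")
  )
}
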
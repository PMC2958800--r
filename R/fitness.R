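#' Dominance hyperbola mapping performance to fitness
#'
#' Fitness follows a saturating hyperbola of relative enzyme performance,
#' `y = a x / (b + x)`, the classic dominance curve of metabolic flux. With
#' the default parameters (a = 1.0005, b = 0.00032, performance relative to
#' wild type so the wild type sits at x = 1) the wild type lies far into a
#' fitness plateau: the half-saturation constant b is ~3000-fold below the
#' wild-type performance.
#'
#' @param a Dimensionless asymptote (> 0).
#' @param b Half-saturation constant on the relative-performance scale
#'   (> 0).
#' @return A `fitness_curve` object.
#' @export
fitness_curve <- function(a = 1.0005, b = 0.00032) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "fitness_curve")
}

#' @export
print.fitness_curve <- function(x, ...) {
  cat(sprintf("<fitness_curve> y = %g x / (%g + x)\n", x$a, x$b))
  invisible(x)
}

#' Relative fitness at a relative performance
#'
#' @param x Relative performance(s), >= 0 (wild type = 1). `Inf` is allowed
#'   and returns the asymptote `a`.
#' @param curve A [fitness_curve()].
#' @return Relative fitness `y = a x / (b + x)`; `y(0) = 0` and
#'   `y -> a` as `x -> Inf`.
#' @export
fitness <- function(x, curve = fitness_curve()) {
  if (any(x < 0)) abort("relative performance must be non-negative",
                        class = "epizyme_validation_error")
  ifelse(is.infinite(x), curve$a, curve$a * x / (curve$b + x))
}

#' Selection coefficient of a mutant performance
#'
#' Fitness difference between the wild type (fixed at relative performance
#' 1) and the mutant: `s = y(1) - y(x)`. Non-negative for any performance
#' loss and zero at the wild type.
#'
#' @param x_mut Mutant relative performance(s), >= 0.
#' @param curve A [fitness_curve()].
#' @return Selection coefficient(s) per generation.
#' @examples
#' selection_coefficient(0.5) # ~3.2e-4: a 50% performance loss barely shows
#' @export
selection_coefficient <- function(x_mut, curve = fitness_curve()) {
  fitness(1, curve) - fitness(x_mut, curve)
}

#' Performance cutoff for a selection-coefficient threshold
#'
#' Solves `s(x*) = threshold` by bisection on the strictly decreasing
#' selection coefficient, to a residual below `tol`. Mutants with relative
#' performance above `x*` have selection coefficients under the threshold.
#'
#' @param s_threshold Positive threshold (per generation).
#' @param curve A [fitness_curve()].
#' @param tol Residual tolerance on `|s(x*) - threshold|`.
#' @return One-row tibble: `x_star`, `residual`, `all_below` (`TRUE`, with
#'   `x_star = 0`, when the threshold exceeds even the total-loss
#'   coefficient `s(0)`).
#' @export
performance_cutoff <- function(s_threshold, curve = fitness_curve(),
                               tol = 1e-12) {
  stopifnot(s_threshold > 0)
  s <- function(x) selection_coefficient(x, curve)
  if (s_threshold >= s(0)) {
    return(tibble(x_star = 0, residual = 0, all_below = TRUE))
  }
  lo <- 0; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (s(mid) > s_threshold) lo <- mid else hi <- mid
    if (abs(s((lo + hi) / 2) - s_threshold) <= tol) break
  }
  x_star <- (lo + hi) / 2
  tibble(x_star = x_star, residual = abs(s(x_star) - s_threshold),
         all_below = FALSE)
}

#' Plateau summary of a mutant panel's fitness effects
#'
#' Maps each mutant's relative performance through the dominance curve and
#' reports the share with selection coefficients below a threshold, with an
#' exact binomial confidence interval, together with the performance cutoff
#' `x*` at the threshold.
#'
#' @param x An `effect_classification` (its `relative_perf` column is used)
#'   or a numeric vector of relative performances.
#' @param s_threshold Selection-coefficient threshold per generation.
#' @param curve A [fitness_curve()].
#' @return One-row tibble: `n`, `n_below`, `fraction_below`, `ci_lo`,
#'   `ci_hi` (95% Clopper-Pearson), `x_star`, `s_threshold`.
#' @export
plateau_summary <- function(x, s_threshold = 1e-5, curve = fitness_curve()) {
  rel <- if (is.data.frame(x)) x$relative_perf else as.numeric(x)
  stopifnot(s_threshold > 0, all(rel >= 0))
  s <- selection_coefficient(rel, curve)
  n_below <- sum(s < s_threshold)
  n <- length(rel)
  ci <- stats::binom.test(n_below, n)$conf.int
  cut <- performance_cutoff(s_threshold, curve)
  tibble(n = n, n_below = n_below, fraction_below = n_below / n,
         ci_lo = ci[1], ci_hi = ci[2],
         x_star = cut$x_star, s_threshold = s_threshold)
}

#' Plot the dominance fitness curve
#'
#' @param object A [fitness_curve()].
#' @param relative_perfs Optional mutant relative performances to mark on
#'   the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fitness_curve
#' @export
autoplot.fitness_curve <- function(object, relative_perfs = NULL, ...) {
  xs <- seq(0, 1.2, length.out = 400)
  dat <- tibble(x = xs, y = fitness(xs, object))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative performance (wild type = 1)",
                  y = "relative fitness") +
    ggplot2::theme_minimal()
  if (!is.null(relative_perfs)) {
    pts <- tibble(x = relative_perfs, y = fitness(relative_perfs, object))
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.6)
  }
  p
}
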
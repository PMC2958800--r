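#' Pairwise deleterious-interaction probability from a recombinant library
#'
#' With `k` deleterious pairs observed among all `choose(n, 2)` pairwise
#' combinations of `n` replacements, the per-pair probability is estimated
#' as `k / choose(n, 2)`.
#'
#' @param n_replacements Number of recombined replacements (>= 2).
#' @param n_deleterious_pairs Number of pairs found deleterious.
#' @return Estimated probability `p`.
#' @examples
#' p_from_pair_library(52, 7) # ~0.0053, "about a half percent"
#' @export
p_from_pair_library <- function(n_replacements, n_deleterious_pairs) {
  stopifnot(n_replacements >= 2, n_deleterious_pairs >= 0)
  n_pairs <- choose(n_replacements, 2)
  if (n_deleterious_pairs > n_pairs) {
    abort(sprintf("%d deleterious pairs exceed the %d possible pairs",
                  n_deleterious_pairs, n_pairs),
          class = "epizyme_validation_error")
  }
  n_deleterious_pairs / n_pairs
}

#' Interaction probability from the observed no-effect fraction
#'
#' Inverts the snowball model `f = (1 - p)^(D - 1)`: if a residue introduced
#' from an orthologue can clash independently with each of the other `D - 1`
#' divergent residues, the chance it has no effect is `f`, giving
#' `p = 1 - f^(1/(D-1))`.
#'
#' @param f Observed fraction of introduced residues with no effect, in
#'   (0, 1\]. `f = 0` returns `p = 1` with a warning (the model cannot
#'   distinguish probabilities once every swap is deleterious).
#' @param D Number of divergent residues between the orthologues (>= 2).
#' @return Estimated probability `p`.
#' @examples
#' p_from_no_effect_fraction(104 / 168, D = 168) # ~0.0029
#' @export
p_from_no_effect_fraction <- function(f, D) {
  if (D < 2 || D != round(D)) {
    abort("D must be an integer >= 2", class = "epizyme_validation_error")
  }
  stopifnot(f >= 0, f <= 1)
  if (f == 0) {
    warn("f = 0: p is not identifiable, returning 1")
    return(1)
  }
  1 - f^(1 / (D - 1))
}

#' Snowball no-effect fraction f(p, D)
#'
#' The probability that a single residue introduced from an orthologue at
#' divergence `D` avoids all `D - 1` potential pairwise clashes:
#' `f = (1 - p)^(D - 1)`. Vectorised over `D` to trace how rapidly the
#' cumulative impact of individually rare interactions grows with
#' divergence.
#'
#' @param p Per-pair deleterious interaction probability in \[0, 1\].
#' @param D Divergence (integer >= 2), possibly a vector.
#' @return `f`, same length as `D`.
#' @export
no_effect_fraction <- function(p, D) {
  stopifnot(p >= 0, p <= 1, all(D >= 2), all(D == round(D)))
  (1 - p)^(D - 1)
}

#' Snowball curve over a divergence range
#'
#' @inheritParams no_effect_fraction
#' @param D_max Largest divergence to tabulate.
#' @param D_min Smallest divergence (default 2).
#' @return A tibble with columns `D` and `f`.
#' @export
snowball_curve <- function(p, D_max, D_min = 2) {
  stopifnot(D_max >= D_min)
  D <- seq.int(D_min, D_max)
  tibble(D = D, f = no_effect_fraction(p, D))
}

#' Compare two interaction-probability estimates
#'
#' @param p_a,p_b Two positive probability estimates.
#' @return One-row tibble: `ratio` (max/min, >= 1) and `fold` (the ratio
#'   rounded to the nearest integer).
#' @examples
#' compare_estimates(p_from_pair_library(52, 7),
#'                   p_from_no_effect_fraction(104 / 168, 168))
#' @export
compare_estimates <- function(p_a, p_b) {
  if (p_a <= 0 || p_b <= 0) {
    abort("both estimates must be positive", class = "epizyme_validation_error")
  }
  ratio <- max(p_a, p_b) / min(p_a, p_b)
  tibble(ratio = ratio, fold = round(ratio))
}

#' Plot the snowball curve
#'
#' @inheritParams snowball_curve
#' @return A ggplot of `f(D)` with a log-scaled y axis.
#' @export
plot_snowball <- function(p, D_max, D_min = 2) {
  dat <- snowball_curve(p, D_max, D_min)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$D, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "divergence D (residues)",
                  y = "P(introduced residue has no effect)",
                  title = sprintf("Snowball curve, p = %.3g", p)) +
    ggplot2::theme_minimal()
}
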
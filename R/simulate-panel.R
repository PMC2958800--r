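#' Specification for a synthetic mutant panel
#'
#' Defaults emulate the study conditions of the orthologue-swap panel the
#' analysis is designed for: 168 mutants assayed in duplicate against a
#' 30-replicate wild-type series with performance 166 mM^-1 s^-1, a
#' no-effect class of 104/168, five fully inactive mutants, the remaining
#' deleterious mutants with Beta-distributed relative performance forming a
#' left shoulder, and Gaussian replicate error with a 5% coefficient of
#' variation.
#'
#' @param n_mutants Panel size.
#' @param neutral_fraction Fraction of mutants with no true effect.
#' @param inactive_count Number of fully inactive mutants (true relative
#'   performance 0), drawn from the non-neutral class.
#' @param deleterious_shape Beta shape parameters for the relative
#'   performance of the remaining deleterious mutants.
#' @param wt_mean True wild-type mean performance (mM^-1 s^-1).
#' @param error_cv Replicate coefficient of variation (sd = cv x true
#'   mean, so inactive mutants measure exactly 0).
#' @param n_replicates_mutant,n_replicates_wt Replication levels.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_mutants = 168, neutral_fraction = 104 / 168,
                       inactive_count = 5, deleterious_shape = c(2, 1.5),
                       wt_mean = 166, error_cv = 0.05,
                       n_replicates_mutant = 2, n_replicates_wt = 30,
                       seed = 1L) {
  stopifnot(n_mutants >= 1, neutral_fraction >= 0, neutral_fraction <= 1,
            inactive_count >= 0, wt_mean > 0, error_cv >= 0,
            n_replicates_mutant >= 1, n_replicates_wt >= 2,
            length(deleterious_shape) == 2, all(deleterious_shape > 0))
  n_neutral <- round(neutral_fraction * n_mutants)
  if (inactive_count > n_mutants - n_neutral) {
    abort("inactive_count exceeds the non-neutral class size",
          class = "epizyme_validation_error")
  }
  structure(list(n_mutants = n_mutants, neutral_fraction = neutral_fraction,
                 inactive_count = inactive_count,
                 deleterious_shape = deleterious_shape,
                 wt_mean = wt_mean, error_cv = error_cv,
                 n_replicates_mutant = n_replicates_mutant,
                 n_replicates_wt = n_replicates_wt,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a synthetic mutant panel
#'
#' Draws true relative performances per the panel specification (point mass at 1 for the
#' neutral class, point mass at 0 for inactive mutants, Beta left tail
#' otherwise), then Gaussian replicate noise with sd proportional to each
#' mutant's true mean. Negative draws are truncated at zero (rare at the
#' default noise level) and counted in the `n_truncated` attribute. The
#' true relative performance of every mutant is carried in the
#' `true_relative_perf` column so that estimator-recovery studies can score
#' against ground truth.
#'
#' @param spec A [panel_spec()].
#' @return A [mutant_panel()] with the extra column `true_relative_perf`.
#' @examples
#' pan <- generate_panel(panel_spec(seed = 42))
#' glance(classify_panel(pan))
#' @export
generate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_mutants
    n_neutral <- round(spec$neutral_fraction * n)
    n_inactive <- spec$inactive_count
    n_delet <- n - n_neutral - n_inactive
    true_rel <- c(rep(1, n_neutral),
                  rep(0, n_inactive),
                  rbeta(n_delet, spec$deleterious_shape[1],
                        spec$deleterious_shape[2]))
    true_rel <- sample(true_rel)
    true_mean <- spec$wt_mean * true_rel

    aa <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
    wt_res <- sample(aa, n, replace = TRUE)
    mut_res <- vapply(wt_res, function(a) sample(setdiff(aa, a), 1),
                      character(1))
    ids <- paste0(wt_res, seq_len(n), mut_res)

    k <- spec$n_replicates_mutant
    reps <- rnorm(n * k,
                  mean = rep(true_mean, each = k),
                  sd = spec$error_cv * rep(true_mean, each = k))
    n_trunc <- sum(reps < 0)
    reps <- pmax(reps, 0)

    wt <- rnorm(spec$n_replicates_wt, spec$wt_mean,
                spec$error_cv * spec$wt_mean)

    dat <- tibble(
      mutant_id = rep(ids, each = k),
      site = rep(seq_len(n), each = k),
      wt_residue = rep(wt_res, each = k),
      mut_residue = rep(mut_res, each = k),
      replicate = rep(seq_len(k), times = n),
      performance = reps,
      true_relative_perf = rep(true_rel, each = k)
    )
    out <- mutant_panel(dat, wt_replicates = wt, reference_name = "WT")
    attr(out, "n_truncated") <- n_trunc
    out
  })
}

#' Histogram of a panel's relative performance distribution
#'
#' @param object A `mutant_panel`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot of per-mutant mean performance relative to the
#'   wild-type mean, with the wild-type error sd marked.
#' @method autoplot mutant_panel
#' @export
autoplot.mutant_panel <- function(object, bins = 40, ...) {
  em <- fit_error_model(object)
  means <- panel_means(object) |>
    mutate(relative_perf = .data$mean_perf / em$mean)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$relative_perf)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65", colour = "grey25") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = 1 + c(-1, 1) * em$sd / em$mean,
                        linetype = 3, colour = "steelblue") +
    ggplot2::labs(x = "relative performance (wild-type mean = 1)",
                  y = "mutants",
                  title = "Distribution of mutational effects") +
    ggplot2::theme_minimal()
}

#' Histogram of classified effects
#'
#' @param object An `effect_classification` from [classify_panel()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot coloured by category.
#' @method autoplot effect_classification
#' @export
autoplot.effect_classification <- function(object, bins = 40, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$relative_perf,
                               fill = .data$category)) +
    ggplot2::geom_histogram(bins = bins, colour = "grey25") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "relative performance (wild-type mean = 1)",
                  y = "mutants") +
    ggplot2::theme_minimal()
}
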
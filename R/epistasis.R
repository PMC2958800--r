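#' Transition-state free-energy difference of a mutant
#'
#' Under simple transition-state theory the performance ratio of mutant to
#' wild type maps to a free-energy difference between their catalytic
#' transition states: `ddG' = -R T log(perf_mut / perf_wt)` with R in
#' kcal mol^-1 K^-1. Positive values mean the mutant is slower; a fully
#' inactive mutant (`perf_mut = 0`) gives `+Inf`.
#'
#' @param perf_mut Mutant performance(s), >= 0 (mM^-1 s^-1).
#' @param perf_wt Wild-type performance, > 0 (same units).
#' @param temperature Temperature in Kelvin (assays at 37 C by default).
#' @return ddG' in kcal mol^-1, vectorised over `perf_mut`.
#' @examples
#' ddg_prime(42, 166) # orthologue vs wild type, ~0.85 kcal/mol
#' @export
ddg_prime <- function(perf_mut, perf_wt, temperature = 310.15) {
  if (perf_wt <= 0) abort("perf_wt must be positive",
                          class = "epizyme_validation_error")
  if (any(perf_mut < 0)) abort("perf_mut must be non-negative",
                               class = "epizyme_validation_error")
  ifelse(perf_mut == 0, Inf,
         -R_KCAL * temperature * log(perf_mut / perf_wt))
}

#' Additive independence prediction of the orthologue performance
#'
#' If mutational effects on performance were additive, combining all
#' replacements would change the wild type by the sum of the individual
#' effects: `wt + sum(perf_i - wt)`. The raw value is returned even when
#' negative; a negative predicted performance is physically impossible and
#' is flagged.
#'
#' @param wt_perf Wild-type performance.
#' @param mutant_perfs Numeric vector of single-mutant performances.
#' @return One-row tibble: `prediction`, `sum_effects`, `impossible`.
#' @export
additive_prediction <- function(wt_perf, mutant_perfs) {
  eff <- sum(mutant_perfs - wt_perf)
  pred <- wt_perf + eff
  tibble(prediction = pred, sum_effects = eff, impossible = pred < 0)
}

#' Multiplicative (free-energy) independence prediction
#'
#' If mutational free-energy effects were independent they would sum, so
#' performances multiply: `wt * prod(perf_i / wt)`, identically
#' `wt * exp(-sum(ddG'_i) / (R T))`. Any fully inactive single mutant drives
#' the prediction to exactly zero (its ddG' is `+Inf`).
#'
#' @inheritParams additive_prediction
#' @param temperature Kelvin; only enters through the equivalent free-energy
#'   form.
#' @param form `"product"` (default) evaluates the performance-ratio
#'   product; `"free_energy"` evaluates `wt * exp(-sum(ddG')/RT)`. The two
#'   agree to full precision for positive performances.
#' @return One-row tibble: `prediction`, `sum_ddg` (kcal mol^-1, `+Inf` when
#'   any mutant is inactive), `exponent` (`-sum_ddg/RT`).
#' @export
multiplicative_prediction <- function(wt_perf, mutant_perfs,
                                      temperature = 310.15,
                                      form = c("product", "free_energy")) {
  form <- match.arg(form)
  if (wt_perf <= 0) abort("wt_perf must be positive",
                          class = "epizyme_validation_error")
  rt <- R_KCAL * temperature
  ddg <- ddg_prime(mutant_perfs, wt_perf, temperature)
  sum_ddg <- sum(ddg)
  pred <- if (any(mutant_perfs == 0)) {
    0
  } else if (form == "product") {
    wt_perf * prod(mutant_perfs / wt_perf)
  } else {
    wt_perf * exp(-sum_ddg / rt)
  }
  tibble(prediction = pred, sum_ddg = sum_ddg, exponent = -sum_ddg / rt)
}

#' Epistasis verdict: are the independence nulls tenable?
#'
#' Compares the observed orthologue performance against both the additive
#' and multiplicative null predictions. A null is untenable when it is
#' physically impossible (non-positive prediction against a positive
#' observation) or when the observation lies more than 3 wild-type error
#' standard deviations away. Epistasis is required when both nulls are
#' untenable.
#'
#' @param wt_perf Wild-type performance.
#' @param mutant_perfs Single-mutant performances (all replacements
#'   separating the two orthologues).
#' @param observed Observed performance of the orthologue.
#' @param error_model An [fit_error_model()] result (its `sd` sets the
#'   3-sd consistency band).
#' @param temperature Kelvin.
#' @return An `epistasis_report`: one-row tibble with `wt_performance`,
#'   `additive_prediction`, `additive_impossible`, `sum_ddg`,
#'   `multiplicative_prediction`, `observed_ortholog`, `verdict`
#'   (`"consistent"` or `"epistasis_required"`).
#' @export
epistasis_verdict <- function(wt_perf, mutant_perfs, observed, error_model,
                              temperature = 310.15) {
  add <- additive_prediction(wt_perf, mutant_perfs)
  mult <- multiplicative_prediction(wt_perf, mutant_perfs, temperature)
  band <- 3 * error_model$sd
  add_bad <- (add$prediction <= 0 && observed > 0) ||
    abs(observed - add$prediction) > band
  mult_bad <- (mult$prediction <= 0 && observed > 0) ||
    abs(observed - mult$prediction) > band
  out <- tibble(
    wt_performance = wt_perf,
    additive_prediction = add$prediction,
    additive_impossible = add$impossible,
    sum_ddg = mult$sum_ddg,
    multiplicative_prediction = mult$prediction,
    observed_ortholog = observed,
    verdict = if (add_bad && mult_bad) "epistasis_required" else "consistent"
  )
  class(out) <- c("epistasis_report", class(out))
  out
}

compensation_levels <- c("none", "partial", "full_to_ortholog", "full_to_wt")

# scalar compensation rule; thresholds applied strongest-first
compensation_call <- function(wt, single, double, ortholog, tol) {
  if (double >= wt * (1 - tol)) "full_to_wt"
  else if (double >= ortholog * (1 - tol)) "full_to_ortholog"
  else if (double >= single * (1 + tol)) "partial"
  else "none"
}

#' Classify compensation of double mutants
#'
#' For a deleterious focal mutation combined with candidate second-site
#' mutations, each double mutant is called, strongest claim first:
#' `full_to_wt` when the double reaches the wild type within tolerance,
#' `full_to_ortholog` when it reaches the orthologue's performance,
#' `partial` when it exceeds the focal single mutant by more than the
#' tolerance, `none` otherwise.
#'
#' @param data Data frame with columns `primary`, `secondary`, `single_perf`
#'   (focal single-mutant performance) and `double_perf`.
#' @param wt Wild-type performance.
#' @param ortholog Orthologue performance.
#' @param tol Relative tolerance in (0, 0.5); default matches the assays'
#'   kinetic standard-error bound of 10%.
#' @return The input tibble with `fold_change` (`double/single`) and ordered
#'   factor `call` added.
#' @examples
#' t1 <- data.frame(primary = "F73L", secondary = "F120A",
#'                  single_perf = 7, double_perf = 44)
#' classify_compensation(t1, wt = 166, ortholog = 42)
#' @export
classify_compensation <- function(data, wt, ortholog, tol = 0.10) {
  stopifnot(tol > 0, tol < 0.5)
  data <- as_tibble(data)
  need <- c("primary", "secondary", "single_perf", "double_perf")
  if (!all(need %in% names(data))) {
    abort(sprintf("data needs columns %s", paste(need, collapse = ", ")),
          class = "epizyme_format_error")
  }
  if (any(c(data$single_perf, data$double_perf, wt, ortholog) < 0)) {
    abort("performances must be non-negative",
          class = "epizyme_validation_error")
  }
  data |>
    mutate(fold_change = .data$double_perf / .data$single_perf,
           call = factor(purrr::map2_chr(.data$single_perf, .data$double_perf,
                                         function(s, d)
                                           compensation_call(wt, s, d, ortholog, tol)),
                         levels = compensation_levels, ordered = TRUE))
}

#' Pairwise versus higher-order interaction readings of a double-mutant table
#'
#' The same compensation table supports two standards of "full restoration":
#' against the wild type (suggesting a simple pairwise interaction with the
#' focal site) or against the lower-performing orthologue (suggesting a
#' higher-order interaction that any single reversion destroys). Both
#' compensator sets are reported side by side; the data cannot distinguish
#' the two hypotheses.
#'
#' @inheritParams classify_compensation
#' @return A tibble with columns `hypothesis` (`"pairwise"` /
#'   `"higher_order"`), `standard` (the performance threshold used) and
#'   `compensator` (secondary mutation labels; zero rows for an empty set).
#' @export
interaction_interpretations <- function(data, wt, ortholog, tol = 0.10) {
  data <- as_tibble(data)
  pairwise <- data$secondary[data$double_perf >= wt * (1 - tol)]
  higher <- data$secondary[data$double_perf >= ortholog * (1 - tol)]
  bind_rows(
    tibble(hypothesis = "pairwise", standard = wt * (1 - tol),
           compensator = as.character(pairwise)),
    tibble(hypothesis = "higher_order", standard = ortholog * (1 - tol),
           compensator = as.character(higher))
  )
}
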
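#' Fit Michaelis-Menten kinetics to rate-versus-substrate data
#'
#' Least-squares fit of the hyperbolic rate law `v = Vmax * S / (Km + S)`.
#' Initial values are deterministic: `Vmax0` is the largest observed rate and
#' `Km0` the substrate concentration at half `Vmax0` by linear interpolation,
#' so repeated fits of the same data always converge identically. If the
#' Levenberg-Marquardt fit fails to converge the estimate falls back to a
#' dense grid search over (Vmax, Km) and the result is flagged
#' (`method = "grid"`).
#'
#' @param data Data frame with columns `substrate_conc` (mM) and `rate`
#'   (uM s^-1), one row per assay point.
#' @param a340_extinction Optional molar extinction coefficient
#'   (M^-1 cm^-1); when supplied, `rate` is interpreted as an absorbance
#'   slope (A340 s^-1) and converted to uM product s^-1 before fitting
#'   (6220 for NADH at 340 nm).
#' @return An `mm_fit` object: estimates `vmax`, `km`, asymptotic standard
#'   errors `se_vmax`, `se_km`, residual standard deviation `sigma`, point
#'   count `n` and fitting `method`. Use [tidy()] / [glance()] for tibbles.
#' @examples
#' pts <- data.frame(substrate_conc = c(0.25, 0.5, 1, 2, 10))
#' pts$rate <- 1.0 * pts$substrate_conc / (1.0 + pts$substrate_conc)
#' fit_michaelis_menten(pts)
#' @export
fit_michaelis_menten <- function(data, a340_extinction = NULL) {
  data <- as_tibble(data)
  if (!all(c("substrate_conc", "rate") %in% names(data))) {
    abort("data needs columns substrate_conc and rate",
          class = "epizyme_format_error")
  }
  s <- data$substrate_conc
  v <- data$rate
  if (!is.null(a340_extinction)) {
    # A/s -> M/s via epsilon * path length 1 cm, then to uM/s
    v <- v / a340_extinction * 1e6
  }
  if (any(s <= 0)) abort("substrate_conc must be positive",
                         class = "epizyme_validation_error")
  if (any(v < 0)) abort("rates must be non-negative",
                        class = "epizyme_validation_error")
  if (length(unique(s)) < 3) {
    abort("need at least 3 distinct substrate concentrations",
          class = "epizyme_insufficient_data")
  }
  if (all(v == 0)) {
    abort("all rates are zero: Michaelis-Menten fit is degenerate",
          class = "epizyme_degenerate_fit")
  }

  start <- mm_start(s, v)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * s / (km + s),
      data = data.frame(s = s, v = v),
      start = start,
      lower = c(vmax = 0, km = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500)
    ),
    error = function(e) NULL
  )

  if (!is.null(fit)) {
    est <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
    out <- list(vmax = unname(est["vmax"]), km = unname(est["km"]),
                se_vmax = unname(se[1]), se_km = unname(se[2]),
                sigma = sqrt(sum(stats::resid(fit)^2) / max(1, length(v) - 2)),
                n = length(v), method = "nls")
  } else {
    g <- mm_grid_search(s, v)
    out <- c(g, list(se_vmax = NA_real_, se_km = NA_real_,
                     sigma = sqrt(g$sse / max(1, length(v) - 2)),
                     n = length(v), method = "grid"))
    out$sse <- NULL
  }
  structure(out, class = "mm_fit")
}

# deterministic start: vmax0 = max rate; km0 = S at vmax0/2 by interpolation
mm_start <- function(s, v) {
  vmax0 <- max(v)
  ord <- order(s)
  km0 <- tryCatch(
    stats::approx(v[ord], s[ord], xout = vmax0 / 2, ties = mean)$y,
    error = function(e) NA_real_
  )
  if (is.na(km0) || km0 <= 0) km0 <- stats::median(s)
  c(vmax = vmax0, km = km0)
}

# dense SSE grid over (vmax, km); used as fallback and as a test oracle
mm_grid_search <- function(s, v, n_grid = 1000,
                           vmax_range = NULL, km_range = NULL) {
  vmax_range <- vmax_range %||% c(max(v) * 0.5, max(v) * 2)
  km_range <- km_range %||% c(min(s) / 10, max(s) * 10)
  vg <- seq(vmax_range[1], vmax_range[2], length.out = n_grid)
  kg <- seq(km_range[1], km_range[2], length.out = n_grid)
  # SSE(vmax, km) = vmax^2 * A(km) - 2 vmax * B(km) + C over the grid,
  # with A = sum h^2, B = sum v h, h = s/(km+s): vectorise over km
  H <- outer(kg, s, function(k, s) s / (k + s))
  A <- rowSums(H^2)
  B <- as.vector(H %*% v)
  sse_min_per_km <- vapply(seq_along(kg), function(i) {
    sse <- vg^2 * A[i] - 2 * vg * B[i] + sum(v^2)
    j <- which.min(sse)
    c(sse[j], vg[j])
  }, numeric(2))
  i <- which.min(sse_min_per_km[1, ])
  list(vmax = sse_min_per_km[2, i], km = kg[i], sse = sse_min_per_km[1, i])
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> Vmax =", format(x$vmax, digits = 6),
      "uM/s, Km =", format(x$km, digits = 6), "mM",
      sprintf("(n = %d, %s)\n", x$n, x$method))
  if (!is.null(x$kcat)) {
    cat("  kcat =", format(x$kcat, digits = 6),
        "/s, performance kcat/Km =", format(x$performance, digits = 6),
        "mM^-1 s^-1\n")
  }
  invisible(x)
}

#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("vmax", "km"),
         estimate = c(x$vmax, x$km),
         std.error = c(x$se_vmax, x$se_km))
}

#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(vmax = x$vmax, km = x$km, kcat = x$kcat %||% NA_real_,
         performance = x$performance %||% NA_real_,
         sigma = x$sigma, nobs = x$n, method = x$method)
}

#' Derive kcat and the performance statistic kcat/Km
#'
#' `kcat = Vmax / [E]` and performance `= kcat / Km`; with Vmax in uM s^-1,
#' enzyme concentration in uM and Km in mM, performance comes out in
#' mM^-1 s^-1. The performance standard error is propagated from the Vmax
#' and Km standard errors by the delta method (relative errors in
#' quadrature).
#'
#' @param fit An `mm_fit` from [fit_michaelis_menten()].
#' @param enzyme_conc Active-site enzyme concentration (uM), > 0.
#' @return The `mm_fit` augmented with `enzyme_conc`, `kcat`, `performance`
#'   and `se_performance`.
#' @export
compute_performance <- function(fit, enzyme_conc) {
  stopifnot(inherits(fit, "mm_fit"))
  if (enzyme_conc <= 0) {
    abort("enzyme_conc must be positive", class = "epizyme_validation_error")
  }
  fit$enzyme_conc <- enzyme_conc
  fit$kcat <- fit$vmax / enzyme_conc
  fit$performance <- fit$kcat / fit$km
  rel2 <- 0
  if (!is.na(fit$se_vmax) && fit$vmax > 0) rel2 <- rel2 + (fit$se_vmax / fit$vmax)^2
  if (!is.na(fit$se_km)) rel2 <- rel2 + (fit$se_km / fit$km)^2
  fit$se_performance <- if (fit$vmax > 0) fit$performance * sqrt(rel2) else 0
  fit
}

#' Batch-fit a table of kinetic assays
#'
#' Fits each mutant's rate-versus-substrate series and derives kcat and
#' performance from its enzyme concentration.
#'
#' @param data Data frame with columns `mutant_id`, `substrate_conc`, `rate`
#'   and `enzyme_conc` (constant within a mutant).
#' @return A tibble with one row per mutant: `vmax`, `km`, `se_vmax`,
#'   `se_km`, `kcat`, `performance`, `se_performance`, `method`.
#' @export
fit_kinetics <- function(data) {
  data <- as_tibble(data)
  need <- c("mutant_id", "substrate_conc", "rate", "enzyme_conc")
  if (!all(need %in% names(data))) {
    abort(sprintf("data needs columns %s", paste(need, collapse = ", ")),
          class = "epizyme_format_error")
  }
  data |>
    tidyr::nest(points = c("substrate_conc", "rate")) |>
    mutate(fit = purrr::map2(.data$points, .data$enzyme_conc, function(p, e) {
      f <- compute_performance(fit_michaelis_menten(p), e)
      tibble(vmax = f$vmax, km = f$km, se_vmax = f$se_vmax, se_km = f$se_km,
             kcat = f$kcat, performance = f$performance,
             se_performance = f$se_performance, method = f$method)
    })) |>
    select(!dplyr::any_of(c("points"))) |>
    tidyr::unnest("fit")
}

#' Predicted reaction rate in the sub-saturating screen
#'
#' At substrate concentrations far below Km the Michaelis-Menten rate is
#' approximately `performance * [E] * [S]`, i.e. proportional to kcat/Km,
#' which is what makes a fixed-concentration screen of double mutants read
#' out performance directly. Returns the exact hyperbolic rate, the linear
#' approximation, and their ratio `exact/linear = Km/(Km+S)` (always <= 1:
#' the linear form over-predicts).
#'
#' @param fit An `mm_fit`; if it lacks `kcat`, supply `enzyme_conc`.
#' @param substrate_conc Substrate concentrations (mM), > 0.
#' @param enzyme_conc Enzyme concentration (uM), used only to derive kcat
#'   when the fit does not already carry it.
#' @return A tibble with columns `substrate_conc`, `exact_rate`,
#'   `linear_rate`, `ratio`.
#' @export
predict_screen_rate <- function(fit, substrate_conc, enzyme_conc = NULL) {
  stopifnot(inherits(fit, "mm_fit"))
  if (any(substrate_conc <= 0)) {
    abort("substrate_conc must be positive", class = "epizyme_validation_error")
  }
  if (is.null(fit$kcat) && !is.null(enzyme_conc)) {
    fit <- compute_performance(fit, enzyme_conc)
  }
  exact <- fit$vmax * substrate_conc / (fit$km + substrate_conc)
  linear <- fit$vmax * substrate_conc / fit$km
  tibble(substrate_conc = substrate_conc,
         exact_rate = exact,
         linear_rate = linear,
         ratio = exact / linear)
}
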
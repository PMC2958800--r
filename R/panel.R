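#' Construct a mutant panel
#'
#' A mutant panel is a tibble with one row per (mutant, replicate)
#' performance measurement, carrying the wild-type reference replicates and
#' optional orthologue performance as attributes. Performance is the
#' specificity constant kcat/Km (mM^-1 s^-1) of each enzyme variant toward
#' its cofactor.
#'
#' @param data A data frame with columns `mutant_id`, `replicate` and
#'   `performance`, and optionally `site`, `wt_residue`, `mut_residue` (parsed
#'   from `mutant_id` labels such as `"F73L"` when absent; indels use the gap
#'   token `"-"`).
#' @param wt_replicates Numeric vector of wild-type reference performance
#'   replicates (same units as `performance`).
#' @param reference_name Label for the wild-type reference enzyme.
#' @param ortholog_performance Optional observed performance of the divergent
#'   orthologue, used by [epistasis_verdict()].
#' @return A `mutant_panel` tibble.
#' @examples
#' pan <- mutant_panel(
#'   data.frame(mutant_id = "F73L", replicate = 1:2, performance = c(7, 7)),
#'   wt_replicates = c(160, 172)
#' )
#' pan
#' @export
mutant_panel <- function(data, wt_replicates = numeric(),
                         reference_name = "WT",
                         ortholog_performance = NA_real_) {
  data <- as_tibble(data)
  need <- c("mutant_id", "replicate", "performance")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("panel is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "epizyme_format_error")
  }
  if (!all(c("site", "wt_residue", "mut_residue") %in% names(data))) {
    parsed <- parse_mutant_labels(data$mutant_id)
    if (!"site" %in% names(data)) data$site <- parsed$site
    if (!"wt_residue" %in% names(data)) data$wt_residue <- parsed$wt_residue
    if (!"mut_residue" %in% names(data)) data$mut_residue <- parsed$mut_residue
  }
  data <- data[, union(c("mutant_id", "site", "wt_residue", "mut_residue",
                         "replicate", "performance"),
                       names(data))]
  out <- structure(data,
                   class = c("mutant_panel", "tbl_df", "tbl", "data.frame"),
                   wt_replicates = as.numeric(wt_replicates),
                   reference_name = reference_name,
                   ortholog_performance = ortholog_performance)
  validate_panel(out)
}

# parse labels like "F73L"; gap token "-" stands for an indel end
parse_mutant_labels <- function(ids) {
  m <- regmatches(ids, regexec("^([A-Z-])([0-9]+)([A-Z-])$", ids))
  bad <- lengths(m) != 4
  tibble(
    site = ifelse(bad, NA_integer_, suppressWarnings(
      as.integer(vapply(m, function(x) if (length(x) == 4) x[3] else NA_character_,
                        character(1))))),
    wt_residue = vapply(m, function(x) if (length(x) == 4) x[2] else NA_character_,
                        character(1)),
    mut_residue = vapply(m, function(x) if (length(x) == 4) x[4] else NA_character_,
                         character(1))
  )
}

validate_panel <- function(panel) {
  if (any(panel$performance < 0, na.rm = TRUE)) {
    bad <- which(panel$performance < 0)[1]
    abort(sprintf("negative performance in row %d (mutant %s)",
                  bad, panel$mutant_id[bad]),
          class = "epizyme_validation_error")
  }
  if (any(!is.na(panel$site) & panel$site < 1)) {
    abort("site indices must be >= 1", class = "epizyme_validation_error")
  }
  same <- !is.na(panel$wt_residue) & !is.na(panel$mut_residue) &
    panel$wt_residue == panel$mut_residue
  if (any(same)) {
    abort(sprintf("mutant %s has identical wild-type and replacement residues",
                  panel$mutant_id[which(same)[1]]),
          class = "epizyme_validation_error")
  }
  wt <- wt_replicates(panel)
  if (any(wt < 0)) {
    abort("negative wild-type replicate performance",
          class = "epizyme_validation_error")
  }
  panel
}

#' Wild-type replicates and orthologue performance of a panel
#'
#' @param panel A `mutant_panel`.
#' @return `wt_replicates()` returns the numeric vector of wild-type reference
#'   replicates; `ortholog_performance()` the stored orthologue performance
#'   (`NA` when not set).
#' @export
wt_replicates <- function(panel) {
  as.numeric(attr(panel, "wt_replicates") %||% numeric())
}

#' @rdname wt_replicates
#' @export
ortholog_performance <- function(panel) {
  attr(panel, "ortholog_performance") %||% NA_real_
}

#' Read a mutant panel from CSV
#'
#' Two layouts are accepted: long (`mutant_id`, `replicate`, `performance`)
#' with one row per replicate, or pre-fitted kinetics (`mutant_id`, `kcat`,
#' `km`) from which performance is computed as `kcat/km`. Rows whose
#' `mutant_id` equals `reference` are taken as wild-type replicates.
#'
#' @param path CSV file path.
#' @param reference `mutant_id` value marking wild-type reference rows.
#' @param ortholog Optional orthologue performance; alternatively a row with
#'   `mutant_id == "ORTHOLOG"` is consumed as the orthologue measurement.
#' @param col_map Optional named character vector mapping the expected column
#'   names to the names actually used in the file, e.g.
#'   `c(performance = "kcat_over_km")`.
#' @return A [mutant_panel()].
#' @export
read_panel <- function(path, reference = "WT", ortholog = NULL,
                       col_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "epizyme_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[std]]] <- std
      }
    }
  }
  kinetic <- all(c("kcat", "km") %in% names(raw))
  if (!kinetic && !"performance" %in% names(raw)) {
    abort("missing column: performance (or kcat + km)",
          class = "epizyme_format_error")
  }
  if (!"mutant_id" %in% names(raw)) {
    abort("missing column: mutant_id", class = "epizyme_format_error")
  }
  if (kinetic && !"performance" %in% names(raw)) {
    if (any(raw$km <= 0)) {
      abort("km must be positive to compute performance",
            class = "epizyme_validation_error")
    }
    raw$performance <- raw$kcat / raw$km
  }
  if (!"replicate" %in% names(raw)) {
    raw <- raw |>
      group_by(.data$mutant_id) |>
      mutate(replicate = dplyr::row_number()) |>
      ungroup()
  }
  is_orth <- raw$mutant_id == "ORTHOLOG"
  orth <- if (!is.null(ortholog)) ortholog
          else if (any(is_orth)) mean(raw$performance[is_orth])
          else NA_real_
  is_wt <- raw$mutant_id == reference
  mutant_panel(raw[!is_wt & !is_orth, , drop = FALSE],
               wt_replicates = raw$performance[is_wt],
               reference_name = reference,
               ortholog_performance = orth)
}

#' Write a mutant panel to CSV
#'
#' The inverse of [read_panel()]: wild-type replicates are written as rows
#' under the panel's reference name and the orthologue performance (if any)
#' under `"ORTHOLOG"`, so that `read_panel(write_panel(p))` reproduces `p`.
#'
#' @param panel A `mutant_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  wt <- wt_replicates(panel)
  core <- as_tibble(panel)[, c("mutant_id", "site", "wt_residue",
                               "mut_residue", "replicate", "performance")]
  extra <- list()
  if (length(wt) > 0) {
    extra <- c(extra, list(tibble(
      mutant_id = attr(panel, "reference_name"), site = NA_integer_,
      wt_residue = NA_character_, mut_residue = NA_character_,
      replicate = seq_along(wt), performance = wt
    )))
  }
  orth <- ortholog_performance(panel)
  if (!is.na(orth)) {
    extra <- c(extra, list(tibble(
      mutant_id = "ORTHOLOG", site = NA_integer_,
      wt_residue = NA_character_, mut_residue = NA_character_,
      replicate = 1L, performance = orth
    )))
  }
  out <- bind_rows(c(list(core), extra))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a stage result to disk
#'
#' Data frames are written as CSV; lists and single-row summaries as a
#' key-value text file (`key: value`, reals at 15 significant digits so a
#' round trip through [read_report()] is faithful to at least 12).
#'
#' @param x A data frame or a (possibly nested-free) named list of scalars.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("output directory does not exist: %s", dir),
          class = "epizyme_io_error")
  }
  if (is.data.frame(x)) {
    readr::write_csv(as_tibble(x), path)
  } else if (is.list(x)) {
    vals <- vapply(x, format_report_value, character(1))
    writeLines(paste0(names(x), ": ", vals), path)
  } else {
    abort("write_report handles data frames and named lists of scalars",
          class = "epizyme_format_error")
  }
  invisible(path)
}

format_report_value <- function(v) {
  if (is.character(v)) return(v)
  if (is.integer(v) || (is.numeric(v) && !is.na(v) && is.finite(v) &&
                        v == round(v) && abs(v) < 2^53)) {
    return(format(v, scientific = FALSE))
  }
  format(v, digits = 15)
}

#' @rdname write_report
#' @return `read_report()` returns the key-value file as a named list with
#'   numeric values where they parse as numbers.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^:]+): (.*)$", lines))
  out <- lapply(kv, function(m) {
    v <- m[3]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(out, vapply(kv, `[`, character(1), 2))
}

#' Run configuration
#'
#' Bundles the tunable constants of the pipeline: assay temperature (used by
#' the transition-state free-energy null), the false-discovery rate for
#' effect classification, the compensation tolerance (from the kinetic
#' standard-error bound of the assays), and the dominance-hyperbola fitness
#' parameters.
#'
#' @param temperature Assay temperature in Kelvin (default 310.15, i.e. 37 C).
#' @param fdr_q False discovery rate for [classify_panel()].
#' @param compensation_tolerance Relative tolerance for compensation calls.
#' @param fitness_a,fitness_b Dominance hyperbola parameters (asymptote and
#'   half-saturation constant on the relative-performance scale).
#' @param seed Integer seed for simulation stages.
#' @return A `run_config` list.
#' @export
run_config <- function(temperature = 310.15, fdr_q = 0.05,
                       compensation_tolerance = 0.10,
                       fitness_a = 1.0005, fitness_b = 0.00032,
                       seed = 1L) {
  stopifnot(temperature > 0, fdr_q > 0, fdr_q < 1,
            compensation_tolerance > 0, compensation_tolerance < 0.5,
            fitness_a > 0, fitness_b > 0)
  structure(list(temperature = temperature, fdr_q = fdr_q,
                 compensation_tolerance = compensation_tolerance,
                 fitness_a = fitness_a, fitness_b = fitness_b,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "epizyme_format_error")
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(" ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

#' @export
`[.mutant_panel` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("mutant_id", "replicate", "performance") %in% names(out))) {
    attr(out, "wt_replicates") <- attr(x, "wt_replicates")
    attr(out, "reference_name") <- attr(x, "reference_name")
    attr(out, "ortholog_performance") <- attr(x, "ortholog_performance")
    class(out) <- class(x)
  }
  out
}

#' @export
print.mutant_panel <- function(x, ...) {
  wt <- wt_replicates(x)
  cat(sprintf("<mutant_panel> %d mutants, %d wild-type replicates (%s)\n",
              length(unique(x$mutant_id)), length(wt),
              attr(x, "reference_name") %||% "WT"))
  NextMethod()
}
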
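#' Simulate two-lineage divergence with cryptic incompatibilities
#'
#' Two lineages diverge from a common ancestor, each fixing derived states
#' at its own set of sites. Residue-pair incompatibilities are drawn on
#' cross-background combinations: for every pair of divergent sites, each
#' state combination that mixes the two lineages' final residues (and is
#' not the purely ancestral pair, which the ancestor proves functional) is
#' deleterious independently with probability `p_pair`. A residue moved
#' between lineages can therefore clash with each of the other `D - 1`
#' divergent residues of the recipient, realising the snowball model
#' `f = (1 - p)^(D - 1)` for derived-residue introductions.
#'
#' The regime governs the within-lineage fixation histories:
#' * `covarion` - fixations are ordered so that no deleterious combination
#'   ever occurs within a lineage (mutations that would clash with the
#'   current genotype wait until their partner site has moved on);
#'   draws admitting no such order (possible only through rare constraint
#'   cycles) are redrawn.
#' * `nearly_neutral` - a fixation may transiently create a deleterious
#'   combination with the current genotype; the compensating fixation at
#'   the partner site follows within `compensation_lag` fixations.
#'
#' @param n_sites Total sites in the protein (>= 2 x fixations).
#' @param p_pair Per-pair deleterious interaction probability in \[0, 1\].
#' @param n_fixations_per_lineage Derived states fixed in each lineage.
#' @param regime `"covarion"` or `"nearly_neutral"`.
#' @param deleterious_effect Relative performance of an incompatible
#'   genotype (single configurable magnitude; the argument is two-state).
#' @param compensation_lag Maximum fixations between creating and resolving
#'   an incompatibility (nearly-neutral regime only).
#' @param seed Optional integer seed.
#' @return An `evol_scenario` object: site sets, final genotypes, the
#'   deleterious combination table, per-lineage fixation histories, and the
#'   audit of transient incompatibilities.
#' @export
simulate_divergence <- function(n_sites, p_pair, n_fixations_per_lineage,
                                regime = c("covarion", "nearly_neutral"),
                                deleterious_effect = 0.5,
                                compensation_lag = 1, seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(p_pair >= 0, p_pair <= 1, n_fixations_per_lineage >= 1,
            n_sites >= 2 * n_fixations_per_lineage,
            deleterious_effect >= 0, deleterious_effect < 1,
            compensation_lag >= 1)
  run <- function() {
    n_fix <- n_fixations_per_lineage
    sites <- sample.int(n_sites, 2 * n_fix)
    s1 <- sort(sites[seq_len(n_fix)])
    s2 <- sort(sites[n_fix + seq_len(n_fix)])
    g1 <- g2 <- rep("0", n_sites)
    g1[s1] <- "1"
    g2[s2] <- "2"

    clashes <- draw_clashes(s1, s2, g1, g2, p_pair)
    hist1 <- order_lineage(s1, "1", clashes, regime, compensation_lag)
    hist2 <- order_lineage(s2, "2", clashes, regime, compensation_lag)
    if (is.null(hist1) || is.null(hist2)) return(NULL) # cycle: redraw
    structure(list(
      n_sites = n_sites, p_pair = p_pair, regime = regime,
      deleterious_effect = deleterious_effect,
      compensation_lag = compensation_lag,
      sites_lineage1 = s1, sites_lineage2 = s2,
      genotype1 = g1, genotype2 = g2,
      incompatible_pairs = clashes,
      lineage_histories = list(lineage1 = hist1$history,
                               lineage2 = hist2$history),
      transients = bind_rows(
        mutate(hist1$transients, lineage = 1L),
        mutate(hist2$transients, lineage = 2L)
      ),
      forced_multi = hist1$forced_multi || hist2$forced_multi
    ), class = "evol_scenario")
  }
  build <- function() {
    for (i in 1:100) {
      out <- run()
      if (!is.null(out)) return(out)
    }
    abort("could not order covarion fixations after 100 redraws",
          class = "epizyme_simulation_error")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Deleterious cross-background state combinations. For each unordered pair
# of divergent sites the two mixed combinations (one residue from each
# final genotype) are candidates; the all-ancestral combination is exempt.
draw_clashes <- function(s1, s2, g1, g2, p_pair) {
  div <- sort(c(s1, s2))
  if (length(div) < 2) {
    return(tibble(site_a = integer(), state_a = character(),
                  site_b = integer(), state_b = character()))
  }
  pairs <- utils::combn(div, 2)
  cand <- bind_rows(
    tibble(site_a = pairs[1, ], state_a = g1[pairs[1, ]],
           site_b = pairs[2, ], state_b = g2[pairs[2, ]]),
    tibble(site_a = pairs[1, ], state_a = g2[pairs[1, ]],
           site_b = pairs[2, ], state_b = g1[pairs[2, ]])
  )
  cand <- cand[!(cand$state_a == "0" & cand$state_b == "0"), ]
  keep <- stats::runif(nrow(cand)) < p_pair
  cand[keep, , drop = FALSE]
}

# Within-lineage deleterious adjacency: W[i, j] = TRUE when the transient
# genotype holding the derived state at sites[i] and the ancestral state at
# sites[j] is deleterious.
within_matrix <- function(sites, state, clashes) {
  k <- length(sites)
  W <- matrix(FALSE, k, k)
  own <- clashes[(clashes$site_a %in% sites) & (clashes$site_b %in% sites), ]
  for (r in seq_len(nrow(own))) {
    ia <- match(own$site_a[r], sites)
    ib <- match(own$site_b[r], sites)
    if (own$state_a[r] == state && own$state_b[r] == "0") W[ia, ib] <- TRUE
    if (own$state_a[r] == "0" && own$state_b[r] == state) W[ib, ia] <- TRUE
  }
  W
}

# Fixation order for one lineage. Covarion: topological order avoiding all
# deleterious transients (NULL when the constraints cycle). Nearly-neutral:
# random order, but a created incompatibility obliges the compensating
# fixation within `lag` steps; candidates that would create more than one
# pending incompatibility are deferred when possible (forced acceptances
# are flagged).
order_lineage <- function(sites, state, clashes, regime, lag) {
  k <- length(sites)
  W <- within_matrix(sites, state, clashes)
  ord <- if (regime == "covarion") {
    covarion_order(W)
  } else {
    neutral_order(W, lag)
  }
  if (is.null(ord)) return(NULL)
  pos <- ord$order
  combos <- which(W, arr.ind = TRUE)
  pos_derived <- match(combos[, 1], pos)
  pos_ancestral <- match(combos[, 2], pos)
  realized <- pos_derived < pos_ancestral
  trans <- tibble(
    site_derived = sites[combos[realized, 1]],
    site_ancestral = sites[combos[realized, 2]],
    resolution_lag = (pos_ancestral - pos_derived)[realized]
  )
  list(
    history = tibble(step = seq_len(k), site = sites[pos],
                     from_state = "0", to_state = state),
    transients = trans,
    forced_multi = isTRUE(ord$forced_multi)
  )
}

covarion_order <- function(W) {
  # W[i, j]: i must not precede j -> j before i; Kahn's algorithm with
  # random tie-breaking
  k <- nrow(W)
  remaining <- seq_len(k)
  out <- integer(0)
  fixed <- logical(k)
  while (length(remaining) > 0) {
    # available: all j with W[i, j] already fixed for every i... constraint
    # is "if W[i, j], j before i", so i is available once all j with
    # W[i, j] are fixed
    avail <- remaining[vapply(remaining, function(i)
      all(fixed[which(W[i, ])]), logical(1))]
    if (length(avail) == 0) return(NULL)
    nxt <- if (length(avail) == 1) avail else sample(avail, 1)
    out <- c(out, nxt)
    fixed[nxt] <- TRUE
    remaining <- setdiff(remaining, nxt)
  }
  list(order = out, forced_multi = FALSE)
}

neutral_order <- function(W, lag) {
  k <- nrow(W)
  queue <- sample.int(k)
  out <- integer(0)
  fixed <- logical(k)
  pending <- integer(0)     # resolver indices with deadlines
  deadlines <- integer(0)
  forced_multi <- FALSE
  step <- 0L
  while (length(out) < k) {
    step <- step + 1L
    if (length(pending) > 0 && min(deadlines) <= step) {
      nxt <- pending[which.min(deadlines)]
    } else {
      cands <- queue[!fixed[queue]]
      creations <- vapply(cands, function(i)
        sum(W[i, ] & !fixed), integer(1))
      budget <- if (length(pending) > 0) 0L else 1L
      ok <- cands[creations <= budget]
      if (length(ok) > 0) {
        nxt <- ok[1]
      } else {
        nxt <- cands[which.min(creations)]
        forced_multi <- TRUE
      }
    }
    out <- c(out, nxt)
    fixed[nxt] <- TRUE
    keep <- pending != nxt
    pending <- pending[keep]
    deadlines <- deadlines[keep]
    new_resolvers <- which(W[nxt, ] & !fixed)
    if (length(new_resolvers) > 0) {
      pending <- c(pending, new_resolvers)
      deadlines <- c(deadlines, rep(step + lag, length(new_resolvers)))
    }
  }
  list(order = out, forced_multi = forced_multi)
}

#' @export
print.evol_scenario <- function(x, ...) {
  cat(sprintf(
    "<evol_scenario> %s regime: %d sites, %d + %d fixations, %d deleterious combos\n",
    x$regime, x$n_sites, length(x$sites_lineage1), length(x$sites_lineage2),
    nrow(x$incompatible_pairs)))
  if (nrow(x$transients) > 0) {
    cat(sprintf("  %d transient within-lineage incompatibilities (max lag %d)\n",
                nrow(x$transients), max(x$transients$resolution_lag)))
  }
  invisible(x)
}

#' Divergent sites of a scenario
#'
#' @param scenario An `evol_scenario`.
#' @return Sorted integer vector of sites where the two lineages differ.
#' @export
divergent_sites <- function(scenario) {
  sort(c(scenario$sites_lineage1, scenario$sites_lineage2))
}

#' Build a scenario from explicit genotypes
#'
#' Low-level constructor for hand-crafted interaction topologies (used by
#' [three_site_masking()] and in exhaustive checks). States are `"0"` for
#' ancestral, any other label for derived.
#'
#' @param genotype1,genotype2 Character state vectors of equal length.
#' @param incompatible_pairs Tibble with columns `site_a`, `state_a`,
#'   `site_b`, `state_b` listing deleterious state combinations
#'   (`site_a < site_b`).
#' @param deleterious_effect Relative performance of an incompatible
#'   genotype.
#' @return An `evol_scenario`.
#' @export
scenario_from_genotypes <- function(genotype1, genotype2, incompatible_pairs,
                                    deleterious_effect = 0.5) {
  stopifnot(length(genotype1) == length(genotype2))
  incompatible_pairs <- as_tibble(incompatible_pairs)
  swapped <- incompatible_pairs$site_a > incompatible_pairs$site_b
  if (any(swapped)) {
    tmp <- incompatible_pairs[swapped, ]
    incompatible_pairs[swapped, ] <- tibble(
      site_a = tmp$site_b, state_a = tmp$state_b,
      site_b = tmp$site_a, state_b = tmp$state_a)
  }
  structure(list(
    n_sites = length(genotype1), p_pair = NA_real_, regime = "manual",
    deleterious_effect = deleterious_effect, compensation_lag = NA_integer_,
    sites_lineage1 = which(genotype1 != "0"),
    sites_lineage2 = which(genotype2 != "0"),
    genotype1 = genotype1, genotype2 = genotype2,
    incompatible_pairs = incompatible_pairs,
    lineage_histories = list(), transients = tibble(),
    forced_multi = FALSE
  ), class = "evol_scenario")
}

# is a state combination at two sites deleterious?
combo_deleterious <- function(scenario, site_i, state_i, site_j, state_j) {
  ip <- scenario$incompatible_pairs
  if (nrow(ip) == 0) return(FALSE)
  a <- pmin(site_i, site_j)
  b <- pmax(site_i, site_j)
  sa <- ifelse(site_i < site_j, state_i, state_j)
  sb <- ifelse(site_i < site_j, state_j, state_i)
  any(ip$site_a == a & ip$site_b == b & ip$state_a == sa & ip$state_b == sb)
}

# brute-force genotype evaluation: functional iff no resident pair of
# states is a deleterious combination (independent oracle for swap logic)
genotype_functional <- function(scenario, genotype) {
  sites <- seq_along(genotype)
  for (i in sites) {
    for (j in sites[sites > i]) {
      if (combo_deleterious(scenario, i, genotype[i], j, genotype[j])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Swap a residue between lineages and score the hybrid genotype
#'
#' Moves one lineage's residue at a divergent site into the other lineage's
#' background. The hybrid has relative performance 1 when the introduced
#' residue forms no deleterious combination with any of the recipient's
#' other divergent residues, and `deleterious_effect` otherwise.
#'
#' @param scenario An `evol_scenario`.
#' @param site A divergent site.
#' @param direction `"1_into_2"` (move lineage 1's residue into lineage 2)
#'   or `"2_into_1"`.
#' @return One-row tibble: `site`, `direction`, `introduced_state`,
#'   `n_clashes`, `performance`.
#' @export
swap_experiment <- function(scenario, site,
                            direction = c("1_into_2", "2_into_1")) {
  direction <- match.arg(direction)
  donor <- if (direction == "1_into_2") scenario$genotype1 else scenario$genotype2
  recip <- if (direction == "1_into_2") scenario$genotype2 else scenario$genotype1
  if (donor[site] == recip[site]) {
    abort(sprintf("site %d is not divergent between the lineages", site),
          class = "epizyme_validation_error")
  }
  introduced <- donor[site]
  others <- setdiff(divergent_sites(scenario), site)
  clash <- vapply(others, function(j)
    combo_deleterious(scenario, site, introduced, j, recip[j]), logical(1))
  tibble(site = site, direction = direction, introduced_state = introduced,
         n_clashes = sum(clash),
         performance = if (any(clash)) scenario$deleterious_effect else 1)
}

#' Swap outcomes for every divergent site
#'
#' @inheritParams swap_experiment
#' @return A tibble with one row per divergent site, as in
#'   [swap_experiment()].
#' @export
swap_outcome_table <- function(scenario,
                               direction = c("1_into_2", "2_into_1")) {
  direction <- match.arg(direction)
  purrr::map_dfr(divergent_sites(scenario),
                 function(s) swap_experiment(scenario, s, direction))
}

#' Three-site interaction chain: masking of epistatic sites
#'
#' Builds the canonical three-site scenario in which the middle site of a
#' pairwise interaction chain is masked: lineage 1 fixes a derived residue
#' at site 1, lineage 2 at sites 2 and 3, and the deleterious combinations
#' chain site 2 to both neighbours (with site 1's derived residue, and with
#' site 3's ancestral residue). Swapping lineage 1's residues into lineage 2
#' then shows a deleterious effect at exactly two of the three interacting
#' sites -- single-residue swaps undercount the sites engaged in epistasis.
#'
#' @param deleterious_effect Relative performance of an incompatible
#'   hybrid.
#' @return The swap outcome table for direction `"1_into_2"`, with the
#'   scenario attached as attribute `"scenario"`.
#' @export
three_site_masking <- function(deleterious_effect = 0.5) {
  sc <- scenario_from_genotypes(
    genotype1 = c("1", "0", "0"),
    genotype2 = c("0", "2", "2"),
    incompatible_pairs = tibble(
      site_a = c(1L, 2L), state_a = c("1", "2"),
      site_b = c(2L, 3L), state_b = c("2", "0")
    ),
    deleterious_effect = deleterious_effect
  )
  out <- swap_outcome_table(sc, "1_into_2")
  out$deleterious <- out$performance < 1
  attr(out, "scenario") <- sc
  out
}
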
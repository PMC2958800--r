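# replay a lineage's history and collect the deleterious status of every
# intermediate genotype (checked over divergent-site pairs only; all other
# sites stay ancestral on both lineages and ancestral pairs are never
# deleterious)
replay_deleterious_steps <- function(sc, lineage) {
  hist <- sc$lineage_histories[[lineage]]
  div <- divergent_sites(sc)
  geno <- rep("0", sc$n_sites)
  bad_steps <- integer(0)
  for (k in seq_len(nrow(hist))) {
    geno[hist$site[k]] <- hist$to_state[k]
    ok <- TRUE
    for (i in seq_along(div)) {
      for (j in seq_along(div)) {
        if (j <= i) next
        if (epizyme:::combo_deleterious(sc, div[i], geno[div[i]],
                                        div[j], geno[div[j]])) ok <- FALSE
      }
    }
    if (!ok) bad_steps <- c(bad_steps, k)
  }
  bad_steps
}

test_that("covarion histories never pass through a deleterious genotype", {
  for (s in 1:60) {
    sc <- simulate_divergence(30, 0.08, 6, "covarion", seed = s)
    expect_equal(nrow(sc$transients), 0)
    expect_length(replay_deleterious_steps(sc, "lineage1"), 0)
    expect_length(replay_deleterious_steps(sc, "lineage2"), 0)
  }
})

test_that("nearly-neutral histories create and then resolve incompatibilities", {
  n_with_transients <- 0
  for (s in 1:60) {
    sc <- simulate_divergence(30, 0.08, 6, "nearly_neutral",
                              compensation_lag = 1, seed = s)
    if (nrow(sc$transients) > 0) {
      n_with_transients <- n_with_transients + 1
      # each created incompatibility is resolved by a later fixation ...
      expect_true(all(is.finite(sc$transients$resolution_lag)))
      expect_true(all(sc$transients$resolution_lag >= 1))
      # ... and by the very next one unless several arose at once
      if (!sc$forced_multi && max(table(sc$transients$site_derived)) == 1) {
        expect_true(all(sc$transients$resolution_lag <= 1))
      }
      # the deleterious intermediate really is deleterious in replay
      bad <- c(replay_deleterious_steps(sc, "lineage1"),
               replay_deleterious_steps(sc, "lineage2"))
      expect_gt(length(bad), 0)
    }
  }
  # regime separation: the nearly-neutral process does visit deleterious
  # intermediates at this interaction density
  expect_gt(n_with_transients, 5)
})

test_that("no incompatibilities means every swap and history is clean", {
  sc <- simulate_divergence(40, 0, 8, "covarion", seed = 3)
  expect_equal(nrow(sc$incompatible_pairs), 0)
  out <- swap_outcome_table(sc, "1_into_2")
  expect_true(all(out$performance == 1))
  out2 <- swap_outcome_table(sc, "2_into_1")
  expect_true(all(out2$performance == 1))
})

test_that("two-site scenario: the hybrid reveals, the reversion restores", {
  # lineages fixed A (site 1) and B (site 2); the A-B combination is
  # deleterious but never tested within either lineage
  sc <- scenario_from_genotypes(
    genotype1 = c("1", "0"),
    genotype2 = c("0", "2"),
    incompatible_pairs = tibble::tibble(site_a = 1L, state_a = "1",
                                        site_b = 2L, state_b = "2"),
    deleterious_effect = 0.3
  )
  # moving A into species 2 creates the deleterious AB genotype
  expect_equal(swap_experiment(sc, 1, "1_into_2")$performance, 0.3)
  expect_equal(swap_experiment(sc, 2, "2_into_1")$performance, 0.3)
  # moving the ancestral residue back restores the ancestral state
  expect_equal(swap_experiment(sc, 1, "2_into_1")$performance, 1)
  expect_equal(swap_experiment(sc, 2, "1_into_2")$performance, 1)
  # a non-diverged site cannot be swapped
  expect_error(swap_experiment(sc, 3, "1_into_2"))
})

test_that("three-site chain masks one of the interacting sites", {
  out <- three_site_masking()
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$deleterious), 2)
  # the masked site is the middle of the chain
  expect_false(out$deleterious[out$site == 2])

  empty <- scenario_from_genotypes(
    c("1", "0", "0"), c("0", "2", "2"),
    tibble::tibble(site_a = integer(), state_a = character(),
                   site_b = integer(), state_b = character())
  )
  none <- swap_outcome_table(empty, "1_into_2")
  expect_equal(sum(none$performance < 1), 0)
})

test_that("swap outcomes match brute-force genotype evaluation on all
           three-site topologies", {
  combos <- tibble::tibble(
    site_a = c(1L, 1L, 2L, 2L),
    state_a = c("1", "1", "0", "2"),
    site_b = c(2L, 3L, 3L, 3L),
    state_b = c("2", "2", "2", "0")
  )
  g1 <- c("1", "0", "0")
  g2 <- c("0", "2", "2")
  for (mask in 0:15) {
    keep <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    sc <- scenario_from_genotypes(g1, g2, combos[keep, ])
    for (dir in c("1_into_2", "2_into_1")) {
      donor <- if (dir == "1_into_2") g1 else g2
      recip <- if (dir == "1_into_2") g2 else g1
      for (site in 1:3) {
        hybrid <- recip
        hybrid[site] <- donor[site]
        expected <- if (epizyme:::genotype_functional(sc, hybrid)) 1 else 0.5
        got <- swap_experiment(sc, site, dir)$performance
        expect_equal(got, expected,
                     info = sprintf("mask=%d dir=%s site=%d", mask, dir, site))
      }
    }
  }
})

test_that("derived-residue swaps follow the snowball no-effect fraction", {
  p <- 0.03
  n_fix <- 10
  D <- 2 * n_fix
  outcomes <- vapply(1:200, function(s) {
    sc <- simulate_divergence(60, p, n_fix, "nearly_neutral", seed = s)
    site <- withr::with_seed(s + 31000L, {
      if (stats::runif(1) < 0.5) sample(sc$sites_lineage1, 1)
      else sample(sc$sites_lineage2, 1)
    })
    dir <- if (site %in% sc$sites_lineage1) "1_into_2" else "2_into_1"
    swap_experiment(sc, site, dir)$performance == 1
  }, logical(1))
  f <- no_effect_fraction(p, D)
  expect_lt(abs(mean(outcomes) - f), 3 * sqrt(f * (1 - f) / length(outcomes)))
})

test_that("scenario bookkeeping: site sets, divergence and histories", {
  sc <- simulate_divergence(50, 0.02, 7, "covarion", seed = 9)
  expect_length(intersect(sc$sites_lineage1, sc$sites_lineage2), 0)
  expect_equal(divergent_sites(sc),
               sort(c(sc$sites_lineage1, sc$sites_lineage2)))
  h1 <- sc$lineage_histories$lineage1
  expect_setequal(h1$site, sc$sites_lineage1)
  expect_equal(h1$from_state, rep("0", 7))
  expect_equal(h1$to_state, rep("1", 7))
  # determinism
  sc2 <- simulate_divergence(50, 0.02, 7, "covarion", seed = 9)
  expect_identical(sc$incompatible_pairs, sc2$incompatible_pairs)
  expect_identical(sc$lineage_histories, sc2$lineage_histories)
})
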
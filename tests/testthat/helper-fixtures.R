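# Build a panel from per-mutant mean performances: replicates are mean +/- dev
# so each mutant's mean is exact. Wild-type replicates default to a constant
# series (error model mean exactly wt).
panel_from_means <- function(mean_perfs, wt = 166, dev = 0,
                             wt_replicates = rep(wt, 4),
                             ortholog = NA_real_) {
  n <- length(mean_perfs)
  ids <- sprintf("M%03d", seq_len(n))
  dat <- tibble::tibble(
    mutant_id = rep(ids, each = 2),
    site = rep(seq_len(n), each = 2),
    wt_residue = "A",
    mut_residue = "V",
    replicate = rep(1:2, times = n),
    performance = pmax(0, rep(mean_perfs, each = 2) + rep(c(-dev, dev), times = n))
  )
  mutant_panel(dat, wt_replicates = wt_replicates,
               ortholog_performance = ortholog)
}

# Brute-force step-up definition of the Benjamini-Hochberg rejection set
brute_force_bh <- function(p, q) {
  m <- length(p)
  sp <- sort(p)
  ok <- which(sp <= seq_len(m) * q / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= sp[max(ok)]
}

# Michaelis-Menten design points used across kinetics tests
mm_points <- function(vmax, km, s = c(0.25, 0.5, 1, 2, 10) * km) {
  tibble::tibble(substrate_conc = s, rate = vmax * s / (km + s))
}

# Table of focal-single + double performances as printed for the F73L screen
f73l_doubles <- function() {
  tibble::tibble(
    primary = "F73L",
    secondary = c("F120A", "F132L", "C136I", "I179V"),
    single_perf = 7,
    double_perf = c(44, 25, 39, 66)
  )
}

# Named vector of true relative performances (one per mutant) from a
# generated panel
panel_truth <- function(pan) {
  d <- dplyr::distinct(tibble::as_tibble(pan),
                       .data$mutant_id, .data$true_relative_perf)
  stats::setNames(d$true_relative_perf, d$mutant_id)
}
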
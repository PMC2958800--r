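---
title: "Detecting cryptic epistasis from orthologue-swap mutant panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic epistasis from orthologue-swap mutant panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epizyme)
library(dplyr)
```

## The experimental design this package analyses

Two orthologous enzymes that share fold and function but differ at many
residues pose a simple question: do those residues evolve independently?
The orthologue-swap design answers it by introducing each divergent residue
of orthologue B, one at a time, into the backbone of orthologue A and
measuring the performance of every single mutant. Performance here is the
specificity constant $k_\mathrm{cat}/K_m$ toward the rate-limiting
substrate, the single scalar that couples enzyme function to growth for a
metabolic enzyme. The motivating system is a bacterial
β-isopropylmalate dehydrogenase (IMDH) pair diverged at 168 of 365 sites,
with the wild-type reference at 166 mM⁻¹s⁻¹ and the orthologue at
42 mM⁻¹s⁻¹, but every stage takes ordinary tabular data and applies to any
enzyme pair.

If sites were independent, each single mutant should perform like a small
perturbation of the reference, and the combined replacements should
reconstitute the orthologue's performance. The pipeline quantifies how
badly both halves of that expectation fail, then asks what the failure
implies for evolution: how often residue pairs interact, how fast such
interactions accumulate with divergence, and how visible any of this is
to selection.

## Decomposing the distribution of mutational effects

`fit_error_model()` summarises repeated wild-type assays as a Gaussian
measurement error; `classify_panel()` runs per-mutant Welch tests (unequal
variances, fractional Satterthwaite degrees of freedom) against the
wild-type replicate series and applies Benjamini–Hochberg control at
`fdr_q` (default 0.05) to call each mutant `decreased`, `unchanged` or
`increased`. A `large_increase` flag marks relative performance above
1.15, the screen's threshold for a functionally enhanced outlier.

The neutral class is also estimated without any test, by reflection:
mutants with no true effect land above the wild-type mean half the time,
so twice the above-mean count estimates the whole no-effect class.
`estimate_neutral_count()` returns that integer together with a
half-Gaussian fit (MLE $\hat\sigma$ = root mean square of the above-mean
deviations) whose agreement with the error sd supports the reflection
logic; the sd ratio is reported with a bootstrap interval rather than a
formal test because the comparison is diagnostic, not inferential. Ties
with the wild-type mean count as "not above" — a conservative choice that
is immaterial on continuous data.

```{r}
pan <- generate_panel(panel_spec(seed = 1))
glance(classify_panel(pan))
estimate_neutral_count(pan, boot = 0) |> select(n_above:error_sd)
```

### A caution on duplicate assays

With only two replicates per mutant the Welch reference distribution is a
poor approximation: its true type-I error at nominal 0.05 is roughly 0.12
against a 30-replicate reference series, and Benjamini–Hochberg control
inherits the distortion, so realised false-discovery proportions on
duplicate-assay panels run well above the nominal `fdr_q`. The package
implements the tests in their standard form and leaves the calibration
properties to be measured; the test suite demonstrates both the
small-sample distortion at duplicate replication and correct calibration
once replication reaches about ten. Counts of "changed" mutants from
duplicate assays should therefore be read as screening calls, not as
error-controlled discoveries — the reflection estimator, which uses only
the sign of deviations, is the robust summary at this replication.

## Independence null models for the orthologue's performance

Two nulls bracket "no epistasis". The additive null sums raw performance
effects: $\mathrm{wt} + \sum_i (P_i - \mathrm{wt})$. The multiplicative
null treats transition-state free energies as additive: each mutant
contributes $\Delta\Delta G'_i = -RT\ln(P_i/\mathrm{wt})$
($R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹, $T$ defaulting to the 310.15 K
assay temperature), so performances multiply,
$\mathrm{wt}\prod_i(P_i/\mathrm{wt}) =
\mathrm{wt}\,e^{-\sum_i \Delta\Delta G'_i/RT}$.
We store $\sum\Delta\Delta G'$ with the convention that positive values
mean slower mutants, and expose the exponent $-\sum\Delta\Delta G'/RT$
separately; a single inactive mutant makes the sum $+\infty$ and the
prediction exactly zero. On a panel with a deleterious left tail the
additive sum goes negative (physically impossible) and any inactive
mutant zeroes the multiplicative prediction, while the real orthologue
performs comparably to the wild type — epistasis is required.

`epistasis_verdict()` formalises this: a null is untenable when it is
impossible (non-positive against a positive observation) or when the
observation sits more than 3 error-sd away. The 3-sd band is a package
decision — the scientific argument is impossibility, and the band only
guards borderline panels; its calibration (≥95% `consistent` verdicts in
a true multiplicative world with assay noise) is property-tested.

```{r}
em <- fit_error_model(pan)
perfs <- panel_truth <- distinct(as_tibble(pan), mutant_id,
                                 true_relative_perf)$true_relative_perf * 166
epistasis_verdict(166, perfs, observed = 42, em) |>
  select(additive_prediction, multiplicative_prediction, verdict)
```

## Compensation calls and their two readings

For a deleterious focal mutation screened against every second-site
mutation, `classify_compensation()` applies thresholds strongest-first:
`full_to_wt` (double reaches wild type within tolerance), then
`full_to_ortholog`, then `partial` (exceeds the single by more than the
tolerance), else `none`. The default 10% tolerance mirrors the assays'
kinetic standard-error bound. `interaction_interpretations()` reports the
same table under both "full restoration" standards side by side, because
the data genuinely support either a pairwise interaction (wild-type
standard) or a higher-order interaction destroyed by any single reversion
(orthologue standard). Where the printed exemplar table and its narrative
disagree — a double mutant described as fully restored while its printed
value sits far below the wild type — the package reports what the
thresholds yield from the numbers and does not reconcile the prose.

## Interaction probability and the snowball

Two estimators of the per-pair deleterious-interaction probability $p$:

* `p_from_pair_library(n, k)`: $k$ deleterious pairs among
  $\binom{n}{2}$ recombined pairs.
* `p_from_no_effect_fraction(f, D)`: inverts $f = (1-p)^{D-1}$, the
  probability that a residue introduced at divergence $D$ clashes with
  none of the other $D-1$ divergent residues.

The exponent $D-1$ follows from counting one independent clash
opportunity per other divergent residue; the alternative convention of
exponent $D$ changes the estimate by under 1% at $D = 168$ and leaves the
cross-check below unchanged, so the convention is documented here rather
than load-bearing. `compare_estimates()` reports the fold difference between
the two routes — about two-fold for the IMDH panel versus the subtilisin
recombinant library (52 replacements, 7 deleterious pairs), which is the
model's own consistency check. `snowball_curve()` traces $f(D)$:
individually rare interactions compound into near-certain incompatibility
within a few hundred residues of divergence.

```{r}
p_lib <- p_from_pair_library(52, 7)
p_panel <- p_from_no_effect_fraction(104 / 168, 168)
c(p_lib = p_lib, p_panel = p_panel)
compare_estimates(p_lib, p_panel)
```

## From performance to selection

Fitness follows a dominance hyperbola of relative performance,
$y = a x /(b + x)$ with printed parameters $a = 1.0005$ and
$b = 0.00032$; $x$ is performance relative to the wild type ($x = 1$),
which places the wild type ~3000-fold beyond the half-saturation constant,
far into a fitness plateau. Selection coefficients are fitness
differences, $s(x) = y(1) - y(x)$, matching the per-generation magnitudes
quoted for chemostat competition. `performance_cutoff()` inverts the
strictly decreasing $s$ by bisection to residual $10^{-12}$; at
$s = 10^{-5}$ per generation the cutoff is $x^\ast \approx 0.97$ — a
mutant can lose 3% of wild-type performance before selection reaches even
$10^{-5}$. `plateau_summary()` applies the curve to a panel's mean
relative performances (measurement error is not propagated through the
curve; the plateau makes the summary insensitive to it) and reports the
sub-threshold share with a Clopper–Pearson interval.

```{r}
performance_cutoff(1e-5)
plateau_summary(classify_panel(pan), s_threshold = 1e-5) |>
  select(fraction_below, ci_lo, ci_hi, x_star)
```

## The synthetic panel generator

No raw replicate table for the 168-mutant panel was ever published, so
`generate_panel()` defines the study conditions the pipeline is validated
under: 168 mutants, neutral fraction 104/168, five fully inactive
mutants, wild-type mean 166 mM⁻¹s⁻¹, duplicate mutant assays against a
30-replicate wild-type series, and Gaussian replicate error proportional
to each mutant's true mean. The 5% coefficient of variation is an
assumption anchored to the published bound that all kinetic standard
errors were below 10% of their estimates; the 30-replicate wild-type
series is likewise a choice (the published series length is unstated, and
"repeatedly assayed" requires enough replicates for a stable error
Gaussian). The deleterious left tail is Beta(2, 1.5) over relative
performance — a broad left shoulder — because only the class sizes, not
the tail shape, are recoverable; analyses that depend on tail shape
(e.g. the sub-threshold fitness fraction) should be read accordingly.
True effects are carried alongside the noisy replicates so estimator
recovery can be scored against ground truth.

What the generator does not emulate: systematic (non-Gaussian) assay
error, correlated errors within expression batches, and any relationship
between a mutant's structural context and its effect size. Passing tests
on generated panels therefore validate the estimators' statistical
behaviour under the stated error model, not the biology of any particular
panel.

## Two-lineage evolution and swap experiments

`simulate_divergence()` grows two lineages from a common ancestor, each
fixing derived residues at its own sites, and draws residue-pair
incompatibilities on *cross-background* state combinations — pairs of
residues that never co-occurred within either lineage — independently
with probability `p_pair` per combination (the all-ancestral combination
is exempt: the ancestor worked). A `swap_experiment()` then moves one
residue between lineages; the hybrid is compromised (a single configurable
`deleterious_effect`, reflecting the two-state functional/compromised
reading of the design) exactly when the introduced residue completes a
deleterious combination. Introducing a *derived* residue faces one
independent clash opportunity per other divergent residue, so the
simulator realises $f = (1-p)^{D-1}$ exactly for derived introductions;
reversions face fewer opportunities because they partially restore
ancestral combinations. This is the package's resolution of a real
tension: a history-consistent incompatibility model cannot give every
swap the full $D-1$ opportunities, and the derived-introduction
convention is the reading under which the snowball formula is exact.

The regimes differ only in fixation order. Covarion histories never pass
through a deleterious intermediate: fixations whose partner residue is
still ancestral wait (a topological sort of the precedence constraints;
draw sets admitting no order, which arise only through rare constraint
cycles at order $p^2$, are redrawn). Nearly-neutral histories may create
a deleterious intermediate and must resolve it within `compensation_lag`
fixations — the compensating substitution follows the slightly deleterious
one, mirroring drift-then-positive-selection. `compensation_lag` has no
empirically fixed value; its default of 1 encodes the strongest version of
"compensation comes next", and the scenario audit (`transients`) records
realised lags so the invariant is checkable. When one fixation creates
several incompatibilities at once the queue cannot resolve all of them
within a lag of 1; such scenarios are flagged (`forced_multi`) rather than
silently reordered.

`three_site_masking()` packages the canonical chain topology in which the
middle site of a three-site interaction chain shows no swap effect while
its two partners do: single-residue swaps undercount interacting sites,
which is why a panel's count of functionally affected sites is a lower
bound on the epistatically engaged ones.

```{r}
three_site_masking()[, c("site", "introduced_state", "performance")]
```

## Numerical and design choices

* Michaelis–Menten fits use deterministic initialisation
  (`Vmax0` = max rate; `Km0` by linear interpolation at half `Vmax0`) and
  Levenberg–Marquardt with `ftol` $10^{-10}$, 500 iterations; failures
  fall back to a dense $(V_{max}, K_m)$ grid search and are flagged
  `method = "grid"`. The grid is also the independent oracle in tests.
* The sub-saturating screen obeys rate $\propto k_\mathrm{cat}/K_m$; the
  linear form always over-predicts the exact hyperbolic rate by the
  factor $(K_m+S)/K_m$, so `predict_screen_rate()` reports both and their
  ratio. Screening Km values are treated in the units given, with the
  A340 extinction conversion (6220 M⁻¹cm⁻¹) available as an opt-in input
  transform rather than hard-wired.
* Welch p-values keep fractional degrees of freedom; the degenerate
  zero-variance-both-sides case is defined as $p = 1$ (equal means) or
  $p = 0$ (unequal), flagged. Benjamini–Hochberg rejections delegate to
  `stats::p.adjust`; an exhaustive brute-force step-up enumeration backs
  it in tests.
* Bisection for $x^\ast$ runs on $[0, 1]$ where $s$ is monotone; 200
  iterations bound the residual far below the $10^{-12}$ tolerance.
* Simulation problem sizes in the test suite (hundreds of panels of
  ~160 mutants, hundreds of divergence scenarios at $D \le 40$) were
  chosen to put 3-SEM/3-sd bands within a few percent of the simulated
  truth.
* Panels serialise to one CSV row per (mutant, replicate); scalar
  summaries serialise as key-value text at 15 significant digits so round
  trips preserve 12. All randomness flows through explicit seeds.

## Known limitations

The motivating study's exact split of changed/unchanged mutants, its
error-Gaussian parameters and its empirical sub-threshold fitness
fraction all depend on raw replicate tables that were never deposited and
cannot be reproduced; the pipeline reproduces the *derived* quantities
(reflection estimate, compensation calls and folds, interaction
probabilities and their two-fold consistency, fitness-plateau geometry)
and validates everything else by property. Higher-order interaction
probabilities are out of scope — the chain argument for multi-site
compensation is qualitative — and the evolution simulator tracks fixation
events, not population-genetic dynamics.
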
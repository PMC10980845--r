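---
title: "Methods: lifespan reorganization of a language connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifespan reorganization of a language connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifeconn)
```

`lifeconn` implements a complete graph-theoretic analysis of how a
131-region language-related functional connectome reorganizes across the
adult lifespan, together with the statistical machinery that links that
reorganization to cognitive performance. This vignette documents the models
and procedures, the tunable parameters and their defaults, the synthetic
cohort generator used for validation, and the numerical and design choices
a maintainer should know about.

## From connectivity matrices to binary graphs

The unit of input is one subject's symmetric ROI × ROI matrix of Fisher-z
transformed correlations. `clean_matrix()` zeroes negative correlations
(a common preprocessing convention for binary graph analysis: negative
edges have no agreed-upon meaning in unsigned path-based metrics), zeroes
the diagonal, and repairs float-level asymmetry by averaging. Asymmetry up
to `1e-6` is treated as numerical debris; anything grosser aborts, because
it indicates corrupted input rather than rounding. Cleaning is idempotent.

`proportional_threshold()` retains the strongest edges at a target density
in the *full-off-diagonal* counting convention: the target is
`floor(density · N · (N−1))` directed entries, i.e. that number halved
(rounded down) undirected pairs. For N = 131 at 15% density this gives
2554 directed entries — 0.15 · 131 · 130 = 2554.5, floored. The convention
matters: counting undirected pairs against `N(N−1)/2` would give 1277, and
the two conventions disagree by one edge whenever the product is odd.
`n_edges_retained` reports the directed-entry count. Ties at the cut are
broken deterministically in (row, column) order; with continuous weights
ties are measure-zero, but the determinism matters for reproducibility and
for degenerate (noise-free) inputs, where whole blocks tie exactly — see
the planted-recovery note below.

Subjects whose thresholded graph has a largest connected component below
80% of nodes are flagged; the analysis drivers exclude them from group
statistics and log the exclusion.

## System-level efficiency and balance

Global efficiency is the mean of inverse shortest-path lengths over ordered
node pairs, with disconnected pairs contributing 0 (the standard
convention; the alternative — dropping such pairs — would *reward*
fragmentation). Local efficiency uses the induced-neighborhood-subgraph
definition: per node, the global efficiency of the subgraph spanned by its
neighbors, 0 for degree < 2. Note this differs from implementations that
compute neighbor-restricted paths in the full graph; the induced-subgraph
form is the one used by the field's reference MATLAB toolbox, and the test
suite pins it against a brute-force BFS oracle.

The integration–segregation balance is
`(E_glob − E_loc) / (E_glob + E_loc)` ∈ [−1, 1], positive when integration
dominates. Both efficiencies of a sparse binarized connectome are typically
such that the balance is negative; what matters for aging is its upward
drift.

`select_density()` formalizes the usual "inspect the curves" choice of
sparsity: across the sweep {10, 12, 15, 17, 20}%, both the global
efficiency curve (increasing in density) and the mean clustering curve
(decreasing after normalization) are min-max normalized over the sweep and
the density minimizing their absolute gap is chosen, ties to the sparser
level. This is a deterministic stand-in for a visual judgment; on a given
cohort it may legitimately pick a different level than 15%.

## Consensus modular structure

Subsystems come from Louvain modularity maximization at resolution
γ = 1.295 — the value that targets resting-state-network granularity on
131-ROI connectomes — wrapped in consensus clustering because single
Louvain runs are order-dependent. `consensus_cluster()` runs Louvain
`n_runs` times, forms the node × node co-assignment frequency matrix,
zeroes entries below τ = 0.5 (nodes that fail to co-assign in at least
half the runs; the threshold is closed, "at least 50%"), re-clusters the
thresholded matrix as a weighted graph at resolution 1, and iterates until
the co-assignment matrix is binary and identical across runs (cap: 100
outer iterations, after which the current partition is returned flagged
unconverged). `group_consensus()` applies the same iteration to the
co-assignment matrix across subjects' partitions.

Defaults: `n_runs = 100` in package functions (the analysis drivers use
100; the procedure is insensitive to this once runs are in the hundreds,
and the co-assignment-vs-counting oracle test runs at `n_runs = 10`).
Exactly tied 50/50 blocks survive the closed threshold; the test suite
pins this behavior. Modules smaller than 4 nodes (e.g. the unassigned ROIs
that end up as singletons) can be dropped for reporting via
`drop_small_modules()` — they are too small for compositional statistics,
whose per-module proportions would be degenerate.

Subsystem annotation weights each member ROI by its percent overlap with
its primary resting-state network, so a module's composition is an
overlap-weighted share summing to 100%.

## Nodal roles

Within-module degree z-scores standardize a node's within-module degree
against its module's distribution (population SD; SD = 0 and singleton
modules yield 0). The participation coefficient is
`1 − Σ_s (k_is/k_i)²`; its normalized variant subtracts the mean PC over
`n_null` module-size-preserving label permutations (default 100),
removing the mechanical dependence of PC on module sizes. Both metrics are
then standardized *across the subject's 131 nodes* (population SD) and cut
into quadrants: connector (`zPC ≥ 0, zWMZ ≥ 1e-5`), provincial
(`zPC < 0, zWMZ ≥ 1e-5`), satellite (`zPC ≥ 0, zWMZ < 1e-5`), peripheral
(`zPC < 0, zWMZ < 1e-5`). The `1e-5` cut on a standardized score is an
"effectively zero" guard kept verbatim from the field's convention; on
continuous data it is indistinguishable from 0, and the quadrants tile the
plane, so every node gets exactly one role.

Roles are computed on the *group* consensus partition by default so that
role proportions are comparable across subjects; passing a subject's own
partition is supported. Role compositions (counts / nodes) are reported at
the system and per-subsystem scope and sum to 1 within each scope.

## Compositional lifespan trends

Proportions are compositional: bounded, unit-sum, and mutually dependent.
Before regression each composition is made strictly positive by
multiplicative zero replacement — zeros become δ (default half the
smallest observed non-zero proportion; the full Bayesian-multiplicative
machinery is not re-implemented, the multiplicative closure it shares is)
— with non-zero parts rescaled so ratios are untouched; then each
proportion is log-odds transformed, `log(x/(1−x))`, which removes the
boundaries while staying interpretable.

Age trends are penalized cubic regression splines (`mgcv`, REML) with a
3-knot basis — small enough that the fit stays near-linear unless the data
demand curvature, mirroring how these analyses guard against overfitting —
with linear adjustment for mean functional connectivity (the average of
positive unthresholded upper-triangle weights), sex, and total
intracranial volume. The smooth's F-test, effective degrees of freedom and
p-value are reported; a companion linear fit supplies the slope `b` with a
95% CI and a partial η² from its t-statistic (`t²/(t²+df)`). Per-subsystem
families use a single factor–smooth model (`y ~ group + s(age, by=group)`)
and Benjamini–Hochberg q-values within the family; the system-level family
is corrected separately.

`inflection_scan()` evaluates the central second difference of the fitted
smooth on an age grid and flags grid points whose simulation band — from
`B` multivariate-normal draws of the coefficient posterior (default 500) —
excludes zero, merging contiguous flags into intervals. Smooths with
edf < 1.1 are treated as linear and return no intervals; a penalized-out
smooth has no curvature worth scanning.

## Probabilistic role trajectories

Ages are binned into younger (18–44), middle (45–55), and older (>55) —
closed bounds on integer years, so 44 is younger and both 45 and 55 are
middle. Per region and bin, role frequencies are empirical subject
fractions. Assuming independence across bins (a modeling assumption forced
by cross-sectional data: the same subject is never observed in two bins),
the probability of a trajectory r1→r2→r3 is the product of the three
frequencies, giving 16 two-group and 64 three-group trajectories whose
probabilities sum to 1 per region.

Selection keeps the argmax trajectory plus every trajectory within the
tolerance band. The band is read as an *absolute* difference of
probability points (`p_max − p ≤ 0.05`) — the plain reading of "within a
5% range from the highest" — with `relative = TRUE` switching to
`p ≥ 0.95 · p_max`; both are defensible and the choice is exposed rather
than buried. A region "reconfigures" when any selected trajectory is
non-constant; because that count grows with the tolerance, the
argmax-only count is reported alongside, and transition-class tallies use
the non-constant selected trajectories.

## Brain–cognition CCA

The cognitive side applies the participant rules first: subjects with more
than 3 missing task scores (of 8) are excluded and logged; remaining
missing values are imputed with the median of the subject's age decile
(deciles of the retained sample); columns are z-scored. Two orthogonal
contrasts over the midlife bins — #1: 56–60 vs the mean of 45–50 and
51–55 (+2/−1/−1), #2: 51–55 vs 45–50 (+1/−1) — are centered and prepended
to the cognitive set only, letting the model express the nonlinear midlife
transition. Confounds (mean FC, sex, TIV) are removed from both sets by
least-squares residualization before the CCA.

The CCA itself is solved by SVD of the whitened cross-covariance
`Sxx^{-1/2} Sxy Syy^{-1/2}` (inverse symmetric square roots via
eigendecomposition, refusing inputs whose smallest eigenvalue is below
`1e-10` of the largest — rank-deficiency should fail loudly, not silently
regularize). It yields `min(pX, pY)` canonical functions with
nonincreasing correlations; Wilks Λ_k = Π_{j≥k}(1−Rc_j²) with Bartlett's
χ² approximation gives per-function p-values. Since variates are defined
only up to sign, each function is oriented so its largest-|r| cognitive
variable has a positive structure coefficient — without this, bootstrap
and cross-validation aggregates would average sign-flipped resamples to
meaningless near-zeros.

Interpretation uses structure coefficients (correlation of each observed
variable with its own set's variate), cross-correlations (brain variables
vs cognitive variates), and mechanism scores: the difference of the two
structure coefficients naming a mechanism (e.g. a provincial→connector
reconfiguration scores `r_connector − r_provincial`). The brain set in the
analysis driver is the 4 roles × 4 subsystems log-odds proportions plus
the system balance (17 columns); the exact brain-variable set is a
configuration choice, not a fixed contract, and `mechanism_scores()`
accepts any named pairs over it.

Robustness: 10-fold cross-validation refits the weights on training folds
and correlates held-out variates (sign-aligned to the full-sample fit, so
a null signal averages to ~0 rather than being rectified upward), and a
nonparametric bootstrap (default 1000) gives percentile intervals for the
canonical correlations and structure coefficients.

## The synthetic cohort generator

No public cohort ships with this kind of study, so validation rests on a
generator whose defaults *are* the study conditions:

* **Connectomes.** Each subject's matrix arises from simulated time series
  (default 150 points): four planted modules of 40/34/32/22 nodes (+3
  unassigned) each carry a latent Gaussian signal; node i's series is
  `w(age)·f_module(i) + b(age)·(Σ_k η_ik f_k + g) + ε`, with within-module
  coupling `w` falling linearly 0.65→0.55 over ages 18–88, between-module
  scale `b` rising 0.32→0.355 by the knee age (default 55) and on to
  0.38, node-specific half-normal cross-loadings η (SD 0.5) emulating
  overlapping resting-state networks, a global signal g, and noise
  (SD 0.5). Fisher-z correlations of these series (clamped to
  |r| ≤ 1−1e-7 so noise-free blocks stay finite) form the matrix. The
  cross-loadings are what keep 15%-density graphs connected: with pure
  block structure the ~2068 within-module pairs always out-rank every
  between-module pair and the thresholded graph falls apart into module
  components, which real cohorts (screened for ≥80% LCC) do not do. With
  `between_coupling ≡ 0` all off-block coupling vanishes and with
  `noise_sd = 0` as well the generator reduces to the exact factor limit,
  which the tests exploit. These coupling values were calibrated once,
  against three qualitative properties the study data possess by
  construction — thresholded graphs pass the LCC rule, the four modules
  are recoverable, and the efficiency balance drifts upward with age —
  and are not revisited.
* **Cognition.** Eight task scores load (8 × 2 default loading matrix
  spanning production, fluency, comprehension, executive and memory
  tasks) on a domain-general factor declining linearly from +1 to −1
  over the age range and a semantic factor following a Gaussian bump
  (SD 15 years) peaking at the knee age, plus noise (SD 0.2) and
  completely-at-random missingness (2%). A subject-level perturbation
  shared between the between-module coupling and the domain-general
  factor plants a brain–cognition link. The generator's spec lists the
  time-series and cognitive noise as separate fields (`noise_sd`,
  `cognitive_noise_sd`) because the two operate on different scales.
* **Role compositions.** `simulate_role_compositions()` bypasses the
  graph stage: role logits follow planted linear lifespan trends
  (defaults: connector +0.5, provincial −0.8, satellite −0.2,
  peripheral +0.3 logits over the age range — signs and rough magnitudes
  chosen to mirror the directions this literature reports), an optional
  Gaussian midlife bump, and noise (SD 0.3), mapped through a softmax.
  This is what lets trend-recovery rates be measured over 50 cohorts of
  n = 300 in seconds instead of re-running fifteen thousand
  connectome-to-partition pipelines.
* **Determinism.** A master seed fixes everything; per-subject sub-seeds
  are derived arithmetically (mod 2³¹) from (seed, subject index), so
  cohorts are reproducible file-for-file and subjects are independent.

What the generator does *not* emulate: head motion and physiological
artifacts, spatial autocorrelation and distance-dependent connectivity,
non-Gaussian BOLD features, site effects, and realistic task-score
distributions (no public means/SDs exist to calibrate against). Passing
tests therefore demonstrate that the *pipeline* is correct and can recover
planted structure of realistic strength — not that real data contain such
structure.

## Numerical choices and degenerate inputs

* Population (biased) SD is used for all per-subject standardization and
  WMZ; zero-SD groups map to 0 rather than NaN.
* Efficiency of disconnected pairs is 0; isolated nodes get PC 0 (with a
  warning) and clustering 0.
* Noise-free planted matrices make whole blocks tie exactly at the
  Fisher-z clamp; proportional thresholding would truncate tied blocks by
  its deterministic tie-break, so exact-recovery checks cluster the
  weighted cleaned matrix directly (the consensus machinery accepts
  weighted graphs).
* The problem sizes used by the test suite and acceptance script —
  exhaustive graph enumeration to 5 nodes with seeded samples at 6–8 and
  20 nodes, 50 replicate cohorts of n = 300–400 for trend recovery,
  100 simulations of n = 500 for CCA recovery, consensus runs in the
  50–100 range — were chosen as the smallest sizes at which the measured
  rates are stable, and are stated in the tests themselves.

## Known limitations

* Louvain is a greedy heuristic; only consensus results are stable, and
  γ = 1.295 is a granularity choice inherited from the 131-ROI context,
  not a universal constant.
* The trajectory model's independence-across-bins assumption cannot
  capture within-subject transitions; it describes cross-sectional
  population drift.
* With small cohorts the CCA overfits in-sample (the analysis driver on
  n = 54 synthetic subjects reports in-sample Rc₁ ≈ 0.90 against an
  out-of-fold 0.40); the cross-validated values are the ones to read.
* The multiplicative zero replacement uses a single δ per dataset; a
  hierarchical Bayesian replacement would propagate uncertainty but adds
  a dependency out of proportion to its effect here.
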
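---
title: "Relating static and time-varying functional connectivity to behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating static and time-varying functional connectivity to behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmodes)
```

## The analysis this package implements

Resting-state fMRI yields, per subject and session, a node-by-time matrix
of regional BOLD signals. Two complementary summaries of these signals can
be related to behavior measured outside the scanner:

* **Static functional connectivity (FC)** — the Pearson correlation
  between every pair of node signals over the whole session, vectorized to
  its unique edges and reduced by PCA.
* **Time-varying FC** — a hidden Markov model (HMM) with Gaussian
  observations is fitted to the concatenated, PCA-reduced group data. Each
  state $k$ has mean activity $\mu_k$ and covariance (connectivity)
  $\Sigma_k$; the chain's transition matrix $\Theta_{l,k}$ gives the
  probability of moving from state $l$ to state $k$. Per subject-session
  summaries are the fractional occupancy (FO) of each state, the FO of
  each *metastate* (a cluster of states that preferentially transition
  among themselves), and mean switching rates across states and
  metastates.

Each arm's features form the $X$ side of a canonical correlation analysis
(CCA) against behavioral factor scores $Y$, with inference by permutations
that respect the repeated-measures structure (all sessions of a subject
move as one block), grouped cross-validation, and post hoc loadings for
interpretation.

Because the emulated study's raw data are not deposited, the package
includes a first-class synthetic generator with known ground truth; all
statistical guarantees quoted below are demonstrated on generated data by
the test suite.

## The synthetic generator

`synth_config()` fixes the study shape: 23 subjects — the first 18 with
three sessions, the last 5 with two (64 subject-session rows) — two
180-volume runs per session at TR = 2 s, and a 12-state chain whose
transition matrix carries a planted 2/9/1 block structure with 0.9
within-block mass (the metastate ground truth). The node count defaults to
a small 20 for desk-scale work; `full_scale = TRUE` selects the 439-node
parcellation, for which the session-grouped concatenation has
$360 \times 23 + 360 \times 23 + 360 \times 18 = 23040$ rows and the edge
vector has $439 \cdot 438 / 2 = 96141$ entries.

Design choices worth making explicit:

* **State emission geometry.** State means sit on an orthogonal grid of
  norm $\sqrt{d}\,\cdot$ `state_mean_scale` with shared spherical
  covariance `noise_sd`$^2 I$, so every pair of states is separated by
  `state_mean_scale` $\sqrt{2d}$ signal units and separability is governed
  by the single ratio `state_mean_scale / noise_sd`.
* **Behavior coupling is planted at the subject-session level**, because
  CCA rows are subject-sessions: the standardized planted combination
  $z$ of the true FOs enters the first latent behavioral factor as
  $f_1 = \rho z + \sqrt{1-\rho^2}\,\varepsilon$, so the population
  correlation of the planted brain and behavior combinations is exactly
  `behavior_coupling` ($\rho$, default 0.85). The 31 observed measures
  (six spatial working-memory, six digit-symbol, three Stroop, four color
  working-memory, eight visual-analogue-scale, three impulsivity-scale
  measures and one box-completion time) load 0.8 on one of 8 factors,
  mirroring the qualitative factor structure of such batteries
  (reaction-time, accuracy, affect, arousal and impulsivity groupings).
  Behavioral measures are modeled as Gaussian factors plus Gaussian
  measurement noise — the simplest distributional form consistent with a
  linear factor model; real batteries are bounded and often skewed.
* **Motion** is a six-parameter smooth random walk with occasional
  one-frame spikes, calibrated so mean framewise displacement lands near
  0.15 mm (plausible for a compliant adult sample; innovation SDs 0.03 mm
  and 6e-4 rad per frame).
* **Phase-randomized surrogates** redraw Fourier phases independently per
  node (conjugate-symmetric, zero-frequency untouched): each node's
  amplitude spectrum — hence autocorrelation — is preserved exactly, while
  cross-node phase relations are destroyed.

What the generator does **not** emulate: hemodynamic convolution, spatial
autocorrelation between nodes within a state, scanner drift or physiological
artifacts, subject-level random effects shared across sessions, and
non-Gaussian behavioral distributions. Passing tests therefore certify the
*statistical machinery* — state recovery, calibration of the permutation
null, factor recovery, planted-mode detection — not robustness to every
property of real fMRI data.

## Preprocessing

The postprocessing chain is fixed: confound regression, then bandpass,
then standardization.

* `expand_confounds()` augments the 8 base regressors (6 motion
  parameters, mean white-matter and mean CSF signal) with temporal
  derivatives (backward difference, first frame zero-padded), squares, and
  squared derivatives — 32 columns.
* `regress_confounds()` projects node signals onto the orthogonal
  complement of the design (intercept always included); dependent columns
  are dropped with a message.
* `bandpass()` is a 4th-order Butterworth applied forward and backward
  (`signal::filtfilt`), giving zero phase shift so state timing is not
  displaced; the band is 0.01–0.1 Hz. The filter family and order are
  conventional defaults — the design is only constrained to be band-limited
  and zero-phase. Columns are demeaned before filtering (DC is outside the
  passband; a nonzero mean would only excite start-up transients).
* No scrubbing and no global-signal regression: temporal contiguity is
  required by the HMM, and global-signal regression is deliberately
  absent.
* `framewise_displacement()` uses the sum of absolute backward differences
  of the three translations plus 50 mm times those of the three rotations
  (radians to arc length on a 50 mm sphere); the first frame is 0.
* `standardize_concat()` concatenates runs within each subject-session,
  standardizes each session block per node (mean 0, SD 1), and stacks the
  blocks session-by-session. Zero-variance nodes are rejected by index.

## HMM inference

`fit_hmm()` infers the model by expectation–maximization on the posterior
density under weak conjugate priors: a symmetric Dirichlet
($1 + 1/K$ per entry, one pseudo-observation per row) on each transition
row and the initial distribution, and an inverse-Wishart
($\Psi_0 = \bar\sigma^2 I$, $\nu_0 = d + 2$, with $\bar\sigma^2$ the mean
feature variance) on each state covariance. This *maximum a posteriori*
EM was chosen over a fully variational treatment because its objective
(log-likelihood plus log-prior) is provably nondecreasing under exact
updates — the property the test suite enforces to $10^{-6}$ on every fit —
while the Dirichlet and inverse-Wishart terms give exactly the
regularization a variational scheme's conjugate priors would: transition
probabilities never hit zero and covariance updates are always positive
definite without ad hoc jitter. Message passing uses the scaled
forward–backward recursion on per-timepoint max-normalized densities, so
posteriors remain finite for inputs with dynamic range up to $10^{\pm30}$.

Chains restart at each subject-session boundary (runs are concatenated
within session, so sessions — not runs — are the natural chain unit); no
transition is counted across blocks, and a block's posteriors are
invariant to every other block. Initialization is k-means on a subsample
of at most 2000 rows; 5 restarts by default, best final objective kept;
convergence at relative objective change below $10^{-5}$ or 500
iterations. A state that loses all occupancy keeps its previous parameters
and raises a warning rather than an error, matching exploratory usage.
Full-scale fits reduce the concatenated data to 25 principal components
first; desk-scale tests fit in the generated feature space directly.
State labels are arbitrary; `align_states()` (exhaustive over
permutations up to $K = 8$, greedy beyond) is provided for evaluation
against ground truth only.

## State summaries

* **FO**: mean posterior probability per state over a block's rows; rows
  sum to 1 by construction.
* **Switching rate**: $\mathrm{SR} = T^{-1}\sum_t \sum_k
  |P(s_{t+1}{=}k) - P(s_t{=}k)|$. The absolute value is taken because the
  signed sum is identically zero; the denominator is the number of
  timepoints $T$, following the stated convention literally
  (`denominator = "T-1"` is available since the alternative reading —
  dividing by the number of transitions — is equally defensible). The rate
  is bounded by 2.
* **Metastates**: single-linkage agglomerative clustering of the rows of
  $\Theta$ under Euclidean distance, cut at 3 clusters by default
  (`n_clusters` is exposed because a dendrogram-based choice is equally
  plausible). Metastate time courses are column sums of member-state
  posteriors; their FO and SR are computed exactly as for states. At the
  defaults this yields the 17-column dynamic feature matrix: 12 state FOs,
  3 metastate FOs, and the two mean switching rates.
* **Spatial overlap**: `overlap_index()` keeps the top 40% of
  positive-valued nodes by value and the top 40% of negative-valued nodes
  by magnitude (fractions of the signed subsets, not of all nodes; ties
  broken by node index) and reports the selected fraction of the network,
  normalizing by network size to remove size bias. The index is invariant
  to positive rescaling of the map.
* **Motion QC**: per-session Pearson correlations of every dynamic
  feature with session mean FD, Benjamini–Hochberg corrected jointly
  across all $17 \times 3 = 51$ tests (the FDR procedure is not named
  beyond "FDR"; BH is the standard choice).

## Behavioral factors

`fit_factors()` standardizes the measures (so results are invariant to
affine rescaling), extracts factors by maximum likelihood, applies promax
rotation with the conventional power 4, and computes regression-method
(Thurstone) scores $Z R^{-1} P \Phi$. The estimator and score method are
not dictated by the emulated analysis beyond "factor analysis with promax
rotation"; maximum likelihood plus regression scores is the common
default pairing. Heywood cases are clipped with a warning. Eight factors
is the study default; the choice is qualitative, so `n_factors` is
exposed rather than automated, and the stability sweep (below) quantifies
how little the first mode depends on it.

## CCA with grouped inference

`cca()` centers both sides (no re-scaling: CCA correlations are
scale-invariant), whitens each side by eigendecomposition of its
covariance — silently reducing rank-deficient sides to numerical rank, as
happens for the 17 dynamic features, whose FO blocks carry 4 exact linear
constraints — and reads modes off the SVD of the whitened
cross-covariance. Successive variates are exactly uncorrelated within
each side.

**Permutation test.** Subjects are exchangeability blocks; a block may
swap only with blocks holding the same number of sessions, so every
permuted row stays aligned with a row of the same session position. When
the whole group is no larger than `n_perm` it is enumerated and p-values
are exact (smallest attainable $p = 1/|G|$, identity included); otherwise
`n_perm` random permutations are drawn and $p = (1 + \#\{r^{perm} \ge
r^{obs}\})/(1 + n_{perm})$ — the add-one convention, so $p$ can never be 0
and a mode that no permutation beats reports $p = 1/(n_{perm}+1)$.
Per-mode comparison is the default (mode $k$ against the permuted $k$-th
correlation); `statistic = "max"` gives family-wise control.

**Cross-validation.** Subjects (never rows) are split 80/20, stratified
by session count so every test set has the same composition (4
three-session + 1 two-session subjects at the study shape); weights and
centers fitted on the training rows project the held-out rows, and the
held-out first-mode correlation is tested by permutation within the test
set. Held-out estimation is projection, not refitting: refitting a
13-by-8-dimensional CCA on 13 rows would be ill-posed. With only five
held-out blocks, pure block exchange admits just $4! \cdot 1! = 24$
rearrangements, most of which leave the majority of rows in place — a
null so coarse and identity-contaminated that even strongly coupled folds
cannot register. The fold test therefore defaults to the full
exchangeability group the generator justifies: block exchange *plus*
session relabelling within subjects (`session_exchange = TRUE`), valid
whenever session order carries no information about the brain–behavior
pairing. For real data with strong session-order effects this assumption
should be revisited, and the option turned off.

**Interpretation.** `posthoc_loadings()` reports the correlation of each
original variable with its side's variate. `mode_stability_sweep()`
re-runs factor analysis, PCA and CCA over a grid of factor counts (1–9)
and component counts (1–20 for the static arm; 180 configurations),
storing each configuration's behavioral loadings on the first variate;
Pearson similarities of these vectors across the grid — bimodally near
$\pm 1$ when a single strong mode dominates, since variate sign is
arbitrary — quantify mode stability. Configurations that fail to fit are
recorded and skipped.

## Numerical choices and problem sizes

Tolerances: transition rows sum to 1 within $10^{-10}$; posterior rows
within $10^{-8}$; rank decisions at a relative eigenvalue tolerance of
$10^{-10}$; EM convergence at relative objective change $10^{-5}$;
objective monotonicity enforced at $10^{-6}$. Cholesky factorizations
fall back to a jitter of $10^{-6}\,\mathrm{tr}(\Sigma)/d$ only when a
user-supplied covariance is numerically singular — fitted covariances are
positive definite by construction.

The test suite demonstrates the pipeline's guarantees at deliberately
modest sizes chosen to make the properties sharp rather than the runs
long: state recovery on 20 chains of 300 frames with 4 well-separated
states (decoding accuracy $\ge 0.90$, transition error $\le 0.05$, FO
recovery $r \ge 0.95$); permutation calibration over 500 null replicates
of the 23-block design at 200 permutations (rejection rate in
$[0.02, 0.09]$ at $\alpha = 0.05$); planted-mode detection and 200-fold
cross-validation at the full 64-row study shape with coupling 0.85. The
`scripts/acceptance.R` entry point recomputes all of these from scratch
at any seed.

## Known limitations

* The HMM observation model is Gaussian with full covariance; no
  autoregressive emissions, and no model selection over $K$.
* Factor analysis requires more rows than measures; at the study's 64
  rows and 31 measures the maximum-likelihood fit is feasible but close
  to its small-sample limit, and Heywood warnings are to be expected on
  unlucky draws.
* Cross-validated significance rates vary noticeably across generated
  datasets at $n = 64$ (a dataset-level property, not Monte Carlo error);
  single-dataset fold rates should be read accordingly.
* Real-data preprocessing upstream of the node time series (registration,
  segmentation, motion estimation, atlas extraction) is out of scope.
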
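---
title: "Backbone extraction for weighted dynamic connectivity: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone extraction for weighted dynamic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sliding-window dynamic functional connectivity (dFC) turns multivariate brain
recordings into a sequence of weighted graphs: one Pearson-correlation
adjacency matrix per temporal window, min–max rescaled to `[0, 1]`. Many of
the ties in such graphs are *reducible* — explainable by the overall activity
levels of the two endpoints plus chance — and carry no information about a
genuine functional relationship. `wbnet` extracts the *backbone*: the
subgraph of ties whose temporal weight profile is incompatible with a null
model in which every link arises from the local propensities of its endpoints
alone.

## The null model

Each node $i$ carries two latent propensities $a_i, b_i \in (0, 1]$. Under
the null, the weights $w_{ij}^t$ of the tie $(i,j)$ over the $\tau$ windows
are i.i.d. Gaussian,

$$ w_{ij}^t \sim \mathcal{N}\!\left(\mu_{ij}, \sigma_{ij}^2\right), \qquad
   \mu_{ij} = a_i a_j, \quad \sigma_{ij} = b_i b_j . $$

The multiplicative structure is what makes the model a *temporal fitness*
model: a node with a large $a_i$ inflates the expected weight of **all** its
ties, so a heavy edge between two high-propensity nodes is unremarkable,
while a moderate edge between two low-propensity nodes can be highly
significant. Gaussianity of windowed weights is an assumption motivated by
central-limit behaviour of windowed correlations; `ks_normality_sweep()`
lets users check it on their own data across window sizes.

Three further assumptions matter in practice: weights of different windows
are treated as independent draws (overlapping windows violate this mildly),
the propensities are constant over the recording, and all pairs share one
weight scale — which is why min–max rescaling is **global per subject** by
default (`rescale_minmax(scope = "global")`). Per-window rescaling is
available but destroys cross-window comparability and is not recommended.

## Estimation

The log-likelihood over unordered pairs $i<j$ is

$$ \ell(a, b) = \sum_{i<j} \Big[ -\tau \log (b_i b_j)
   - \tfrac{\tau}{2}\log 2\pi
   - \sum_{t=1}^{\tau} \frac{(w_{ij}^t - a_i a_j)^2}{2 (b_i b_j)^2} \Big]. $$

(Summing ordered pairs would double every term without moving the optimum.)
`solve_latent()` estimates the propensities from the $2N$ first-order
moment conditions

$$ \sum_{j \ne i} \left( a_i a_j - \bar w_{ij} \right) = 0, \qquad
   \sum_{j \ne i} \Big( \tfrac{1}{\tau}\textstyle\sum_t (w_{ij}^t - a_i a_j)^2
   - (b_i b_j)^2 \Big) = 0, $$

with $\bar w_{ij}$ the time-mean weight. Two points deserve emphasis:

* **Moment equations vs the exact score.** These conditions are unbiased
  moment equations ($E[\bar w_{ij}] = a_i a_j$ under the null) but are not
  algebraically identical to the stationarity conditions of $\ell$: the exact
  score weights each term by $a_j / \sigma_{ij}^2$. The two coincide in
  homogeneous networks. The package treats the moment system as the primary
  estimator and ships `fit_latent_direct()`, a BFGS maximizer of $\ell$ in
  log-parameters with an analytic gradient, as the labelled alternative and
  cross-check; the test suite verifies their agreement on homogeneous
  fixtures.

* **Two-stage structure.** The mean block does not involve $b$, so it is
  solved first for $a$; the spread block is then solved for $b$ with $a$
  fixed. Substituting $\beta_i = b_i^2$ makes both blocks the *same*
  product-moment system $\sum_{j\ne i}(x_i x_j - M_{ij}) = 0$, one with
  $M = \bar w$ and one with $M$ the matrix of mean squared deviations.

### Numerics

One solver (`solve_product_system()`, internal) serves both blocks:

* positivity is enforced by iterating in $\log x$ rather than by box
  constraints; the upper bound 1 is *not* enforced (rarely binding for
  min–max-scaled data) but violations trigger a warning;
* a full Newton step with the analytic Jacobian is tried first (quadratic
  convergence near the root); if it fails to reduce the residual sum of
  squares the step falls back to Levenberg–Marquardt damping, a guaranteed
  descent direction;
* the damped iteration can still park in a local minimum of
  $\|r\|^2$ from an unlucky start, so the solver restarts deterministically
  from a homogeneous and a degree-proportional initial point and keeps the
  best iterate;
* convergence is declared when the max-norm of the stacked residuals is at
  most `tol` (default `1e-10`); non-convergence returns the best iterate
  with `converged = FALSE` and a warning, never an error;
* pairs with zero temporal variance keep the system's dimension — their
  fitted $\sigma_{ij}$ is floored at `1e-12` in `pair_distributions()`.

The initialization follows the degree rule
$a_i^{(0)} = \sum_j \bar w_{ij} \,/\, (2 \sum_{i<j} \bar w_{ij})$ (so the
initial $a$ sums to 1), and mirrors the same normalization on per-pair
empirical temporal SDs for $b^{(0)}$ — the spread analogue is not prescribed
anywhere, and the degree-normalization logic applies unchanged. Both are
clipped into $[10^{-6}, 1]$.

A caveat for very small networks: at $N = 3$ the product system has a closed
form that can demand a negative pairwise product, i.e. no positive root
exists; the solver then honestly reports non-convergence. Backbone analysis
is meaningful from a handful of nodes upward.

## Selecting significant ties

Given fitted $\mu^*_{ij}, \sigma^*_{ij}$, window $t$ of pair $(i,j)$ is
flagged when $w_{ij}^t$ **strictly** exceeds the null's upper
$(1-\alpha)$-quantile $\mu^*_{ij} + \sigma^*_{ij} z_{1-\alpha}$. The test is
one-sided by design: only excess weight is evidence of an irreducible tie.
The per-window p value is the upper-tail probability
$p = 1 - \Phi\!\big((w - \mu^*)/\sigma^*\big)$, and flagging is exactly
equivalent to $p < \alpha$ — the suite asserts this cellwise.

A pair enters the binary backbone iff its flag count is strictly above
`count_fraction * tau` (default: more than half the windows; at even $\tau$
a count of exactly $\tau/2$ is rejected). Thresholds are constant across
windows because the fitted null is stationary.

Tunable parameters, defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.2 | upper-tail level; equivalently the 80th-percentile cut `c = 1 - alpha` used in the standard analysis setup |
| `count_fraction` | 0.5 | temporal persistence required for admission (`count > tau/2`) |
| `correction` | `"none"` | `bonferroni_count` divides `alpha` by the number of tested pairs $N(N-1)/2$ (the conventional choice); `bonferroni_weight_sum` divides by the total summed edge weight, a nonstandard variant kept for completeness with a warning |
| `width`, `overlap` | — | window size and overlap in time points; 20 windows with overlap 5 is a typical resting-state setup, overlap 2 for very short windows |

The **weighted** backbone assigns admitted pairs the temporal mean of
$w_{ij}^t - \text{threshold}_{ij}$ (`signed_mean`; windows below threshold
contribute negatively). A `positive_mean` variant averages only exceedances.
The measure is pluggable because only the averaging idea, not a formula, is
standard. **Group consensus** (`group_consensus()`) is the cellwise mean of
per-subject binary backbones; entries below `display_floor` (default 0.05)
are zeroed *only* in the display copy used for figures, never in the stored
consensus.

## Surrogate baselines

Two classical time-series nulls are provided for comparison, sharing the
acceptance pipeline so that the three methods are directly comparable:

* **ARR** (autoregressive randomization): a VAR(p) is fitted by least
  squares on mean-centred signals (with an intercept that absorbs any
  residual offset — this also makes the noiseless generate-then-fit round
  trip exact). Each surrogate starts from $p$ successive time points drawn
  at random from the original series and iterates the recursion with fresh
  Gaussian innovations. Default order $p = 1$, configurable; the order is a
  modelling choice, not something the data dictate here. The model is fitted
  once per full series (a per-window fit is statistically fragile at common
  window sizes).
* **PR** (phase randomization): one uniform random phase per frequency,
  applied to **every** node's Fourier transform (per-node phases are
  deliberately not offered — they would destroy the cross-correlations the
  null must preserve), Hermitian symmetry enforced, inverse transform.
  Amplitude spectra are preserved exactly; because a common per-frequency
  rotation is unitary, zero-lag cross-covariances are preserved to machine
  precision.

The per-link decision rule is the standard surrogate construction: a
pair-window is flagged when the original weight strictly exceeds the
$k$-th order statistic of its $M$ surrogate weights, $k = \lceil (1-\alpha) M
\rceil$ (requiring $M \alpha \ge 1$ and $M \ge 20$), and flags aggregate with
the same `count > tau/2` rule. Surrogate tensors are rescaled with the
*original* subject's min–max bounds so all weights share one scale.

When the input is a tensor with no underlying node time series (the
injected-link benchmark), `detection_benchmark()` applies the surrogates to
each pair's temporal weight sequence instead: PR treats the $\tau \times P$
matrix of pair series as one multivariate series, while the AR route fits
one univariate AR(p) per pair sequence — a joint VAR across all
$P = N(N-1)/2$ pairs would be unidentifiable at $P \gg \tau$.

## What the synthetic generator does and does not emulate

`simulate_null_tensor()` draws propensities uniformly from configurable
ranges (default $(0.2, 0.9)$ for both $a$ and $b$, the parameter-recovery
study conditions) and weights i.i.d. from the implied pair Gaussians, one
draw per unordered pair per window. Weights are **not** clipped to `[0, 1]`
by default: the Gaussian null has unbounded support, and clipping would bias
recovery tests; a `clip` flag exists for realism experiments.
`plant_significant_ties()` elevates chosen pairs by a multiple of their null
SD (known positives); `inject_random_links()` overwrites chosen pairs'
weights with Uniform(0, 1) draws in all windows by default (an additive mode
and a window fraction are configurable — the benchmark's defaults are a
declared choice, not an inference about any particular dataset);
`simulate_var_series()` provides stationary VAR(1) inputs for the surrogate
machinery with a 200-step discarded burn-in.

The generator reproduces the *statistical* structure the method assumes and
nothing more. It does not emulate haemodynamics (no HRF convolution or
balloon dynamics), spatial autocorrelation of parcels, scanner drift or
motion artefacts, negative-correlation blocks, or temporally varying
propensities. Passing tests therefore certify the inferential machinery —
calibration under the model's own null, recovery of its parameters,
detection of planted violations — not robustness to the full messiness of
real recordings, which should be assessed with `ks_normality_sweep()` and
the surrogate comparisons on the data at hand.

The injected-link benchmark uses a weak-null regime (`a_range = (0.2, 0.5)`,
so null means at most 0.25, and `b_range = (0.1, 0.4)`) in which Uniform(0,1)
injections are anomalous in level — the regime of interest for a detection
experiment; the latent-model route scores essentially perfectly there while
per-pair surrogate baselines, which see only each pair's own (entirely
corrupted) sequence, hover near chance. That ordering is the structural
point; the per-pair-sequence surrogate adaptation means the ARR/PR numbers
are not comparable to time-series-level surrogate tests.

## Evaluation utilities: formulas and choices

* **Normality sweep.** Each pair's $\tau$ weights are KS-tested against a
  Gaussian with that pair's sample mean and SD, and p values are averaged
  over pairs. Because the reference parameters are estimated from the same
  sample, the plain KS p value is conservative (Lilliefors-type bias): under
  a true Gaussian the mean p value sits well above 0.5 rather than at 0.5.
  `method = "lilliefors"` (via the `nortest` package) applies the corrected
  reference distribution. Zero-variance pairs are skipped and counted.
* **MPE.** The mean percentage error between two network matrices is
  $100 \cdot \mathrm{mean}|x_{ij} - y_{ij}| \,/\,
  \max(\mathrm{mean}|y_{ij}|, \varepsilon)$ over off-diagonal cells — a
  matrix-level normalization chosen because a cellwise ratio would divide by
  zero on sparse binary backbones. The reference is the second argument; the
  window-stability sweep (`stability_across_windows()`) symmetrizes the
  normalizer (average of both matrices' mean absolute values) so its
  pairwise comparison table is symmetric with a zero diagonal.
* **Detection AUC.** Midrank Mann–Whitney formula; the tests cross-check it
  against brute-force enumeration over positive–negative pairs.
* **VAR recovery checks** average the least-squares estimate over a few
  replicate series before the per-entry comparison: the single-series
  sampling error at $T = 1000$ sits right at the tolerance of interest, and
  averaging turns a borderline stochastic check into a stable one without
  loosening it.

## Problem sizes

The shipped tests and the acceptance script use sizes chosen to give the
Monte Carlo checks adequate power while staying lightweight: parameter
recovery at $N = 30$, $\tau = 500$ over 10 replicates (with a
$\tau \in \{50, 200, 800\}$ consistency curve), null calibration over at
least $10^5$ pair-trials at $\tau = 20$, phase-randomization fidelity at
$T = 4096$ with $M = 50$ surrogates, and the injection benchmark at
$N = 30$, $\tau = 20$ with 100 corrupted pairs.

## Known limitations

* Propensities are constant over the recording; slow drifts in node activity
  masquerade as significant ties. Time-varying extensions are out of scope.
* The moment estimator inherits the printed equations' divergence from the
  exact score on strongly heterogeneous networks; `fit_latent_direct()`
  exists precisely to quantify that gap case by case.
* All pairs must share one window count $\tau$; ragged segmentations are not
  supported.
* The Gaussian null is untruncated even though rescaled weights live in
  `[0, 1]`; for very low/high means with large spreads the implied tail mass
  outside the interval is a model approximation.
* Window overlap induces dependence between consecutive windows that the
  i.i.d. likelihood ignores; large overlaps make the effective $\tau$
  smaller than the nominal one.
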
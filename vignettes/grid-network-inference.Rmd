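---
title: "Inferring grid-cell network structure from noise correlations and kinetic Ising couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring grid-cell network structure from noise correlations and kinetic Ising couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the methods implemented in `gridnet`: the
statistical model, the estimation and numerical choices, the design of
the synthetic-data generator used for validation, and the package's known
limitations. Code chunks are shown but not evaluated at build time; the
README's worked example runs the same chain end to end with its actual
output.

## 1. Scientific question

Grid cells fire on the vertices of a hexagonal lattice tiling the
environment. Within a *module* — a group of cells sharing lattice spacing
and orientation — cells differ only by a two-dimensional spatial *phase*.
Continuous-attractor models of grid formation require recurrent
connectivity organized by that phase: net excitation between cells at
small phase separation, net inhibition at large separation (a Mexican
hat). The question the package addresses is whether such structure can be
read out of simultaneously recorded spike trains, over and above what the
cells' shared spatial tuning trivially induces.

Two complementary readouts are implemented:

1. **Noise correlations** conditioned on position: correlations of
   firing-rate fluctuations across repeated visits to the same spatial
   bin. Conditioning on position removes the tuning-induced signal
   correlation, so any residual covariation reflects shared input or
   interaction.
2. **Kinetic Ising couplings**: effective interaction strengths in a
   binary, one-time-step-memory model fitted by maximum likelihood, with
   the spatial tuning absorbed into per-cell external fields.

Both quantities are then regressed on the pairwise spatial phase
distance.

## 2. The kinetic Ising model

Spike trains are binarized into `dt = 10` ms bins, `S_i(t) = +1` if cell
`i` spiked in bin `t` and `−1` otherwise. The model is a
one-step-memory Markov chain: given the population state at `t`, the next
states are conditionally independent with

```
P(S_i(t+1) | S(t)) = exp(S_i(t+1) H_i(t)) / (2 cosh H_i(t)),
H_i(t) = h_i(t) + Σ_j J_ij S_j(t).
```

`J_ij` is the directed coupling from cell `j` onto cell `i`, and
`h_i(t) = Σ_k α_ik x_k(t)` is the external field, a linear combination of
time-varying covariates `x_k(t)` shared across cells with per-cell
coefficients. The log-likelihood over the `T − 1` transitions is

```
L = Σ_{i,t} [ S_i(t+1) H_i(t) − log 2 cosh H_i(t) ],
```

in natural logarithms throughout. Because the transition factorizes over
cells, `L` splits into one concave problem per cell. Substituting
`p = (1 + tanh H)/2` shows each problem is exactly a logistic regression
of the 0/1 spike indicator on the predictor matrix scaled by two; the
test suite exploits this identity by checking `ki_fit` against
`glm.fit(..., family = binomial())`.

### Field designs

The covariate blocks (`design_*` functions, combined by `ki_design`) are:

- **constant** — one all-ones column, the per-cell bias;
- **box** — the arena split into `K × K` equal squares, a one-hot
  indicator per time bin (`K = 4` gives 16 coarse covariates at 37.5 cm;
  `K = 20` gives 400 covariates at 7.5 cm);
- **Gaussian spatial basis** — `M × M` bump centres on a regular grid,
  covariate `exp(−(Δx² + Δy²)/r²)` with radius `r` (default 8.5 cm and
  `M = 15`), a smooth low-dimensional alternative to the fine box;
- **angular** — 10 von-Mises-like bumps `exp(−d(θ, c_k)²/(π/6)²)` at
  equispaced centres, with `d` the wrapped angular distance; one
  `design_angular` component each serves LFP theta phase, head
  direction, and running direction;
- **speed** — running speed averaged over a centred 100 ms window.

Nested designs allow likelihood-based comparison: adding covariates can
only increase the training log-likelihood, and the evaluation tools
penalize that (Section 5).

### Optimization

`ki_fit` solves each cell's concave problem by Newton's method with step
halving (`newton_cell`). The gradient is the residual form
`Σ_t (S_i(t+1) − tanh H_i(t)) x(t)`; the Hessian uses the weights
`1 − tanh² H`. Convergence is declared when the gradient norm falls below
`tol` scaled by the number of observations, or when step halving stalls
at machine precision in the parameters — the latter matters for
separable or near-deterministic cells, where the unregularized optimum
has coefficients drifting to infinity while the likelihood plateaus. A
quadratic penalty `lambda` is available for such cases; a cell that never
spikes triggers a warning. Fits report `converged`, the final gradient
norm, and the number of parameters, and `print.gn_fit` summarizes them.

Couplings can be switched off (`couplings = FALSE`) for field-only
models, self-couplings excluded, and the likelihood can be evaluated or
fitted on an arbitrary subset of transitions (`pairs`), which is how
held-out scoring works.

## 3. Grid geometry

`compute_rate_map` bins spikes and occupancy at 3 cm, smooths both with
a Gaussian kernel (FFT convolution via `stats::convolve`, with masked
bins zeroed so unvisited bins cannot poison the result), and divides.
`spatial_autocorrelogram` computes the Pearson correlation of the map
with itself at every 2-D lag over jointly valid bins.
`estimate_spacing_orientation` lightly smooths the autocorrelogram, finds
8-neighbourhood local maxima with parabolic sub-bin refinement, keeps the
six peaks nearest the centre, and reports spacing as the median peak
radius and orientation as the circular mean of the peak angles with
period 60°.

`phase_offset` cross-correlates two maps and returns the peak nearest
zero lag: the smallest displacement mapping one cell's pattern onto the
other's. `normalized_phase_distance` folds an offset into the lattice's
fundamental domain — the search over lattice translations is centred on
the nearest lattice point so arbitrarily large offsets fold correctly —
and divides by the spacing. Its maximum over all offsets is
`0.5 / cos 30° ≈ 0.577`, attained when one lattice's vertices sit at the
centres of the other's triangles; `max_phase_distance` verifies this by
brute force and is the package's acceptance target.

`assign_modules` clusters cells in (log spacing, scaled orientation)
space by recursive 2-means bisection. A split is accepted only if its
mean silhouette is at least 0.5 *and* exceeds the 95th percentile of
silhouettes obtained on Gaussian reference samples matched to the
cluster's covariance. The second condition is essential: small clusters
of structureless noise routinely reach silhouettes near 0.6, so a fixed
threshold over-splits, while a global silhouette criterion under-splits
when one very distant module masks the separation between two nearby
ones. Cells more than three within-module standard deviations of spacing
from their module mean are left unassigned.

## 4. Noise correlations

`smooth_rates` converts spikes to instantaneous rates (Gaussian kernel,
FFT). `segment_visits` discretizes the trajectory into spatial bins
(default 20 cm) and splits the session into contiguous *visits* to each
bin, recording each visit's mean rate per cell. For every bin with at
least two visits, `noise_correlation_matrix` correlates the per-visit
mean rates of each cell pair across visits, then averages the per-bin
correlations (unweighted) into `C_ij`. Degenerate bins (a constant cell,
too few visits) are skipped and counted.

`noise_correlation_stability` repeats the analysis on random halves of
the visits (20 splits) and reports the correlation between the two
halves' `C` matrices — a model-free reliability check.
`correlation_vs_phase_regression` is an ordinary least-squares regression
of any pairwise statistic on phase distance with the usual t-based
standard errors and p-values; it is used for both noise correlations and
couplings.

## 5. Model evaluation

`score_model` computes `AIC = −2 lnL + 2k` and the Akaike-corrected
log-likelihood `lnL − k`; the correction is applied to held-out
likelihoods as well, so models are compared on the same scale whether
scored in-sample or out-of-sample. `pair_partition` randomly splits the
`T − 1` transitions in half; `cross_half_likelihood` fits on one half and
evaluates on the other, which is the package's main guard against the
nesting problem (more covariates always win on training likelihood).
`coupling_stability` correlates two coupling matrices over all entries,
self-couplings, and within- versus between-module pairs.
`module_variance_test` is a two-sided F test (`stats::var.test`)
comparing the variance of within-module to between-module couplings.
`pair_filters` implements the control analyses: dropping pairs where both
cells phase-precess (possible common theta drive) or pairs recorded on
the same tetrode (possible spike-sorting artefacts).

## 6. Theta analysis

`extract_theta_phase` finds the dominant LFP frequency in the 4–12 Hz
band by FFT, band-passes ±2 Hz around it, and takes the analytic-signal
phase, averaged circularly within each 10 ms bin. `theta_preference`
estimates a cell's preferred phase by a von Mises kernel density estimate
whose concentration is chosen by leave-one-out cross-validation, flagging
low-resultant (untuned) cells. `phase_precession_test` computes, for each
spike, the signed distance to the nearest firing-field centre projected
onto the running direction, and tests the circular–linear association
between that covariate and spike phase: the statistic is the
circular–linear correlation, the null distribution comes from permuting
phases against positions, and the slope is found by maximizing the
resultant of the phase residuals. A cell is called precessing when the
permutation p-value is below `alpha` *and* the slope is negative (phase
advances across the field).

## 7. The synthetic generator and its realism

`generate_population` builds a session from: a smoothed random-walk
(Ornstein–Uhlenbeck velocity) trajectory with reflective walls in a
150 cm arena; an 8 Hz theta rhythm; per-cell hexagonal rate functions
(sum-of-Gaussian bumps on the lattice, with spacing, orientation, phase,
peak rate, optional multiplicative theta and head-direction modulation,
and a session-mean rate target); and spiking in one of two modes.
`rate_bernoulli` draws each bin independently with
`p = 1 − exp(−rate · dt)`. `kinetic_ising` converts those probabilities
to per-bin fields `h = atanh(2p − 1)`, subtracts the mean-field coupling
drive `J·E[S]` so realized rates stay on target, and samples the chain
sequentially (the one compiled routine, since the recursion cannot be
vectorized). With `J = 0` the two modes are distributionally identical,
which the tests verify.

Default parameters mimic published module statistics — spacings near
46, 55, and 93 cm, orientations near 30°, mean rates of a few Hz — and
the test fixtures add per-cell spacing (±2%) and orientation (±0.8°)
jitter so module assignment is tested on realistically inhomogeneous
populations. One consequence is worth recording: with per-cell lattice
jitter, the *relative phase* of two cells is no longer a single
well-defined quantity across a large arena (the offset between the two
patterns drifts by several centimetres from one side to the other), so
sub-bin phase-recovery accuracy is only meaningful — and only tested —
for cells sharing an exact lattice, which is the idealization under which
within-module phase is defined in the first place.

## 8. Numerical choices

- `log 2 cosh H` is evaluated in the stable form
  `|H| + log1p(exp(−2|H|))`, avoiding overflow at large fields.
- All smoothing uses FFT convolution; masked entries are zeroed before
  transforming (an `NA` times a zero weight is `NA` in R and would
  otherwise contaminate every output bin), and tiny negative round-off
  values in rates are clamped to zero.
- Newton steps are halved until the likelihood increases; convergence is
  on the gradient norm with a parameter-stall escape for separable data.
- Circular quantities use resultant-vector means; orientation averaging
  uses period-60° phasors.
- All stochastic steps take explicit seeds, and the pipeline re-run with
  the same seed is bit-identical.

## 9. Validation strategy

Every module is tested against independent oracles rather than stored
outputs: exhaustive enumeration of the likelihood on tiny systems,
central finite differences against the analytic gradient, `glm.fit` as a
reference solver, closed-form F statistics, brute-force searches for
angular and lattice-folding code, and ground-truth recovery from the
generator (couplings to PCC ≥ 0.95 at half a million bins, spacing to
5%, orientation to 3°, shared-lattice phase to half a map bin).
Statistical machinery is calibrated on null data: permutation and F tests
are checked to reject at the nominal rate, and noise correlations of
conditionally independent cells are checked to centre on zero. Error
bounds in tests are derived from observed Fisher information or binomial
confidence bands rather than tuned constants.

## 10. Limitations

- The kinetic Ising couplings are *effective*, not anatomical: common
  input not captured by the field design appears as coupling. The control
  filters and field comparisons mitigate but cannot eliminate this.
- One-step memory at 10 ms cannot represent slower synaptic or bursting
  dynamics; couplings summarize all lagged dependence at a single lag.
- The noise-correlation estimator needs repeated visits per bin; short
  sessions or large bins trade spatial resolution against visit counts.
- Module assignment assumes modules are separated in (spacing,
  orientation); overlapping modules distinguishable only by phase
  coherence are out of scope.
- The generator's lattice is perfectly stable over the session; real
  grids drift and shear, which would blur both geometry estimates and
  phase-conditioned statistics.
- Phase-precession detection uses a simple projected-distance covariate;
  it is a classifier for the control analysis, not a full model of
  precession.
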
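---
title: "Worm-like-chain flexibility and conformational dynamics of SMC dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worm-like-chain flexibility and conformational dynamics of SMC dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcflex)
```

## The measurement problem

Structural-maintenance-of-chromosomes (SMC) heterodimers such as condensin's
Smc2-Smc4 consist of two ~45-nm antiparallel coiled-coil arms joined at a
globular hinge, each arm ending in an ATPase head. High-speed AFM in liquid
yields movies in which the positions of the two heads and the hinge can be
marked frame by frame. Two quantitative questions follow:

1. **How stiff are the coiled coils?** Treating each arm as a polymer, the
   head-to-hinge distance is an end-to-end distance whose distribution is
   governed by the arm's persistence length $L_p$ and contour length $L_c$.
2. **Which conformation is the dimer in, and how does it change over
   time?** Heads can engage each other (ring-like "O"), the hinge
   ("butterfly" B when both do, P when one does), or neither (open "V"),
   and the classes interconvert on sub-second timescales.

smcflex implements both analyses, plus a synthetic-movie generator with
known ground truth so that every stage can be validated end to end without
any raw image data.

## The worm-like chain model

A 2D worm-like chain of contour length $L_c$ is discretized into
$N = \mathrm{round}(L_c / L_s)$ segments of length $L_s$ (default 0.2 nm;
any residual arc shorter than $L_s/2$ is dropped by the rounding).
Successive segment directions differ by independent Gaussian deflection
angles with

$$\operatorname{Var}(\alpha) = L_s / L_p .$$

This convention makes the tangent correlation of a surface-equilibrated
(2D) chain decay as $\langle \cos\theta(s) \rangle = e^{-s/(2L_p)}$, and
integrating it twice gives the closed-form mean squared end-to-end distance

$$\langle R^2 \rangle = 4 L_p L_c
  \left[ 1 - \frac{2L_p}{L_c}\left(1 - e^{-L_c/(2L_p)}\right) \right],$$

implemented in `msd_closed_form()`. Some descriptions of this
discretization state the angular variance as $L_p/L_s$; that expression is
dimensionally inconsistent (an angle variance cannot grow with stiffness)
and incompatible with the closed form above, so the package uses $L_s/L_p$
throughout. The tests verify the choice against numerical integration of
the tangent correlation and against the simulated decay rate.

Chains are strictly two-dimensional — molecules equilibrate on the mica
surface before imaging — and ideal: no excluded volume, no
force-extension mechanics, no twist-bend coupling. The first segment of a
simulated chain points along $+x$; end-to-end statistics are rotation
invariant, so nothing is lost.

`rivetti_estimator()` provides the classical moment method: invert the
closed form at the empirical mean square (bracketed monotone root search on
$L_p \in [10^{-3}, 10^6]$ nm, relative tolerance $10^{-6}$). It is exact
when the sample is an unbiased draw from the model, but it uses only the
second moment: if small end-to-end distances are missing — as happens in
real data whenever a head engages the hinge and the frame is excluded — the
mean square, and hence the estimate, is biased upward. The package's
property tests assert this direction of bias explicitly.

## Histogram least-squares fitting

`fit_wlc()` estimates $(L_p, L_c)$ jointly by comparing the binned density
of the measured end-to-end distances with densities simulated at candidate
parameter values, scored by the sum of squared per-bin differences. There
is no closed form for the full 2D end-to-end *distribution*, and published
approximations cover only narrow stiffness regimes, which is why the
predicted densities are generated by Monte Carlo.

Choices that matter, with defaults:

* **Bins**: 2-nm bins on [0, 60] nm. This resolves the broad ~25-nm peak
  of a 3.8/46 chain with more than ten occupied bins even at a few hundred
  data points. Densities are normalized by the total sample size, so mass
  outside the range counts against a candidate that pushes it there.
* **Search**: $L_p \in [1, 20]$ nm, $L_c \in [20, 80]$ nm, a 15 × 15 grid,
  then three refinement rounds that halve the window around the running
  minimum (clipped to the initial ranges). A minimum within one final grid
  spacing of the initial boundary sets `boundary_warning`.
* **Ensemble size**: 2 × 10^4 chains per evaluation by default. Larger
  ensembles (the `chains_per_eval` field) sharpen the score surface at
  proportional cost; 10^5–10^6 are natural choices on a cluster.
* **Common random numbers**: every grid evaluation reuses the same derived
  seed, so simulation jitter is strongly correlated across candidates and
  largely cancels in the argmin, and the fitted surface is a deterministic
  function of `config$seed`.
* **Data below the first bin edge are kept.** Truncation near zero is a
  property of particular datasets (engagement censoring), not of the
  fitter.

`confidence_sd()` computes one-SD confidence intervals by the parametric
Monte-Carlo route: simulate replicate datasets of the fitted size at
$(\hat L_p, \hat L_c)$, refit each identically, and report the standard
deviations of the refitted parameters. This is the package's reading of a
"graphical Monte Carlo" error estimate: the spread of the estimator under
the fitted model.

```{r, eval = FALSE}
d <- simulate_end_to_end(wlc_params(3.8, 46, n_chains = 2000), seed = 1)
fit <- fit_wlc(d, fit_config(seed = 2))
fit
```

At this sample size (2000 distances) the refitting SD of $\hat L_p$ is
about 0.15–0.2 nm, so recovery of the generating 3.8 nm to within ±0.2 nm
is the expected behaviour, and the acceptance test asserts exactly that.

## Conformational geometry and classification

Per frame, the geometry is three numbers: the head-head distance $hh$ and
the two head-hinge distances $(g_1, g_2)$, all Euclidean and invariant
under rigid motions. Classification uses two engagement thresholds
(both 7 nm by default — the observed head-hinge distance density has a dip
near 7 nm separating an engaged peak at ~2.4 nm from the open population,
and the engaged head-head peak at 2.5 ± 1.3 nm sits well below it):

| class | condition |
|---|---|
| B | $g_1 \le 7$ and $g_2 \le 7$ |
| O | not B, $hh \le 7$ |
| P | not B or O, exactly one $g_i \le 7$ |
| V | everything else |

The precedence B > O > P > V closes the corner cases: when all three
domains co-locate the frame counts as butterfly, and the quadrants are
exhaustive and mutually exclusive for any positive thresholds. Distances
exactly at a threshold count as engaged. Frames with missing landmarks are
`UNCLASSIFIED`, never an error, and they break transition chains in
`annotate_movie()` — no transition is counted across a gap.

`hinge_angle()` measures the opening angle between the arms as the angle
between chords from the hinge to the point 5 nm along each arm trace
(about 1.3 persistence lengths). Single-segment tangents at the hinge are
dominated by thermal bending noise; a chord of roughly one persistence
length averages over it while remaining local to the hinge. The arc length
is configurable (`thresholds(tangent_arc = ...)`).

`gaussian_peak()` fits $A e^{-(x-\mu)^2/2\sigma^2}$ to a windowed binned
density by Levenberg-Marquardt least squares. Windowing (default [0, 10] nm
for engaged peaks, [10, 60] nm for the open population) isolates one mode
of a bimodal distribution. Histograms with fewer than three occupied bins
fall back to the moment estimates of the binned density, so a degenerate
point mass returns $\sigma$ below the bin width instead of a fitting error.

## The synthetic-data generator

`generate_movie()` emulates the statistical structure the analysis
assumes:

* two independent WLC arms ($L_p$ = 3.8 nm, $L_c$ = 46 nm, $L_s$ = 0.2 nm
  by default) anchored at the hinge with uniformly random directions;
* a first-order Markov state process over V/O/B/P, one step per 0.1-s
  frame. The default matrix keeps a state with probability 0.9 and
  distributes the rest in proportion to the stationary weights
  (V 0.25, O 0.40, B 0.20, P 0.15), chosen so that a quarter of frames are
  open-V, O is the most abundant class, and O↔B exchange dominates the
  switching — the qualitative pattern seen in liquid-AFM recordings. The
  dwell structure is illustrative, not fitted to measured kinetics;
* state-conditional geometry by rejection sampling: engaged distances are
  drawn from zero-truncated Gaussians (head-head 2.5 ± 1.3 nm, head-hinge
  2.4 ± 1.9 nm) and unconstrained arm pairs are re-simulated until they
  realize the draw within ±0.5 nm. With $L_c/L_p \approx 12$ the single-arm
  return probability below 7 nm is a few percent, so rejection is cheap and
  — unlike any pinned-end construction — preserves the exact conditional
  WLC ensemble. The generator imposes the same 7-nm open/engaged
  constraints the classifier uses (for O and P states this includes keeping
  the non-engaged arms open), so ground truth and classification agree by
  construction up to localization noise;
* isotropic Gaussian localization noise (SD 0.5 nm by default) on the
  emitted landmarks only; ground truth and arm traces stay noiseless.

What it deliberately does **not** emulate: AFM height maps, tip
convolution, scanner drift, frame-to-frame correlation of the arm
configurations within a state, segmentation ambiguity, or ATP-dependent
kinetics. Passing round-trip tests therefore demonstrates that the
pipeline's inference is self-consistent under the model's assumptions —
not that those assumptions hold for any particular instrument.

`generate_end_to_end_dataset()` reproduces the fitting scenario: only
V-state (open) frames contribute, both arms each, noiseless by default.
Because the V condition removes arm distances below 7 nm, this conditional
sample has an inflated mean square (~624 vs 584 nm² at the defaults) — the
same censoring that inflates the moment estimator on real data, and the
reason `run_pipeline()`'s recovered $\hat L_p$ is accepted in a [3, 5] nm
band rather than at ±0.2 nm.

## Randomness and determinism

One top-level seed drives everything. `derive_seed(seed, index)` maps it
to independent child streams per operation, so adding a stage never
perturbs the draws of existing stages; all simulation kernels use R's RNG
(including inside the compiled code), so `set.seed()` semantics apply
everywhere, and identical seeds give bit-identical outputs — files
included.

## Validation scale

The shipped test-suite and acceptance runs use desk-scale problem sizes
chosen to keep a full run in the tens of minutes on one core: one
default-configuration fit (2 × 10^4 chains/evaluation, ~900 evaluations)
for the headline recovery check, 9-point grids with 4000–5000
chains/evaluation for the parameter-recovery sweep and replicate-SD
checks, a 10^6-chain ensemble for the distribution-peak location (the peak
is flat to ~1% over 21–27 nm, so smaller ensembles do not localize its
argmax bin reliably), and movies of 250–1000 frames. All sizes are plain
configuration fields and scale up unchanged.

## Known limitations

* Strictly 2D, surface-equilibrated chains; no 3D mode.
* The two arms are modelled as identical homogeneous polymers; real coiled
  coils have sequence-dependent local flexibility.
* The hinge-angle operation needs arm traces; it cannot be computed from
  the three landmarks alone.
* The Markov transition matrix of the generator is a modelling convenience;
  its dwell times are not calibrated against measured kinetics.
* Landmark detection itself (from height maps) is out of scope: the
  package starts from landmark tables.
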
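# smcflex

Quantitative analysis of single-molecule AFM movies of
structural-maintenance-of-chromosomes (SMC) dimers — condensin's Smc2-Smc4
and relatives. The package is aimed at single-molecule biophysicists who
have per-frame landmark coordinates (two ATPase heads and the hinge, in nm)
and want to quantify (i) the mechanical flexibility of the ~45-nm
coiled-coil arms and (ii) the conformational state dynamics of the dimer.

## What it computes

**Coiled-coil stiffness.** Each arm is modelled as a two-dimensional
worm-like chain (WLC): contour length $L_c$ discretized into segments
$L_s = 0.2$ nm with Gaussian deflection angles of variance $L_s/L_p$, which
gives the surface-equilibrated tangent correlation
$\langle\cos\theta(s)\rangle = e^{-s/(2L_p)}$ and

$$\langle R^2\rangle \;=\; 4 L_p L_c\!\left[1-\frac{2L_p}{L_c}\!\left(1-e^{-L_c/(2L_p)}\right)\right].$$

Because the full end-to-end *distribution* has no closed form, $(L_p, L_c)$
are fitted by least-squares comparison of the measured end-to-end distance
histogram with Monte-Carlo simulated histograms over a refined parameter
grid (`fit_wlc()`), with one-SD confidence intervals from parametric
replicate refits (`confidence_sd()`). The classical moment estimator that
inverts $\langle R^2\rangle$ (`rivetti_estimator()`) is included as a
cross-check; it is biased upward whenever small distances are censored from
the sample, e.g. by head-hinge engagement.

**Conformational dynamics.** Per-frame head-head and head-hinge distances
and hinge opening angles (`head_head_distance()`, `head_hinge_distances()`,
`hinge_angle()`), classification into the four conformational classes —
V (open), O (heads engaged), B ("butterfly", both heads at the hinge),
P (one head at the hinge) — via 7-nm engagement thresholds
(`classify_frames()`), Gaussian fits to distance-histogram peaks
(`gaussian_peak()`), and movie annotation with class frequencies and
state-transition counts (`annotate_movie()`).

**Synthetic ground truth.** `generate_movie()` produces landmark tables,
arm traces and true state sequences from WLC arms plus a Markov state
process (frame interval 0.1 s), so the whole pipeline is testable without
any raw AFM data.

## Worked example

```r
library(smcflex)

# a synthetic 300-frame movie at the default conditions
mov <- generate_movie(synth_config(n_frames = 300, seed = 7))
ann <- annotate_movie(mov$frames)
ann
#> movie annotation: 300 analyzed frames (every 1)
#>   class frequencies: V 25.0%, O 45.3%, B 16.7%, P 13.0%
#>   transitions counted: 299

# persistence-length fit on 2000 simulated end-to-end distances
d <- simulate_end_to_end(wlc_params(3.8, 46, n_chains = 2000),
                         seed = derive_seed(1, 1))
fit <- fit_wlc(d, fit_config(seed = derive_seed(1, 2)))
fit
#> WLC histogram fit (n = 2000 distances)
#>   L_p = 3.67 (sd not computed) nm
#>   L_c = 45.7 (sd not computed) nm
```

The class frequencies recover the generator's stationary state mixture
(V 0.25, O 0.40, B 0.20, P 0.15) to within counting noise, and the fit
recovers the generating persistence length (3.8 nm) and contour length
(46 nm) within one refitting SD (~0.2 nm and ~1.5 nm at this sample size).
`run_pipeline(pipeline_config(...))` chains the stages — synthesize,
classify, extract open-state arm distances, fit — and writes TSV/JSON
artifacts; `inst/cli/smcflex.R` exposes the same stages as shell
subcommands (`simulate-wlc`, `synth`, `classify`, `fit`, `run`).

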
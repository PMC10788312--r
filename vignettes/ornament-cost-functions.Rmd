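---
title: "Cost functions of purely sexual ornaments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost functions of purely sexual ornaments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ornacost)
```

## The question

Shortening an ornament and measuring the performance drop is routinely used
to infer the selective force behind the ornament: an *incremental* cost
function (performance rises monotonically as the ornament shrinks) is read
as evidence of pure sexual selection, a *concave* one (performance rises,
peaks, then falls) as evidence that viability selection placed the trait
near a performance optimum. `ornacost` formalises why that inference fails
when a compensatory trait has coevolved with the ornament: the manipulation
moves the ornament while the compensation stays put, and a compensation
tuned to the full ornament *overcompensates* a reduced one.

## The performance-surface model

Performance over ornament $x_1$ and compensatory trait $x_2$ is the
quadratic approximation standard in selection analysis,

$$W(x_1,x_2)=\tfrac12\gamma_{11}x_1^2+\beta_1x_1+\tfrac12\gamma_{22}x_2^2+
\beta_2x_2+\gamma_{12}x_1x_2+\alpha .$$

All coordinates and coefficients are unitless. The linear gradients
$\beta_1,\beta_2$ are carried throughout so the general form is supported,
although the canonical scenario sets them to zero and places the
performance peak at the origin. With $\gamma_{11}<0$ and $\gamma_{22}<0$
the sign of $\gamma_{12}^2-\gamma_{11}\gamma_{22}$ decides the geometry
(`classify_geometry()`): negative gives an elliptical peak, positive a
saddle (total fitness unbounded, refused by `current_state()`), zero the
degenerate ridge along which compensation cancels the ornament's cost
exactly. Because exact equality is measure-zero in floating point, the
ridge case is detected at a configurable relative tolerance, default
$10^{-9}$.

Fixing compensation at $k$ (what a manipulation does) yields the
one-dimensional quadratic with maximiser

$$x_1^{peak}=-\frac{\gamma_{12}k+\beta_1}{\gamma_{11}},$$

obtained by completing the square: $W=\tfrac12\gamma_{11}\bigl(x_1+
(\gamma_{12}k+\beta_1)/\gamma_{11}\bigr)^2+\text{const}$, so the maximiser
is the *negative* of the bracketed shift. The sign matters: with $k>0$,
$\gamma_{12}>0$, $\gamma_{11}<0$ the peak is strictly positive, which is
the whole result — reduction first helps, then hurts. Verbal statements of
this quantity sometimes drop the minus sign; the package documents and
tests the signed form, since the unsigned one contradicts the qualitative
claims it is meant to support. `classify_cost_shape()` adds a fourth
category, `decreasing`, for peaks at or beyond the current ornament value:
the three classical labels (concave / incremental / flat) do not cover
that case, and mislabelling it would hide exactly the pattern a
viability-built trait produces.

Cost is everywhere reported as *best achievable performance minus
performance*, so cost is non-negative and zero at the relevant optimum.

## The evolved state

`current_state()` maximises $W + s\,x_1$ for a sexual-selection gradient
$s\ge 0$ by solving the $2\times 2$ stationarity system; the solution's
compensation always lies on the ridge line $x_2=-(\gamma_{12}x_1+\beta_2)/
\gamma_{22}$, i.e. the evolved phenotype is perfectly compensated *for its
own ornament*. For $\beta=0$ the manipulation-path peak equals
$(\gamma_{12}^2/\gamma_{11}\gamma_{22})\,x_1^\ast$, a fraction strictly
inside $(0,1)$ of the evolved ornament — the property-based tests verify
this over 200 random surfaces drawn from the compensation regime
($\gamma_{11},\gamma_{22}\sim U(-10,-0.5)$,
$\gamma_{12}$ a $U(0.05,0.95)$ multiple of $\sqrt{\gamma_{11}\gamma_{22}}$).

## The toy experiment and its generator

The discrete game in `solve_toy_game()` mirrors the balancing-toy
argument: survival requires |tilt| below a cutoff (30° by default),
reproduction goes to the longest-tailed survivors. Tail length is treated
as continuous but compared on a user-configurable grid (default 0–110 mm
in 10 mm steps) with wings as a binary compensation; ties return the full
tie set rather than an arbitrary pick, since the argument only needs
existence and uniqueness under the default parameters. With the calibrated
tilt model the unique ESS is the fully elongated winged morph.

`generate_experiment()` emulates the shortening experiment on that morph.
The tilt model is deliberately minimal: the net moment is the remaining
straw mass (uniform density, 0.4 g per 160 mm) times a fixed tail arm,
minus twice the wing mass (0.8 g each) times a wing arm, and tilt is
linear in net moment (small-angle approximation) with the absolute value
taken at the end, clipped at 90°. Linearity in remaining length makes the
noise-free |angle| profile exactly convex in the manipulation with an
interior minimum, which is the qualitative feature the statistical stage
must recover; an arctan variant could be swapped in behind `tilt_angle()`
without touching anything else. The pivot geometry of the real toy is
unknown, so the arms and the degree-per-moment scale are free calibration
constants, not physical claims.

`calibrate_generator()` pins the model to three anchor morphs: the
ancestral toy at 4.87°, the full winged morph at 22.37°, and a wingless
30 mm morph at 36.60°. In the parameterisation (baseline, angle scale,
angle scale × wing moment) the three conditions are linear, so the
least-squares solve is exact; equal anchors force a zero angle scale and
raise a calibration error, and any anchor missed by more than 5 % relative
error aborts with the residuals. Full elongation is fixed at 110 mm
because a −80 mm manipulation must leave 30 mm.

Noise enters additively in degrees — a per-toy baseline offset
(SD 0.45°, matching an among-individual variance of about 0.2) and a
per-photo error (SD 2°, which puts the photo-to-photo repeatability of the
default design near 0.99) — matching the random-intercept structure of the
analysis model. Individual effects in degrees rather than in moments keep
the generative and analysis models aligned.

What the generator does *not* emulate: photograph digitisation and angle
measurement, any non-Gaussian or heteroscedastic error, toy-specific pivot
geometry, and the folding of signed tilt into |angle| near zero is a
simulator artefact rather than measured physics. Passing tests therefore
show that the pipeline recovers the structure this generator encodes, not
that real measurements obey it.

## The statistical stage

Replicates are averaged per (individual, treatment) cell; an incomplete
crossing errors rather than imputes. Repeatability is the one-way ANOVA
intraclass correlation with the Lessells–Boag effective group size
$n_0$; groups default to the 20 cells (df 19, 20 for the standard design),
with grouping by individual available but non-default. Zero within-group
variance returns $r=1$; all-singleton groups are an error.

The manipulation predictor is scaled before fitting. The default is a
z-score using the mean and $(n-1)$ SD of the *distinct* treatment levels
(for 0…−80 mm: $\pm1.2649, \pm0.6325, 0$), chosen because coefficient
magnitudes in the low tens are numerically consistent with a unit-variance
predictor and wildly inconsistent with raw millimetres; `"center"` and
`"raw"` are exposed for sensitivity analysis.

`gibbs_lmm()` samples the Gaussian random-intercept model with the
standard conjugate cycle. Defaults emulate the documented defaults of the
MCMCglmm-style samplers this analysis is usually run with: 13 000
iterations, 3 000 burn-in, thinning 10, a fixed-effect normal prior of
variance $10^{10}$, and inverse-gamma variance priors parameterised as
$(V=1,\nu=0.002)$. Three chains are run by default — single-chain runs
leave $\hat R$ undefined — seeded as `seed + chain - 1`, so everything is
reproducible bit-for-bit. $\hat R$ is the classic
$\sqrt{((n-1)/n\,W + B/n)/W}$; duplicated chains give a value at most
$1+10^{-12}$, and 1.2 is used as the convergence threshold throughout.
pMCMC is the two-sided tail probability floored at $1/n_{draws}$.

The cost-shape verdict is a package convention: each posterior draw votes
on whether the angle curve is convex with its vertex
$-b_{lin}/(2b_{quad})$ inside the manipulated range, and `concave_cost` /
`incremental_cost` require 95 % posterior mass; anything else is
`inconclusive`. Coefficient significance alone cannot distinguish an
interior from an exterior vertex, which is why the verdict is vertex-based.

## Numerical and design choices

* Equality and flatness tolerances default to $10^{-9}$ and are arguments,
  never hidden constants.
* `run_pipeline()` derives per-stage seeds from one master seed by a fixed
  affine map modulo $2^{31}-1$, so stages can be rerun in isolation and a
  config plus seed reproduces the whole report.
* Degenerate inputs fail loudly with classed conditions
  (`ornacost_unbounded_fitness`, `ornacost_calibration_failure`,
  `ornacost_rank_deficient`, …) rather than returning NA.
* Problem sizes in the test suite: oracle grids at $10^{-3}$–$10^{-4}$
  resolution with local refinement, 200-surface property sweeps, 100
  simulated datasets for coverage (20 individuals × 5 treatments each),
  and chains of 53 000 iterations where a sampler mean is compared with the
  REML/GLS oracle — sizes chosen so Monte Carlo error sits well below the
  assertion tolerances.

## Known limitations

Two traits only — multi-trait compensation and canonical rotation of the
$\gamma$ matrix are out of scope, as are evolutionary dynamics (the game
compares endpoint fitness, not trajectories), non-Gaussian responses,
random slopes, and estimating $\gamma$ from field data. The balanced-design
shortcut GLS = OLS used by the oracle tests does not hold for unbalanced
data, and the sampler, while general, is only validated on designs like
those it ships for.
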
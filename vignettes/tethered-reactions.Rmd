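---
title: "Modelling tethered dephosphorylation: from sensorgrams to molecular reach"
author: "tetherspr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tethered dephosphorylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherspr)
```

# The science

Cytoplasmic phosphatases such as SHP-1 are recruited to phosphorylated
receptor tails (PD-1, SLAM) through their SH2 domains and then act on other
phosphorylated sites *within reach* of their anchor. How far the tethered
catalytic domain extends — the **molecular reach** `L` — controls both the
effective substrate concentration it experiences and what fraction of the
membrane it can patrol. `tetherspr` implements the complete quantitative
pipeline for measuring and interpreting this quantity from surface plasmon
resonance (SPR) experiments in which the enzyme is injected over a surface
of immobilized phosphorylated peptides: the enzyme binds a peptide via SH2,
dephosphorylates neighbouring peptides in *trans*, and thereby erases its
own binding sites, producing a characteristic multiphasic sensorgram (fast
rise, reach-limited decay, slow solution-catalysis tail, dissociation after
the injection ends).

## The reach kernel and the unit dictionary

A tethered catalytic site is distributed around its anchor with the
isotropic Gaussian density

$$\sigma(r) = \left(\frac{3}{2\pi L^2}\right)^{3/2}
  \exp\!\left(-\frac{3 r^2}{2 L^2}\right),$$

which integrates to 1 over space ([reach_kernel()]). Two co-anchored sites
therefore see each other at an effective local concentration
$\sigma^* = 1/L^3$; `sigma_star_from_reach()` and `reach_from_sigma_star()`
convert between the two using the SI Avogadro constant
(1 µM = 6.02214076×10⁻⁷ nm⁻³), e.g. `L = 14.5 nm ⇔ σ* = 544.6 µM`.
Component reaches add in quadrature: in the SPR assay the acting enzyme's
anchor and its target each sit on a tether, so
$L^2 = 2L_\mathrm{tether}^2 + L_\mathrm{enzyme}^2$ (`combine_reach()`,
`parse_tether_reach()`).

For flexible tethers the worm-like chain gives
$L = \sqrt{l_c\,l_p}$ with contour length $l_c$ and persistence length
$l_p$. A second convention, $\sqrt{2 l_c l_p}$, also circulates; both are
exposed via `tether_spec(convention = ...)` because the quadrature law above
combined with PEG contour lengths yields the factor-4 slope
$L^2 = 4 N_\mathrm{PEG} l_\mathrm{PEG} l_p + L_\mathrm{enzyme}^2$
used by the tether-series regression, while predictions for amino-acid
tails conventionally use the first form. Defaults
(`unit_length = persistence_length = 0.4` nm) are the standard values for
PEG repeats and random amino-acid chains.

# The MPDPDE forward model

The mean-field description of tethered reactions must track spatial
correlations: an enzyme bound at one site preferentially destroys
*nearby* phosphorylated sites, so the survivors become anticorrelated with
bound enzymes. The multicenter particle density PDE (MPDPDE) closes the
hierarchy at pair level. Its nondimensional state is the free and bound
phosphorylated site densities $n_A, n_B$ and three radial correlation
functions on separations $r$ (in units of $L$): the free–bound pair
correlation $Y(r)$ and the autocorrelations $X_A(r)$, $X_B(r)$. The five
rate parameters are

* `p1 = k_on·[enzyme]`, `p2 = k_off` — binding and unbinding,
* `p3 = kcat_tethered·[peptide]` — the mean-field tethered sink,
* `p4 = kcat_tethered·σ*` — the proximal (pair-correlation) sink,
* `p5 = kcat_solution·[enzyme]` — catalysis from solution.

The $n_A$ equation carries the kernel-weighted radial integral of $Y$
(normalized so it reduces to $-p_3 n_A n_B$ when $Y \equiv 1$); the $Y$ and
$X_A$ equations carry bipolar double integrals coupling them to the
correlation field, and density-ratio factors $n_A/n_B$, $n_B/n_A$ appear in
the pair-renewal terms. These ratios follow from pair-density bookkeeping:
for instance binding converts A–B pairs into B–B pairs at rate
$p_1 n_A n_B Y$, so $\dot X_B = 2 p_1 (n_A/n_B)(Y - X_B)$, and analogously
for the other renewal terms. The ratios are floored at denominator 1e-12
with the whole term zeroed below it; the flooring only ever acts in the
first instants when $n_B \approx 0$ and the bracket is simultaneously
$\approx 0$.

A structural consequence worth knowing: the autocorrelations can exceed 1.
Survivors of tethered catalysis are spatially clustered (they persist
exactly where no bound enzyme is within reach), and the pair renewal keeps
$Y \le \max X_A$. Both behaviours are confirmed against the stochastic
particle simulator, so the test suite asserts $Y \le \max X_A$ and
boundedness rather than $Y \le 1$.

## Observable

The fitted signal is piecewise: zero before the injection start
$p_\mathrm{start}$, then amplitude·$n_B$ plus a linear nonspecific drift
$n_\mathrm{ns}\,(t - p_\mathrm{start})$ during the injection, then
amplitude·$n_B$ alone after $p_\mathrm{stop}$, where the analyte inputs
($p_1$, $p_5$) are switched off. The drift is implemented as ramping from
zero at the injection start; with the alternative reading
$n_\mathrm{ns}\, t$ the two differ only by a constant absorbed into the
baseline. The `amplitude` maps the nondimensional bound fraction to
response units; synthetic data uses a known amplitude and fits may fix it
from the immobilization level or co-fit it (`fit_amplitude`).

## Numerics

The radial grid (`radial_grid()`) is uniform with $n \ge 64$ nodes up to
$r_\mathrm{max} \ge 5$ (kernel mass beyond 5 is below 1e-8; default 64
nodes to 6). On a uniform grid the bipolar limits $r \pm r'$ fall exactly
on nodes, so the double integrals reduce to differences of a cumulative
trapezoid — no interpolation — making each right-hand-side evaluation
O(n²) with small constants; nodes beyond the kernel support are skipped.
Two integration routes share one compiled right-hand side:

* **Reference**: adaptive Adams integration via `deSolve`
  (rtol 1e-6, atol 1e-8 default), used by `integrate_mpdpde()`, the
  synthetic-data generator, and `spr_objective()`. Doubling the grid
  changes the bound fraction by < 0.5% sup-norm; the Langmuir limit is
  reproduced to < 1e-5.
* **Fixed-step RK4** (internal, used by the fitting and sampling stacks):
  a fixed grid makes the model output a *smooth* function of the
  parameters. With adaptive control, step-size decisions flip with
  parameter perturbations and put noise of the order of the solver
  tolerance into finite-difference Jacobians, which demonstrably stalls
  least-squares descent. At dt = 0.05 s the two routes agree to ~2×10⁻⁶
  signal units (far below instrument noise); dt = 0.1 s (used during
  annealing and scaled-down fits) agrees to ~3×10⁻⁵. The sampler uses a
  coarse output grid (dt = 0.25 s, refined 5× near the injection start and
  stop where the signal is strongly curved) with linear interpolation,
  accurate to ~1.5×10⁻³ signal units.

States decaying into the subnormal floating-point range are clamped to
zero at 1e-14 (they are physically zero and subnormal arithmetic is slow).

# The stochastic particle oracle

`sample_sites()` places a Poisson number of immobilized sites uniformly in
a periodic box (≥ 4 reach units a side); `simulate_particles()` runs an
exact Gillespie simulation with minimum-image distances: free
phosphorylated sites bind at `p1` and lose their phosphate to solution at
`p5`; bound sites unbind at `p2`; and a bound enzyme dephosphorylates each
free phosphorylated site at distance $r$ at rate
$(p_3/\rho)\,\hat\sigma(r)$, with $\hat\sigma$ the unit-reach kernel and
$\rho$ the site density. Because $p_3 = k_\mathrm{cat}[\mathrm{peptide}]$
and $\rho = [\mathrm{peptide}]L^3$ while $p_4 = k_\mathrm{cat}/L^3$, this
single microscopic channel satisfies $p_4 = p_3/\rho$ identically — the
PDE's $p_3$ (mean sink) and $p_4$ (pair sink) terms are two moments of the
same process, and PDE/oracle comparisons set $p_4 = p_3/\rho$. Ensemble
means agree with the PDE within Monte-Carlo error across binding-dominated,
strongly tethered, and solution-catalysis regimes (about 430 sites per
run, 30 replicates per regime in the test suite), which is the package's
primary evidence that the equations, their regularizations and the
quadrature are implemented correctly.

# Fitting

`fit_sensorgram()` estimates the eight observable parameters by simulated
annealing on the sum of squared errors with the polynomial cooling
schedule $T(s) = T_0 (1 - (s/n)^4)$, $T_0$ = SSE of the initial guess,
single-parameter Gaussian proposals whose scales adapt during the first
30% of steps, best-ever tracking, and three restarts by default, followed
by a deterministic polish. Initial constants: k_on = 0.1 µM⁻¹s⁻¹,
σ* = 544.6 µM, kcat(tethered) = 0.01, kcat(solution) = 0.002 µM⁻¹s⁻¹,
k_off from an exponential fit to the dissociation tail
(`initial_koff()`), injection timing read off the trace, drift from the
baseline shift.

Design choices that the optimization landscape forced:

* **Coordinates.** The search runs in
  $(\log p_1, \log p_2, \log p_3, \log \sigma^*, \log p_5,
  n_\mathrm{ns}, p_\mathrm{start}, p_\mathrm{stop})$. The landscape has
  well-separated local basins in which tethered structure is traded
  against solution catalysis with $\sigma^*$ running to extreme values;
  in $(p_3, p_4)$ coordinates those basins lie close to the standard
  initial guess, in $\sigma^*$ coordinates they are several log-units
  away and the physically plausible basin dominates the search region.
* **Polish.** Quasi-Newton (BFGS) descent over the six smooth
  coordinates, then Levenberg–Marquardt on the residual vector, run from
  both the annealing optimum and the initial guess, keeping the better
  endpoint. Pure Levenberg–Marquardt from the standard initial guess
  reliably walks into a defective basin along a curved valley; the
  quasi-Newton stage does not.
* **Injection timing** defaults to *fixed* at its trace-derived estimate
  (`fit_timing = "fixed"`). With little or no nonspecific drift the
  observable has no sharp feature at the injection end, and a freely
  fitted $p_\mathrm{stop}$ absorbs reach information (a +0.1 s error in
  $p_\mathrm{stop}$ can shift the recovered reach by tens of percent).
  The injection schedule is set by the instrument and is known; when the
  drift is appreciable its discontinuity at $p_\mathrm{stop}$ pins the
  parameter and `fit_timing = "free"` is appropriate.

On synthetic traces at the study conditions with 1% multiplicative noise,
the scaled-down pipeline (10³ annealing steps, one restart, polish)
recovers k_off and K_D with median errors below 1% and the molecular
reach with median error about 6% over ten seeds.

# Identifiability by MCMC

`spr_mcmc()` samples the posterior under a Gaussian i.i.d. likelihood
$\exp(-\mathrm{SSE}/2s^2)$ — the noise scale taken from best-fit residuals
or supplied — with flat priors on the rates (positive half-line), on
$n_\mathrm{ns}$ and $p_\mathrm{stop}$, and $p_\mathrm{start}$ bounded
below 0.3 s. Proposals are scalar moves whose sizes adapt toward the 0.44
acceptance rate (the classic single-component optimum) during an
adaptation phase and are then frozen; the chain grows until the third and
fourth quarters of every marginal agree under the two-sample
Kolmogorov–Smirnov test (`ks_converged()`, level 0.05 per parameter, no
multiplicity correction) or a length cap.

Two refinements keep the scalar-update scheme effective at practical chain
lengths. The random walk runs in the fitting coordinates (log rates,
log σ*, with the on/off pair expressed as $\log p_1$ and
$\log p_2/p_1$) with the exact Jacobian added to the log-posterior, so the
target is still the flat-prior posterior over the rates themselves; and
halfway through adaptation the proposal basis is rotated to the principal
axes of the adaptation samples, after which each eigendirection keeps its
own adapted scale. Strongly correlated combinations — precisely the slow,
weakly identified directions — are then updated as single coordinates.
Without the rotation the realized chains explore only the narrow
conditional widths and understate every marginal.

`posterior_summary()` reports means, KDE modes, credible intervals and
correlations, plus two robustness-aware mode statistics: a mode count that
requires a genuine valley between peaks, and the fraction of probability
mass in the modal peak's basin — the operational version of "most of the
mass concentrated in a single peak", stable where ripple-level mode
counting on finite chains is not. The test-suite coverage experiment uses
additive-noise synthetic traces (so the Gaussian likelihood is exactly
specified, as a coverage experiment requires) with nonspecific drift
(which pins $p_\mathrm{stop}$), chains of 5000 kept samples after 2000
adaptation steps, and checks that the true local concentration lies in the
95% interval and all marginals are single-peaked in at least 8 of 10
seeded runs.

# Isolating the enzyme's reach

`reach_table()` averages replicate σ* values per tether length and
transforms the average to a single $L^2$ (the order matters and matches
the reporting convention of the assay), propagating the replicate scatter
by the delta method, $\mathrm{err}(L^2) = \tfrac23 (L^2/\sigma^*)\,
\mathrm{sd}(\sigma^*)$ — accurate to ~10% of a brute-force Monte-Carlo
transformation up to a coefficient of variation of 0.1, degrading to ~14%
by cv 0.2 as the curvature of the −2/3 power grows. `peg_reach_fit()`
regresses $L^2$ on the PEG linker number by unweighted OLS (a weighted
option exists), excluding the zero-linker construct by default (directly
coupled peptides suffer steric hindrance at the surface); the square root
of the intercept is the enzyme reach and the slope estimates
$4 l_\mathrm{PEG} l_p$. On the tabulated series this yields ≈13.3 nm.
When coverage of the intercept matters, regress replicate-level $L^2$
values rather than per-length means: a four-point fit leaves two degrees
of freedom and ±2·SE then covers barely 80%.

# Membrane predictions

With receptor–enzyme complexes scattered over the cell surface at density
$\rho_0$ (copies over the sphere area, `density_from_copy_number()`), the
effective enzyme concentration at a substrate is the planar integral of
the reach kernel, $C_\mathrm{eff} = \sqrt{3/2\pi}\,\rho_0/L_\mathrm{rxn}$,
and the fraction of substrates with at least one complex within reach is
Poissonian, $P_{\ge 1} = 1 - \exp(-\pi\rho_0 L_\mathrm{rxn}^2)$
(`effective_concentration()`, `coverage_probability()`,
`density_for_coverage()`). The plane approximation is excellent
(cell radius ≫ reach). At 80,000 copies on a 5-µm sphere and the measured
combined reach of 14.6 nm the coverage is ≈15%, and 90% coverage requires
≈0.0034 nm⁻², an order of magnitude above the uniform estimate — receptor
clustering is needed for broad substrate control. The planar closed form
is verified against 2D quadrature and against a Monte-Carlo
plane-dropping experiment. One caveat: at the uniform density the closed
form gives an effective concentration of tens of µM, not the ~1000 µM
sometimes quoted for comparable figures; the prefactor used here is the
one derived and unit-tested from the kernel itself, and we flag rather
than reproduce that larger value.

# The synthetic-data generator

`simulate_sensorgram()` is the package's stand-in for instrument data (no
raw traces from the original experiments are deposited). Defaults define
the study conditions: 0.1 µM enzyme injected for 45 s over 100 µM
immobilized peptide — a typical dextran-surface local concentration; at an
order of magnitude lower immobilization the tethered phase carries too
little information and the reach becomes practically unidentifiable, which
is not the regime the assay operates in — amplitude 500 RU per unit bound
fraction, 10 Hz sampling, injection start 0.1 s, 20 s of dissociation,
additive Gaussian noise at peak SNR ≈ 50 (multiplicative and drift
components available). Ground truth always travels with the trace
metadata. `table2_params()` carries the published mean constants for the
eight peptide constructs and seeds synthetic experiments spanning the
assay's regimes; `simulate_peg_series()` generates σ* replicate tables
under the linear squared-reach law with lognormal scatter.

What the generator does *not* emulate: reference-cell subtraction
artifacts, bulk refractive-index jumps, mass-transport limitation, or
baseline wander beyond the linear drift. Passing the recovery tests
therefore shows the estimation machinery is correct and well-conditioned
at realistic signal-to-noise, not that every instrument artifact is
handled.

# Problem sizes and scaled-down presets

The full fitting protocol (10⁵ annealing steps, three restarts) is the
package default. The test suite exercises scaled-down presets chosen as
the smallest sizes at which each property is cleanly decided: 10³
annealing steps with one restart plus polish for recovery (10 seeds),
5000-sample chains for the coverage experiment (10 runs), 30-replicate
particle ensembles of ≈430 sites for the oracle comparison (3 regimes),
and 15-s injections at 5 Hz for solver-level unit tests.

# Known limitations

* The fitting landscape is genuinely multimodal; with very short
  annealing and no polish the optimizer can settle in a defective basin.
  The shipped polish makes this rare at the study conditions, but fits of
  unusual data should be inspected (`plot()`, restart SSEs).
* Single-trace fitting only (as in the protocol); no global multi-trace
  fits.
* The scalar-update sampler, even with the rotated basis, mixes slowly on
  near-flat directions; credible intervals from short chains understate
  weakly identified parameters. Use the KS convergence flag and chain
  length diagnostics.
* The membrane module treats clustering only as elevated local density;
  no receptor/substrate diffusion dynamics.
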
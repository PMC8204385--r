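# tetherspr

Tethered enzyme reaction kinetics from surface plasmon resonance.

When a cytoplasmic phosphatase such as SHP-1 is recruited by its SH2
domains to a phosphorylated receptor tail (PD-1, SLAM), it
dephosphorylates other sites *within reach* of its anchor. That reach —
the **molecular reach of the reaction**, `L` — sets the effective
substrate concentration the tethered enzyme experiences
(`σ* = 1/L³`) and decides what fraction of a cell membrane a scattered
population of receptor–enzyme complexes can actually patrol. `tetherspr`
is for biophysicists who measure tethered reactions by SPR and want to
turn sensorgrams into reach, binding and catalysis constants, and those
into membrane-scale predictions.

The package implements:

* **Forward model** — the multicenter particle density PDE (MPDPDE) for
  an enzyme injected over immobilized phosphorylated peptides: mean free
  and bound site densities coupled to radial pair/auto-correlation
  functions, with rates `p1 = k_on[E]`, `p2 = k_off`,
  `p3 = kcat(teth)[P]`, `p4 = kcat(teth)·σ*`, `p5 = kcat(sol)[E]`, and
  the extended piecewise observable with linear nonspecific drift
  (`integrate_mpdpde()`, `spr_observable()`).
* **Ground truth** — an exact Gillespie particle simulator of the
  microscopic process with the Gaussian reach kernel
  (`simulate_particles()`), used to validate the PDE closure.
* **Fitting** — simulated annealing with the quartic cooling schedule
  plus a quasi-Newton/Levenberg–Marquardt polish on a smooth fixed-step
  forward model (`fit_sensorgram()`), and Metropolis–Hastings
  identifiability analysis with adaptive scalar updates (0.44 target
  acceptance) and a quarter-wise Kolmogorov–Smirnov stopping rule
  (`spr_mcmc()`).
* **Reach analysis** — σ* → L conversion, delta-method error
  propagation, the PEG tether-length regression
  `L² = 4·N_PEG·l_PEG·l_p + L_enzyme²` isolating the enzyme's own reach
  (`peg_reach_fit()`), and quadrature parsing/combination of component
  reaches (`parse_tether_reach()`, `combine_reach()`).
* **Membrane predictions** — effective concentration
  `C_eff = √(3/2π)·ρ₀/L` and Poisson substrate coverage
  `P≥1 = 1 − exp(−πρ₀L²)` for receptor–enzyme complexes on a cell
  surface (`coverage_probability()`, `density_for_coverage()`).
* **Synthetic data** — multiphasic sensorgrams with known ground truth
  at realistic conditions and noise (`simulate_sensorgram()`), the
  published mean constants for eight peptide constructs
  (`table2_params()`), and σ* replicate series
  (`simulate_peg_series()`).

Units everywhere: lengths nm, times s, concentrations µM.

## Worked example: from fitted σ* to the enzyme's reach and membrane coverage

The tabulated mean local concentrations for the PEG-linker series
(PEG0/3/6/12/28 coupled to the PD-1 ITSM peptide) convert to squared
reaches and fall on a line in the linker number; the intercept is the
enzyme's own reach:

```r
library(tetherspr)

tb <- table2_params()
series <- tb[tb$name %in% c("PEG0", "PEG3", "PEG6", "PEG12", "PEG28"), ]
tab <- reach_table(data.frame(n_peg = series$n_peg,
                              sigma_star = series$sigma_star))
peg_reach_fit(tab)   # PEG0 excluded by default (steric hindrance)
#> PEG-series reach regression (4 tether lengths, excluding N_PEG = 0)
#>   L^2 = 176 + 7.88 x N_PEG   (R^2 = 0.939, slope p = 0.031)
#>   enzyme reach L = 13.3 +/- 0.83 nm
```

So the phosphatase alone reaches ≈13 nm — between its crystal-structure
(5.3 nm) and maximally stretched (20.4 nm) estimates,
`shp1_reference_reach()`. Parsing the enzyme out of the combined reach
measured on the full PD-1 tail (σ* = 400 µM → L = 16 nm) gives the
receptor tail's contribution, and scattering such complexes at a
physiological density over a T-cell membrane predicts how much substrate
they can see:

```r
L_pd1  <- parse_tether_reach(16, 13.0)
L_cplx <- combine_reach(c(L_pd1, 13.0))
rho    <- density_from_copy_number(80000)   # copies on a 5-um sphere
sc     <- membrane_scenario(rho, L_receptor = L_pd1, L_enzyme = 13)

round(L_pd1, 2); round(L_cplx, 1)
#> [1] 6.6
#> [1] 14.6
round(100 * coverage_probability(sc), 1)
#> [1] 15.6
signif(density_for_coverage(0.9, sc$L_rxn), 2)
#> [1] 0.0034
```

A uniformly distributed receptor–enzyme population covers only ~15% of
membrane substrates; reaching 90% requires ~0.0034 nm⁻², an order of
magnitude more — receptor–substrate co-clustering, not diffusion, is
what broad substrate control would take.

To fit a sensorgram end to end, simulate one (or read your own with
`read_sensorgram()`) and call the fitter; `print`, `summary`, `coef`,
`predict`, `residuals` and `plot` methods apply:

```r
phys <- list(k_on = 0.34, k_off = 1.8, kcat_tethered = 0.042,
             kcat_solution = 0.031, sigma_star = 210)   # PEG28-like truth
tr  <- simulate_sensorgram(phys, noise = noise_model(seed = 1))
fit <- fit_sensorgram(tr, spr_conditions(0.1, 100), n_steps = 1e4, seed = 1)
plot(fit); summary(fit)
ch  <- spr_mcmc(tr, spr_conditions(0.1, 100), fit)      # identifiability
```

The methods vignette (`vignettes/tethered-reactions.Rmd`) documents the
model equations, the optimization landscape and the design decisions in
detail.

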
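Package: tetherspr
Title: Tethered Enzyme Reaction Kinetics from Surface Plasmon Resonance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, fits and interprets surface plasmon resonance (SPR)
    sensorgrams of tethered enzymatic reactions, in which an enzyme recruited
    to a surface-anchored substrate acts on neighbouring substrates within its
    molecular reach. Provides a forward integrator for the multicenter
    particle density PDE (MPDPDE) model of binding, tethered catalysis and
    solution catalysis with nonspecific-drift extensions; an exact stochastic
    particle simulator used as ground truth; simulated-annealing parameter
    estimation with a least-squares polish; Metropolis-Hastings
    identifiability analysis with a quarter-wise Kolmogorov-Smirnov stopping
    rule; worm-like chain reach estimation from PEG-tether series by
    regression of squared reach on linker number; and analytic predictions of
    effective concentration and substrate coverage for receptor-enzyme
    complexes on cell membranes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, minpack.lm, stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
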
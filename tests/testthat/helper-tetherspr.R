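# shared fixtures, all built in code

# PEG28-construct physical constants (37C means)
peg28_physical <- function() {
  list(k_on = 0.34, k_off = 1.8, kcat_tethered = 0.042,
       kcat_solution = 0.031, sigma_star = 210)
}

std_conditions <- function() spr_conditions(shp1_conc = 0.1, peptide_conc = 100)

# short, fast synthetic experiment for solver-heavy tests: 15-s injection,
# 10-s dissociation, 5 Hz
quick_conditions <- function() {
  spr_conditions(shp1_conc = 0.1, peptide_conc = 100, injection_duration = 15)
}

quick_trace <- function(noise = noise_model(additive_sd = 0),
                        physical = peg28_physical()) {
  simulate_sensorgram(physical, quick_conditions(), noise,
                      amplitude = 500, p_start = 0.1)
}
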
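# Synthetic sensorgrams with known ground truth.  The generator is the
# package's stand-in for instrument data: no raw traces from the original
# SPR experiments are deposited anywhere, so every downstream stage
# (fitting, MCMC, reach regression) is validated on traces whose true
# parameters are known exactly.

#' Measurement-noise description for synthetic sensorgrams
#'
#' @param additive_sd standard deviation of i.i.d. Gaussian noise in signal
#'   units; \code{NULL} (default) means peak signal / 50, i.e. a peak
#'   signal-to-noise ratio of about 50, matching the visual noise level of
#'   published traces.
#' @param multiplicative_cv coefficient of variation of multiplicative
#'   Gaussian noise (signal * (1 + cv * eps)); default 0.
#' @param drift_n_ns linear nonspecific drift in signal units per second
#'   accruing during the injection; default 0.
#' @param sampling_rate samples per second (default 10).
#' @param seed integer seed for reproducible noise; \code{NULL} uses the
#'   current RNG stream.
#' @return an object of class \code{"noise_model"}.
#' @export
noise_model <- function(additive_sd = NULL, multiplicative_cv = 0,
                        drift_n_ns = 0, sampling_rate = 10, seed = NULL) {
  if (!is.null(additive_sd)) stopifnot(additive_sd >= 0)
  stopifnot(multiplicative_cv >= 0, sampling_rate > 0)
  structure(list(additive_sd = additive_sd,
                 multiplicative_cv = multiplicative_cv,
                 drift_n_ns = drift_n_ns, sampling_rate = sampling_rate,
                 seed = seed),
            class = "noise_model")
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic SPR sensorgram
#'
#' Forward-simulates the MPDPDE observable for known physical constants and
#' overlays measurement noise.  The trace covers a short pre-injection
#' baseline, the injection (association, reach-limited tethered decay,
#' solution-catalysis tail, optional linear drift) and the dissociation
#' phase after the injection ends.  The ground truth is attached to the
#' trace metadata, so no synthetic data set is ever separated from the
#' parameters that produced it.
#'
#' @param physical named list of physical constants as in [as_nondim()].
#' @param conditions an [spr_conditions()]; default 0.1 uM enzyme analyte
#'   over 100 uM immobilized peptide (a typical dextran-surface local
#'   concentration) with a 45-s injection.
#' @param noise a [noise_model()].
#' @param amplitude signal units per unit bound fraction (default 500,
#'   a typical immobilization level in RU).
#' @param p_start injection start time, s (default 0.1).
#' @param t_end trace end, s; default injection end + 20 s of dissociation.
#' @param grid,rtol,atol forwarded to [integrate_mpdpde()].
#' @return an [spr_trace()]; \code{attr(, "metadata")} holds
#'   \code{physical}, \code{params} (the true [nondim_params()]),
#'   \code{conditions} and \code{noise}.
#' @export
simulate_sensorgram <- function(physical,
                                conditions = spr_conditions(0.1, 100),
                                noise = noise_model(), amplitude = 500,
                                p_start = 0.1, t_end = NULL,
                                grid = radial_grid(), rtol = 1e-6,
                                atol = 1e-8) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(t_end)) t_end <- p_start + conditions$injection_duration + 20
  params <- as_nondim(physical, conditions, n_ns = noise$drift_n_ns,
                      p_start = p_start,
                      p_stop = p_start + conditions$injection_duration,
                      amplitude = amplitude)
  times <- seq(0, t_end, by = 1 / noise$sampling_rate)
  z <- .model_signal(params, times, grid, rtol, atol)
  sd_add <- if (is.null(noise$additive_sd)) max(z) / 50 else noise$additive_sd
  z_noisy <- with_seed(noise$seed, {
    out <- z
    if (noise$multiplicative_cv > 0)
      out <- out * (1 + noise$multiplicative_cv * rnorm(length(out)))
    if (sd_add > 0) out <- out + rnorm(length(out), sd = sd_add)
    out
  })
  spr_trace(times, z_noisy,
            metadata = list(physical = physical, params = params,
                            conditions = conditions, noise = noise,
                            additive_sd = sd_add, noiseless = z))
}

#' Fitted biophysical constants for each peptide construct
#'
#' Mean fitted parameters (with the replicate count and the standard error
#' of the mean for the local concentration) for the eight peptide
#' constructs characterised by the SPR assay: the PEG-linker series
#' (PEG0/3/6/12/28 repeats coupled to the PD-1 ITSM peptide, 37C), PEG28 at
#' 10C, and the full-length PD-1 (55 aa) and SLAM (69 aa) cytoplasmic-tail
#' peptides.  Units: k_on and both kcat in uM^-1 s^-1, k_off in s^-1, K_D
#' and sigma_star in uM, L in nm.
#'
#' @return data.frame with one row per construct.
#' @export
table2_params <- function() {
  data.frame(
    name = c("PEG0", "PEG3", "PEG6", "PEG12", "PEG28", "PEG28_10C",
             "PD1", "SLAM"),
    n_peg = c(0, 3, 6, 12, 28, 28, NA, NA),
    n_rep = c(3, 5, 6, 5, 14, 8, 3, 3),
    k_on = c(0.19, 0.22, 0.31, 0.25, 0.34, 0.28, 0.21, 0.02),
    k_off = c(1.9, 1.6, 1.5, 1.7, 1.8, 0.8, 2.4, 1.7),
    K_D = c(10.4, 8.0, 4.9, 7.2, 6.1, 2.9, 11.0, 130),
    K_D_se = c(0.2, 1.0, 0.3, 0.9, 0.8, 0.2, 2.0, 40),
    L = c(10.9, 13.4, 16.0, 16.0, 19.7, 12.0, 16.0, 31.2),
    sigma_star = c(1300, 690, 410, 400, 210, 960, 400, 55),
    sigma_star_se = c(100, 90, 77, 100, 40, 260, 100, 6),
    kcat_tethered = c(0.041, 0.047, 0.033, 0.034, 0.042, 0.0036, 0.040,
                      0.036),
    kcat_solution = c(0.020, 0.040, 0.027, 0.030, 0.031, 0.0047, 0.023,
                      0.0058),
    stringsAsFactors = FALSE)
}

# physical-constant list for one named construct
.table2_physical <- function(name) {
  tb <- table2_params()
  row <- tb[tb$name == name, ]
  if (nrow(row) != 1) stop("unknown construct: ", name)
  list(k_on = row$k_on, k_off = row$k_off,
       kcat_tethered = row$kcat_tethered,
       kcat_solution = row$kcat_solution, sigma_star = row$sigma_star)
}

#' Generate a synthetic PEG-series sigma* replicate table
#'
#' Draws replicate local-concentration values for a ladder of PEG tether
#' lengths under the linear squared-reach law
#' \eqn{L^2 = 4 N_{PEG} l_{PEG} l_p + L_{enzyme}^2}, with multiplicative
#' lognormal replicate scatter (keeping sigma* positive).
#'
#' @param L_enzyme true enzyme reach, nm.
#' @param l_p persistence length, nm (default 0.4).
#' @param l_peg contour length per PEG repeat, nm (default 0.4).
#' @param peg_lengths linker counts (default c(3, 6, 12, 28)).
#' @param replicates replicates per length.
#' @param noise_cv coefficient of variation of the replicate scatter.
#' @param seed integer seed.
#' @return data.frame (\code{n_peg}, \code{replicate}, \code{sigma_star});
#'   the true per-length sigma* values are attached as
#'   \code{attr(, "truth")}.
#' @export
simulate_peg_series <- function(L_enzyme = 13, l_p = 0.4, l_peg = 0.4,
                                peg_lengths = c(3, 6, 12, 28),
                                replicates = 5, noise_cv = 0.15,
                                seed = NULL) {
  stopifnot(L_enzyme > 0, replicates >= 1, noise_cv >= 0)
  L2 <- 4 * peg_lengths * l_peg * l_p + L_enzyme^2
  sigma_true <- sigma_star_from_reach(sqrt(L2))
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    d <- data.frame(
      n_peg = rep(peg_lengths, each = replicates),
      replicate = rep(seq_len(replicates), times = length(peg_lengths)),
      sigma_star = rep(sigma_true, each = replicates) *
        rlnorm(length(peg_lengths) * replicates,
               meanlog = -sdlog^2 / 2, sdlog = sdlog))
    attr(d, "truth") <- data.frame(n_peg = peg_lengths, L2 = L2,
                                   sigma_star = sigma_true)
    d
  })
}
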
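# Membrane-scale predictions: when enzyme-loaded receptors are scattered
# over a cell surface, how concentrated does the tethered enzyme appear to
# a substrate, and what fraction of substrates lie within reach at all?
# The cell surface is treated as a plane (cell radius >> molecular reach)
# carrying a homogeneous Poisson field of receptor-enzyme complexes.

#' Membrane scenario for tethered-reaction predictions
#'
#' @param rho0 receptor-enzyme surface density, nm^-2.
#' @param L_receptor,L_enzyme,L_substrate component reaches, nm; combined
#'   in quadrature into the reaction reach.
#' @param cytosolic_conc reference cytosolic enzyme concentration, uM
#'   (default 1, for comparison with the effective concentration).
#' @return object of class \code{"membrane_scenario"} with the derived
#'   \code{L_rxn}.
#' @export
membrane_scenario <- function(rho0, L_receptor = 6.55, L_enzyme = 13,
                              L_substrate = 0, cytosolic_conc = 1) {
  stopifnot(rho0 >= 0, L_receptor >= 0, L_enzyme >= 0, L_substrate >= 0)
  structure(list(rho0 = rho0, L_receptor = L_receptor, L_enzyme = L_enzyme,
                 L_substrate = L_substrate,
                 L_rxn = combine_reach(c(L_receptor, L_enzyme, L_substrate)),
                 cytosolic_conc = cytosolic_conc),
            class = "membrane_scenario")
}

#' Receptor surface density from copy number
#'
#' Copies spread uniformly over a spherical cell: density = copies / (4 pi r^2).
#'
#' @param copies receptor copies per cell.
#' @param cell_radius cell radius in nm (default 5000, a T cell).
#' @return density in nm^-2.
#' @examples
#' density_from_copy_number(80000)  # ~2.5e-4 nm^-2
#' @export
density_from_copy_number <- function(copies, cell_radius = 5000) {
  stopifnot(copies >= 0, cell_radius > 0)
  copies / (4 * pi * cell_radius^2)
}

#' Effective enzyme concentration at a membrane substrate
#'
#' Planar integral of the reach kernel over the receptor field,
#' \eqn{C_{eff} = \int\!\!\int \sigma(r)\, \rho_0\, dA
#'      = \sqrt{3/(2\pi)}\, \rho_0 / L_{rxn}}
#' (closed form of the 2D Gaussian integral), converted to uM.
#'
#' @param scenario a [membrane_scenario()] with \code{L_rxn > 0}.
#' @return effective concentration in uM.
#' @export
effective_concentration <- function(scenario) {
  stopifnot(inherits(scenario, "membrane_scenario"))
  if (scenario$L_rxn <= 0) stop("reaction reach must be positive")
  nm3_to_um(sqrt(3 / (2 * pi)) * scenario$rho0 / scenario$L_rxn)
}

#' Fraction of substrates within reach of a receptor-enzyme complex
#'
#' With receptors Poisson-distributed on the plane, the number within a
#' disk of radius \eqn{L_{rxn}} around a substrate is Poisson with mean
#' \eqn{\lambda = \pi \rho_0 L_{rxn}^2}, so the coverage probability is
#' \eqn{P_{\ge 1} = 1 - e^{-\pi \rho_0 L_{rxn}^2}}.
#'
#' @param scenario a [membrane_scenario()].
#' @return probability in [0, 1].
#' @examples
#' sc <- membrane_scenario(density_from_copy_number(80000))
#' coverage_probability(sc)  # ~0.15
#' @export
coverage_probability <- function(scenario) {
  stopifnot(inherits(scenario, "membrane_scenario"))
  1 - exp(-pi * scenario$rho0 * scenario$L_rxn^2)
}

#' Receptor density required for a target coverage
#'
#' Exact inverse of [coverage_probability()]:
#' \eqn{\rho_0 = -\ln(1 - target) / (\pi L_{rxn}^2)}.
#'
#' @param target coverage fraction in (0, 1).
#' @param L_rxn reaction reach, nm.
#' @return density in nm^-2.
#' @examples
#' density_for_coverage(0.9, 14.6)  # ~0.0034 nm^-2
#' @export
density_for_coverage <- function(target, L_rxn) {
  if (!is.numeric(target) || any(target <= 0) || any(target >= 1))
    stop("target coverage must lie strictly between 0 and 1")
  stopifnot(L_rxn > 0)
  -log(1 - target) / (pi * L_rxn^2)
}
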
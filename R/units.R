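# Unit dictionary shared by every module: lengths in nm, times in s,
# concentrations in uM.  Conversions happen here and nowhere else.

# 1 uM expressed as molecules per nm^3 (2019 SI Avogadro constant):
# 1e-6 mol/L * 6.02214076e23 / (1e24 nm^3/L) = 6.02214076e-7 nm^-3
.UM_PER_NM3 <- 6.02214076e-7

#' Effective local concentration from molecular reach
#'
#' The effective (local) concentration experienced between two co-anchored
#' sites whose reaction has molecular reach \code{L} is \eqn{\sigma^* = 1/L^3},
#' converted from molecules per cubic nanometre to micromolar.
#'
#' @param L molecular reach in nm (positive).
#' @return local concentration \eqn{\sigma^*} in \eqn{\mu}M.
#' @examples
#' sigma_star_from_reach(14.5)  # ~544.6 uM
#' @export
sigma_star_from_reach <- function(L) {
  stopifnot(is.numeric(L))
  if (any(!is.finite(L)) || any(L <= 0))
    stop("molecular reach L must be positive and finite")
  (1 / L^3) / .UM_PER_NM3
}

#' Molecular reach from effective local concentration
#'
#' Inverse of [sigma_star_from_reach()]: \eqn{L = (\sigma^*)^{-1/3}} with
#' \eqn{\sigma^*} first converted from \eqn{\mu}M to nm\eqn{^{-3}}.
#'
#' @param sigma_star local concentration in \eqn{\mu}M (positive).
#' @return molecular reach in nm.
#' @examples
#' reach_from_sigma_star(544.6)  # ~14.5 nm
#' reach_from_sigma_star(400)    # ~16 nm
#' @export
reach_from_sigma_star <- function(sigma_star) {
  stopifnot(is.numeric(sigma_star))
  if (any(!is.finite(sigma_star)) || any(sigma_star <= 0))
    stop("local concentration sigma* must be positive and finite")
  (sigma_star * .UM_PER_NM3)^(-1 / 3)
}

#' Gaussian reach kernel
#'
#' Probability density (per nm^3) that a tethered catalytic site is found at
#' separation \code{r} from its anchor, for a reaction of molecular reach
#' \code{L}:
#' \deqn{\sigma(r) = \left(\frac{3}{2\pi L^2}\right)^{3/2}
#'       \exp\left(-\frac{3 r^2}{2 L^2}\right).}
#' The kernel integrates to 1 over three-dimensional space; its integral over
#' the two-dimensional plane through the anchor is \eqn{(3/(2\pi))^{1/2}/L}.
#'
#' @param r separation(s) in nm, non-negative.
#' @param L molecular reach in nm (positive scalar).
#' @return local density in nm^-3 at each \code{r}.
#' @export
reach_kernel <- function(r, L) {
  stopifnot(is.numeric(r), is.numeric(L), length(L) == 1)
  if (any(r < 0)) stop("separation r must be non-negative")
  if (!is.finite(L) || L <= 0) stop("molecular reach L must be positive")
  (3 / (2 * pi * L^2))^1.5 * exp(-1.5 * r^2 / L^2)
}

#' Tether description for worm-like chain reach estimates
#'
#' @param n_units number of chain units (PEG linkers or amino acids),
#'   non-negative integer.
#' @param unit_length contour length per unit in nm (default 0.4, appropriate
#'   both for a PEG repeat and for an amino acid).
#' @param persistence_length persistence length in nm (default 0.4, the value
#'   for random amino-acid chains).
#' @param convention either \code{"wlc_sqrt_lclp"} (\eqn{L = \sqrt{l_c l_p}})
#'   or \code{"wlc_sqrt_2lclp"} (\eqn{L = \sqrt{2 l_c l_p}}).  Both forms are
#'   in circulation for the worm-like chain end-to-end scale; predictions for
#'   receptor tails conventionally use the first, while the PEG-series
#'   regression slope encodes the factor-4 form (see [peg_reach_fit()]).
#' @return an object of class \code{"tether_spec"}.
#' @export
tether_spec <- function(n_units, unit_length = 0.4, persistence_length = 0.4,
                        convention = c("wlc_sqrt_lclp", "wlc_sqrt_2lclp")) {
  convention <- match.arg(convention)
  stopifnot(length(n_units) == 1, n_units >= 0, n_units == round(n_units),
            unit_length > 0, persistence_length > 0)
  structure(list(n_units = as.integer(n_units), unit_length = unit_length,
                 persistence_length = persistence_length,
                 convention = convention,
                 contour_length = n_units * unit_length),
            class = "tether_spec")
}

#' Worm-like chain reach of a tether
#'
#' Predicted molecular reach of a flexible tether from its contour length
#' \eqn{l_c = n \cdot l_{unit}} and persistence length \eqn{l_p}, under the
#' convention stored in the [tether_spec()].
#'
#' @param tether a [tether_spec()] object.
#' @return reach in nm; 0 (with a warning) for a degenerate zero-length tether.
#' @examples
#' wlc_reach(tether_spec(55))  # 55-aa receptor tail: ~3.0 nm
#' @export
wlc_reach <- function(tether) {
  stopifnot(inherits(tether, "tether_spec"))
  if (tether$n_units == 0) {
    warning("degenerate tether with 0 units: reach is 0")
    return(0)
  }
  lc <- tether$contour_length
  lp <- tether$persistence_length
  switch(tether$convention,
         wlc_sqrt_lclp = sqrt(lc * lp),
         wlc_sqrt_2lclp = sqrt(2 * lc * lp))
}

#' Structure-based reference reaches for SHP-1
#'
#' Documented reference values for the reach of the SHP-1 phosphatase
#' measured on its crystal structure (distance from the SH2 anchor to the
#' catalytic pocket in the closed conformation) and at maximal stretch of the
#' inter-domain linkers.  These bracket the functional reach determined
#' experimentally by the PEG-series intercept (about 13 nm).
#'
#' @return named numeric vector, nm: \code{crystal} = 5.3, \code{stretch} = 20.4.
#' @export
shp1_reference_reach <- function() {
  c(crystal = 5.3, stretch = 20.4)
}

# internal: uM <-> nm^-3
um_to_nm3 <- function(x) x * .UM_PER_NM3
nm3_to_um <- function(x) x / .UM_PER_NM3
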
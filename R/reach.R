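# From fitted local concentrations to molecular reach: per-tether averaging
# with delta-method errors, the PEG-series regression isolating the enzyme
# reach, and the quadrature rules for parsing and combining component
# reaches.
#
# Geometry: in the SPR assay both the acting enzyme's anchor and the target
# site sit on tethers, so the reaction reach obeys
# L^2 = L_tether^2 + L_tether^2 + L_enzyme^2 (two tether contributions plus
# the enzyme, added in quadrature).  With worm-like chain tethers of
# contour length N_PEG * l_PEG this gives the linear law
# L^2 = 4 * N_PEG * l_PEG * l_p + L_enzyme^2, whose vertical intercept is
# the squared enzyme reach.

#' Per-tether reach table from sigma* replicates
#'
#' Averages replicate local concentrations per tether length and transforms
#' the average to a single squared reach, with the standard deviation of
#' sigma* propagated to L^2 by the delta method:
#' \eqn{err(L^2) = (2/3) (L^2/\sigma^*) \, sd(\sigma^*)}.
#'
#' @param data data.frame with columns \code{n_peg} and \code{sigma_star}
#'   (uM), one row per replicate (as produced by [simulate_peg_series()]).
#' @return data.frame with one row per tether length: \code{n_peg},
#'   \code{sigma_star_mean}, \code{sigma_star_sd}, \code{n_replicates},
#'   \code{L}, \code{L_squared}, \code{L_squared_err}.  Rows with
#'   non-positive mean sigma* are dropped with a warning.
#' @export
reach_table <- function(data) {
  stopifnot(all(c("n_peg", "sigma_star") %in% names(data)))
  sp <- split(data$sigma_star, data$n_peg)
  rows <- lapply(names(sp), function(k) {
    x <- sp[[k]]
    data.frame(n_peg = as.numeric(k), sigma_star_mean = mean(x),
               sigma_star_sd = if (length(x) > 1) sd(x) else 0,
               n_replicates = length(x))
  })
  tab <- do.call(rbind, rows)
  bad <- tab$sigma_star_mean <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with non-positive mean sigma*")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab <- tab[order(tab$n_peg), , drop = FALSE]
  tab$L <- reach_from_sigma_star(tab$sigma_star_mean)
  tab$L_squared <- tab$L^2
  tab$L_squared_err <- (2 / 3) * tab$L_squared / tab$sigma_star_mean *
    tab$sigma_star_sd
  rownames(tab) <- NULL
  tab
}

#' Enzyme reach by regression of squared reach on PEG linker number
#'
#' Ordinary least squares of \eqn{L^2} on \eqn{N_{PEG}}; under the
#' worm-like chain law the intercept is the squared enzyme reach and the
#' slope estimates \eqn{4 l_{PEG} l_p}.  The zero-linker construct is
#' excluded by default: directly coupled peptides suffer steric hindrance
#' at the surface and bias the line.
#'
#' @param table output of [reach_table()] (or any data.frame with
#'   \code{n_peg}, \code{L_squared}, optionally \code{L_squared_err}).
#' @param exclude linker counts to drop (default 0).
#' @param weighted use weights 1/L_squared_err^2 (default FALSE,
#'   plain OLS).
#' @return object of class \code{"peg_fit"}: \code{L_enzyme} (nm),
#'   \code{L_enzyme_se} (delta method from the intercept SE),
#'   \code{intercept}, \code{slope} with SEs, \code{r_squared},
#'   \code{p_value} (slope), and the underlying \code{lm} fit.
#' @export
peg_reach_fit <- function(table, exclude = 0, weighted = FALSE) {
  stopifnot(all(c("n_peg", "L_squared") %in% names(table)))
  d <- table[!(table$n_peg %in% exclude), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 tether lengths after exclusion")
  w <- if (weighted) {
    if (is.null(d$L_squared_err) || any(d$L_squared_err <= 0))
      stop("weighted fit needs positive L_squared_err")
    1 / d$L_squared_err^2
  } else NULL
  fit <- lm(L_squared ~ n_peg, data = d, weights = w)
  sm <- suppressWarnings(summary(fit))  # exact synthetic lines are legitimate
  ic <- sm$coefficients["(Intercept)", ]
  sl <- sm$coefficients["n_peg", ]
  if (ic[["Estimate"]] <= 0)
    stop("negative intercept: no real enzyme reach; slope = ",
         signif(sl[["Estimate"]], 3), ", intercept = ",
         signif(ic[["Estimate"]], 3))
  L_enz <- sqrt(ic[["Estimate"]])
  structure(list(L_enzyme = L_enz,
                 L_enzyme_se = ic[["Std. Error"]] / (2 * L_enz),
                 intercept = ic[["Estimate"]],
                 intercept_se = ic[["Std. Error"]],
                 slope = sl[["Estimate"]], slope_se = sl[["Std. Error"]],
                 r_squared = sm$r.squared,
                 p_value = sl[["Pr(>|t|)"]],
                 excluded = exclude, weighted = weighted,
                 data = d, lm = fit),
            class = "peg_fit")
}

#' @export
print.peg_fit <- function(x, ...) {
  cat(sprintf("PEG-series reach regression (%d tether lengths%s)\n",
              nrow(x$data),
              if (length(x$excluded)) paste0(", excluding N_PEG = ",
                                             paste(x$excluded, collapse = ","))
              else ""))
  cat(sprintf("  L^2 = %.3g + %.3g x N_PEG   (R^2 = %.3f, slope p = %.2g)\n",
              x$intercept, x$slope, x$r_squared, x$p_value))
  cat(sprintf("  enzyme reach L = %.3g +/- %.2g nm\n",
              x$L_enzyme, x$L_enzyme_se))
  invisible(x)
}

#' @export
summary.peg_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.peg_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope,
    L_enzyme = object$L_enzyme)
}

#' @export
predict.peg_fit <- function(object, n_peg = NULL, ...) {
  if (is.null(n_peg)) n_peg <- object$data$n_peg
  unname(predict(object$lm, newdata = data.frame(n_peg = n_peg)))
}

#' @export
plot.peg_fit <- function(x, ...) {
  d <- x$data
  plot(d$n_peg, d$L_squared, pch = 16, xlab = "number of PEG linkers",
       ylab = expression(L^2 ~ (nm^2)), xlim = c(0, max(d$n_peg) * 1.05), ...)
  if (!is.null(d$L_squared_err))
    arrows(d$n_peg, d$L_squared - d$L_squared_err,
           d$n_peg, d$L_squared + d$L_squared_err,
           angle = 90, code = 3, length = 0.03)
  abline(x$lm, col = "red", lty = 2)
  mtext(sprintf("intercept^1/2 = %.1f nm", x$L_enzyme), side = 3, adj = 1)
  invisible(x)
}

#' Parse a single tether's reach out of the reaction reach
#'
#' In the SPR geometry two identical tethers and the enzyme contribute in
#' quadrature, so the tether (receptor-tail) reach is
#' \eqn{L_{tether} = \sqrt{(L^2 - L_{enzyme}^2)/2}}.
#'
#' @param L_rxn reaction reach, nm.
#' @param L_enzyme enzyme reach, nm (must be smaller than \code{L_rxn}).
#' @return tether reach in nm.
#' @examples
#' parse_tether_reach(16, 13)    # PD-1 tail: ~6.6 nm
#' parse_tether_reach(31.2, 13)  # SLAM tail: ~20 nm
#' @export
parse_tether_reach <- function(L_rxn, L_enzyme) {
  stopifnot(L_rxn > 0, L_enzyme >= 0)
  if (L_rxn <= L_enzyme)
    stop("reaction reach (", L_rxn, " nm) must exceed enzyme reach (",
         L_enzyme, " nm); tether contribution undefined")
  sqrt((L_rxn^2 - L_enzyme^2) / 2)
}

#' Combine component reaches in quadrature
#'
#' Component reaches add as a root sum of squares, each counted with its
#' multiplicity: two tethers plus one enzyme in the SPR geometry, or
#' receptor + enzyme + substrate on a membrane.
#'
#' @param components component reaches, nm (non-negative).
#' @param multiplicities integer multiplicities (default all 1).
#' @return combined reach in nm.
#' @examples
#' combine_reach(c(6.55, 13))  # receptor-enzyme complex: ~14.6 nm
#' @export
combine_reach <- function(components, multiplicities = rep(1, length(components))) {
  stopifnot(all(components >= 0), all(multiplicities >= 0),
            length(components) == length(multiplicities))
  sqrt(sum(multiplicities * components^2))
}
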
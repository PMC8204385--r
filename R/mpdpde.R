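# Forward model: the extended multicenter particle density PDE (MPDPDE)
# for tethered dephosphorylation in an SPR flow cell.
#
# Nondimensional state: nA (free phosphorylated sites), nB (enzyme-bound
# phosphorylated sites), and radial correlation functions Y (A-B pair),
# XA (A-A), XB (B-B) on separations r expressed in units of the molecular
# reach L.  Rates: p1 = k_on*[enzyme], p2 = k_off, p3 = kcat_tethered*[peptide],
# p4 = kcat_tethered*sigma*, p5 = kcat_solution*[enzyme].

.CPRE <- (3 / (2 * pi))^1.5  # kernel prefactor (3/(2*pi))^(3/2)

#' Uniform radial grid for the MPDPDE correlation functions
#'
#' Separations are nondimensional (units of the molecular reach L), on
#' uniform nodes \eqn{r_k = k \Delta r}, \eqn{k = 1 \dots n}.  The Gaussian
#' kernel mass beyond \code{r_max = 5} is below 1e-8, so truncation at the
#' default 6 is numerically exact.
#'
#' @param n_nodes number of radial nodes (>= 64).
#' @param r_max truncation radius in units of L (>= 5).
#' @return an object of class \code{"radial_grid"}.
#' @export
radial_grid <- function(n_nodes = 64L, r_max = 6) {
  stopifnot(n_nodes >= 64, r_max >= 5)
  n <- as.integer(n_nodes)
  r <- seq(r_max / n, r_max, length.out = n)
  dr <- r_max / n
  w <- rep(dr, n)
  w[c(1L, n)] <- dr / 2
  structure(list(n = n, r = r, dr = dr, r_max = r_max, w = w,
                 kern = exp(-1.5 * r^2)),
            class = "radial_grid")
}

#' Nondimensional MPDPDE parameters
#'
#' The five kinetic rates of the tethered-reaction model plus the nuisance
#' terms of the extended observable: linear nonspecific drift \code{n_ns}
#' (signal units per second, accruing between injection start and stop),
#' injection start/stop times \code{p_start} and \code{p_stop} (s), and the
#' \code{amplitude} mapping the nondimensional bound fraction nB to
#' instrument response units.
#'
#' @param p1 binding rate k_on*[enzyme], 1/s.
#' @param p2 unbinding rate k_off, 1/s.
#' @param p3 tethered catalysis rate kcat_tethered*[peptide], 1/s.
#' @param p4 proximal catalysis rate kcat_tethered*sigma*, 1/s.
#' @param p5 solution catalysis rate kcat_solution*[enzyme], 1/s.
#' @param n_ns nonspecific drift, signal/s.
#' @param p_start injection start, s.
#' @param p_stop injection end, s (> p_start).
#' @param amplitude signal units per unit nB.
#' @return an object of class \code{"nondim_params"}.
#' @export
nondim_params <- function(p1, p2, p3, p4, p5, n_ns = 0, p_start = 0,
                          p_stop = 45, amplitude = 1) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5)
  if (any(!is.finite(p)) || any(p < 0))
    stop("rates p1..p5 must be finite and non-negative")
  if (p_start < 0) stop("p_start must be non-negative")
  if (p_stop <= p_start) stop("p_stop must exceed p_start")
  if (amplitude <= 0) stop("amplitude must be positive")
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, n_ns = n_ns,
                 p_start = p_start, p_stop = p_stop, amplitude = amplitude),
            class = "nondim_params")
}

#' Experimental conditions of an SPR injection
#'
#' @param shp1_conc analyte (enzyme) concentration, uM.
#' @param peptide_conc immobilized peptide concentration, uM.
#' @param injection_duration s (default 45).
#' @param temperature free-text label.
#' @return an object of class \code{"spr_conditions"}.
#' @export
spr_conditions <- function(shp1_conc, peptide_conc, injection_duration = 45,
                           temperature = "37C") {
  stopifnot(shp1_conc > 0, peptide_conc > 0, injection_duration > 0)
  structure(list(shp1_conc = shp1_conc, peptide_conc = peptide_conc,
                 injection_duration = injection_duration,
                 temperature = temperature),
            class = "spr_conditions")
}

#' Map physical constants to nondimensional rates
#'
#' Applies the parameter dictionary p1 = k_on*[enzyme], p2 = k_off,
#' p3 = kcat_tethered*[peptide], p4 = kcat_tethered*sigma*,
#' p5 = kcat_solution*[enzyme].
#'
#' @param physical named list or vector with \code{k_on} (uM^-1 s^-1),
#'   \code{k_off} (s^-1), \code{kcat_tethered} (uM^-1 s^-1),
#'   \code{kcat_solution} (uM^-1 s^-1), \code{sigma_star} (uM).
#' @param conditions an [spr_conditions()] object.
#' @param ... passed to [nondim_params()] (\code{n_ns}, \code{p_start},
#'   \code{p_stop}, \code{amplitude}).
#' @return a [nondim_params()] object.
#' @export
as_nondim <- function(physical, conditions, ...) {
  ph <- as.list(physical)
  need <- c("k_on", "k_off", "kcat_tethered", "kcat_solution", "sigma_star")
  if (!all(need %in% names(ph)))
    stop("physical constants must include: ", paste(need, collapse = ", "))
  nondim_params(p1 = ph$k_on * conditions$shp1_conc,
                p2 = ph$k_off,
                p3 = ph$kcat_tethered * conditions$peptide_conc,
                p4 = ph$kcat_tethered * ph$sigma_star,
                p5 = ph$kcat_solution * conditions$shp1_conc,
                ...)
}

#' Map nondimensional rates back to physical constants
#'
#' Inverts the parameter dictionary given the experiment's concentrations and
#' derives K_D = k_off/k_on and the molecular reach L = (sigma*)^(-1/3).
#'
#' @param params a [nondim_params()] object.
#' @param conditions an [spr_conditions()] object.
#' @return named list: \code{k_on}, \code{k_off}, \code{K_D},
#'   \code{kcat_tethered}, \code{kcat_solution}, \code{sigma_star} (uM),
#'   \code{L} (nm).  \code{sigma_star} and \code{L} are \code{NA} when
#'   p3 = 0 (no tethered catalysis: the reach is unidentifiable).
#' @export
as_physical <- function(params, conditions) {
  kcat_t <- params$p3 / conditions$peptide_conc
  if (params$p3 > 0) {
    sigma_star <- params$p4 / kcat_t
    L <- if (sigma_star > 0) reach_from_sigma_star(sigma_star) else NA_real_
  } else {
    sigma_star <- NA_real_
    L <- NA_real_
  }
  k_on <- params$p1 / conditions$shp1_conc
  list(k_on = k_on, k_off = params$p2,
       K_D = params$p2 / k_on,
       kcat_tethered = kcat_t,
       kcat_solution = params$p5 / conditions$shp1_conc,
       sigma_star = sigma_star, L = L)
}

#' MPDPDE right-hand side (reference implementation)
#'
#' Time derivative of the full field state.  This pure-R version is the
#' readable reference; [integrate_mpdpde()] uses an equivalent compiled
#' routine (the two are cross-checked in the test suite).
#'
#' The five equations comprise (a) mean densities nA, nB with the catalytic
#' sink \eqn{-4\pi (3/(2\pi))^{3/2} p_3 n_A n_B \int r'^2 e^{-3r'^2/2} Y\,dr'}
#' (which reduces to \eqn{-p_3 n_A n_B} when Y = 1); (b) the proximal sink
#' \eqn{-(3/(2\pi))^{3/2} p_4 e^{-3r^2/2} Y} in the Y equation; and (c)
#' bipolar double integrals
#' \eqn{\int dr' \int_{|r-r'|}^{r+r'} dq\, q r' e^{-3r'^2/2} Y(r')(X(q)-1)}
#' coupling Y and XA to the correlation field.  Density ratios nB/nA and
#' nA/nB are floored (denominator 1e-12, term zeroed below it).
#'
#' @param state list with \code{nA}, \code{nB} (scalars) and \code{Y},
#'   \code{XA}, \code{XB} (length-n vectors on \code{grid$r}).
#' @param params a [nondim_params()] object (only p1..p5 enter).
#' @param grid a [radial_grid()].
#' @return list of the same shape holding time derivatives.
#' @export
mpdpde_rhs <- function(state, params, grid) {
  n <- grid$n
  stopifnot(length(state$Y) == n, length(state$XA) == n, length(state$XB) == n)
  nA <- state$nA; nB <- state$nB
  Y <- state$Y; XA <- state$XA; XB <- state$XB
  rAB <- if (nA > 1e-12) nB / nA else 0
  rBA <- if (nB > 1e-12) nA / nB else 0
  I1 <- sum(grid$w * grid$r^2 * grid$kern * Y)
  dnA <- -(params$p1 + params$p5) * nA + params$p2 * nB -
    4 * pi * .CPRE * params$p3 * nA * nB * I1
  dnB <- params$p1 * nA - params$p2 * nB
  # cumulative trapezoid of s*(X(s)-1) from s = 0 over nodes c(0, r)
  ctz <- function(X) {
    f <- c(0, grid$r * (X - 1))
    cumsum(c(0, (f[-1] + f[-(n + 1)]) / 2 * grid$dr))
  }
  GY <- ctz(Y); GXB <- ctz(XB)
  # bipolar limits r_i + r_j and |r_i - r_j| fall exactly on grid nodes
  iu <- pmin(outer(seq_len(n), seq_len(n), `+`), n) + 1L
  il <- abs(outer(seq_len(n), seq_len(n), `-`)) + 1L
  fY <- grid$w * grid$r * grid$kern * Y
  JXB <- as.vector(matrix(GXB[iu] - GXB[il], n, n) %*% fY)
  JY <- as.vector(matrix(GY[iu] - GY[il], n, n) %*% fY)
  dY <- params$p1 * rBA * (XA - Y) + params$p2 * rAB * (XB - Y) -
    .CPRE * params$p4 * grid$kern * Y -
    2 * pi * .CPRE * params$p3 * nB * Y / grid$r * JXB
  dXA <- 2 * params$p2 * rAB * (Y - XA) -
    4 * pi * .CPRE * params$p3 * nB * XA / grid$r * JY
  dXB <- 2 * params$p1 * rBA * (Y - XB)
  list(nA = dnA, nB = dnB, Y = dY, XA = dXA, XB = dXB)
}

# pack parameters + grid for the compiled derivs
.pack_parms <- function(p15, grid) {
  c(grid$n, grid$dr, .CPRE, p15, grid$r, grid$w, grid$kern)
}

# y0 and state (de)flattening
.y0 <- function(grid) c(1, 0, rep(1, 3 * grid$n))

# one integration phase at fixed rates; times must start at the phase origin
.ode_phase <- function(y0, times, p15, grid, rtol, atol, compiled,
                       maxsteps = 5000) {
  if (compiled) {
    .Call("C_set_mpdpde_parms", as.double(.pack_parms(p15, grid)),
          PACKAGE = "tetherspr")
    deSolve::ode(y = y0, times = times, func = "mpdpde_derivs",
                 parms = NULL, dllname = "tetherspr", method = "adams",
                 rtol = rtol, atol = atol, maxsteps = maxsteps)
  } else {
    n <- grid$n
    f <- function(t, y, parms) {
      st <- list(nA = y[1], nB = y[2], Y = y[3:(2 + n)],
                 XA = y[(3 + n):(2 + 2 * n)], XB = y[(3 + 2 * n):(2 + 3 * n)])
      pr <- list(p1 = p15[1], p2 = p15[2], p3 = p15[3], p4 = p15[4],
                 p5 = p15[5])
      d <- mpdpde_rhs(st, pr, grid)
      list(c(d$nA, d$nB, d$Y, d$XA, d$XB))
    }
    deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                 method = "adams", rtol = rtol, atol = atol)
  }
}

#' Integrate the MPDPDE forward in time
#'
#' Error-controlled integration from the pristine initial state
#' (nA = 1, nB = 0, Y = XA = XB = 1) on the PDE clock, whose origin is the
#' injection start.  At \code{p_stop - p_start} the analyte input is switched
#' off (p1 = p5 = 0) to model the dissociation phase; the integration is
#' split into the two phases at that instant.
#'
#' @param params a [nondim_params()] object.
#' @param grid a [radial_grid()].
#' @param times requested output times on the PDE clock (s, non-negative,
#'   increasing).
#' @param rtol,atol solver tolerances (defaults 1e-6, 1e-8).
#' @param compiled use the compiled right-hand side (default) or the pure-R
#'   reference implementation.
#' @param maxsteps solver work cap per output interval; exceeding it raises
#'   an error (during fitting this rejects pathologically stiff proposals
#'   quickly instead of grinding through them).
#' @return list with \code{time}, \code{nA}, \code{nB} (vectors) and
#'   \code{Y}, \code{XA}, \code{XB} (time-by-node matrices).
#' @export
integrate_mpdpde <- function(params, grid = radial_grid(), times,
                             rtol = 1e-6, atol = 1e-8, compiled = TRUE,
                             maxsteps = 5000) {
  stopifnot(inherits(params, "nondim_params"), inherits(grid, "radial_grid"))
  times <- as.double(times)
  if (length(times) < 1 || any(diff(times) <= 0) || times[1] < 0)
    stop("times must be non-negative and strictly increasing")
  tau_stop <- params$p_stop - params$p_start
  p15 <- c(params$p1, params$p2, params$p3, params$p4, params$p5)
  n <- grid$n

  run <- function(y0, tt, p) {
    out <- suppressWarnings(
      .ode_phase(y0, tt, p, grid, rtol, atol, compiled, maxsteps))
    if (attr(out, "istate")[1] < 0 || nrow(out) < length(tt))
      stop("MPDPDE solver failed; last valid time ",
           signif(out[nrow(out), 1], 6), " s")
    out
  }

  dedup <- function(tt) tt[c(TRUE, diff(tt) > 1e-9)]
  if (all(times <= tau_stop)) {
    tt <- dedup(if (times[1] > 0) c(0, times) else times)
    out <- run(.y0(grid), tt, p15)
  } else {
    t1 <- times[times < tau_stop]
    tt1 <- dedup(sort(unique(c(0, t1, tau_stop))))
    out1 <- run(.y0(grid), tt1, p15)
    y_sw <- out1[nrow(out1), -1]
    t2 <- times[times >= tau_stop]
    tt2 <- dedup(sort(unique(c(tau_stop, t2))))
    p15b <- p15; p15b[c(1, 5)] <- 0  # injection over: p1 = p5 = 0
    out2 <- run(y_sw, tt2, p15b)
    out <- rbind(out1, out2[-1, , drop = FALSE])
  }
  keep <- vapply(times, function(t) which.min(abs(out[, 1] - t)), 1L)
  out <- out[keep, , drop = FALSE]
  list(time = out[, 1], nA = out[, 2], nB = out[, 3],
       Y = out[, 4:(3 + n), drop = FALSE],
       XA = out[, (4 + n):(3 + 2 * n), drop = FALSE],
       XB = out[, (4 + 2 * n):(3 + 3 * n), drop = FALSE])
}

#' Model-predicted sensorgram
#'
#' The piecewise observable fitted to SPR traces: zero before injection
#' start, bound signal plus linear nonspecific drift during the injection,
#' and bound signal alone afterwards,
#' \deqn{Z(t) = 0,\; t < p_{start};\quad
#'   Z(t) = n_{ns}(t - p_{start}) + A\, n_B(t - p_{start}),\;
#'   p_{start} \le t \le p_{stop};\quad
#'   Z(t) = A\, n_B(t - p_{start}),\; t > p_{stop}.}
#' The drift ramps from zero at injection start and, like the piecewise form
#' it mirrors, vanishes when the buffer wash resumes.
#'
#' @param traj output of [integrate_mpdpde()].
#' @param params the [nondim_params()] used to produce \code{traj}.
#' @param times absolute experiment times (s) at which to evaluate Z;
#'   defaults to \code{traj$time + p_start}.
#' @return data.frame of class \code{"spr_trace"} with columns \code{time},
#'   \code{signal}.
#' @export
spr_observable <- function(traj, params, times = NULL) {
  if (is.null(times)) times <- traj$time + params$p_start
  tau <- times - params$p_start
  nB <- approx(traj$time, traj$nB, xout = pmax(tau, 0), rule = 2)$y
  z <- params$amplitude * nB
  z[tau < 0] <- 0
  during <- tau >= 0 & times <= params$p_stop
  z[during] <- z[during] + params$n_ns * tau[during]
  spr_trace(times, z)
}

# internal one-call forward model: absolute times -> predicted signal vector
.model_signal <- function(params, times, grid, rtol = 1e-6, atol = 1e-8,
                          compiled = TRUE, maxsteps = 5000) {
  tau <- sort(unique(c(0, pmax(times - params$p_start, 0))))
  traj <- integrate_mpdpde(params, grid, tau, rtol, atol, compiled, maxsteps)
  spr_observable(traj, params, times)$signal
}

# fixed-step RK4 forward model used by the fitting stack: the fixed grid
# makes the signal a smooth function of the parameters, so numerical
# Jacobians in the polish are clean; dt = 0.05 s keeps the discretization
# error far below instrument noise at the rates of interest
.model_signal_rk4 <- function(params, times, grid, dt = 0.05,
                              coarse = FALSE) {
  tau <- pmax(times - params$p_start, 0)
  p15 <- c(params$p1, params$p2, params$p3, params$p4, params$p5)
  .Call("C_set_mpdpde_parms", as.double(.pack_parms(p15, grid)),
        PACKAGE = "tetherspr")
  tswitch <- params$p_stop - params$p_start
  if (coarse) {
    # integrate on a grid of dt steps (refined near the injection start
    # and stop, where the bound fraction is strongly curved) and
    # interpolate; the interpolation error stays far below noise and the
    # output remains smooth in the parameters
    fine <- dt / 5
    t_hi <- max(tau) + dt
    tau_u <- sort(unique(c(
      seq(0, min(4, t_hi), by = fine),                      # association rise
      seq(tswitch, min(tswitch + 2, t_hi), by = fine),      # dissociation drop
      seq(0, t_hi, by = dt), tswitch)))
    nm <- .Call("C_mpdpde_rk4", as.double(tau_u), as.double(dt),
                as.double(tswitch), PACKAGE = "tetherspr")
    nB <- approx(tau_u, nm[, 2], xout = tau)$y
  } else {
    tau_u <- sort(unique(c(0, tau)))
    nm <- .Call("C_mpdpde_rk4", as.double(tau_u), as.double(dt),
                as.double(tswitch), PACKAGE = "tetherspr")
    nB <- nm[match(tau, tau_u), 2]
  }
  z <- params$amplitude * nB
  z[times < params$p_start] <- 0
  during <- times >= params$p_start & times <= params$p_stop
  z[during] <- z[during] + params$n_ns * tau[during]
  z
}
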
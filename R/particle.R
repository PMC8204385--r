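# Exact stochastic simulator of the microscopic tethered-reaction process:
# phosphorylated peptide sites immobilized at random positions, enzyme
# binding/unbinding from solution, and pairwise trans-dephosphorylation of
# free phosphorylated sites by bound enzymes with the Gaussian reach kernel.
# Serves as ground truth for the MPDPDE closure.
#
# Microscopic rate dictionary (nondimensional, lengths in units of L):
# a free phosphorylated site binds enzyme at p1, loses its phosphate to
# solution enzyme at p5, and is dephosphorylated by the bound enzyme at
# site i at rate (p3/density) * sigma_hat(r_ij), where
# sigma_hat(r) = (3/(2*pi))^(3/2) exp(-3 r^2/2) is the unit-reach kernel.
# A bound site unbinds at p2.  Because p3 = kcat*[peptide] and
# density = [peptide]*L^3 while p4 = kcat*sigma* = kcat/L^3, the single
# pairwise channel realizes p4 = p3/density exactly: the PDE's p3
# (mean-field sink) and p4 (proximal pair sink) terms are two moments of
# this one microscopic process.  PDE comparisons therefore set
# p4 = p3/density.

#' Sample an immobilized particle system
#'
#' Sites are placed uniformly at random in a periodic cubic box, with a
#' Poisson-distributed total count, mirroring the random immobilization of
#' peptides on the sensor surface (dextran matrix, treated as 3D).
#'
#' @param density expected sites per unit volume, in kernel units
#'   (equals peptide concentration times L^3).
#' @param box_side box edge in units of L; must be at least 4 so that the
#'   minimum-image truncation of the reach kernel is negligible (default 6).
#' @param seed integer seed.
#' @return object of class \code{"particle_system"}: \code{positions}
#'   (n x 3 matrix), \code{density}, \code{box_side}, \code{n_sites}.
#' @export
sample_sites <- function(density, box_side = 6, seed = NULL) {
  stopifnot(density >= 0)
  if (box_side < 4)
    stop("box_side must be >= 4 reach units (kernel truncation bias)")
  with_seed(seed, {
    n <- stats::rpois(1, density * box_side^3)
    pos <- matrix(runif(3 * n, 0, box_side), ncol = 3)
    structure(list(positions = pos, density = density, box_side = box_side,
                   n_sites = n),
              class = "particle_system")
  })
}

# periodic minimum-image pairwise distance matrix
.min_image_dist <- function(pos, box) {
  n <- nrow(pos)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- abs(outer(pos[, k], pos[, k], `-`))
    dk <- pmin(dk, box - dk)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Simulate the microscopic tethered reaction (Gillespie)
#'
#' Direct stochastic simulation with exponential waiting times; all rates
#' are recomputed (incrementally) after every event.  Site states: free
#' phosphorylated, enzyme-bound phosphorylated, dephosphorylated
#' (absorbing: dephosphorylated sites never rebind, since the enzyme's SH2
#' domains require the phosphate).
#'
#' @param system a [sample_sites()] result.
#' @param params a [nondim_params()]; p1, p2, p3, p5 are used directly and
#'   the pairwise channel realizes p4 = p3/density (see source notes).
#' @param t_end simulation horizon, s.
#' @param seed integer seed.
#' @return list of class \code{"particle_run"}: \code{events} (data.frame
#'   time/event/site), step functions \code{time}, \code{nA}, \code{nB}
#'   (fractions of initial sites), and \code{n_sites}.
#' @export
simulate_particles <- function(system, params, t_end, seed = NULL) {
  stopifnot(inherits(system, "particle_system"),
            inherits(params, "nondim_params"), t_end > 0)
  n <- system$n_sites
  p1 <- params$p1; p2 <- params$p2; p5 <- params$p5
  if (n == 0) {
    return(structure(list(events = data.frame(time = numeric(0),
                                              event = character(0),
                                              site = integer(0)),
                          time = c(0, t_end), nA = c(0, 0), nB = c(0, 0),
                          n_sites = 0L),
                     class = "particle_run"))
  }
  S <- if (params$p3 > 0 && system$density > 0) {
    d <- .min_image_dist(system$positions, system$box_side)
    m <- (params$p3 / system$density) * .CPRE * exp(-1.5 * d^2)
    diag(m) <- 0
    m
  } else matrix(0, n, n)

  with_seed(seed, {
    state <- rep.int(0L, n)  # 0 free-phospho, 1 bound, 2 dephosphorylated
    catU <- rep.int(0, n)    # tethered-catalysis rate on each site
    t_now <- 0
    ev_t <- numeric(0); ev_e <- character(0); ev_s <- integer(0)
    rec_t <- 0; rec_a <- 1; rec_b <- 0
    nU <- n; nBnd <- 0L
    repeat {
      isU <- state == 0L
      rates_u <- if (nU > 0) (p1 + p5) + catU[isU] else numeric(0)
      total <- sum(rates_u) + nBnd * p2
      if (total <= 0) break
      t_now <- t_now + rexp(1, total)
      if (t_now > t_end) break
      if (runif(1) < nBnd * p2 / total) {
        # unbinding
        i <- which(state == 1L)
        i <- if (length(i) > 1) i[sample.int(length(i), 1)] else i
        state[i] <- 0L
        catU <- catU - S[i, ]
        nBnd <- nBnd - 1L; nU <- nU + 1L
        ev <- "unbind"
      } else {
        ui <- which(isU)
        j <- ui[sample.int(length(ui), 1, prob = rates_u)]
        rj <- p1 + p5 + catU[j]
        u <- runif(1) * rj
        if (u < p1) {
          state[j] <- 1L
          catU <- catU + S[j, ]
          nBnd <- nBnd + 1L; nU <- nU - 1L
          ev <- "bind"
        } else {
          state[j] <- 2L
          nU <- nU - 1L
          ev <- if (u < p1 + p5) "dephos_solution" else "dephos_tethered"
        }
        i <- j
      }
      ev_t <- c(ev_t, t_now); ev_e <- c(ev_e, ev); ev_s <- c(ev_s, i)
      rec_t <- c(rec_t, t_now)
      rec_a <- c(rec_a, nU / n); rec_b <- c(rec_b, nBnd / n)
    }
    structure(list(events = data.frame(time = ev_t, event = ev_e,
                                       site = ev_s),
                   time = c(rec_t, t_end),
                   nA = c(rec_a, rec_a[length(rec_a)]),
                   nB = c(rec_b, rec_b[length(rec_b)]),
                   n_sites = n),
              class = "particle_run")
  })
}

# evaluate a run's step functions at given times
.run_at <- function(run, times) {
  f <- function(v) approx(run$time, v, xout = times, method = "constant",
                          rule = 2)$y
  list(nA = f(run$nA), nB = f(run$nB))
}

#' Ensemble mean and standard error of particle runs
#'
#' @param runs list of [simulate_particles()] results (>= 2).
#' @param times common evaluation grid; default 101 points spanning the
#'   shortest run.
#' @return data.frame: \code{time}, \code{nA}, \code{nB}, \code{nA_se},
#'   \code{nB_se} (standard error of the ensemble mean).
#' @export
ensemble_average <- function(runs, times = NULL) {
  stopifnot(length(runs) >= 2)
  if (is.null(times)) {
    tmax <- min(vapply(runs, function(r) max(r$time), 0))
    times <- seq(0, tmax, length.out = 101)
  }
  a <- vapply(runs, function(r) .run_at(r, times)$nA, numeric(length(times)))
  b <- vapply(runs, function(r) .run_at(r, times)$nB, numeric(length(times)))
  m <- length(runs)
  data.frame(time = times,
             nA = rowMeans(a), nB = rowMeans(b),
             nA_se = apply(a, 1, sd) / sqrt(m),
             nB_se = apply(b, 1, sd) / sqrt(m))
}
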
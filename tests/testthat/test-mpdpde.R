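# MPDPDE forward model: right-hand side structure, limits with closed
# forms, conservation laws, solver-route agreement, grid convergence

unit_state <- function(grid, nA = 1, nB = 0) {
  list(nA = nA, nB = nB, Y = rep(1, grid$n), XA = rep(1, grid$n),
       XB = rep(1, grid$n))
}

test_that("null and pure-binding dynamics behave as conservation demands", {
  g <- radial_grid()
  # all rates zero: nothing moves
  d0 <- mpdpde_rhs(unit_state(g, 0.7, 0.2),
                   nondim_params(0, 0, 0, 0, 0, p_stop = 1), g)
  expect_equal(unlist(d0), unlist(d0) * 0, tolerance = 0)
  # binding only: sites swap between free and bound, correlations frozen
  db <- mpdpde_rhs(unit_state(g, 0.6, 0.3),
                   nondim_params(2, 1, 0, 0, 0, p_stop = 1), g)
  expect_equal(db$nA + db$nB, 0, tolerance = 1e-14)
  expect_equal(db$Y, rep(0, g$n), tolerance = 1e-12)
  expect_equal(db$XA, rep(0, g$n))
  expect_equal(db$XB, rep(0, g$n), tolerance = 1e-12)
})

test_that("the catalytic sink reduces to p3*nA*nB under flat correlations", {
  # independent quadrature of the kernel's radial integral
  g <- radial_grid(128, 8)
  p <- nondim_params(0, 0, 0.7, 0, 0, p_stop = 1)
  d <- mpdpde_rhs(unit_state(g, 0.5, 0.4), p, g)
  quad <- integrate(function(r) r^2 * exp(-1.5 * r^2), 0, Inf,
                    rel.tol = 1e-12)$value
  expect_equal(4 * pi * (3 / (2 * pi))^1.5 * quad, 1, tolerance = 1e-9)
  expect_equal(d$nA, -0.7 * 0.5 * 0.4, tolerance = 1e-3)
})

test_that("compiled and reference right-hand sides integrate identically", {
  g <- radial_grid()
  p <- nondim_params(0.5, 1.2, 0.8, 2, 0.05, p_stop = 3)
  tt <- seq(0, 4, by = 0.5)
  a <- integrate_mpdpde(p, g, tt)
  b <- integrate_mpdpde(p, g, tt, compiled = FALSE)
  expect_equal(a$nB, b$nB, tolerance = 1e-10)
  expect_equal(a$Y, b$Y, tolerance = 1e-10)
})

test_that("binding-only integration matches the Langmuir closed form", {
  g <- radial_grid()
  tt <- seq(0, 5, by = 0.05)
  sol <- integrate_mpdpde(nondim_params(1, 1, 0, 0, 0, p_stop = 10), g, tt)
  expect_lt(max(abs(sol$nB - 0.5 * (1 - exp(-2 * tt)))), 1e-5)
  expect_lt(max(abs(sol$nA + sol$nB - 1)), 1e-6)
  # pure solution catalysis: exponential loss of free sites
  sol2 <- integrate_mpdpde(nondim_params(0, 0, 0, 0, 0.4, p_stop = 10),
                           g, tt)
  expect_lt(max(abs(sol2$nA - exp(-0.4 * tt))), 1e-5)
})

test_that("phospho-site density depletes monotonically and stays bounded", {
  g <- radial_grid()
  p <- nondim_params(0.4, 1.8, 4.2, 8.8, 0.003, p_stop = 30)
  sol <- integrate_mpdpde(p, g, seq(0, 40, by = 0.25))
  tot <- sol$nA + sol$nB
  expect_true(all(diff(tot) <= 1e-9))
  expect_true(all(tot <= 1 + 1e-9))
  expect_true(all(sol$nA >= -1e-9) && all(sol$nB >= -1e-9))
  expect_gt(min(sol$Y), -1e-6)
  # autocorrelations can exceed 1 (survivors of tethered catalysis are
  # spatially clustered, a behaviour confirmed by the particle oracle),
  # but the cross-correlation never exceeds the A-A autocorrelation:
  # freshly formed pairs renew Y toward XA
  expect_lt(max(sol$Y - apply(sol$XA, 1, max)), 1e-6)
  expect_lt(max(sol$XA), 1.2)
})

test_that("the solution is converged on the default radial grid", {
  p <- nondim_params(0.034, 1.8, 4.2, 8.8, 0.003, p_stop = 30)
  tt <- seq(0, 40, by = 0.5)
  a <- integrate_mpdpde(p, radial_grid(), tt)
  b <- integrate_mpdpde(p, radial_grid(128, 8), tt)
  expect_lt(max(abs(a$nB - b$nB)) / max(a$nB), 0.005)
})

test_that("fixed-step and adaptive integrations of the observable agree", {
  g <- radial_grid()
  p <- nondim_params(0.034, 1.8, 4.2, 8.8, 0.003, n_ns = 0.02,
                     p_start = 0.1, p_stop = 45.1, amplitude = 500)
  tt <- seq(0, 65, by = 0.1)
  z_ref <- tetherspr:::.model_signal(p, tt, g, 1e-8, 1e-10)
  z_rk <- tetherspr:::.model_signal_rk4(p, tt, g, 0.05)
  expect_lt(max(abs(z_ref - z_rk)), 1e-4)
  z_coarse <- tetherspr:::.model_signal_rk4(p, tt, g, 0.25, coarse = TRUE)
  expect_lt(max(abs(z_ref - z_coarse)), 5e-3)
})

test_that("the observable follows the piecewise injection form", {
  g <- radial_grid()
  p <- nondim_params(1, 1, 0, 0, 0, n_ns = 0.05, p_start = 2, p_stop = 10,
                     amplitude = 3)
  tt <- seq(0, 15, by = 0.01)
  traj <- integrate_mpdpde(p, g, seq(0, 13, by = 0.01))
  z <- spr_observable(traj, p, tt)
  # zero before injection start
  expect_true(all(z$signal[tt < 2] == 0))
  # no-drift case is the pure scaled bound fraction
  p0 <- nondim_params(1, 1, 0, 0, 0, p_start = 2, p_stop = 10, amplitude = 3)
  z0 <- spr_observable(traj, p0, tt)
  i <- tt >= 2
  nB <- approx(traj$time, traj$nB, xout = tt[i] - 2)$y
  expect_equal(z0$signal[i], 3 * nB, tolerance = 1e-9)
  # drift accrues from injection start and vanishes at the stop:
  # discontinuity of size n_ns * (p_stop - p_start)
  before <- z$signal[max(which(tt <= 10))]
  after <- z$signal[min(which(tt > 10))]
  # drop = drift accrued over the injection, up to the bound-signal decay
  # across one sample
  expect_lt(abs((before - after) - 0.05 * 8), 0.03)
})

test_that("invalid grids, parameters and time vectors are rejected", {
  expect_error(radial_grid(32), "n_nodes")
  expect_error(radial_grid(64, 3), "r_max")
  expect_error(nondim_params(-1, 1, 0, 0, 0), "non-negative")
  expect_error(nondim_params(1, 1, 0, 0, 0, p_start = 5, p_stop = 4),
               "exceed")
  g <- radial_grid()
  p <- nondim_params(1, 1, 0, 0, 0, p_stop = 5)
  expect_error(integrate_mpdpde(p, g, c(1, 0.5)), "increasing")
})

test_that("physical and nondimensional parameters round-trip", {
  cond <- spr_conditions(0.25, 80)
  phys <- list(k_on = 0.34, k_off = 1.8, kcat_tethered = 0.042,
               kcat_solution = 0.031, sigma_star = 210)
  p <- as_nondim(phys, cond)
  back <- as_physical(p, cond)
  for (nm in names(phys))
    expect_equal(back[[nm]], phys[[nm]], tolerance = 1e-12)
  expect_equal(back$K_D, phys$k_off / phys$k_on, tolerance = 1e-12)
  expect_equal(back$L, reach_from_sigma_star(210), tolerance = 1e-12)
  # no tethered catalysis: reach flagged unidentifiable
  p0 <- nondim_params(1, 1, 0, 0, 0, p_stop = 45)
  expect_true(is.na(as_physical(p0, cond)$L))
})
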
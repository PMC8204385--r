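# fitting machinery: initial guesses, objective, annealing mechanics,
# best-of selection.  Full parameter recovery lives in test-acceptance.R.

test_that("tail fitting recovers a clean exponential decay rate", {
  tt <- seq(0, 60, by = 0.1)
  z <- ifelse(tt < 45, 5, 5 * exp(-1.8 * (tt - 45)))
  tr <- spr_trace(tt, z)
  expect_equal(initial_koff(tr, 45), 1.8, tolerance = 0.01)
  # flat tail: fallback with warning
  flat <- spr_trace(tt, rep(2, length(tt)))
  expect_warning(k <- initial_koff(flat, 45), "decay")
  expect_equal(k, 1.0)
  expect_error(initial_koff(spr_trace(1:5, rep(0, 5)), 45), "10 samples")
})

test_that("tail estimate is adequate on a full model trace", {
  tr <- quick_trace()
  k <- initial_koff(tr, attr(tr, "metadata")$params$p_stop)
  expect_lt(abs(k - 1.8) / 1.8, 0.15)
})

test_that("injection start is read off the trace", {
  tr <- quick_trace()
  expect_lt(abs(tetherspr:::.injection_start(tr) - 0.1), 0.15)
})

test_that("the objective is zero at truth and rises with perturbation", {
  tr <- quick_trace()          # noiseless
  truth <- attr(tr, "metadata")$params
  g <- radial_grid()
  s0 <- spr_objective(truth, tr, g)
  expect_lt(s0, 1e-6 * sum(tr$signal^2))
  p2x <- truth; p2x$p2 <- truth$p2 * 2
  expect_gt(spr_objective(p2x, tr, g), s0 + 1)
  # constant offset on both model and data cancels
  tr_off <- spr_trace(tr$time, tr$signal + 7)
  z <- tetherspr:::.model_signal(truth, tr$time, g) + 7
  expect_equal(sum((z - tr_off$signal)^2), s0, tolerance = 1e-6)
})

test_that("optimizer coordinates round-trip through the parameter map", {
  p <- nondim_params(0.034, 1.8, 4.2, 8.82, 0.0031, n_ns = 0.02,
                     p_start = 0.1, p_stop = 45.1, amplitude = 500)
  th <- tetherspr:::.to_theta(p, pep = 100)
  back <- tetherspr:::.from_theta(th, pep = 100, amplitude = 500)
  for (nm in names(p)) expect_equal(back[[nm]], p[[nm]], tolerance = 1e-12)
})

test_that("zero-temperature annealing is greedy descent", {
  # on a smooth bowl, accepted moves never increase the objective
  objfun <- function(th) sum((th - c(1, -2))^2)
  res <- tetherspr:::.sa_run(objfun, c(5, 5), n_steps = 400, seed = 3,
                             scales0 = c(0.5, 0.5), t0 = 0)
  expect_lt(res$sse, objfun(c(5, 5)))
  expect_lt(sum((res$theta - c(1, -2))^2), 8)
})

test_that("annealing with the polynomial schedule improves the objective", {
  objfun <- function(th) sum(th^2) + 2 * sin(3 * th[1])^2
  r1 <- tetherspr:::.sa_run(objfun, c(4, -4), n_steps = 2000, seed = 1,
                            scales0 = c(0.3, 0.3))
  r2 <- tetherspr:::.sa_run(objfun, c(4, -4), n_steps = 2000, seed = 2,
                            scales0 = c(0.3, 0.3))
  expect_lt(r1$sse, 1)
  expect_lt(r2$sse, 1)
  # two seeds agree to within a factor of a few near the optimum
  expect_lt(max(r1$sse, r2$sse) / max(min(r1$sse, r2$sse), 1e-3), 100)
})

test_that("best_of selects by SSE with the lowest-seed tie rule", {
  mk <- function(sse, seed) structure(list(sse = sse, seed = seed),
                                      class = "spr_fit")
  fits <- list(mk(3, 1), mk(1, 5), mk(2, 2))
  expect_equal(best_of(fits)$sse, 1)
  expect_identical(best_of(fits[2]), fits[[2]])
  ties <- list(mk(1, 9), mk(1, 4))
  expect_equal(best_of(ties)$seed, 4)
  expect_error(best_of(list()), "no fits")
})

test_that("a noiseless quick trace is fitted to high accuracy", {
  tr <- quick_trace()
  cond <- quick_conditions()
  fit <- fit_sensorgram(tr, cond, n_steps = 1000, n_restarts = 1, seed = 1,
                        dt = 0.1)
  ph <- fit$physical
  expect_lt(abs(ph$k_off / 1.8 - 1), 0.05)
  expect_lt(abs(ph$K_D / (1.8 / 0.34) - 1), 0.05)
  # methods are coherent
  expect_equal(length(fitted(fit)), nrow(tr))
  expect_equal(residuals(fit), tr$signal - fitted(fit))
  expect_named(coef(fit), c("p1", "p2", "p3", "p4", "p5", "n_ns",
                            "p_start", "p_stop", "amplitude"))
  expect_output(print(fit), "MPDPDE")
  expect_s3_class(summary(fit), "summary.spr_fit")
})
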
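# reach table, PEG-series regression, parse/combine quadrature rules

table2_sigma_rows <- function() {
  tb <- table2_params()
  tb[tb$name %in% c("PEG0", "PEG3", "PEG6", "PEG12", "PEG28"),
     c("n_peg", "sigma_star", "sigma_star_se")]
}

test_that("reach table averages sigma* then transforms, with delta-method error", {
  d <- data.frame(n_peg = rep(28, 3), sigma_star = c(200, 210, 220))
  tab <- reach_table(d)
  expect_equal(tab$sigma_star_mean, 210)
  expect_equal(tab$L, reach_from_sigma_star(210), tolerance = 1e-12)
  # printed pair 210 <-> 19.7 agrees within mutual rounding
  expect_equal(tab$L, 19.7, tolerance = 0.015)
  expect_equal(tab$L_squared_err,
               (2 / 3) * tab$L_squared / 210 * sd(c(200, 210, 220)),
               tolerance = 1e-12)
  # zero scatter -> zero propagated error
  tab0 <- reach_table(data.frame(n_peg = c(3, 3), sigma_star = c(500, 500)))
  expect_equal(tab0$L_squared_err, 0)
})

test_that("delta-method error matches a Monte-Carlo transformation oracle", {
  # first-order propagation vs brute-force transformation of normal draws;
  # the curvature of the -2/3 power makes the approximation degrade with
  # the coefficient of variation (about 14% off by cv = 0.2)
  set.seed(11)
  mu <- 400
  for (cv in c(0.05, 0.1, 0.2)) {
    draws <- rnorm(1e5, mu, cv * mu)
    draws <- draws[draws > 0]
    L2_mc <- sd(reach_from_sigma_star(draws)^2)
    L2 <- reach_from_sigma_star(mu)^2
    delta <- (2 / 3) * L2 / mu * (cv * mu)
    expect_equal(delta, L2_mc, tolerance = if (cv <= 0.1) 0.1 else 0.2)
  }
})

test_that("non-positive mean sigma* rows are rejected with a warning", {
  d <- data.frame(n_peg = c(1, 1, 2), sigma_star = c(-5, -1, 300))
  expect_warning(tab <- reach_table(d), "non-positive")
  expect_equal(tab$n_peg, 2)
})

test_that("PEG regression recovers the enzyme reach from the fitted series", {
  tab <- reach_table(do.call(rbind, lapply(seq_len(nrow(table2_sigma_rows())),
    function(i) {
      r <- table2_sigma_rows()[i, ]
      data.frame(n_peg = r$n_peg, sigma_star = r$sigma_star)
    })))
  fit <- peg_reach_fit(tab)  # excludes PEG0 by default
  expect_gt(fit$L_enzyme, 13.0 - 0.8)
  expect_lt(fit$L_enzyme, 13.0 + 0.8)
  expect_equal(nrow(fit$data), 4)
  # L^2 is monotone non-decreasing in N_PEG on these data
  expect_true(all(diff(tab$L_squared) >= 0))
})

test_that("regression is exact on a noiseless synthetic line", {
  n <- c(3, 6, 12, 28)
  lp <- 0.35
  tab <- data.frame(n_peg = n, L_squared = 4 * n * 0.4 * lp + 169)
  fit <- peg_reach_fit(tab, exclude = integer(0))
  expect_equal(fit$L_enzyme, 13, tolerance = 1e-10)
  expect_equal(fit$slope, 4 * 0.4 * lp, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("regression interval covers the truth at realistic scatter", {
  # scatter matched to the fitted-series dispersion.  The regression is
  # run on replicate-level squared reaches so the intercept SE carries
  # honest degrees of freedom (a 4-point fit of means would leave only
  # two and +/- 2 SE would cover barely 80%).
  set.seed(21)
  n_sim <- 300
  hits <- 0
  for (i in seq_len(n_sim)) {
    d <- simulate_peg_series(L_enzyme = 13, replicates = 5, noise_cv = 0.25)
    d <- d[d$sigma_star > 0, ]
    tab <- data.frame(n_peg = d$n_peg,
                      L_squared = reach_from_sigma_star(d$sigma_star)^2)
    fit <- peg_reach_fit(tab, exclude = integer(0))
    if (abs(fit$L_enzyme - 13) <= 2 * fit$L_enzyme_se) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.85)
})

test_that("degenerate regressions are reported, not silently returned", {
  expect_error(peg_reach_fit(data.frame(n_peg = c(3, 6), L_squared = c(1, 2))),
               "at least 3")
  down <- data.frame(n_peg = c(3, 6, 12, 28), L_squared = c(-44, -38, -26, 6))
  expect_error(peg_reach_fit(down, exclude = integer(0)), "intercept")
})

test_that("component parsing matches the published reach decomposition", {
  # PD-1 tail from combined 16 nm and enzyme 13 nm
  expect_equal(parse_tether_reach(16, 13), 6.55, tolerance = 0.15 / 6.55)
  # SLAM tail from 31.2 nm
  expect_equal(signif(parse_tether_reach(31.2, 13), 2), 20)
  # enzyme-free limit
  expect_equal(parse_tether_reach(10, 0), 10 / sqrt(2), tolerance = 1e-12)
  expect_error(parse_tether_reach(12, 13), "exceed")
})

test_that("combine_reach is the quadrature sum with multiplicities", {
  expect_equal(combine_reach(c(6.55, 13)), 14.6, tolerance = 0.01)
  expect_equal(combine_reach(5), 5)
  expect_equal(combine_reach(c(0, 7)), 7)
  # SPR geometry: two tethers + enzyme
  expect_equal(combine_reach(c(3, 13), c(2, 1)), sqrt(2 * 9 + 169),
               tolerance = 1e-12)
})

test_that("parse and combine are mutual inverses", {
  for (L in c(16, 31.2)) {
    tether <- parse_tether_reach(L, 13)
    expect_equal(combine_reach(c(tether, 13), c(2, 1)), L, tolerance = 1e-12)
  }
})
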
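# synthetic-data generator: noise layering, fixtures, PEG-series tables

test_that("zero noise reproduces the deterministic observable", {
  tr <- quick_trace(noise_model(additive_sd = 0, sampling_rate = 5))
  md <- attr(tr, "metadata")
  z <- spr_observable(
    integrate_mpdpde(md$params, radial_grid(),
                     sort(unique(c(0, pmax(tr$time - md$params$p_start, 0))))),
    md$params, tr$time)
  expect_equal(tr$signal, z$signal, tolerance = 1e-12)
})

test_that("a fixed seed gives a bitwise-identical trace", {
  nm <- noise_model(additive_sd = 0.1, seed = 77, sampling_rate = 5)
  t1 <- quick_trace(nm); t2 <- quick_trace(nm)
  expect_identical(t1$signal, t2$signal)
  t3 <- quick_trace(noise_model(additive_sd = 0.1, seed = 78,
                                sampling_rate = 5))
  expect_false(identical(t1$signal, t3$signal))
})

test_that("ground truth always rides along with synthetic data", {
  tr <- quick_trace()
  md <- attr(tr, "metadata")
  expect_s3_class(md$params, "nondim_params")
  expect_named(md$physical,
               c("k_on", "k_off", "kcat_tethered", "kcat_solution",
                 "sigma_star"), ignore.order = TRUE)
  d <- simulate_peg_series(seed = 3)
  expect_s3_class(attr(d, "truth"), "data.frame")
})

test_that("synthetic traces show the published multiphasic shape", {
  tr <- simulate_sensorgram(peg28_physical(), std_conditions(),
                            noise_model(additive_sd = 0), amplitude = 500,
                            p_start = 0.1)
  p_stop <- attr(tr, "metadata")$params$p_stop
  inj <- tr$signal[tr$time <= p_stop]
  i_pk <- which.max(inj)
  # one interior maximum: rise, then decay during the injection
  expect_gt(i_pk, 1)
  expect_lt(i_pk, length(inj))
  expect_lt(tr$time[i_pk], 10)           # early peak
  expect_lt(inj[length(inj)], inj[i_pk]) # decayed below the peak
  # late-injection decay is slower than the early tethered decay
  slope <- function(a, b) {
    i <- tr$time >= a & tr$time <= b
    unname(coef(lm(tr$signal[i] ~ tr$time[i]))[2])
  }
  expect_lt(abs(slope(35, 45)), abs(slope(tr$time[i_pk] + 0.5, 10)))
  # dissociation drop after injection end
  expect_lt(tr$signal[which.min(abs(tr$time - (p_stop + 3)))],
            tr$signal[which.min(abs(tr$time - p_stop))])
})

test_that("the construct table matches the published fits", {
  tb <- table2_params()
  expect_equal(nrow(tb), 8)
  slam <- tb[tb$name == "SLAM", ]
  expect_equal(slam$k_on, 0.02)
  expect_equal(slam$sigma_star, 55)
  # the tabulated K_D is a replicate-level average, so it matches the
  # ratio of the averaged rates only within its uncertainty (most visibly
  # for the SLAM construct, whose k_on is small and noisy)
  expect_true(all(abs(tb$K_D - tb$k_off / tb$k_on) <= 3 * tb$K_D_se))
  # printed (sigma*, L) pairs consistent with the conversion to rounding
  expect_equal(reach_from_sigma_star(tb$sigma_star), tb$L, tolerance = 0.02)
  # temperature effect: ~4.5-fold sigma* increase at 10C
  expect_equal(tb$sigma_star[tb$name == "PEG28_10C"] /
                 tb$sigma_star[tb$name == "PEG28"], 4.5, tolerance = 0.02)
})

test_that("PEG-series generator honours the squared-reach law", {
  d0 <- simulate_peg_series(L_enzyme = 13, noise_cv = 0, seed = 1)
  fit <- peg_reach_fit(reach_table(d0), exclude = integer(0))
  expect_equal(fit$L_enzyme, 13, tolerance = 1e-9)
  expect_equal(fit$slope, 4 * 0.4 * 0.4, tolerance = 1e-9)
  # replicate scatter shrinks the intercept uncertainty roughly as 1/sqrt(n)
  se_for <- function(reps, seed) {
    f <- peg_reach_fit(reach_table(
      simulate_peg_series(replicates = reps, noise_cv = 0.15, seed = seed)),
      exclude = integer(0))
    f$L_enzyme_se
  }
  se5 <- median(vapply(1:20, function(s) se_for(5, s), 0))
  se20 <- median(vapply(1:20, function(s) se_for(20, s), 0))
  expect_lt(se20, se5 / 1.4)
  expect_gt(se20, se5 / 3.5)
})
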
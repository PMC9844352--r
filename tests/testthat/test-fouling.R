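test_that("simulate_series follows the per-cycle site-loss recursion", {
  p <- ref_params()
  cfg <- ref_config(gain = 1.8)
  s <- simulate_series(5e-7, 1800, p, cfg, a = 0.25, cycles = 10)
  # one-step hand evaluation (isotherm -> exponential approach -> decrement)
  expect_equal(s$eld[1], 5e-11)
  expect_equal(s$bound[1], 5.10043e-12, tolerance = 1e-5)
  expect_equal(s$eld[2], 5e-11 - 0.25 * s$bound[1])
  # recursion holds at every cycle
  expect_equal(s$eld[-1], s$eld[-10] - 0.25 * s$bound[-10])
  # gain is applied to the predicted current
  expect_equal(s$ipa, bound_to_current(s$bound, cfg))
  expect_error(simulate_series(5e-7, 1800, p, cfg, a = 1.2, cycles = 5),
               "\\[0, 1\\]")
})

test_that("a = 0 reduces to the fouling-free forward model", {
  p <- ref_params()
  cfg <- ref_config()
  s <- simulate_series(5e-7, 1800, p, cfg, a = 0, cycles = 20)
  expect_true(all(s$eld == 5e-11))
  expect_equal(s$ipa, rep(s$ipa[1], 20))
  expect_equal(s$ipa[1],
               bound_to_current(adsorption_at_time(5e-7, 1800, p), cfg))
})

test_that("fouling series invariants: monotone site loss and conservation", {
  p <- ref_params()
  cfg <- ref_config(gain = 1.8)
  for (a in c(0.1, 0.25, 0.9, 1)) {
    s <- simulate_series(5e-7, 1800, p, cfg, a = a, cycles = 50)
    expect_true(all(diff(s$eld) <= 0))
    expect_true(all(s$eld >= 0))
    expect_true(all(diff(s$ipa) < 0))
    # conservation: total fouled sites equal a * cumulative bound, exactly
    eld_final <- s$eld[50] - a * s$bound[50]
    expect_equal(p$ELD_tot - eld_final, a * sum(s$bound),
                 tolerance = 1e-14)
  }
  # limiting case: saturating concentration, long accumulation, a = 1
  s1 <- simulate_series(1e-2, 1e7, p, cfg, a = 1, cycles = 2)
  expect_lt(s1$eld[2] / p$ELD_tot, 1e-4)
})

test_that("fit_fouling recovers a from self-generated data", {
  p <- ref_params()
  cfg <- ref_config(gain = 1.8)
  s <- simulate_series(5e-7, 1800, p, cfg, a = 0.25, cycles = 50)
  fit <- fit_fouling(s, p, cfg)
  expect_equal(fit$a, 0.25, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_equal(fit$fit_start_cycle, 7)
  # degenerate observations are refused
  s$ipa <- rep(1e-6, 50)
  expect_error(fit_fouling(s, p, cfg), "degenerate")
})

test_that("fit_fouling honours fit_start_cycle and tolerates a rise phase", {
  p <- ref_params()
  cfg <- ref_config(gain = 1.8)
  obs <- gen_fouling(p, cfg, a = 0.25, rise = list(m = 7, amplitude = 0.5))
  # cycles 1-7 carry the un-modelled rise; the default start cycle skips them
  fit <- fit_fouling(obs, p, cfg)
  expect_equal(fit$a, 0.25, tolerance = 0.02)
  # fitting from cycle 1 drags the estimate away from truth
  fit1 <- fit_fouling(obs, p, cfg, fit_start_cycle = 1)
  expect_gt(abs(fit1$a - 0.25), abs(fit$a - 0.25))
  expect_error(fit_fouling(obs[1:8, ], p, cfg, fit_start_cycle = 7),
               "at least 5")
})

test_that("fit_fouling can estimate the gain jointly when flagged", {
  p <- ref_params()
  cfg <- ref_config(gain = 1.8)
  s <- simulate_series(5e-7, 1800, p, cfg, a = 0.25, cycles = 50)
  fit <- fit_fouling(s, p, ref_config(gain = 1.0), fit_gain = TRUE)
  expect_equal(fit$a, 0.25, tolerance = 0.01)
  expect_equal(fit$gain, 1.8, tolerance = 0.01)
})

test_that("predict_titration wraps the simulator and shows fouling loss", {
  p <- ref_params()
  cfg <- ref_config(gain = 1.8)
  seq8 <- c(0.01, 0.05, 0.1, 0.5, 1, 2.5, 5, 10) * 1e-6
  free <- predict_titration(seq8, 1800, p, cfg, a = 0)
  fouled <- predict_titration(seq8, 1800, p, cfg, a = 0.25)
  # fouling-free titration equals the pointwise forward model
  expect_equal(free$ipa,
               bound_to_current(adsorption_at_time(seq8, 1800, p), cfg))
  # accumulated fouling depresses the top of the curve
  expect_true(all(fouled$ipa[7:8] < free$ipa[7:8]))
  expect_error(predict_titration(rev(seq8), 1800, p, cfg, a = 0.25),
               "ascending")
})

test_that("titration prediction matches an independent loop oracle", {
  p <- ref_params()
  cfg <- ref_config(gain = 1.8)
  seq8 <- c(0.01, 0.05, 0.1, 0.5, 1, 2.5, 5, 10) * 1e-6
  pred <- predict_titration(seq8, 1800, p, cfg, a = 0.25)
  # oracle: direct transcription of the per-cycle procedure, written
  # independently of simulate_series
  eld <- 5e-11
  ipa_oracle <- numeric(8)
  for (i in seq_along(seq8)) {
    C <- seq8[i]
    eq <- C * eld / (7e-7 + C)
    b <- eq * (1 - exp(-(C * 130 + 9.1e-5) * 1800))
    ipa_oracle[i] <- 1.8 * (4 * 96485.33212^2 /
                            (4 * 8.314462618 * 298.15)) * 0.4 * b
    eld <- eld - 0.25 * b
  }
  expect_equal(pred$ipa, ipa_oracle, tolerance = 1e-12)
})

test_that("fouling CSV round trip preserves the series and metadata", {
  p <- ref_params()
  cfg <- ref_config(gain = 1.8)
  s <- simulate_series(5e-7, 1800, p, cfg, a = 0.25, cycles = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fouling_csv(s, path)
  back <- read_fouling_csv(path)
  expect_equal(back$ipa, s$ipa, tolerance = 1e-12)
  expect_equal(back$concentration, s$concentration)
  expect_equal(attr(back, "t_acc"), 1800)
  fit <- fit_fouling(back, p, cfg)
  expect_equal(fit$a, 0.25, tolerance = 1e-3)
})
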
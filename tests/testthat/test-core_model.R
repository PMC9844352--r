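test_that("parameter containers validate their invariants", {
  expect_error(kinetic_params(K_D = -1, ELD_tot = 5e-11), "K_D")
  expect_error(kinetic_params(ELD_tot = 0), "ELD_tot")
  # K_D derived from the rates when omitted
  p <- kinetic_params(k_on = 130, k_off = 9.1e-5, ELD_tot = 5e-11)
  expect_equal(p$K_D, 7e-7)
  # inconsistent triple is reported, not silently accepted
  expect_warning(
    kinetic_params(K_D = 1e-6, k_on = 130, k_off = 9.1e-5, ELD_tot = 5e-11),
    "disagree")
  expect_silent(
    kinetic_params(K_D = 7e-7, k_on = 130, k_off = 9.1e-5, ELD_tot = 5e-11))
  expect_error(electrochem_config(n = 1.5, scan_rate = 0.4), "integer")
  expect_error(electrochem_config(scan_rate = -1), "scan_rate")
  expect_error(electrochem_config(scan_rate = 0.4, gain = 0), "gain")
})

test_that("equilibrium_bound evaluates the Langmuir isotherm", {
  p <- ref_params()
  expect_identical(equilibrium_bound(0, p), 0)
  # half saturation at C = K_D
  expect_equal(equilibrium_bound(7e-7, p), 2.5e-11)
  # hand-evaluated: 1e-6 * 5e-11 / 1.7e-6
  expect_equal(equilibrium_bound(1e-6, p), 2.941176470588e-11,
               tolerance = 1e-10)
  expect_error(equilibrium_bound(-1e-9, p), "C")
  expect_error(equilibrium_bound(1e-6, p, eld = -1), "eld")
})

test_that("equilibrium_bound is concave increasing and saturates below eld", {
  p <- ref_params()
  C <- 10^seq(-9, -4, length.out = 60)
  b <- equilibrium_bound(C, p)
  expect_true(all(diff(b) > 0))
  expect_true(all(diff(diff(b) / diff(C)) < 0))  # decreasing slope
  expect_true(all(b < p$ELD_tot))
})

test_that("adsorption_at_time matches the exponential-approach law", {
  p <- ref_params()
  expect_identical(adsorption_at_time(1e-6, 0, p), 0)
  # one time constant: 63.2% of equilibrium
  tau <- 1 / ref_lambda(1e-6)
  expect_equal(adsorption_at_time(1e-6, tau, p),
               (1 - exp(-1)) * equilibrium_bound(1e-6, p), tolerance = 1e-12)
  # 15 h at 1 uM is effectively equilibrium (lambda*t ~ 11.9)
  expect_equal(adsorption_at_time(1e-6, 5.4e4, p),
               equilibrium_bound(1e-6, p), tolerance = 1e-4)
  expect_error(adsorption_at_time(1e-6, -1, p), "t_acc")
})

test_that("adsorption is monotone in C and t and bounded by eld", {
  p <- ref_params()
  C <- c(1e-8, 1e-7, 1e-6, 1e-5)
  t <- c(10, 100, 1000, 10000)
  for (tt in t) {
    expect_true(all(diff(adsorption_at_time(C, tt, p)) > 0))
  }
  for (cc in C) {
    expect_true(all(diff(adsorption_at_time(cc, t, p)) > 0))
    expect_true(all(adsorption_at_time(cc, t, p) < p$ELD_tot))
  }
})

test_that("limit equivalence: time-dependent -> equilibrium at lambda*t = 20", {
  p <- ref_params()
  for (C in c(1e-8, 5e-7, 1e-6, 1e-5)) {
    t20 <- 20 / ref_lambda(C)
    expect_equal(adsorption_at_time(C, t20, p), equilibrium_bound(C, p),
                 tolerance = 1e-8)
  }
})

test_that("desorption decays exponentially with half-life ln2/k_off", {
  p <- ref_params()
  b0 <- 3e-11
  expect_identical(desorption_at_time(b0, 0, p), b0)
  t_half <- log(2) / 9.1e-5  # = 7617 s
  expect_equal(desorption_at_time(b0, t_half, p), b0 / 2, tolerance = 1e-12)
  expect_equal(desorption_at_time(b0, 1e9, p), 0, tolerance = 1e-20)
  expect_error(desorption_at_time(-b0, 10, p), "bound0")
})

test_that("bound_to_current implements the adsorption-limited conversion", {
  cfg <- ref_config()
  expect_identical(bound_to_current(0, cfg), 0)
  # n=2, T=298.15 K, nu=0.4 V/s, gain=1: ~1.50e-5 A for 1e-11 mol
  expect_equal(bound_to_current(1e-11, cfg), 1.502e-5, tolerance = 1e-3)
  # linear and homogeneous in bound and scan rate
  expect_equal(bound_to_current(3e-11, cfg), 3 * bound_to_current(1e-11, cfg))
  cfg2 <- electrochem_config(scan_rate = 0.8)
  expect_equal(bound_to_current(1e-11, cfg2), 2 * bound_to_current(1e-11, cfg))
  # gain scales the output
  expect_equal(bound_to_current(1e-11, ref_config(gain = 1.8)),
               1.8 * bound_to_current(1e-11, cfg))
})

test_that("current_to_bound is the exact inverse of bound_to_current", {
  cfg <- ref_config(gain = 1.8)
  expect_identical(current_to_bound(0, cfg), 0)
  for (b in c(1e-13, 2.94e-11, 5e-11)) {
    expect_equal(current_to_bound(bound_to_current(b, cfg), cfg), b,
                 tolerance = 1e-12)
  }
  expect_error(current_to_bound(-1e-6, cfg), "Ipa")
})

test_that("concentration_from_current inverts the forward chain", {
  p <- ref_params()
  cfg <- ref_config()
  expect_identical(concentration_from_current(0, 1800, p, cfg), 0)
  for (C in c(1e-8, 1e-7, 5e-7, 2e-6)) {
    ipa <- bound_to_current(adsorption_at_time(C, 1800, p), cfg)
    expect_equal(concentration_from_current(ipa, 1800, p, cfg), C,
                 tolerance = 1e-6)
  }
  # infeasible: current implying full site occupancy
  ceiling_A <- bound_to_current(p$ELD_tot, cfg)
  expect_error(concentration_from_current(ceiling_A * 1.01, 1800, p, cfg),
               "infeasible")
})

test_that("inversion agrees with a fine-grid scan oracle", {
  p <- ref_params()
  cfg <- ref_config()
  # independent oracle: locate the crossing on a dense log grid, then refine
  # by bisection on the forward model only
  oracle <- function(ipa, t_acc) {
    grid <- 10^seq(-12, -3, length.out = 2000)
    f <- bound_to_current(adsorption_at_time(grid, t_acc, p), cfg) - ipa
    i <- which(f >= 0)[1]
    lo <- grid[i - 1]; hi <- grid[i]
    for (k in 1:80) {
      mid <- sqrt(lo * hi)
      fm <- bound_to_current(adsorption_at_time(mid, t_acc, p), cfg) - ipa
      if (fm < 0) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  set.seed(11)
  for (k in 1:25) {
    C <- 10^stats::runif(1, -8.5, -5.5)
    t_acc <- stats::runif(1, 60, 54000)
    ipa <- bound_to_current(adsorption_at_time(C, t_acc, p), cfg)
    expect_equal(concentration_from_current(ipa, t_acc, p, cfg),
                 oracle(ipa, t_acc), tolerance = 1e-6)
  }
})
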
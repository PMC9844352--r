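# A bare ramp trace carrying an arbitrary current channel, for filter tests.
ramp_trace <- function(current, fs = 2000) {
  cv_trace(seq(0.1, 0.5, length.out = length(current)), current,
           sampling_rate = fs, scan_rate = 0.4)
}

test_that("cv_trace validates channels and metadata", {
  expect_error(cv_trace(1:3, 1:2, 2000, 0.4), "equal length")
  expect_error(cv_trace(c(0.1, 0.2), c(0, 0), sampling_rate = 0,
                        scan_rate = 0.4), "sampling_rate")
  expect_error(cv_trace(c(0.1, 0.6), c(0, 0), 2000, 0.4,
                        sweep_window = c(0.1, 0.5)), "outside")
})

test_that("low-pass smoothing meets its frequency-response contract", {
  fs <- 2000
  tt <- seq(0, 1, length.out = fs)
  mid <- 500:1500  # avoid edges when measuring amplitude
  amp_after <- function(f0, cutoff = 3) {
    tr <- ramp_trace(sin(2 * pi * f0 * tt), fs)
    sm <- lowpass_smooth(tr, cutoff)
    max(abs(sm$current[mid]))
  }
  # DC preserved (unit gain at zero frequency, up to float accumulation)
  const <- ramp_trace(rep(2.5e-6, fs), fs)
  expect_equal(lowpass_smooth(const, 3)$current, const$current,
               tolerance = 1e-6)
  # passband: cutoff/6 preserved within 1%
  expect_gt(amp_after(0.5), 0.99)
  # half power (amplitude 1/sqrt(2)) at the cutoff, within 15%
  expect_equal(amp_after(3)^2, 0.5, tolerance = 0.15)
  # strong attenuation far above cutoff
  expect_lt(amp_after(100), 0.05)
  # monotone attenuation above the cutoff
  amps <- vapply(c(4, 8, 16, 32, 64), amp_after, numeric(1))
  expect_true(all(diff(amps) < 0))
  # zero phase: a slow sinusoid peaks at the same sample
  slow <- sin(2 * pi * 0.5 * tt)
  smoothed <- lowpass_smooth(ramp_trace(slow, fs), 3)$current
  expect_equal(which.max(smoothed[mid]), which.max(slow[mid]))
  expect_error(lowpass_smooth(ramp_trace(slow, fs), 1000), "Nyquist")
})

test_that("extract_peak recovers a synthetic peak and its location", {
  cfg <- ref_config()
  tr <- gen_trace(1.0e-6, epa = 0.33, peak_sd = 0.03, config = cfg)
  pk <- extract_peak(tr)
  expect_false(pk$no_peak)
  expect_equal(pk$ipa, 1.0e-6, tolerance = 0.02)
  expect_equal(pk$epa, 0.33, tolerance = 0.005)
})

test_that("extract_peak is exactly invariant to adding a straight line", {
  cfg <- ref_config()
  tr <- gen_trace(1.0e-6, config = cfg)
  pk0 <- extract_peak(tr)
  tr2 <- tr
  tr2$current <- tr$current + 5e-6 + 3e-5 * tr$potential
  pk2 <- extract_peak(tr2)
  expect_equal(pk2$ipa, pk0$ipa, tolerance = 1e-12)
  expect_identical(pk2$epa, pk0$epa)
})

test_that("extract_peak contract cases: no peak, windows, boundary", {
  cfg <- ref_config()
  # zero current: no-peak result, not an error
  flat <- ramp_trace(rep(0, 2000))
  pk <- extract_peak(flat)
  expect_true(pk$no_peak)
  expect_true(is.na(pk$ipa))
  # current strictly below the extrapolated baseline: no-peak
  neg <- gen_trace(0, config = cfg)
  neg$current <- neg$current - 1e-8 * (neg$potential >= 0.25)
  expect_true(extract_peak(neg)$no_peak)
  # peak centred beyond the window end: maximum lands on the edge sample
  edge <- gen_trace(1e-6, epa = 0.48, config = cfg)
  expect_true(extract_peak(edge)$boundary_peak)
  # invalid windows
  tr <- gen_trace(1e-6, config = cfg)
  expect_error(extract_peak(tr, baseline_window = c(0.1, 0.3),
                            peak_window = c(0.25, 0.45)), "overlap")
  expect_error(extract_peak(tr, peak_window = c(0.25, 0.60)), "sweep")
})

test_that("smoothing at a peak-covering cutoff barely changes a clean peak", {
  cfg <- ref_config()
  tr <- gen_trace(1.0e-6, config = cfg)
  raw <- extract_peak(tr)$ipa
  smoothed <- extract_peak(lowpass_smooth(tr, 30))$ipa
  expect_lt(abs(smoothed - raw) / raw, 0.01)
})

test_that("the default 3 Hz cutoff attenuates a narrow synthetic peak", {
  # The synthetic Gaussian peak (sd 0.03 V at 0.4 V/s) has spectral width
  # ~2.1 Hz, overlapping a 3 Hz half-power cutoff: ~12% amplitude loss is
  # inherent to the stated processing, not an implementation defect.
  cfg <- ref_config()
  tr <- gen_trace(1.0e-6, config = cfg)
  ratio <- extract_peak(lowpass_smooth(tr, 3))$ipa / extract_peak(tr)$ipa
  expect_equal(ratio, 0.878, tolerance = 0.02)
})

test_that("trace CSV round trip is lossless including metadata", {
  cfg <- ref_config()
  tr <- gen_trace(1e-6, config = cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$potential, tr$potential, tolerance = 1e-12)
  expect_equal(back$current, tr$current, tolerance = 1e-12)
  expect_equal(back$sampling_rate, tr$sampling_rate)
  expect_equal(back$scan_rate, tr$scan_rate)
  expect_equal(back$meta$true_ipa_A, 1e-6)
})

test_that("trace parser reports missing metadata and malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# scan_rate_V_per_s = 0.4", "potential_V,current_A",
               "0.1,1e-6"), path)
  expect_error(read_trace(path), "sampling_rate_Hz")
  writeLines(c("# sampling_rate_Hz = 2000", "# scan_rate_V_per_s = 0.4",
               "potential_V,current_A", "0.1,1e-6", "0.2,bogus"), path)
  expect_error(read_trace(path), "line 5")
  # shuffled metadata order parses identically
  writeLines(c("# scan_rate_V_per_s = 0.4", "# sampling_rate_Hz = 2000",
               "potential_V,current_A", "0.1,1e-6", "0.2,2e-6"), path)
  tr <- read_trace(path)
  expect_equal(tr$sampling_rate, 2000)
  expect_equal(tr$current, c(1e-6, 2e-6))
})
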
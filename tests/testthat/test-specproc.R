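test_that("smoothing: fixed point, impulse response, variance reduction", {
  const <- new_spectrum(1:50, rep(5, 50))
  expect_equal(smooth_spectrum(const, 5)$intensity, rep(5, 50))
  expect_equal(smooth_spectrum(const, 9, "savitzky_golay")$intensity,
               rep(5, 50))

  impulse <- new_spectrum(1:11, c(rep(0, 5), 1, rep(0, 5)))
  sm <- smooth_spectrum(impulse, 3)
  expect_equal(sm$intensity[5:7], rep(1 / 3, 3))
  expect_equal(sum(sm$intensity), 1)  # interior mass conserved

  set.seed(42)
  noise <- new_spectrum(1:500, abs(rnorm(500)) + 1)
  sm9 <- smooth_spectrum(noise, 9)
  expect_lt(var(sm9$intensity), var(noise$intensity))

  expect_error(smooth_spectrum(const, 4), "odd")
  expect_error(smooth_spectrum(const, 51), "length")
})

test_that("SNIP baseline: reconstruction, bounds, exponential removal", {
  mz <- seq(2000, 12000, by = 2)
  base <- 10 * exp(-mz / 3000)
  sp <- new_spectrum(mz, base)
  res <- remove_baseline(sp, 60)
  expect_equal(res$corrected$intensity + res$baseline$intensity,
               sp$intensity)
  expect_true(all(res$baseline$intensity <= sp$intensity + 1e-12))
  expect_true(all(res$corrected$intensity >= 0))
  # pure baseline, no peaks: almost everything removed
  expect_lt(max(res$corrected$intensity), 0.02 * max(sp$intensity))

  zero <- new_spectrum(mz, rep(0, length(mz)))
  rz <- remove_baseline(zero, 10)
  expect_equal(max(rz$corrected$intensity), 0)
  expect_equal(max(rz$baseline$intensity), 0)
})

test_that("SNIP preserves baseline-free peak apexes within 5%", {
  panel <- globin_panel()
  prof <- disease_profile("control", c(alpha = 0.8, beta = 0.6, gamma = 0.1),
                          between_sample_cv = 0)
  sp <- simulate_spectrum(panel, prof, quiet_acq(), seed = 1)$spectrum
  res <- remove_baseline(sp, 60)
  for (centre in c(15127.4, 15868.2, 16953.0)) {
    win <- abs(sp$mz - centre) < 30
    before <- max(sp$intensity[win])
    after <- max(res$corrected$intensity[win])
    expect_lt(abs(after - before) / before, 0.05)
  }
})

test_that("pick_peaks finds exactly the injected apexes at zero noise", {
  panel <- globin_panel()
  prof <- disease_profile("beta_thal", c(alpha = 1, beta = 0.5, gamma = 0.2),
                          between_sample_cv = 0)
  acq <- quiet_acq()
  sp <- simulate_spectrum(panel, prof, acq, seed = 1)$spectrum
  peaks <- pick_peaks(sp, snr_min = 3, min_spacing = 10)
  expect_equal(nrow(peaks), 8)  # 4 species x 2 charges
  expected <- sort(unlist(lapply(c("alpha", "beta", "gamma",
                                   "internal_standard"), function(s) {
    c(mz_reference(panel, s, 1), mz_reference(panel, s, 2))
  })))
  expect_true(all(abs(peaks$mz_obs - expected) <= acq$sampling_step))
  expect_false(is.unsorted(peaks$mz_obs))
})

test_that("pick_peaks false-positive rate under the noise model is below 1", {
  # Monte-Carlo over the generator's noise model: exponential baseline plus
  # additive Gaussian noise truncated at zero, no peaks, then the standard
  # smooth / SNIP / pick chain
  mz <- seq(2000, 6000, by = 2)
  base <- 0.05 * exp(-mz / 3000)
  n_fp <- vapply(1:100, function(s) {
    set.seed(s)
    y <- pmax(base + rnorm(length(mz), 0, 0.002), 0)
    sp <- smooth_spectrum(new_spectrum(mz, y), 7)
    corr <- remove_baseline(sp, 60)$corrected
    nrow(pick_peaks(corr, snr_min = 5, min_spacing = 10))
  }, numeric(1))
  expect_lte(mean(n_fp), 1)
})

test_that("pick_peaks merges peaks closer than min_spacing, keeping the taller", {
  y <- rep(0, 30)
  y[10] <- 1; y[11] <- 0.2; y[12] <- 0.8   # two maxima 2 Th apart
  sp <- new_spectrum(1:30, y)
  peaks <- pick_peaks(sp, snr_min = 0, min_spacing = 5)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$mz_obs, 10)
  expect_equal(peaks$intensity, 1)
  # all-zero spectrum: empty list, not an error
  expect_equal(nrow(pick_peaks(new_spectrum(1:30, rep(0, 30)), 3, 5)), 0)
})

test_that("one-point IS recalibration inverts an injected ppm shift", {
  panel <- globin_panel()
  prof <- disease_profile("beta_thal", c(alpha = 1, beta = 0.8, gamma = 0.1),
                          between_sample_cv = 0)
  acq <- acquisition_model(mz_range = c(7000, 18000), sampling_step = 0.1,
                           noise_sd = 0, baseline_amplitude = 0,
                           calibration_shift_ppm = 1000)
  sp <- simulate_spectrum(panel, prof, acq, seed = 1)$spectrum
  peaks <- pick_peaks(sp, snr_min = 3, min_spacing = 10)
  cal <- calibrate_mz(peaks, panel, search_ppm = 5000)
  expect_false(cal$calibration_failed)
  expect_equal(cal$correction_factor, 1 / 1.001, tolerance = 1e-5)
  beta_ref <- mz_reference(panel, "beta", 1)
  obs <- cal$peaks$mz_obs[which.min(abs(cal$peaks$mz_obs - beta_ref))]
  expect_lt(abs((obs - beta_ref) / beta_ref * 1e6), 20)
})

test_that("calibration is exact at zero shift and idempotent", {
  panel <- globin_panel()
  ref_is <- mz_reference(panel, "internal_standard", 1)
  peaks <- data.frame(mz_obs = c(mz_reference(panel, "beta", 1), ref_is),
                      intensity = c(1, 2), snr = c(10, 10))
  cal <- calibrate_mz(peaks, panel)
  expect_identical(cal$correction_factor, 1)
  cal2 <- calibrate_mz(cal$peaks, panel)
  expect_lt(abs(cal2$correction_factor - 1), 1e-9)
})

test_that("missing internal standard flags calibration failure", {
  peaks <- data.frame(mz_obs = c(15127.4, 15868.2), intensity = c(1, 1),
                      snr = c(10, 10))
  cal <- calibrate_mz(peaks, globin_panel())
  expect_true(cal$calibration_failed)
  expect_true(is.na(cal$correction_factor))
  expect_true(calibrate_mz(peaks[0, ], globin_panel())$calibration_failed)
})

test_that("peak matching applies the 3000 ppm window greedily and uniquely", {
  panel <- globin_panel()
  beta_ref <- mz_reference(panel, "beta", 1)
  # 15,900.0 is ~2004 ppm from the beta 1+ reference: assigned
  p1 <- data.frame(mz_obs = 15900, intensity = 1, snr = 10)
  a1 <- match_peaks(p1, panel)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$species, "beta")
  expect_equal(a1$charge, 1L)
  expect_equal(a1$ppm_error, (15900 - beta_ref) / beta_ref * 1e6)
  expect_lt(abs(a1$ppm_error - 2003.6), 1)
  # 16,000.0 is ~8305 ppm away: not assigned to beta (and ~3000+ from IS too)
  a2 <- match_peaks(data.frame(mz_obs = 16000, intensity = 1, snr = 10),
                    panel)
  expect_false(any(a2$species == "beta"))
  # an exact reference m/z gives zero ppm error
  a3 <- match_peaks(data.frame(mz_obs = beta_ref, intensity = 1, snr = 10),
                    panel)
  expect_equal(a3$ppm_error, 0)
  # two candidates for one slot: the closer wins, the other stays unassigned
  p4 <- data.frame(mz_obs = c(beta_ref + 1, beta_ref + 20),
                   intensity = c(1, 2), snr = c(10, 10))
  a4 <- match_peaks(p4, panel)
  expect_equal(sum(a4$species == "beta" & a4$charge == 1), 1)
  expect_equal(a4$mz_obs[a4$species == "beta"], beta_ref + 1)
  expect_true(all(abs(a4$ppm_error) <= 3000))
  expect_false(anyDuplicated(paste(a4$species, a4$charge)) > 0)
})

test_that("IS normalisation divides by same-charge IS with 1+ fallback", {
  a <- make_assignments(c("beta", "internal_standard"), c(1, 1),
                        c(1200, 600))
  n <- normalize_assignments(a)
  expect_equal(n$intensity_norm[n$species == "beta"], 2)
  expect_equal(n$intensity_norm[n$species == "internal_standard"], 1)

  # whole-spectrum scaling leaves normalised intensities unchanged (exact)
  a10 <- a; a10$intensity_raw <- a10$intensity_raw * 10
  expect_identical(normalize_assignments(a10)$intensity_norm,
                   n$intensity_norm)

  # IS 2+ missing: gamma 2+ falls back to IS 1+ with a flag
  b <- make_assignments(c("gamma", "internal_standard"), c(2, 1), c(30, 600))
  nb <- normalize_assignments(b)
  expect_equal(nb$intensity_norm[nb$species == "gamma"], 0.05)
  expect_true("is2_fallback" %in% attr(nb, "qc_flags"))

  # one_plus mode always divides by IS 1+
  c2 <- make_assignments(c("beta", "internal_standard", "internal_standard"),
                         c(2, 1, 2), c(100, 400, 200))
  n2 <- normalize_assignments(c2, method = "one_plus")
  expect_equal(n2$intensity_norm[n2$species == "beta"], 0.25)
  n2s <- normalize_assignments(c2, method = "same_charge")
  expect_equal(n2s$intensity_norm[n2s$species == "beta"], 0.5)

  # no IS at all: sample-level QC failure flag
  d <- make_assignments("beta", 1, 100)
  nd <- normalize_assignments(d)
  expect_true("is_missing" %in% attr(nd, "qc_flags"))
})

test_that("end-to-end beta quantification tracks abundance within 2%", {
  panel <- globin_panel()
  acq <- acquisition_model(noise_sd = 0, calibration_shift_ppm = 1000)
  ladder <- seq(0.2, 2, length.out = 10)
  norm_beta <- vapply(ladder, function(b) {
    prof <- disease_profile("beta_thal", c(alpha = 1, beta = b, gamma = 0.1),
                            between_sample_cv = 0)
    sp <- simulate_spectrum(panel, prof, acq, seed = 1)$spectrum
    a <- process_spectrum(sp, panel)$assignments
    a$intensity_norm[a$species == "beta" & a$charge == 1]
  }, numeric(1))
  slope <- median(norm_beta / ladder)
  expect_lt(max(abs(norm_beta - slope * ladder) / (slope * ladder)), 0.02)
})

test_that("process_spectrum reports QC flags for missing slots", {
  panel <- globin_panel()
  prof <- disease_profile("control", c(alpha = 1, beta = 1, gamma = 0),
                          between_sample_cv = 0)
  proc <- process_spectrum(
    simulate_spectrum(panel, prof, quiet_acq(), seed = 2)$spectrum, panel)
  expect_true(all(c("slot_missing:gamma_1", "slot_missing:gamma_2") %in%
                    proc$qc_flags))
  expect_equal(nrow(proc$assignments), 6)
})
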
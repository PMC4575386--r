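# Smoothing, baseline estimation/subtraction, calibration reference
# selection and sqrt-domain recalibration.

test_that("moving-average smoothing matches an explicit convolution", {
  sp <- flat_spectrum(value = 42, n = 300)
  expect_equal(smooth_spectrum(sp, 50)$intensity, rep(42, 300))
  expect_identical(smooth_spectrum(sp, 1), sp)

  # unit impulse, window 51: oracle is a direct loop over shrinking windows
  x <- rep(0, 201); x[101] <- 1
  imp <- raw_spectrum(seq_len(201) + 2000, x)
  sm <- smooth_spectrum(imp, 51)$intensity
  oracle <- vapply(seq_along(x), function(i) {
    win <- max(1, i - 25):min(length(x), i + 25)
    mean(x[win])
  }, numeric(1))
  expect_equal(sm, oracle)
  expect_true(all(abs(sm[76:126] - 1 / 51) < 1e-12))
  expect_error(smooth_spectrum(flat_spectrum(n = 10), 50), "exceeds")
})

test_that("smoothing preserves total ion current of interior signals", {
  set.seed(11)
  x <- rep(0, 2000)
  x[500:1500] <- abs(rnorm(1001, 100, 20))
  sp <- raw_spectrum(seq_len(2000) + 2000, x)
  sm <- smooth_spectrum(sp, 50)
  expect_equal(sum(sm$intensity), sum(x), tolerance = 0.005)
})

test_that("baseline estimation recovers smooth baselines and ignores peaks", {
  fl <- flat_spectrum(100, n = 2000)
  bl <- estimate_baseline(fl, 100)
  expect_equal(bl[200:1800], rep(100, 1601))

  # decaying exponential, no peaks/noise: oracle is the analytic curve
  mz <- seq(2000, 20000, by = 0.2)
  amp <- 150
  truth <- amp * exp(-(mz - 2000) / 3000)
  sp <- raw_spectrum(mz, truth)
  est <- estimate_baseline(sp, 100)
  expect_lt(max(abs(est - truth)), 0.02 * amp)

  # a narrow peak on a zero baseline is not absorbed
  x <- rep(0, 2000)
  x[1000 + (-10:10)] <- 500 * exp(-((-10:10)^2) / 18)
  pk <- raw_spectrum(seq_len(2000) + 2000, x)
  expect_lt(max(estimate_baseline(pk, 100)[990:1010]), 1e-9)
  expect_error(estimate_baseline(flat_spectrum(n = 50), 100), "exceeds")
  expect_error(estimate_baseline(fl, 2), "at least 3")
})

test_that("baseline subtraction clips at zero and reports the clip count", {
  sp <- flat_spectrum(100, n = 500)
  zero <- subtract_baseline(sp, sp$intensity)
  expect_true(all(zero$intensity == 0))
  same <- subtract_baseline(sp, rep(0, 500))
  expect_equal(same$intensity, sp$intensity)
  expect_equal(same$n_clipped, 0L)
  over <- subtract_baseline(sp, rep(c(90, 110), each = 250))
  expect_true(all(over$intensity >= 0))
  expect_equal(over$n_clipped, 250L)
  expect_error(subtract_baseline(sp, rep(0, 10)), "length")
})

test_that("calibration references are majority-held and evenly spread", {
  masses <- seq(3000, 18000, length.out = 20)
  mk <- function(masses, id) {
    peak_list(data.frame(mass = masses,
                         abundance = rep(500, length(masses)),
                         snr = rep(20, length(masses))), sample_id = id)
  }
  lists <- lapply(1:12, function(i) mk(masses, paste0("s", i)))
  refs <- select_calibration_peaks(lists, n_refs = 10)
  expect_length(refs, 10)
  expect_true(all(vapply(refs, function(r) any(abs(masses - r) < 1e-9),
                         logical(1))))
  expect_equal(refs, sort(refs))

  # a peak present in only 1 of 12 spectra is never selected
  lists2 <- lists
  lists2[[1]] <- mk(sort(c(masses, 9999)), "s1")
  refs2 <- select_calibration_peaks(lists2, n_refs = 19)
  expect_false(any(abs(refs2 - 9999) < 1))

  # fewer qualifying clusters than requested: returned with a warning
  lists3 <- lapply(1:6, function(i) mk(masses[1:5], paste0("s", i)))
  expect_warning(refs3 <- select_calibration_peaks(lists3, n_refs = 10),
                 "only 5")
  expect_length(refs3, 5)
  expect_error(select_calibration_peaks(lists[1:2]), "at least 3")
})

test_that("sqrt-domain recalibration inverts a known affine drift", {
  true_masses <- seq(3000, 17000, length.out = 10)
  drift <- function(m) (1.0005 * sqrt(m) + 0.002)^2
  pl <- peak_list(data.frame(mass = drift(true_masses),
                             abundance = rep(500, 10), snr = rep(20, 10)),
                  sample_id = "s")
  cal <- calibrate(pl, true_masses)
  # the fitted inverse slope undoes the synthetic drift
  expect_equal(cal$calibration$a, 1 / 1.0005, tolerance = 1e-5)
  err_17k <- abs((cal$calibration$a * sqrt(drift(17000)) +
                    cal$calibration$b)^2 - 17000)
  expect_lt(err_17k, 0.5)
  expect_equal(cal$peaks$mass, true_masses, tolerance = 1e-6)

  # identity drift: fitted map stays (numerically) the identity
  pl0 <- peak_list(data.frame(mass = true_masses, abundance = rep(500, 10),
                              snr = rep(20, 10)), sample_id = "s")
  cal0 <- calibrate(pl0, true_masses)
  expect_equal(cal0$calibration$a, 1, tolerance = 1e-9)
  expect_equal(cal0$peaks$mass, true_masses, tolerance = 1e-9)

  # calibration never worsens the RMS residual, and is idempotent
  pre <- sqrt(mean((drift(true_masses) - true_masses)^2))
  post <- sqrt(mean(cal$calibration$residuals_post_da^2))
  expect_lte(post, pre)
  cal2 <- calibrate(cal, true_masses)
  expect_equal(cal2$peaks$mass, cal$peaks$mass, tolerance = 1e-9)

  # a single matchable reference is underdetermined
  one <- peak_list(data.frame(mass = 5000, abundance = 500, snr = 20),
                   sample_id = "s")
  expect_error(calibrate(one, true_masses), "fewer than 2")
})

test_that("spectra can be calibrated through their detected peaks", {
  pk <- test_peaks_df(masses = seq(4000, 16000, length.out = 6),
                      abundance = rep(2000, 6))
  m <- test_model(pk, grid_step = 0.2)
  sp <- preprocess_spectrum(simulate_spectrum(m, "tox", 1, FALSE, seed = 1))
  # impose a known drift on the axis, then calibrate back
  drifted <- sp
  drifted$mz <- (1.0003 * sqrt(sp$mz) - 0.001)^2
  cal <- calibrate(drifted, reference_masses = pk$mass)
  pl <- detect_peaks(cal)
  expect_equal(pl$peaks$mass, pk$mass, tolerance = 1e-4)
  expect_s3_class(cal$calibration, "calibration_model")
})
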
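test_that("welch psd realizes 0.5 Hz bins and localizes tones", {
  rec0 <- make_recording(rep(0, 5000))
  psd0 <- welch_psd(rec0)
  expect_equal(diff(psd0$freqs[1:2]), 0.5)
  expect_true(all(psd0$power == 0))

  psd10 <- welch_psd(make_recording(sinusoid(10)))
  expect_equal(psd10$freqs[which.max(psd10$power)], 10)
})

test_that("welch psd satisfies Parseval against a direct periodogram", {
  set.seed(7)
  x <- rnorm(5000)
  psd <- welch_psd(make_recording(x))
  total <- sum(psd$power) * 0.5
  expect_equal(total, 1, tolerance = 0.1)
  # independent oracle: raw one-sided periodogram of the same signal
  X <- fft(x)[1:2501]
  raw <- Mod(X)^2 / (250 * 5000)
  raw[2:2500] <- 2 * raw[2:2500]
  expect_equal(total, sum(raw) * 0.05, tolerance = 0.1)
})

test_that("welch psd of a stationary process is shift-invariant in expectation", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.6), 5000))
  base <- welch_psd(make_recording(x))
  band0 <- band_power(base, 3, 40)
  shifted <- vapply(1:10, function(i) {
    k <- sample.int(4999, 1)
    band_power(welch_psd(make_recording(c(x[(k + 1):5000], x[1:k]))), 3, 40)
  }, numeric(1))
  expect_equal(mean(shifted), band0, tolerance = 0.05)
})

test_that("gapped windows are excluded and too-gappy recordings error", {
  set.seed(9)
  x <- rnorm(5000)
  gm <- rep(FALSE, 5000)
  gm[1000:1300] <- TRUE
  with_gap <- welch_psd(make_recording(x, gap_mask = gm))
  # the same signal with the gap region zeroed yields identical spectrum:
  # proof that gapped windows are skipped, not used
  x2 <- x; x2[1000:1300] <- 0
  with_gap2 <- welch_psd(make_recording(x2, gap_mask = gm))
  expect_equal(with_gap$power, with_gap2$power)

  gm_all <- rep(TRUE, 5000)
  expect_error(welch_psd(make_recording(x, gap_mask = gm_all)), "insufficient")
})

test_that("session averaging is the per-bin arithmetic mean", {
  p <- model_spectrum()
  expect_equal(average_session_psd(list(p))$power, p$power)
  expect_equal(average_session_psd(list(p, p))$power, p$power)
  p3 <- power_spectrum(p$freqs, 3 * p$power, "absolute")
  expect_equal(average_session_psd(list(p, p3))$power, 2 * p$power)
  bad <- power_spectrum(p$freqs + 1, p$power, "absolute")
  expect_error(average_session_psd(list(p, bad)), "grid")
})

test_that("relative spectra are percentages of 3-100 Hz power", {
  f <- seq(0, 125, 0.5)
  flat <- power_spectrum(f, rep(2, length(f)), "absolute")
  rel <- relative_spectrum(flat)
  sel <- f >= 3 & f <= 100
  expect_equal(sum(rel$power[sel]), 100, tolerance = 1e-9)
  expect_equal(length(unique(round(rel$power, 12))), 1)
  # scale invariance
  rel2 <- relative_spectrum(power_spectrum(f, 2 * flat$power, "absolute"))
  expect_equal(rel2$power, rel$power)
  # single nonzero bin
  one <- rep(0, length(f)); one[f == 10] <- 5
  rel3 <- relative_spectrum(power_spectrum(f, one, "absolute"))
  expect_equal(rel3$power[f == 10], 100)
  expect_true(all(rel3$power[f != 10] == 0))
})

test_that("the Lorentzian aperiodic model honors its anchor points", {
  expect_equal(aperiodic_model(1, A = 7, f_k = 3, chi = 1.8, f_min = 1), 7)
  expect_equal(aperiodic_model(1e-3, A = 2, f_k = 0.2, chi = 2, f_min = 1e-3), 2)
  # chi = 0: flat
  f <- c(1, 5, 20, 64)
  expect_equal(aperiodic_model(f, 4, 2, 0, 1), rep(4, 4))
  # far knee: power decays to ~A/2 at f = f_k
  val <- aperiodic_model(100, A = 1, f_k = 100, chi = 2, f_min = 1)
  expect_equal(val, (100^2 + 1) / (2 * 100^2), tolerance = 1e-12)
  expect_equal(val, 0.5, tolerance = 1e-4)
  expect_error(aperiodic_model(-1, 1, 1, 1), "positive")
})

test_that("specparam recovers its own generating model", {
  # noiseless, no peaks
  fit <- specparam(model_spectrum(A = 10, f_k = 0.5, chi = 1.5))
  expect_lt(abs(fit$aperiodic$chi - 1.5), 0.05)
  expect_equal(nrow(fit$peaks), 0)
  expect_gt(fit$r_squared, 0.999)
  expect_false(classify_knee(fit))

  # aperiodic + one alpha peak + small noise
  set.seed(10)
  psd <- model_spectrum(peaks = data.frame(a = 0.4, f_c = 10, w = 1.5),
                        noise_sd = 0.02)
  fit2 <- specparam(psd)
  alpha <- fit2$peaks[fit2$peaks$f_c >= 7 & fit2$peaks$f_c <= 14, ]
  alpha <- alpha[which.max(alpha$a), ]
  expect_lt(abs(alpha$f_c - 10), 0.25)
  expect_lt(abs(alpha$w - 1.5), 0.5)

  # knee spectrum classifies as kneed
  fit3 <- specparam(model_spectrum(A = 5, f_k = 8, chi = 2.2))
  expect_true(classify_knee(fit3))
  expect_lt(abs(fit3$aperiodic$f_k - 8), 0.5)
})

test_that("the peak cap holds even with many well-separated peaks", {
  pks <- data.frame(a = rep(0.5, 10), f_c = seq(6, 60, length.out = 10), w = 1.2)
  fit <- specparam(model_spectrum(peaks = pks))
  expect_lte(nrow(fit$peaks), 8)
})

test_that("periodic spectra are aperiodic residuals and scale-invariant", {
  psd <- model_spectrum(A = 10, f_k = 0.4, chi = 1.6)
  fit <- specparam(psd)
  per <- periodic_spectrum(psd, fit)
  expect_lt(max(abs(per$power)), 1e-3)

  pk <- data.frame(a = 0.35, f_c = 11, w = 1.5)
  psd2 <- model_spectrum(A = 10, f_k = 0.4, chi = 1.6, peaks = pk)
  per2 <- periodic_spectrum(psd2, specparam(psd2))
  bump <- pk$a * exp(-(per2$freqs - pk$f_c)^2 / (2 * pk$w^2))
  expect_lt(max(abs(per2$power - bump)), 0.02)

  # multiplying the absolute spectrum shifts A, leaving the residual alone
  psd3 <- power_spectrum(psd2$freqs, 10 * psd2$power, "absolute")
  per3 <- periodic_spectrum(psd3, specparam(psd3))
  expect_equal(per3$power, per2$power, tolerance = 1e-3)
})

test_that("knee classification uses a strict threshold at f_min", {
  fake <- function(f_k) structure(list(aperiodic = list(f_k = f_k, f_min = 1)),
                                  class = "specparam")
  expect_false(classify_knee(fake(0.3)))
  expect_true(classify_knee(fake(5)))
  expect_false(classify_knee(fake(1)))
})

test_that("negative-frequency peak mass is non-increasing in lambda", {
  set.seed(12)
  # a broad low-frequency peak tempts mass over negative frequencies
  psd <- model_spectrum(A = 10, f_k = 0.3, chi = 1.2,
                        peaks = data.frame(a = 0.5, f_c = 2, w = 6),
                        noise_sd = 0.01)
  masses <- vapply(c(0, 100, 10000), function(l) {
    fit <- specparam(psd, specparam_settings(lambda = l))
    alphadbs:::.neg_freq_mass(fit$peaks)
  }, numeric(1))
  expect_true(all(diff(masses) <= 1e-8))
})

test_that("parameter recovery holds across the generator priors", {
  set.seed(13)
  n <- 40
  chi_err <- fc_err <- r2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    chi <- runif(1, 1, 2)
    a <- runif(1, 0.2, 0.6); fc <- runif(1, 8, 12); w <- runif(1, 1, 2)
    psd <- model_spectrum(A = runif(1, 2, 20), f_k = runif(1, 0.05, 0.5),
                          chi = chi, peaks = data.frame(a = a, f_c = fc, w = w),
                          noise_sd = 0.05)
    fit <- specparam(psd)
    chi_err[i] <- abs(fit$aperiodic$chi - chi)
    apk <- fit$peaks[fit$peaks$f_c >= 7 & fit$peaks$f_c <= 14, ]
    fc_err[i] <- if (nrow(apk) > 0) abs(apk$f_c[which.max(apk$a)] - fc) else NA
    r2[i] <- fit$r_squared
  }
  expect_lt(median(chi_err), 0.1)
  expect_lt(median(fc_err, na.rm = TRUE), 0.25)
  expect_gt(mean(r2), 0.95)
})
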
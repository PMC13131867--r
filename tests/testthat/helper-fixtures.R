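# shared fixture builders; everything is generated in code at test time

make_recording <- function(samples, fs = 250, pair = c(0, 1), gap_mask = NULL,
                           patient = "P01", hemisphere = "L", session = 1,
                           date = "2024-01-15") {
  recording(patient, hemisphere, session, pair, samples, fs = fs,
            gap_mask = gap_mask, recorded_at = date)
}

sinusoid <- function(freq, fs = 250, duration_s = 20, amplitude = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  amplitude * sin(2 * pi * freq * t + phase)
}

# tiny default-physics cohort for integration tests
small_cohort <- function(n_patients = 3, n_sessions = 2, seed = 11, ...) {
  simulate_cohort(generator_config(n_patients = n_patients,
                                   n_sessions = n_sessions, ...), seed = seed)
}

fit_grid <- function() seq(1, 65, by = 0.5)

# model spectrum on the fit grid: aperiodic + optional peaks (log10 units)
model_spectrum <- function(A = 10, f_k = 0.5, chi = 1.5, peaks = NULL,
                           freqs = fit_grid(), noise_sd = 0, f_min = 1) {
  lp <- log10(aperiodic_model(freqs, A, f_k, chi, f_min))
  if (!is.null(peaks))
    for (i in seq_len(nrow(peaks)))
      lp <- lp + peaks$a[i] * exp(-(freqs - peaks$f_c[i])^2 / (2 * peaks$w[i]^2))
  if (noise_sd > 0) lp <- lp + stats::rnorm(length(freqs), sd = noise_sd)
  power_spectrum(freqs, 10^lp, kind = "absolute")
}
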
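#' Construct a power spectrum object
#'
#' Container for a one-sided power spectral density on a uniform frequency
#' grid. Three kinds circulate through the pipeline: \code{"absolute"}
#' (µV²/Hz), \code{"relative"} (percent of 3–100 Hz total) and
#' \code{"periodic"} (log10-power residual above the aperiodic fit).
#'
#' @param freqs Strictly increasing, uniformly spaced frequency grid (Hz).
#' @param power Power values, same length as \code{freqs}.
#' @param kind One of \code{"absolute"}, \code{"relative"}, \code{"periodic"}.
#' @param source Optional identifier of the originating recording.
#' @return An object of class \code{power_spectrum}.
#' @export
power_spectrum <- function(freqs, power, kind = c("absolute", "relative", "periodic"),
                           source = NULL) {
  kind <- match.arg(kind)
  freqs <- as.numeric(freqs)
  power <- as.numeric(power)
  if (length(freqs) != length(power)) stop("freqs and power must have equal length")
  if (length(freqs) > 1) {
    d <- diff(freqs)
    if (any(d <= 0)) stop("freqs must be strictly increasing")
    if (max(d) - min(d) > 1e-8 * max(d)) stop("freqs must be uniformly spaced")
  }
  if (kind == "absolute" && any(power < -1e-12)) stop("absolute power must be nonnegative")
  structure(list(freqs = freqs, power = power, kind = kind, source = source),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum: %s, %d bins, %.1f-%.1f Hz, df = %.2f Hz>\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs),
              if (length(x$freqs) > 1) diff(x$freqs[1:2]) else NA_real_))
  invisible(x)
}

#' Welch power spectral density of a recording
#'
#' Estimates the one-sided PSD with 1-second Hann windows at 50% overlap.
#' The FFT of each window is zero-padded to twice the window length, which
#' yields 0.5 Hz frequency bins at the nominal 250 Hz sampling rate. Windows
#' that contain any reconstructed (gap-masked) sample are skipped so that
#' interpolated stretches cannot bias the spectrum.
#'
#' @param rec A \code{recording} object (see \code{\link{recording}}).
#' @return A \code{power_spectrum} of kind \code{"absolute"} in µV²/Hz.
#' @export
welch_psd <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  x <- rec$samples
  n <- round(fs)              # 1-second window
  if (length(x) < 2 * n) stop("insufficient clean data: recording shorter than 2 s")
  hop <- n %/% 2
  starts <- seq(1, length(x) - n + 1, by = hop)
  gm <- rec$gap_mask
  valid <- vapply(starts, function(s) !any(gm[s:(s + n - 1)]), logical(1))
  starts <- starts[valid]
  if (length(starts) < 3) stop("insufficient clean data: fewer than 3 gap-free windows")
  nfft <- 2L * n              # zero-pad to realize fs/(2n) = 0.5 Hz bins
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))   # periodic Hann
  U <- sum(w^2)
  nfreq <- nfft %/% 2 + 1L
  segs <- matrix(0, nfft, length(starts))
  for (j in seq_along(starts))
    segs[seq_len(n), j] <- x[starts[j]:(starts[j] + n - 1)] * w
  X <- stats::mvfft(segs)[seq_len(nfreq), , drop = FALSE]
  psd <- rowSums(Mod(X)^2) / (length(starts) * fs * U)
  # one-sided: double everything except DC and Nyquist
  psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  freqs <- (0:(nfreq - 1)) * fs / nfft
  power_spectrum(freqs, psd, kind = "absolute",
                 source = recording_id(rec))
}

#' Average repeated spectra within a session
#'
#' Clean repeats of the same bipolar pair within a session are combined by the
#' arithmetic mean per frequency bin before spectral parameterization, so each
#' pair contributes one spectrum per session.
#'
#' @param spectra List of \code{power_spectrum} objects on identical grids.
#' @return A single \code{power_spectrum}.
#' @export
average_session_psd <- function(spectra) {
  if (length(spectra) == 0) stop("no spectra to average")
  f0 <- spectra[[1]]$freqs
  for (s in spectra) {
    if (length(s$freqs) != length(f0) || any(abs(s$freqs - f0) > 1e-9))
      stop("mismatched frequency grids")
  }
  pw <- rowMeans(vapply(spectra, function(s) s$power, numeric(length(f0))))
  power_spectrum(f0, pw, kind = spectra[[1]]$kind, source = spectra[[1]]$source)
}

#' Relative power spectrum
#'
#' Converts an absolute spectrum to percentage units by dividing each bin by
#' the sum of power over the 3–100 Hz range and multiplying by 100.
#'
#' @param psd A \code{power_spectrum} of kind \code{"absolute"}.
#' @return A \code{power_spectrum} of kind \code{"relative"}; its values sum
#'   to 100 over 3–100 Hz.
#' @export
relative_spectrum <- function(psd) {
  stopifnot(inherits(psd, "power_spectrum"), psd$kind == "absolute")
  if (min(psd$freqs) > 3 || max(psd$freqs) < 100)
    stop("grid must cover 3-100 Hz")
  sel <- psd$freqs >= 3 & psd$freqs <= 100
  tot <- sum(psd$power[sel])
  if (tot <= 0) stop("zero total power in 3-100 Hz range")
  power_spectrum(psd$freqs, 100 * psd$power / tot, kind = "relative",
                 source = psd$source)
}
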
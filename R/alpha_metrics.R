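#' Mean band power by trapezoidal integration
#'
#' Average power over a frequency band: the trapezoidal integral of the
#' spectrum over [lo, hi] divided by the band width. Endpoints falling
#' between grid nodes are linearly interpolated.
#'
#' @param spec A \code{power_spectrum}.
#' @param lo,hi Band edges, Hz, with \code{lo < hi}, inside the grid.
#' @return Mean power over the band (same units as the spectrum).
#' @export
band_power <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (lo >= hi) stop("lo must be < hi")
  f <- spec$freqs; p <- spec$power
  if (lo < min(f) || hi > max(f)) stop("band outside the frequency grid")
  inner <- f > lo & f < hi
  fb <- c(lo, f[inner], hi)
  pb <- c(stats::approx(f, p, xout = lo)$y, p[inner],
          stats::approx(f, p, xout = hi)$y)
  pracma::trapz(fb, pb) / (hi - lo)
}

#' Individual alpha peak frequency
#'
#' The fitted Gaussian peak with center frequency in the alpha band of
#' largest amplitude, if any; otherwise the frequency of the largest interior
#' local maximum of the periodic spectrum within the band; otherwise absent
#' (\code{NA}).
#'
#' @param fit A \code{specparam} fit (or NULL to force the fallback path).
#' @param periodic The \code{power_spectrum} of kind \code{"periodic"}.
#' @param band Alpha band, Hz (default c(7, 14)).
#' @return Peak frequency in Hz, or \code{NA_real_} if none.
#' @export
individual_alpha_peak <- function(fit, periodic, band = c(7, 14)) {
  if (!is.null(fit)) {
    pk <- fit$peaks
    inb <- pk$f_c >= band[1] & pk$f_c <= band[2]
    if (any(inb)) {
      pk <- pk[inb, , drop = FALSE]
      return(pk$f_c[which.max(pk$a)])
    }
  }
  stopifnot(inherits(periodic, "power_spectrum"))
  f <- periodic$freqs; p <- periodic$power
  sel <- which(f >= band[1] & f <= band[2])
  if (length(sel) < 3) return(NA_real_)
  i <- sel[-c(1, length(sel))]
  locmax <- i[p[i] > p[i - 1] & p[i] > p[i + 1]]
  if (length(locmax) == 0) return(NA_real_)
  f[locmax[which.max(p[locmax])]]
}

#' Narrowband power around the individual alpha peak
#'
#' Mean power in the ±2.5 Hz interval centered on the individual peak
#' frequency; the window is clipped to the grid if it overruns an edge.
#'
#' @param spec A \code{power_spectrum}.
#' @param peak Individual peak frequency, Hz.
#' @param halfwidth Half window width, Hz (default 2.5).
#' @return Mean power over the (possibly clipped) window.
#' @export
peak_alpha_power <- function(spec, peak, halfwidth = 2.5) {
  if (is.null(peak) || is.na(peak))
    stop("no individual peak available; use the canonical band instead")
  lo <- max(peak - halfwidth, min(spec$freqs))
  hi <- min(peak + halfwidth, max(spec$freqs))
  band_power(spec, lo, hi)
}

#' Summarize alpha power within a hemisphere
#'
#' Reduces the per-pair alpha values of one hemisphere (up to 6 bipolar
#' pairs) to a single number, either the maximum over pairs or their mean.
#'
#' @param values Numeric vector of per-pair alpha values.
#' @param strategy "max_pair" or "mean_pairs".
#' @return A single number.
#' @export
hemisphere_summary <- function(values, strategy = c("max_pair", "mean_pairs")) {
  strategy <- match.arg(strategy)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no pair values to summarize")
  if (strategy == "max_pair") max(values) else mean(values)
}

#' Min-max normalization within a lead
#'
#' Maps values to [0, 1] by (v - min)/(max - min), computed within each lead.
#' Degenerate leads (max == min) map to all zeros and raise the
#' \code{"degenerate"} attribute so cohort runs do not abort.
#'
#' @param values Numeric vector (>= 2 values, one lead).
#' @return Normalized values in [0, 1]; attribute \code{"degenerate"} is TRUE
#'   when the input range was zero.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  rng <- range(values)
  if (rng[2] == rng[1]) {
    out <- rep(0, length(values))
    attr(out, "degenerate") <- TRUE
    warning("degenerate lead: all values equal; normalized to 0")
    return(out)
  }
  out <- (values - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}
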
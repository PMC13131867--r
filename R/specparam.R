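#' Lorentzian aperiodic spectral model with knee
#'
#' Evaluates the aperiodic component
#' \deqn{L(f) = A \frac{f_k^\chi + f_{min}^\chi}{f_k^\chi + f^\chi}}
#' where \eqn{A} is the power fitted at the minimal reliable frequency
#' \eqn{f_{min}}, \eqn{f_k} the knee frequency at which the log-log slope
#' changes, and \eqn{\chi} the aperiodic exponent governing the decay above
#' the knee. For \eqn{f_k \gg f_{min}} the power decays to \eqn{A/2} at
#' \eqn{f = f_k}. Spectra with no knee are encoded by \eqn{f_k < f_{min}}.
#'
#' @param f Frequencies (Hz), all \eqn{\ge f_{min} > 0}.
#' @param A Aperiodic offset (power at \code{f_min}).
#' @param f_k Knee frequency (Hz).
#' @param chi Aperiodic exponent (log-log slope above the knee).
#' @param f_min Minimal reliable frequency (Hz), default 1.
#' @return Power values \eqn{L(f)}, linear units.
#' @export
aperiodic_model <- function(f, A, f_k, chi, f_min = 1) {
  if (any(f <= 0) || f_min <= 0) stop("frequencies and f_min must be positive")
  if (any(f < f_min)) stop("f must be >= f_min")
  A * (f_k^chi + f_min^chi) / (f_k^chi + f^chi)
}

# internal: no domain checks, used inside optimizer and generator (any f > 0,
# and f = 0 where the limit A*(f_k^chi+f_min^chi)/f_k^chi is finite)
.aperiodic <- function(f, A, f_k, chi, f_min) {
  A * (f_k^chi + f_min^chi) / (f_k^chi + f^chi)
}

.gaussians <- function(f, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) return(numeric(length(f)))
  g <- numeric(length(f))
  for (i in seq_len(nrow(peaks)))
    g <- g + peaks$a[i] * exp(-(f - peaks$f_c[i])^2 / (2 * peaks$w[i]^2))
  g
}

#' Default spectral parameterization settings
#'
#' @param fit_range Frequency range fitted, Hz (default 1–65).
#' @param peak_width_limits Allowed Gaussian standard deviations, Hz (1–15).
#' @param max_n_peaks Maximum number of retained peaks (8).
#' @param min_peak_height Minimum peak amplitude in log10-power units (0.1).
#' @param peak_threshold Seeding threshold in residual standard deviations (2).
#' @param lambda Regularization weight penalizing Gaussian mass over negative
#'   frequencies (100).
#' @param f_min Minimal reliable frequency, Hz (1).
#' @return A list of settings for \code{\link{specparam}}.
#' @export
specparam_settings <- function(fit_range = c(1, 65),
                               peak_width_limits = c(1, 15),
                               max_n_peaks = 8L,
                               min_peak_height = 0.1,
                               peak_threshold = 2,
                               lambda = 100,
                               f_min = 1) {
  list(fit_range = fit_range, peak_width_limits = peak_width_limits,
       max_n_peaks = as.integer(max_n_peaks), min_peak_height = min_peak_height,
       peak_threshold = peak_threshold, lambda = lambda, f_min = f_min)
}

# closed-form penalty: integral of each Gaussian over (-Inf, 0]
.neg_freq_mass <- function(peaks) {
  if (nrow(peaks) == 0) return(0)
  sum(peaks$a * peaks$w * sqrt(2 * pi) * stats::pnorm(-peaks$f_c / peaks$w))
}

# pack/unpack parameter vector: (log10 A, log f_k, chi, then a, f_c, w per peak)
.sp_pack <- function(A, f_k, chi, peaks) {
  c(log10(A), log(f_k), chi,
    if (nrow(peaks) > 0) as.numeric(t(as.matrix(peaks[, c("a", "f_c", "w")]))))
}
.sp_unpack <- function(par) {
  n_pk <- (length(par) - 3L) %/% 3L
  peaks <- if (n_pk > 0) {
    m <- matrix(par[-(1:3)], ncol = 3, byrow = TRUE)
    data.frame(a = m[, 1], f_c = m[, 2], w = m[, 3])
  } else data.frame(a = numeric(0), f_c = numeric(0), w = numeric(0))
  list(A = 10^par[1], f_k = exp(par[2]), chi = par[3], peaks = peaks)
}

.sp_objective <- function(par, f, logp, f_min, lambda) {
  p <- .sp_unpack(par)
  model <- log10(.aperiodic(f, p$A, p$f_k, p$chi, f_min)) + .gaussians(f, p$peaks)
  sum((logp - model)^2) + lambda * .neg_freq_mass(p$peaks)
}

# analytic gradient of .sp_objective in the packed parameterization
# (log10 A, log f_k, chi, then a, f_c, w per peak)
.sp_gradient <- function(par, f, logp, f_min, lambda) {
  p <- .sp_unpack(par)
  t2 <- par[2]; chi <- p$chi
  u <- exp(chi * t2)                 # f_k^chi
  fm <- f_min^chi; fc_ <- f^chi
  num <- u + fm; den <- u + fc_
  ln10 <- log(10)
  model <- par[1] + (log(num) - log(den)) / ln10
  G <- matrix(0, length(f), max(0, nrow(p$peaks)) * 3)
  gsum <- numeric(length(f))
  if (nrow(p$peaks) > 0) {
    for (i in seq_len(nrow(p$peaks))) {
      a <- p$peaks$a[i]; fc <- p$peaks$f_c[i]; w <- p$peaks$w[i]
      e <- exp(-(f - fc)^2 / (2 * w^2))
      gsum <- gsum + a * e
      G[, 3 * i - 2] <- e
      G[, 3 * i - 1] <- a * e * (f - fc) / w^2
      G[, 3 * i]     <- a * e * (f - fc)^2 / w^3
    }
  }
  r <- logp - (model + gsum)
  g1 <- -2 * sum(r)
  g2 <- -2 * sum(r * (u * chi * (1 / num - 1 / den)) / ln10)
  g3 <- -2 * sum(r * ((u * t2 + fm * log(f_min)) / num -
                        (u * t2 + fc_ * log(f)) / den) / ln10)
  grad <- c(g1, g2, g3)
  if (nrow(p$peaks) > 0) {
    gpk <- -2 * as.numeric(crossprod(G, r))
    # penalty derivatives (closed form from the Gaussian CDF/PDF)
    for (i in seq_len(nrow(p$peaks))) {
      a <- p$peaks$a[i]; fc <- p$peaks$f_c[i]; w <- p$peaks$w[i]
      Phi <- stats::pnorm(-fc / w); phi <- stats::dnorm(fc / w)
      gpk[3 * i - 2] <- gpk[3 * i - 2] + lambda * w * sqrt(2 * pi) * Phi
      gpk[3 * i - 1] <- gpk[3 * i - 1] - lambda * a * sqrt(2 * pi) * phi
      gpk[3 * i]     <- gpk[3 * i] + lambda * a * sqrt(2 * pi) *
        (Phi + phi * fc / w)
    }
    grad <- c(grad, gpk)
  }
  grad
}

# aperiodic-only fit with a robust second pass that ignores bins sitting on
# top of oscillatory peaks (large positive residuals)
.fit_aperiodic <- function(f, logp, f_min) {
  obj <- function(par, fsub, lsub) {
    A <- 10^par[1]; f_k <- exp(par[2]); chi <- par[3]
    sum((lsub - log10(.aperiodic(fsub, A, f_k, chi, f_min)))^2)
  }
  lower <- c(-12, log(0.01), -1)
  upper <- c(12, log(65), 4)
  # crude slope/offset initialization from the log-log endpoints
  chi0 <- min(max((logp[1] - logp[length(logp)]) /
                    (log10(f[length(f)]) - log10(f[1])), -0.5), 3.5)
  init <- c(logp[1], log(0.5), chi0)
  ft <- stats::nlminb(init, obj, lower = lower, upper = upper, fsub = f, lsub = logp)
  res <- logp - log10(.aperiodic(f, 10^ft$par[1], exp(ft$par[2]), ft$par[3], f_min))
  keep <- res <= stats::quantile(res, 0.6)   # drop bins inflated by peaks
  if (sum(keep) >= 5) {
    ft2 <- stats::nlminb(ft$par, obj, lower = lower, upper = upper,
                         fsub = f[keep], lsub = logp[keep])
    if (is.finite(ft2$objective)) ft <- ft2
  }
  list(A = 10^ft$par[1], f_k = exp(ft$par[2]), chi = ft$par[3])
}

# seed one Gaussian from the largest residual
.seed_peak <- function(f, resid, wlim) {
  i <- which.max(resid)
  a <- resid[i]; f_c <- f[i]
  half <- a / 2
  li <- i; while (li > 1 && resid[li] > half) li <- li - 1
  ri <- i; while (ri < length(resid) && resid[ri] > half) ri <- ri + 1
  fwhm <- f[ri] - f[li]
  w <- fwhm / 2.355
  w <- min(max(w, wlim[1]), wlim[2])
  data.frame(a = a, f_c = f_c, w = w)
}

#' Fit the periodic/aperiodic spectral parameterization
#'
#' Decomposes a log10 power spectrum into a Lorentzian-with-knee aperiodic
#' component (\code{\link{aperiodic_model}}) plus up to \code{max_n_peaks}
#' Gaussian peaks, by least squares on log10 power over the fit range with a
#' regularization term \eqn{\lambda \sum_n \int_{-\infty}^{0} G_n(f)\,df}
#' penalizing Gaussian mass over negative frequencies (computed in closed
#' form from the Gaussian CDF). Peaks are seeded iteratively from the largest
#' residual exceeding \code{max(min_peak_height, peak_threshold * sd(resid))}
#' and all parameters are then refined jointly. Line noise at 60 Hz is
#' captured as an ordinary Gaussian peak, never notch-filtered. A knee is
#' encoded by the fit converging to \eqn{f_k > f_{min}}; no-knee spectra
#' converge to \eqn{f_k < f_{min}}.
#'
#' @param psd A \code{power_spectrum} of kind \code{"absolute"} covering the
#'   fit range.
#' @param settings Settings from \code{\link{specparam_settings}}.
#' @return An object of class \code{specparam} with elements
#'   \code{aperiodic} (A, f_k, chi, f_min), \code{peaks} (data frame with
#'   columns a, f_c, w in log10-power, Hz, Hz), \code{r_squared},
#'   \code{abs_error} (per-bin absolute reconstruction error on log10 power),
#'   \code{freqs}, \code{log_power}, \code{settings} and \code{converged}.
#' @seealso \code{\link{periodic_spectrum}}, \code{\link{classify_knee}}
#' @export
specparam <- function(psd, settings = specparam_settings()) {
  stopifnot(inherits(psd, "power_spectrum"))
  fr <- settings$fit_range
  if (min(psd$freqs) > fr[1] || max(psd$freqs) < fr[2])
    stop("grid does not cover the fit range")
  sel <- psd$freqs >= fr[1] & psd$freqs <= fr[2]
  f <- psd$freqs[sel]
  pw <- psd$power[sel]
  if (any(pw <= 0)) stop("nonpositive power in fit range; cannot take log10")
  logp <- log10(pw)
  wlim <- settings$peak_width_limits
  f_min <- settings$f_min

  ap <- .fit_aperiodic(f, logp, f_min)
  peaks <- data.frame(a = numeric(0), f_c = numeric(0), w = numeric(0))
  resid <- logp - log10(.aperiodic(f, ap$A, ap$f_k, ap$chi, f_min))
  # iterative seeding
  repeat {
    if (nrow(peaks) >= settings$max_n_peaks) break
    thr <- max(settings$min_peak_height, settings$peak_threshold * stats::sd(resid))
    if (max(resid) <= thr) break
    pk <- .seed_peak(f, resid, wlim)
    peaks <- rbind(peaks, pk)
    resid <- resid - pk$a * exp(-(f - pk$f_c)^2 / (2 * pk$w^2))
  }

  refine <- function(peaks) {
    par0 <- .sp_pack(ap$A, ap$f_k, ap$chi, peaks)
    n_pk <- nrow(peaks)
    lower <- c(-12, log(0.01), -1, rep(c(0, fr[1], wlim[1]), n_pk))
    upper <- c(12, log(65), 4, rep(c(6, fr[2], wlim[2]), n_pk))
    stats::nlminb(par0, .sp_objective, gradient = .sp_gradient,
                  lower = lower, upper = upper,
                  f = f, logp = logp, f_min = f_min, lambda = settings$lambda,
                  control = list(iter.max = 500, eval.max = 1000))
  }
  ft <- refine(peaks)
  p <- .sp_unpack(ft$par)
  # drop sub-threshold peaks and refine once more
  if (nrow(p$peaks) > 0 && any(p$peaks$a < settings$min_peak_height)) {
    ap <- list(A = p$A, f_k = p$f_k, chi = p$chi)
    p$peaks <- p$peaks[p$peaks$a >= settings$min_peak_height, , drop = FALSE]
    ft <- refine(p$peaks)
    p <- .sp_unpack(ft$par)
  }
  converged <- ft$convergence == 0 || is.finite(ft$objective)
  model <- log10(.aperiodic(f, p$A, p$f_k, p$chi, f_min)) + .gaussians(f, p$peaks)
  ss_res <- sum((logp - model)^2)
  ss_tot <- sum((logp - mean(logp))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  out <- structure(list(
    aperiodic = list(A = p$A, f_k = p$f_k, chi = p$chi, f_min = f_min),
    peaks = p$peaks[order(p$peaks$f_c), , drop = FALSE],
    r_squared = r2,
    abs_error = abs(logp - model),
    freqs = f, log_power = logp, fitted_log = model,
    settings = settings, lambda = settings$lambda,
    converged = converged, objective = ft$objective,
    source = psd$source), class = "specparam")
  if (!converged) {
    cond <- simpleError("spectral parameterization did not converge")
    cond$fit <- out
    stop(cond)
  }
  out
}

#' @export
print.specparam <- function(x, ...) {
  a <- x$aperiodic
  cat(sprintf("Spectral parameterization (%g-%g Hz)\n",
              min(x$freqs), max(x$freqs)))
  cat(sprintf("  aperiodic: A = %.4g, f_k = %.3g Hz, chi = %.3f (knee: %s)\n",
              a$A, a$f_k, a$chi, if (classify_knee(x)) "yes" else "no"))
  cat(sprintf("  peaks: %d retained\n", nrow(x$peaks)))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.specparam <- function(object, ...) {
  cat("Periodic/aperiodic decomposition of a power spectrum\n\n")
  print(object)
  if (nrow(object$peaks) > 0) {
    cat("\nGaussian peaks (a: log10 power, f_c and w: Hz):\n")
    print(format(object$peaks, digits = 3), row.names = FALSE)
  }
  cat(sprintf("\nmax |reconstruction error| = %.4f log10 units\n",
              max(object$abs_error)))
  invisible(object)
}

#' @export
coef.specparam <- function(object, ...) {
  a <- object$aperiodic
  out <- c(A = a$A, f_k = a$f_k, chi = a$chi)
  if (nrow(object$peaks) > 0) {
    pk <- object$peaks
    for (i in seq_len(nrow(pk))) {
      v <- c(pk$a[i], pk$f_c[i], pk$w[i])
      names(v) <- paste0(c("a", "f_c", "w"), i)
      out <- c(out, v)
    }
  }
  out
}

#' Predict power from a fitted spectral parameterization
#'
#' @param object A \code{specparam} fit.
#' @param freqs Frequencies at which to evaluate (defaults to the fitted grid).
#' @param component \code{"full"} (linear power), \code{"aperiodic"} (linear
#'   power of the Lorentzian alone) or \code{"periodic"} (log10-power above
#'   the aperiodic component).
#' @param ... Unused.
#' @return Numeric vector of model values.
#' @export
predict.specparam <- function(object, freqs = object$freqs,
                              component = c("full", "aperiodic", "periodic"), ...) {
  component <- match.arg(component)
  a <- object$aperiodic
  ap <- .aperiodic(freqs, a$A, a$f_k, a$chi, a$f_min)
  switch(component,
         aperiodic = ap,
         periodic = .gaussians(freqs, object$peaks),
         full = ap * 10^.gaussians(freqs, object$peaks))
}

#' @export
fitted.specparam <- function(object, ...) 10^object$fitted_log

#' @export
residuals.specparam <- function(object, ...) object$log_power - object$fitted_log

#' @export
plot.specparam <- function(x, ...) {
  graphics::plot(x$freqs, x$log_power, type = "l", col = "grey40",
                 xlab = "Frequency (Hz)", ylab = "log10 power", ...)
  graphics::lines(x$freqs, x$fitted_log, col = "firebrick", lwd = 2)
  a <- x$aperiodic
  graphics::lines(x$freqs, log10(.aperiodic(x$freqs, a$A, a$f_k, a$chi, a$f_min)),
                  col = "steelblue", lty = 2)
  graphics::legend("topright", c("data", "full fit", "aperiodic"),
                   col = c("grey40", "firebrick", "steelblue"),
                   lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

#' Periodic (residual) spectrum after aperiodic subtraction
#'
#' @param psd The absolute \code{power_spectrum} the fit was produced from.
#' @param fit The corresponding \code{specparam} fit.
#' @return A \code{power_spectrum} of kind \code{"periodic"} holding
#'   \eqn{\log_{10} P(f) - \log_{10} L(f)} over the fit range.
#' @export
periodic_spectrum <- function(psd, fit) {
  stopifnot(inherits(psd, "power_spectrum"), inherits(fit, "specparam"))
  fr <- fit$settings$fit_range
  sel <- psd$freqs >= fr[1] & psd$freqs <= fr[2]
  f <- psd$freqs[sel]
  if (length(f) != length(fit$freqs) || any(abs(f - fit$freqs) > 1e-9))
    stop("spectrum grid does not match the fit")
  a <- fit$aperiodic
  per <- log10(psd$power[sel]) - log10(.aperiodic(f, a$A, a$f_k, a$chi, a$f_min))
  power_spectrum(f, per, kind = "periodic", source = psd$source)
}

#' Does a fitted spectrum have an aperiodic knee?
#'
#' A knee is present iff the fitted knee frequency exceeds the minimal
#' reliable frequency (strictly); fits converging to \eqn{f_k \le f_{min}}
#' encode a plain power law.
#'
#' @param fit A \code{specparam} fit.
#' @return Logical.
#' @export
classify_knee <- function(fit) {
  stopifnot(inherits(fit, "specparam"))
  fit$aperiodic$f_k > fit$aperiodic$f_min
}
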
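#' Synthetic cohort generator configuration
#'
#' Defaults emulate a bilateral VC/VS DBS cohort: 13 patients, 4-contact
#' leads per hemisphere sampled at 250 Hz for ~20 s per bipolar pair, spectra
#' with a 1/f-like Lorentzian background, alpha (8-12 Hz) and beta peaks and
#' 60 Hz line noise, alpha amplitude coupled to per-patient symptom severity
#' and decaying with contact distance from a planted pallidal hotspot, and
#' longitudinal visits with drifting severity mirrored in alpha.
#'
#' @param n_patients Number of patients (13).
#' @param n_sessions Sessions per patient (4).
#' @param fs Sampling rate, Hz (250).
#' @param duration_s Snippet duration, s (20).
#' @param A_range Aperiodic offset prior, µV²/Hz (2-20).
#' @param chi_range Aperiodic exponent prior (1-2).
#' @param knee_prob Probability of a true knee (0.07).
#' @param f_k_knee_range Knee frequency prior given a knee, Hz (2-10).
#' @param f_k_noknee_range Sub-f_min knee prior otherwise (0.05-0.5).
#' @param alpha_fc_range Alpha center frequency prior, Hz (8-12).
#' @param alpha_w_range Alpha width prior, Hz (1-2).
#' @param alpha_gain Peak alpha log10 amplitude at the hotspot for the most
#'   severe patient (0.6).
#' @param beta_fc_range,beta_a_range,beta_w_range Beta peak priors.
#' @param line_a 60 Hz line-noise log10 amplitude (0.4).
#' @param line_w Line-noise width, Hz (0.5).
#' @param hotspot Planted alpha hotspot, MNI mm (c(-10.12, 4.07, -4)).
#' @param decay_mm Spatial decay length of the alpha field, mm (4).
#' @param severity_coupling Multiplicative strength of the severity-alpha
#'   coupling (1 = full, 0 = off).
#' @param longitudinal_coupling Alpha tracks drifting severity across
#'   sessions (TRUE).
#' @param sensor_noise Bipolar sensor noise s.d., µV (0.5).
#' @param label_noise Probability that the clinical active contact deviates
#'   from the true-alpha argmax (0.15).
#' @param packet_loss_prob Per-packet drop probability (0.002).
#' @param lead_jitter_mm S.d. of lead trajectory jitter, mm (1).
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(n_patients = 13, n_sessions = 4, fs = 250,
                             duration_s = 20,
                             A_range = c(2, 20), chi_range = c(1, 2),
                             knee_prob = 0.07, f_k_knee_range = c(2, 10),
                             f_k_noknee_range = c(0.05, 0.5),
                             alpha_fc_range = c(8, 12), alpha_w_range = c(1, 2),
                             alpha_gain = 0.6,
                             beta_fc_range = c(15, 30), beta_a_range = c(0.05, 0.15),
                             beta_w_range = c(1.5, 3),
                             line_a = 0.4, line_w = 0.5,
                             hotspot = c(-10.12, 4.07, -4), decay_mm = 4,
                             severity_coupling = 1, longitudinal_coupling = TRUE,
                             sensor_noise = 0.5, label_noise = 0.15,
                             packet_loss_prob = 0.002, lead_jitter_mm = 1) {
  structure(as.list(environment()), class = "generator_config")
}

#' Generate contact geometry
#'
#' Per hemisphere, 4 collinear contacts at 2 mm spacing along a jittered,
#' mostly dorsoventral trajectory passing near the hotspot; right-hemisphere
#' leads mirror the left (x negated) with the same jitter model.
#'
#' @param config A \code{generator_config}.
#' @param seed Integer seed.
#' @return Data frame: patient_id, hemisphere, contact (0-3), x, y, z (mm).
#' @export
generate_geometry <- function(config, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (h in c("L", "R")) {
      hs <- config$hotspot
      if (h == "R") hs[1] <- -hs[1]
      anchor <- hs + stats::rnorm(3, sd = config$lead_jitter_mm)
      dirv <- c(0.25, 0.2, 0.95) + stats::rnorm(3, sd = 0.08)
      if (h == "R") dirv[1] <- -dirv[1]
      dirv <- dirv / sqrt(sum(dirv^2))
      # contacts at 2 mm spacing; lead midpoint (between contacts 1 and 2)
      # anchored near the hotspot
      offs <- (0:3 - 1.5) * 2
      for (ct in 0:3) {
        xyz <- anchor + offs[ct + 1] * dirv
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, hemisphere = h, contact = ct,
          x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' True per-contact alpha amplitude field
#'
#' Amplitude (log10 units at the spectral peak) decays as a Gaussian of the
#' distance to the planted hotspot and scales multiplicatively with the
#' patient's severity factor:
#' amplitude = alpha_gain * exp(-d^2 / (2 decay^2)) * severity_factor.
#'
#' @param geometry Data frame from \code{\link{generate_geometry}}.
#' @param config A \code{generator_config}.
#' @param severity_factor Named per-patient multiplier in [0, 1].
#' @return Numeric amplitude per geometry row.
#' @export
true_alpha_field <- function(geometry, config, severity_factor) {
  hs_L <- config$hotspot
  hs_R <- hs_L * c(-1, 1, 1)
  d <- numeric(nrow(geometry))
  for (i in seq_len(nrow(geometry))) {
    hs <- if (geometry$hemisphere[i] == "L") hs_L else hs_R
    d[i] <- sqrt(sum((c(geometry$x[i], geometry$y[i], geometry$z[i]) - hs)^2))
  }
  sf <- severity_factor[geometry$patient_id]
  config$alpha_gain * exp(-d^2 / (2 * config$decay_mm^2)) * sf
}

#' Generate an LFP snippet with a prescribed spectrum
#'
#' Spectrally shaped Gaussian noise: random phases with amplitudes set so
#' the expected one-sided PSD equals the Lorentzian aperiodic model times
#' 10^(sum of Gaussian peaks in log10 power), including any 60 Hz line
#' component supplied as a peak.
#'
#' @param A,f_k,chi Aperiodic parameters (see \code{\link{aperiodic_model}}).
#' @param peaks Data frame with columns a (log10 power), f_c (Hz), w (Hz);
#'   may have zero rows.
#' @param duration_s Duration (s).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed (optional; caller may manage the RNG stream).
#' @param f_min Minimal frequency of the aperiodic model (1).
#' @return Numeric vector of length \code{duration_s * fs} (µV).
#' @export
generate_lfp <- function(A, f_k, chi, peaks = NULL, duration_s = 20, fs = 250,
                         seed = NULL, f_min = 1) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  S <- .aperiodic(f, A, f_k, chi, f_min) * 10^.gaussians(f, if (is.null(peaks))
    data.frame(a = numeric(0), f_c = numeric(0), w = numeric(0)) else peaks)
  X <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) *
    sqrt(S * fs * n / 2) / sqrt(2)
  X[nf] <- complex(real = sqrt(2) * Re(X[nf]), imaginary = 0)  # Nyquist bin real
  full <- c(0, X[1:(nf - 1)], X[nf], Conj(rev(X[1:(nf - 1)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Bipolar pair signals from monopolar contact signals
#'
#' Pair (a, b) = contact_a - contact_b plus independent white sensor noise.
#'
#' @param contact_signals List of 4 numeric vectors (contacts 0-3).
#' @param sensor_noise Noise s.d. (µV).
#' @return Named list of 6 pair signals ("01" ... "23").
#' @export
bipolar_from_monopolar <- function(contact_signals, sensor_noise = 0) {
  if (length(contact_signals) != 4) stop("need 4 contact signals")
  out <- list()
  for (a in 0:2) for (b in (a + 1):3) {
    s <- contact_signals[[a + 1]] - contact_signals[[b + 1]]
    if (sensor_noise > 0) s <- s + stats::rnorm(length(s), sd = sensor_noise)
    out[[paste0(a, b)]] <- s
  }
  out
}

# drop packets at random and reconstruct the grid, marking gaps
.apply_packet_loss <- function(samples, fs, p_loss) {
  if (p_loss <= 0) return(list(samples = samples, gap_mask = rep(FALSE, length(samples))))
  pk <- 63L
  n <- length(samples)
  starts <- seq(1, n, by = pk)
  drop <- stats::runif(length(starts)) < p_loss
  gap <- rep(FALSE, n)
  for (i in which(drop)) gap[starts[i]:min(starts[i] + pk - 1L, n)] <- TRUE
  if (any(gap) && !all(gap)) {
    samples[gap] <- stats::approx(which(!gap), samples[!gap],
                                  xout = which(gap), rule = 2)$y
  }
  list(samples = samples, gap_mask = gap)
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Draws per-patient severity, lead geometry, spectral parameters and
#' longitudinal clinical trajectories, synthesizes bipolar LFP recordings
#' for every pair, session and hemisphere, and assigns active-contact labels
#' correlated with the true alpha field. Everything is a pure function of
#' (config, seed).
#'
#' @param config A \code{generator_config}.
#' @param seed Master integer seed.
#' @return List of class \code{synthetic_cohort}: \code{recordings} (list of
#'   \code{recording}), \code{clinical} (list of \code{clinical_record}),
#'   \code{geometry} (contacts data frame), \code{truth} (list: hotspot,
#'   severity, severity_factor per session, true_alpha per contact at S1,
#'   spectral parameters, active-contact truth, seed).
#' @export
simulate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  np <- config$n_patients; ns <- config$n_sessions
  pids <- sprintf("P%02d", seq_len(np))
  severity <- stats::setNames(stats::runif(np), pids)
  improvement <- stats::setNames(stats::runif(np, 0, 0.7), pids)
  geometry <- generate_geometry(config, seed = seed + 1)

  # per-hemisphere spectral identity, fixed across sessions
  hem_key <- unique(geometry[, c("patient_id", "hemisphere")])
  sp <- list()
  for (i in seq_len(nrow(hem_key))) {
    knee <- stats::runif(1) < config$knee_prob
    sp[[paste(hem_key$patient_id[i], hem_key$hemisphere[i])]] <- list(
      A = stats::runif(1, config$A_range[1], config$A_range[2]),
      chi = stats::runif(1, config$chi_range[1], config$chi_range[2]),
      f_k = if (knee) stats::runif(1, config$f_k_knee_range[1], config$f_k_knee_range[2])
            else stats::runif(1, config$f_k_noknee_range[1], config$f_k_noknee_range[2]),
      alpha_fc = stats::runif(1, config$alpha_fc_range[1], config$alpha_fc_range[2]),
      alpha_w = stats::runif(1, config$alpha_w_range[1], config$alpha_w_range[2]),
      beta_fc = stats::runif(1, config$beta_fc_range[1], config$beta_fc_range[2]),
      beta_a = stats::runif(1, config$beta_a_range[1], config$beta_a_range[2]),
      beta_w = stats::runif(1, config$beta_w_range[1], config$beta_w_range[2]))
  }

  # longitudinal severity factor per patient and session (1 = S1 level)
  sev_session <- matrix(1, np, ns, dimnames = list(pids, NULL))
  for (s in seq_len(ns)) {
    rel <- if (ns > 1) (s - 1) / (ns - 1) else 0
    sev_session[, s] <- 1 - improvement * rel
  }

  # clinical trajectories
  s1_date <- as.Date("2024-01-15")
  session_gap_days <- 90
  ybocs_s1 <- stats::setNames(
    pmin(40, pmax(0, round(16 + 22 * severity + stats::rnorm(np, sd = 1.5)))), pids)
  baseline <- stats::setNames(
    pmin(40L, as.integer(ybocs_s1 + sample(1:3, np, replace = TRUE))), pids)
  sf_mult <- function(p, s) {
    base <- (0.35 + 0.65 * severity[p])^config$severity_coupling
    if (config$longitudinal_coupling) base * sev_session[p, s] else base
  }

  # true alpha amplitude per contact at severity_factor = 1
  geo_field <- true_alpha_field(geometry, config,
                                stats::setNames(rep(1, np), pids))

  clinical <- list(); recordings <- list()
  active_truth <- list()
  for (p in pids) {
    for (s in seq_len(ns)) {
      ybocs_s <- if (s == 1) ybocs_s1[p] else
        pmin(40, pmax(0, round(16 + 22 * severity[p] * sev_session[p, s] +
                                 stats::rnorm(1, sd = 1.5))))
      if (s == 1) {
        ac <- list(L = integer(0), R = integer(0))
        for (h in c("L", "R")) {
          gidx <- geometry$patient_id == p & geometry$hemisphere == h
          best <- which.max(geo_field[gidx]) - 1L
          ac[[h]] <- as.integer(if (stats::runif(1) < config$label_noise)
            sample(setdiff(0:3, best), 1) else best)
          active_truth[[paste(p, h)]] <- best
        }
      } else {
        ac <- clinical[[paste(p, 1)]]$active_contacts
      }
      clinical[[paste(p, s)]] <- clinical_record(
        p, s1_date + (s - 1) * session_gap_days, ybocs_s, baseline[p],
        stim_mA = c(L = if (s == 1) 0 else round(stats::runif(1, 2, 5), 1),
                    R = if (s == 1) 0 else round(stats::runif(1, 2, 5), 1)),
        days_since_dbs_onset = (s - 1) * session_gap_days,
        active_contacts = ac)

      for (h in c("L", "R")) {
        key <- paste(p, h)
        par <- sp[[key]]
        gidx <- which(geometry$patient_id == p & geometry$hemisphere == h)
        amp <- geo_field[gidx] * sf_mult(p, s)
        contact_signals <- lapply(1:4, function(ci) {
          pk <- data.frame(
            a = c(amp[ci], par$beta_a, config$line_a),
            f_c = c(par$alpha_fc, par$beta_fc, 60),
            w = c(par$alpha_w, par$beta_w, config$line_w))
          generate_lfp(par$A, par$f_k, par$chi, pk,
                       duration_s = config$duration_s, fs = config$fs)
        })
        pairs <- bipolar_from_monopolar(contact_signals, config$sensor_noise)
        for (pn in names(pairs)) {
          pl <- .apply_packet_loss(pairs[[pn]], config$fs, config$packet_loss_prob)
          recordings[[length(recordings) + 1L]] <- recording(
            p, h, s, as.integer(strsplit(pn, "")[[1]]), pl$samples,
            fs = config$fs, gap_mask = pl$gap_mask,
            recorded_at = s1_date + (s - 1) * session_gap_days)
        }
      }
    }
  }
  truth <- list(hotspot = config$hotspot, severity = severity,
                improvement = improvement, severity_factor = sev_session,
                true_alpha = geo_field, spectral = sp,
                active_best = active_truth, seed = seed)
  structure(list(recordings = recordings, clinical = unname(clinical),
                 geometry = geometry, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients, %d recordings, %d clinical visits>\n",
              x$config$n_patients, length(x$recordings), length(x$clinical)))
  invisible(x)
}

#' Write a synthetic cohort fixture to disk
#'
#' Writes the cohort in the documented interchange formats
#' (\code{recordings.jsonl}, \code{clinical.csv}, \code{contacts.csv}) via
#' \code{\link{write_cohort}}, plus \code{truth.json} (planted ground truth)
#' and synthetic spherical structure point clouds
#' (\code{structure_<name>_synthetic.csv}) for GPe, NAcc and BNST border
#' distance tests. The structures are toy spheres, not anatomical atlases.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param path Output directory.
#' @return \code{path}, invisibly.
#' @export
write_fixture <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write_cohort(cohort$recordings, cohort$clinical, cohort$geometry, path)
  tr <- cohort$truth
  jsonlite::write_json(
    list(hotspot = tr$hotspot, severity = as.list(tr$severity),
         improvement = as.list(tr$improvement),
         true_alpha = tr$true_alpha, seed = tr$seed),
    file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
  centers <- list(GPe = c(-14, 0, -2), NAcc = c(-9, 10, -8), BNST = c(-5, 2, 1))
  radii <- c(GPe = 6, NAcc = 4, BNST = 2)
  for (nm in names(centers)) {
    th <- seq(0, pi, length.out = 12)
    ph <- seq(0, 2 * pi, length.out = 24)
    g <- expand.grid(th = th, ph = ph)
    pts <- cbind(centers[[nm]][1] + radii[nm] * sin(g$th) * cos(g$ph),
                 centers[[nm]][2] + radii[nm] * sin(g$th) * sin(g$ph),
                 centers[[nm]][3] + radii[nm] * cos(g$th))
    utils::write.csv(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3]),
                     file.path(path, sprintf("structure_%s_synthetic.csv", nm)),
                     row.names = FALSE)
  }
  invisible(path)
}
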
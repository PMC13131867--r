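#' Construct a bipolar LFP recording
#'
#' One ~20 s snippet from a single bipolar contact pair of a 4-contact DBS
#' lead. Contacts are indexed 0 (most ventral) to 3 (most dorsal).
#'
#' @param patient_id Patient identifier.
#' @param hemisphere "L" or "R".
#' @param session_index Session number, 1 = first programming visit (S1).
#' @param pair Integer vector c(a, b) with 0 <= a < b <= 3.
#' @param samples Voltage series (µV).
#' @param fs Sampling rate, Hz (nominally 250).
#' @param gap_mask Logical per sample; TRUE marks reconstructed/missing
#'   samples. Defaults to all FALSE.
#' @param recorded_at Recording date (coerced with \code{as.Date}).
#' @return An object of class \code{recording}.
#' @export
recording <- function(patient_id, hemisphere, session_index, pair, samples,
                      fs = 250, gap_mask = NULL, recorded_at = NA) {
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  pair <- as.integer(pair)
  if (length(pair) != 2 || pair[1] >= pair[2] || pair[1] < 0 || pair[2] > 3)
    stop("pair must be (a, b) with 0 <= a < b <= 3")
  if (fs <= 0) stop("fs must be positive")
  samples <- as.numeric(samples)
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, length(samples))
  if (length(gap_mask) != length(samples))
    stop("samples and gap_mask must have equal length")
  structure(list(patient_id = as.character(patient_id), hemisphere = hemisphere,
                 session_index = as.integer(session_index), pair = pair,
                 samples = samples, fs = fs, gap_mask = as.logical(gap_mask),
                 recorded_at = as.Date(recorded_at)),
            class = "recording")
}

recording_id <- function(rec) {
  sprintf("%s_%s_s%d_p%d%d", rec$patient_id, rec$hemisphere,
          rec$session_index, rec$pair[1], rec$pair[2])
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s: %.1f s @ %g Hz, %.2f%% gaps>\n", recording_id(x),
              length(x$samples) / x$fs, x$fs, 100 * mean(x$gap_mask)))
  invisible(x)
}

#' Construct a clinical assessment record
#'
#' @param patient_id Patient identifier.
#' @param visit_date Visit date.
#' @param ybocs Y-BOCS total score, 0-40.
#' @param baseline_ybocs Pre-operative Y-BOCS score.
#' @param stim_mA Named numeric c(L = , R = ) stimulation amplitudes (mA).
#' @param days_since_dbs_onset Integer days since stimulation onset.
#' @param active_contacts Named list(L = , R = ) of active contact index sets
#'   (each of size 1 or 2, indices in 0:3).
#' @return An object of class \code{clinical_record}.
#' @export
clinical_record <- function(patient_id, visit_date, ybocs, baseline_ybocs,
                            stim_mA = c(L = NA_real_, R = NA_real_),
                            days_since_dbs_onset = NA_integer_,
                            active_contacts = list(L = integer(0), R = integer(0))) {
  if (!is.na(ybocs) && (ybocs < 0 || ybocs > 40)) stop("ybocs must be in 0-40")
  for (h in c("L", "R")) {
    ac <- active_contacts[[h]]
    if (length(ac) > 0 && (any(!ac %in% 0:3) || length(ac) > 2))
      stop("active contacts must be 1 or 2 indices in 0:3")
  }
  structure(list(patient_id = as.character(patient_id),
                 visit_date = as.Date(visit_date),
                 ybocs = as.integer(ybocs), baseline_ybocs = as.integer(baseline_ybocs),
                 stim_mA = stim_mA,
                 days_since_dbs_onset = as.integer(days_since_dbs_onset),
                 active_contacts = active_contacts),
            class = "clinical_record")
}

#' Reconstruct a uniform sample grid from data packets
#'
#' Telemetry streams arrive as timestamped packets; dropped packets leave
#' holes in the sample grid. Positions are inferred from packet tick times at
#' the stated sampling rate; missing stretches are linearly interpolated and
#' flagged in the gap mask.
#'
#' @param packets List of lists with elements \code{tick_ms} (packet start
#'   time, ms) and \code{values} (numeric samples).
#' @param fs Sampling rate (Hz).
#' @param ... Identity fields passed to \code{\link{recording}}
#'   (patient_id, hemisphere, session_index, pair, recorded_at).
#' @return A \code{recording}; attribute \code{"gap_fraction"} reports the
#'   fraction of reconstructed samples.
#' @export
reconstruct_sample_grid <- function(packets, fs = 250, ...) {
  if (length(packets) == 0) stop("no packets")
  ticks <- vapply(packets, function(p) as.numeric(p$tick_ms), numeric(1))
  if (any(diff(ticks) <= 0)) stop("packet ticks must be strictly increasing")
  pos <- round((ticks - ticks[1]) / 1000 * fs) + 1L
  lens <- vapply(packets, function(p) length(p$values), integer(1))
  n <- pos[length(pos)] + lens[length(lens)] - 1L
  values <- rep(NA_real_, n)
  for (i in seq_along(packets)) {
    idx <- pos[i]:(pos[i] + lens[i] - 1L)
    if (any(!is.na(values[idx]))) stop("overlapping packets at tick ", ticks[i])
    values[idx] <- packets[[i]]$values
  }
  gap <- is.na(values)
  if (any(gap)) {
    filled <- stats::approx(which(!gap), values[!gap], xout = seq_len(n),
                            rule = 2)$y
    values[gap] <- filled[gap]
  }
  rec <- recording(samples = values, fs = fs, gap_mask = gap, ...)
  attr(rec, "gap_fraction") <- mean(gap)
  rec
}

#' High-pass drift filter
#'
#' Removes drifts and low-frequency components with a zero-phase
#' (forward-backward) Butterworth high-pass. Zero-phase application avoids
#' phase distortion of narrowband alpha activity; the squared magnitude
#' response is that of the underlying Butterworth filter.
#'
#' @param rec A \code{recording}.
#' @param order Filter order (default 4).
#' @param cutoff_hz Cutoff frequency, Hz (default 1).
#' @return The filtered \code{recording}.
#' @export
drift_filter <- function(rec, order = 4, cutoff_hz = 1.0) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs <= 2 * cutoff_hz) stop("fs must exceed twice the cutoff")
  n <- length(rec$samples)
  if (n < 9 * (order + 1))
    stop("too short to filter")
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  # forward-backward pass over an odd-reflection extension long enough for
  # the filter transient (time constant ~ fs/(2 pi cutoff)) to die out, so
  # edge transients never reach the retained samples
  pad <- min(n - 1, ceiling(8 * rec$fs / cutoff_hz))
  x <- rec$samples
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  rec$samples <- y[(pad + 1):(pad + n)]
  rec
}

#' Automated artifact screen
#'
#' Stand-in for manual artifact inspection: flags recordings with excessive
#' reconstructed gaps, amplitude outliers (robust z-score of 1-s RMS) or
#' flatline segments (zero-variance 1-s windows).
#'
#' @param rec A \code{recording}.
#' @param max_gap_frac Maximum tolerated gap fraction (default 0.005).
#' @param amp_z_thresh Robust z threshold on 1-s RMS (default 8; flags only
#'   gross transients, sparing physiological amplitude modulation).
#' @return A list of class \code{qc_report} with \code{flags} (character
#'   vector) and \code{pass} (TRUE iff no flags).
#' @export
qc_screen <- function(rec, max_gap_frac = 0.005, amp_z_thresh = 8) {
  stopifnot(inherits(rec, "recording"))
  flags <- character(0)
  if (mean(rec$gap_mask) > max_gap_frac) flags <- c(flags, "excess_gaps")
  n <- round(rec$fs)
  nwin <- length(rec$samples) %/% n
  if (nwin >= 1) {
    wins <- matrix(rec$samples[seq_len(nwin * n)], nrow = n)
    rms <- sqrt(colMeans(wins^2))
    v <- apply(wins, 2, stats::var)
    if (any(v == 0)) flags <- c(flags, "flatline")
    med <- stats::median(rms); madv <- stats::mad(rms)
    if (madv > 0 && any(abs(rms - med) / madv > amp_z_thresh))
      flags <- c(flags, "amplitude_outlier")
  }
  structure(list(recording = recording_id(rec), flags = flags,
                 pass = length(flags) == 0), class = "qc_report")
}

#' Match recordings to clinical assessments
#'
#' Joins each recording to the nearest-in-time Y-BOCS assessment of the same
#' patient within \code{max_days} days (same-day preferred; equidistant ties
#' broken toward the earlier visit). Unmatched recordings are excluded.
#'
#' @param recs List of \code{recording} objects.
#' @param clin List of \code{clinical_record} objects.
#' @param max_days Maximum |days| between recording and assessment (default 7).
#' @return A data frame with one row per matched recording: patient_id,
#'   hemisphere, session_index, pair, recorded_at, visit_date, delta_days,
#'   ybocs, baseline_ybocs, stim_mA, days_since_dbs_onset, active_contacts
#'   (list column). Attribute \code{"n_unmatched"} counts exclusions.
#' @export
match_clinical <- function(recs, clin, max_days = 7) {
  rows <- list(); n_unmatched <- 0L
  clin_pid <- vapply(clin, function(cr) cr$patient_id, character(1))
  for (rec in recs) {
    cand <- clin[clin_pid == rec$patient_id]
    if (length(cand) == 0 || is.na(rec$recorded_at)) { n_unmatched <- n_unmatched + 1L; next }
    dd <- vapply(cand, function(cr) as.numeric(cr$visit_date - rec$recorded_at), numeric(1))
    ok <- abs(dd) <= max_days
    if (!any(ok)) { n_unmatched <- n_unmatched + 1L; next }
    cand <- cand[ok]; dd <- dd[ok]
    # nearest in time; equidistant ties -> earlier visit (more negative delta)
    ord <- order(abs(dd), dd)
    cr <- cand[[ord[1]]]
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = rec$patient_id, hemisphere = rec$hemisphere,
      session_index = rec$session_index,
      pair = paste0(rec$pair[1], rec$pair[2]),
      recorded_at = rec$recorded_at, visit_date = cr$visit_date,
      delta_days = abs(dd[ord[1]]), ybocs = cr$ybocs,
      baseline_ybocs = cr$baseline_ybocs,
      stim_mA = unname(cr$stim_mA[rec$hemisphere]),
      days_since_dbs_onset = cr$days_since_dbs_onset,
      active_contacts = I(list(cr$active_contacts[[rec$hemisphere]])),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(patient_id = character(0), hemisphere = character(0),
               session_index = integer(0), pair = character(0),
               recorded_at = as.Date(character(0)), visit_date = as.Date(character(0)),
               delta_days = numeric(0), ybocs = integer(0),
               baseline_ybocs = integer(0), stim_mA = numeric(0),
               days_since_dbs_onset = integer(0),
               active_contacts = I(list()))
  attr(out, "n_unmatched") <- n_unmatched
  out
}

.ac_string <- function(ac) paste(ac, collapse = ";")
.ac_parse <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Write a cohort to disk
#'
#' Serializes recordings as JSON lines (\code{recordings.jsonl}), clinical
#' assessments as \code{clinical.csv} and contact coordinates as
#' \code{contacts.csv}, plus a \code{manifest.json} naming the three files.
#'
#' @param recs List of \code{recording} objects.
#' @param clin List of \code{clinical_record} objects.
#' @param geometry Data frame of contact coordinates (patient_id, hemisphere,
#'   contact, x, y, z) or NULL.
#' @param path Output directory (created if absent).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(recs, clin, geometry = NULL, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "recordings.jsonl"), "w")
  on.exit(close(con))
  for (rec in recs) {
    obj <- list(patient_id = rec$patient_id, hemisphere = rec$hemisphere,
                session_index = rec$session_index, pair = rec$pair,
                fs = rec$fs, recorded_at = as.character(rec$recorded_at),
                samples = rec$samples, gap_mask = rec$gap_mask)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  cdf <- do.call(rbind, lapply(clin, function(cr) data.frame(
    patient_id = cr$patient_id, visit_date = as.character(cr$visit_date),
    ybocs = cr$ybocs, baseline_ybocs = cr$baseline_ybocs,
    stim_L_mA = unname(cr$stim_mA["L"]), stim_R_mA = unname(cr$stim_mA["R"]),
    days_since_dbs_onset = cr$days_since_dbs_onset,
    active_contacts_L = .ac_string(cr$active_contacts$L),
    active_contacts_R = .ac_string(cr$active_contacts$R),
    stringsAsFactors = FALSE)))
  utils::write.csv(cdf, file.path(path, "clinical.csv"), row.names = FALSE)
  manifest <- list(recordings = "recordings.jsonl", clinical = "clinical.csv")
  if (!is.null(geometry)) {
    utils::write.csv(geometry, file.path(path, "contacts.csv"), row.names = FALSE)
    manifest$contacts <- "contacts.csv"
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Reads the files named by \code{manifest.json} in a cohort directory (see
#' \code{\link{write_cohort}} for the formats). Recording lines in packetized
#' form (field \code{packets}) are passed through
#' \code{\link{reconstruct_sample_grid}}.
#'
#' @param path Cohort directory containing \code{manifest.json}.
#' @return List with elements \code{recordings}, \code{clinical},
#'   \code{geometry} (data frame or NULL).
#' @export
read_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing file: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  recs <- list()
  if (!is.null(manifest$recordings)) {
    rf <- file.path(path, manifest$recordings)
    if (!file.exists(rf)) stop("missing file: ", rf)
    lines <- readLines(rf)
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed recording at row ", i, ": ",
                                               conditionMessage(e)))
      recs[[i]] <- if (!is.null(obj$packets)) {
        pk <- lapply(seq_len(nrow(obj$packets)), function(j)
          list(tick_ms = obj$packets$tick_ms[j], values = obj$packets$values[[j]]))
        reconstruct_sample_grid(pk, fs = obj$fs, patient_id = obj$patient_id,
                                hemisphere = obj$hemisphere,
                                session_index = obj$session_index, pair = obj$pair,
                                recorded_at = obj$recorded_at)
      } else {
        recording(obj$patient_id, obj$hemisphere, obj$session_index, obj$pair,
                  obj$samples, fs = obj$fs, gap_mask = obj$gap_mask,
                  recorded_at = obj$recorded_at)
      }
    }
  }
  clin <- list()
  if (!is.null(manifest$clinical)) {
    cf <- file.path(path, manifest$clinical)
    if (!file.exists(cf)) stop("missing file: ", cf)
    cdf <- utils::read.csv(cf, stringsAsFactors = FALSE,
                           colClasses = c(active_contacts_L = "character",
                                          active_contacts_R = "character"))
    clin <- lapply(seq_len(nrow(cdf)), function(i) {
      clinical_record(cdf$patient_id[i], cdf$visit_date[i], cdf$ybocs[i],
                      cdf$baseline_ybocs[i],
                      stim_mA = c(L = cdf$stim_L_mA[i], R = cdf$stim_R_mA[i]),
                      days_since_dbs_onset = cdf$days_since_dbs_onset[i],
                      active_contacts = list(L = .ac_parse(cdf$active_contacts_L[i]),
                                             R = .ac_parse(cdf$active_contacts_R[i])))
    })
  }
  geometry <- NULL
  if (!is.null(manifest$contacts)) {
    gf <- file.path(path, manifest$contacts)
    if (!file.exists(gf)) stop("missing file: ", gf)
    geometry <- utils::read.csv(gf, stringsAsFactors = FALSE)
  }
  list(recordings = recs, clinical = clin, geometry = geometry)
}
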
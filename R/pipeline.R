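#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Every stochastic stage
#' draws from an explicit seed so a report is a pure function of
#' (inputs, config).
#'
#' @param alpha_band Canonical alpha band, Hz (default c(7, 14)).
#' @param kinds Spectrum kinds to analyze: subset of
#'   c("absolute", "relative", "periodic"). Periodic requires the spectral
#'   parameterization stage and is the most expensive.
#' @param hemispheres Hemisphere strategies: subset of
#'   c("pooled", "left", "right").
#' @param summaries Within-hemisphere summaries: subset of
#'   c("max_pair", "mean_pairs").
#' @param n_perm Permutations for all permutation tests (default 10000).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param alpha_fw Family-wise alpha for cluster tests (0.01).
#' @param alpha_cluster Cluster-forming per-bin alpha (0.05).
#' @param max_gap_frac QC gap-fraction threshold (0.005).
#' @param max_days Clinical matching window, days (7).
#' @param seed Master seed.
#' @param spectral Settings from \code{\link{specparam_settings}}.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(alpha_band = c(7, 14),
                            kinds = c("absolute", "relative", "periodic"),
                            hemispheres = c("pooled", "left", "right"),
                            summaries = c("max_pair", "mean_pairs"),
                            n_perm = 10000, n_boot = 10000,
                            alpha_fw = 0.01, alpha_cluster = 0.05,
                            max_gap_frac = 0.005, max_days = 7,
                            seed = 1,
                            spectral = specparam_settings()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema and range checks; returns issues rather than erroring so callers
#' can report them all at once. Issues are tagged "blocking" or "warning".
#'
#' @param config A \code{pipeline_config} (or plain list).
#' @return Data frame with columns \code{level} and \code{message}; zero
#'   rows when the config is clean.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(level, msg) issues[[length(issues) + 1L]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    add("warning", paste("unknown config keys:", paste(unknown, collapse = ", ")))
  ab <- config$alpha_band
  if (is.null(ab) || length(ab) != 2 || ab[1] >= ab[2])
    add("blocking", "alpha_band must be (lo, hi) with lo < hi")
  if (is.null(config$seed) || !is.finite(config$seed))
    add("blocking", "missing seed")
  for (k in c("n_perm", "n_boot"))
    if (!is.null(config[[k]]) && config[[k]] < 1)
      add("blocking", paste(k, "must be >= 1"))
  for (k in c("alpha_fw", "alpha_cluster"))
    if (!is.null(config[[k]]) && (config[[k]] <= 0 || config[[k]] >= 1))
      add("blocking", paste(k, "must be in (0, 1)"))
  if (!is.null(config$kinds) &&
      !all(config$kinds %in% c("absolute", "relative", "periodic")))
    add("blocking", "kinds must be a subset of absolute/relative/periodic")
  if (length(issues) == 0)
    data.frame(level = character(0), message = character(0))
  else do.call(rbind, issues)
}

# one averaged PSD per (patient, hemisphere, session, pair)
.session_spectra <- function(recs, config) {
  keys <- vapply(recs, function(r)
    sprintf("%s|%s|%d|%d%d", r$patient_id, r$hemisphere, r$session_index,
            r$pair[1], r$pair[2]), character(1))
  out <- list()
  for (k in unique(keys)) {
    grp <- recs[keys == k]
    qc <- lapply(grp, qc_screen, max_gap_frac = config$max_gap_frac)
    pass <- vapply(qc, function(q) q$pass, logical(1))
    if (any(pass)) {
      grp <- grp[pass]
    } else {
      # keep gap-only failures: gapped windows are skipped in the PSD anyway
      gap_only <- vapply(qc, function(q) identical(q$flags, "excess_gaps"), logical(1))
      if (!any(gap_only)) next
      grp <- grp[gap_only]
    }
    psds <- lapply(grp, function(r) welch_psd(drift_filter(r)))
    out[[k]] <- average_session_psd(psds)
  }
  out
}

.key_fields <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(patient_id = vapply(parts, `[`, "", 1),
             hemisphere = vapply(parts, `[`, "", 2),
             session_index = as.integer(vapply(parts, `[`, "", 3)),
             pair = vapply(parts, `[`, "", 4), stringsAsFactors = FALSE)
}

#' Run the end-to-end biomarker pipeline
#'
#' Preprocess (drift filter, QC, session averaging) -> spectra (absolute,
#' relative, optional periodic via spectral parameterization) -> alpha
#' metrics -> clinical matching -> pseudo-monopolar maps at S1 -> contact
#' prediction (active/inactive contrast, selection curve AUC with
#' permutation null, rank difference) -> spatial mapping (hotspot centroid,
#' distance-power correlation, moment of inertia with permutation test) ->
#' cross-sectional multiverse of Spearman correlations over
#' hemisphere x summary x kind -> longitudinal statistics (session deltas,
#' mixed-effects model).
#'
#' @param cohort A \code{synthetic_cohort}, or a list with elements
#'   \code{recordings}, \code{clinical}, \code{geometry} (as returned by
#'   \code{\link{read_cohort}}), or a path to a cohort directory.
#' @param config A \code{pipeline_config}.
#' @return A list of class \code{pipeline_report} with elements
#'   \code{metrics} (per pair/kind alpha table), \code{cross_sectional}
#'   (multiverse grid), \code{contact_prediction}, \code{spatial},
#'   \code{longitudinal}, \code{config}.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  iss <- validate_config(config)
  if (any(iss$level == "blocking"))
    stop("invalid config: ", paste(iss$message[iss$level == "blocking"],
                                   collapse = "; "))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  recs <- cohort$recordings; clin <- cohort$clinical; geometry <- cohort$geometry
  stage <- "spectra"
  report <- tryCatch({
    spectra <- .session_spectra(recs, config)
    keys <- names(spectra)
    meta <- .key_fields(keys)

    fits <- periodic <- NULL
    if ("periodic" %in% config$kinds) {
      stage <- "spectral parameterization"
      fits <- lapply(spectra, specparam, settings = config$spectral)
      periodic <- mapply(periodic_spectrum, spectra, fits, SIMPLIFY = FALSE)
    }

    stage <- "alpha metrics"
    ab <- config$alpha_band
    metrics <- list()
    for (i in seq_along(keys)) {
      fit_i <- if (!is.null(fits)) fits[[i]] else NULL
      per_i <- if (!is.null(periodic)) periodic[[i]] else NULL
      pf <- if (!is.null(per_i)) individual_alpha_peak(fit_i, per_i, band = ab)
            else NA_real_
      for (kind in config$kinds) {
        spec_k <- switch(kind, absolute = spectra[[i]],
                         relative = relative_spectrum(spectra[[i]]),
                         periodic = per_i)
        metrics[[length(metrics) + 1L]] <- cbind(
          meta[i, ], kind = kind,
          canonical_alpha = band_power(spec_k, ab[1], ab[2]),
          peak_freq = pf,
          peak_alpha = if (!is.na(pf)) peak_alpha_power(spec_k, pf) else NA_real_,
          row.names = NULL)
      }
    }
    metrics <- do.call(rbind, metrics)

    stage <- "clinical matching"
    matched <- match_clinical(recs, clin, max_days = config$max_days)
    mkey <- unique(matched[, c("patient_id", "hemisphere", "session_index",
                               "ybocs", "baseline_ybocs", "stim_mA",
                               "days_since_dbs_onset")])
    table_full <- merge(metrics, mkey,
                        by = c("patient_id", "hemisphere", "session_index"))

    stage <- "contact prediction"
    s1 <- metrics[metrics$session_index == 1 & metrics$kind == config$kinds[1], ]
    leads <- unique(s1[, c("patient_id", "hemisphere")])
    maps <- list(); rankings <- list(); optimal <- list()
    norm_est <- numeric(0); norm_act <- logical(0)
    clin_pid <- vapply(clin, function(cr) cr$patient_id, character(1))
    drop_lead <- logical(nrow(leads))
    for (j in seq_len(nrow(leads))) {
      sub <- s1[s1$patient_id == leads$patient_id[j] &
                  s1$hemisphere == leads$hemisphere[j], ]
      pw <- stats::setNames(sub$canonical_alpha, sub$pair)
      mp <- pseudo_monopolar(pw, lead = as.list(leads[j, ]))
      if (any(!is.finite(mp$estimate))) {
        warning("lead ", leads$patient_id[j], " ", leads$hemisphere[j],
                " dropped: too few clean pairs for monopolar mapping")
        drop_lead[j] <- TRUE
        maps[[j]] <- mp
        rankings[[j]] <- NA
        optimal[[j]] <- integer(0)
        next
      }
      maps[[j]] <- mp
      rankings[[j]] <- rank_contacts(mp)
      cr1 <- clin[clin_pid == leads$patient_id[j]]
      cr1 <- cr1[[which.min(vapply(cr1, function(cr) cr$visit_date, numeric(1)))]]
      optimal[[j]] <- cr1$active_contacts[[leads$hemisphere[j]]]
      nv <- minmax_normalize(mp$estimate)
      norm_est <- c(norm_est, nv)
      act <- rep(FALSE, 4); act[optimal[[j]] + 1L] <- TRUE
      norm_act <- c(norm_act, act)
    }
    leads <- leads[!drop_lead, , drop = FALSE]
    maps <- maps[!drop_lead]
    rankings <- rankings[!drop_lead]
    optimal <- optimal[!drop_lead]
    curve <- selection_curve(rankings, optimal)
    contact_pred <- list(
      curve = curve, auc = auc(curve), chance = auc(chance_curve(4)),
      active_vs_inactive = compare_active_inactive(
        norm_est, norm_act, n_iter = config$n_perm, seed = config$seed),
      auc_test = auc_permutation_test(rankings, optimal,
                                      n_perm = config$n_perm, seed = config$seed),
      rank_difference = rank_difference(rankings, optimal,
                                        n_boot = config$n_boot,
                                        n_perm = config$n_perm, seed = config$seed))

    stage <- "spatial mapping"
    spatial <- NULL
    if (!is.null(geometry)) {
      pooled <- pool_hemispheres(geometry)
      coords <- NULL; est <- numeric(0); lead_lab <- character(0)
      for (j in seq_len(nrow(leads))) {
        gi <- which(pooled$patient_id == leads$patient_id[j] &
                      pooled$hemisphere == leads$hemisphere[j])
        gi <- gi[order(pooled$contact[gi])]
        coords <- rbind(coords, as.matrix(pooled[gi, c("x", "y", "z")]))
        est <- c(est, maps[[j]]$estimate)
        lead_lab <- c(lead_lab, rep(paste(leads$patient_id[j],
                                          leads$hemisphere[j]), length(gi)))
      }
      dist <- spatial_distribution(coords, est)
      ctr <- top_percentile_centroid(dist, pct = 5)
      I <- moment_of_inertia(dist)
      spatial <- list(
        centroid = ctr,
        inertia = I, radius_gyration = radius_of_gyration(I),
        distance_correlation = distance_power_correlation(
          dist, ctr, n_boot = config$n_boot, seed = config$seed),
        inertia_test = inertia_permutation_test(
          dist, lead_lab, n_perm = config$n_perm, seed = config$seed))
    }

    stage <- "cross-sectional statistics"
    grid <- expand.grid(hemisphere = config$hemispheres,
                        summary = config$summaries, kind = config$kinds,
                        stringsAsFactors = FALSE)
    cells <- list()
    t1 <- table_full[table_full$session_index == 1, ]
    for (g in seq_len(nrow(grid))) {
      sub <- t1[t1$kind == grid$kind[g], ]
      if (grid$hemisphere[g] == "left") sub <- sub[sub$hemisphere == "L", ]
      if (grid$hemisphere[g] == "right") sub <- sub[sub$hemisphere == "R", ]
      agg <- stats::aggregate(canonical_alpha ~ patient_id + hemisphere + ybocs,
                              data = sub, FUN = function(v)
                                hemisphere_summary(v, grid$summary[g]))
      cell <- if (nrow(agg) >= 4 && stats::sd(agg$ybocs) > 0 &&
                  stats::sd(agg$canonical_alpha) > 0) {
        within(spearman_bootstrap(agg$canonical_alpha, agg$ybocs,
                                  n_boot = config$n_boot,
                                  n_perm = config$n_perm, seed = config$seed),
               {ci_lo <- ci[1]; ci_hi <- ci[2]; rm(ci)})
      } else {
        warning("cross-sectional cell ", paste(grid[g, ], collapse = "/"),
                " has too few usable units; reported as NA")
        list(R = NA_real_, p_value = NA_real_, ci_lo = NA_real_,
             ci_hi = NA_real_)
      }
      cells[[g]] <- cbind(grid[g, ], cell, row.names = NULL)
    }
    cross <- do.call(rbind, cells)

    stage <- "longitudinal statistics"
    longi <- NULL
    if (max(table_full$session_index) > 1) {
      lt <- table_full[table_full$kind == config$kinds[1], ]
      agg <- stats::aggregate(
        canonical_alpha ~ patient_id + hemisphere + session_index + ybocs +
          stim_mA + days_since_dbs_onset, data = lt, FUN = max)
      names(agg)[names(agg) == "canonical_alpha"] <- "alpha"
      sd_tab <- session_deltas(agg)
      delta_cor <- if (nrow(sd_tab) >= 4 &&
                       stats::sd(sd_tab$delta_ybocs_pct) > 0 &&
                       stats::sd(sd_tab$delta_alpha_log) > 0)
        spearman_bootstrap(sd_tab$delta_ybocs_pct, sd_tab$delta_alpha_log,
                           n_boot = config$n_boot, n_perm = config$n_perm,
                           seed = config$seed) else NULL
      lme <- tryCatch(fit_lme(agg, model = "pooled_interaction"),
                      error = function(e) NULL)
      longi <- list(deltas = sd_tab, delta_correlation = delta_cor, lme = lme)
    }

    list(metrics = metrics, table = table_full, cross_sectional = cross,
         contact_prediction = contact_pred, spatial = spatial,
         longitudinal = longi, config = config)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d metric rows, %d cross-sectional cells\n",
              nrow(x$metrics), nrow(x$cross_sectional)))
  cat(sprintf("  contact prediction AUC = %.3f (chance %.2f)\n",
              x$contact_prediction$auc, x$contact_prediction$chance))
  if (!is.null(x$spatial))
    cat(sprintf("  inertia = %.1f mm^2 (radius of gyration %.2f mm)\n",
                x$spatial$inertia, x$spatial$radius_gyration))
  invisible(x)
}
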
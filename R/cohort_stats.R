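#' Split patients into severity groups
#'
#' Median split on Y-BOCS at the first recording session: patients at or
#' above the split value are "more severe". An explicit threshold override
#' is supported (e.g. Y-BOCS >= 30).
#'
#' @param ybocs Named numeric vector of S1 Y-BOCS scores (names = patient ids).
#' @param threshold Optional explicit threshold; if given, more severe means
#'   \code{ybocs >= threshold}.
#' @return List with \code{less_severe} and \code{more_severe} (patient ids)
#'   and \code{threshold} used.
#' @export
stratify_severity <- function(ybocs, threshold = NULL) {
  if (length(ybocs) < 2) stop("need at least 2 patients")
  if (length(unique(ybocs)) == 1) stop("all Y-BOCS identical: cannot stratify")
  thr <- if (is.null(threshold)) stats::median(ybocs) else threshold
  more <- ybocs >= thr
  list(less_severe = names(ybocs)[!more], more_severe = names(ybocs)[more],
       threshold = thr)
}

#' Responder classification
#'
#' Responder iff Y-BOCS improved by at least 35% relative to the
#' pre-operative baseline (inclusive).
#'
#' @param baseline_ybocs Pre-operative Y-BOCS (> 0).
#' @param ybocs Current Y-BOCS.
#' @return Logical.
#' @export
classify_responder <- function(baseline_ybocs, ybocs) {
  if (any(baseline_ybocs <= 0)) stop("baseline Y-BOCS must be positive")
  100 * (baseline_ybocs - ybocs) / baseline_ybocs >= 35
}

# contiguous same-sign supra-threshold runs; mass = sum of the statistic;
# non-finite statistics (e.g. zero-variance bins) never form clusters
.find_clusters <- function(tstat, above) {
  bad <- !is.finite(tstat)
  tstat[bad] <- 0
  above[bad | is.na(above)] <- FALSE
  sgn <- sign(tstat) * above
  r <- rle(sgn)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values != 0
  if (!any(keep)) return(data.frame(start = integer(0), end = integer(0),
                                    mass = numeric(0)))
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep), function(i)
               sum(tstat[starts[i]:ends[i]]), numeric(1)))
}

.welch_t <- function(mA, vA, nA, mB, vB, nB) {
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  list(t = t, df = df)
}

#' Cluster-based permutation test on power spectra
#'
#' Frequency-wise two-sample contrast of spectra with cluster-based
#' correction of the family-wise error rate. Per bin, an unpaired Welch t or
#' paired t statistic is computed; bins exceeding the two-sided t critical
#' value at \code{alpha_cluster} form candidate clusters of contiguous bins
#' with the same sign, scored by the summed t (cluster mass). The null is
#' the distribution of the maximum absolute cluster mass over label
#' permutations (unpaired) or within-unit sign flips (paired). Clusters with
#' corrected p below \code{alpha_fw} are significant.
#'
#' @param groupA,groupB Matrices, units x frequency bins, on a common grid.
#'   For \code{paired = TRUE} rows must be matched and equal in number.
#' @param freqs Frequency grid (bin centers, Hz).
#' @param paired Paired contrast (sign-flip null)?
#' @param alpha_fw Family-wise alpha (default 0.01).
#' @param alpha_cluster Cluster-forming per-bin alpha, two-sided (default 0.05).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return An object of class \code{cluster_result}: data frame
#'   \code{clusters} (f_lo, f_hi, mass, p_value, significant), per-bin
#'   \code{tstat}, \code{freqs}, \code{alpha_fw}.
#' @export
cluster_permutation_spectra <- function(groupA, groupB, freqs, paired = FALSE,
                                        alpha_fw = 0.01, alpha_cluster = 0.05,
                                        n_perm = 10000, seed = 1) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB) || ncol(groupA) != length(freqs))
    stop("spectra must share a common frequency grid")
  nA <- nrow(groupA); nB <- nrow(groupB)
  if (nA < 2 || nB < 2) stop("need at least 2 units per group")
  set.seed(seed)
  if (paired) {
    if (nA != nB) stop("paired contrast requires matched units")
    D <- groupA - groupB
    n <- nA
    m2 <- colMeans(D^2)
    stat_fun <- function(md) {
      v <- (m2 - md^2) * n / (n - 1)
      md / sqrt(v / n)
    }
    tobs <- stat_fun(colMeans(D))
    tcrit <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
    above_obs <- abs(tobs) > tcrit
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    MD <- crossprod(D, S) / n            # bins x n_perm
    V <- (m2 - MD^2) * n / (n - 1)
    TP <- MD / sqrt(V / n)
    null <- vapply(seq_len(n_perm), function(p) {
      tp <- TP[, p]
      cl <- .find_clusters(tp, abs(tp) > tcrit)
      if (nrow(cl) == 0) 0 else max(abs(cl$mass))
    }, numeric(1))
  } else {
    X <- rbind(groupA, groupB)
    n <- nA + nB
    wt <- .welch_t(colMeans(groupA), apply(groupA, 2, stats::var), nA,
                   colMeans(groupB), apply(groupB, 2, stats::var), nB)
    tobs <- wt$t
    above_obs <- abs(tobs) > stats::qt(1 - alpha_cluster / 2, df = wt$df)
    X2 <- X^2
    # group-A membership indicator per permutation; all bin-wise moments in
    # two matrix products
    M <- matrix(0, n, n_perm)
    for (p in seq_len(n_perm)) M[sample.int(n, nA), p] <- 1
    tX <- t(X); tX2 <- t(X2)
    sumA <- tX %*% M; sumA2 <- tX2 %*% M
    totS <- colSums(X); totS2 <- colSums(X2)
    MA <- sumA / nA; MB <- (totS - sumA) / nB
    VA <- (sumA2 / nA - MA^2) * nA / (nA - 1)
    VB <- ((totS2 - sumA2) / nB - MB^2) * nB / (nB - 1)
    SE2 <- VA / nA + VB / nB
    TP <- (MA - MB) / sqrt(SE2)
    DF <- SE2^2 / ((VA / nA)^2 / (nA - 1) + (VB / nB)^2 / (nB - 1))
    TC <- stats::qt(1 - alpha_cluster / 2, df = DF)
    null <- vapply(seq_len(n_perm), function(p) {
      tp <- TP[, p]
      cl <- .find_clusters(tp, abs(tp) > TC[, p])
      if (nrow(cl) == 0) 0 else max(abs(cl$mass))
    }, numeric(1))
  }
  cl <- .find_clusters(tobs, above_obs)
  p <- vapply(cl$mass, function(m) .perm_p(null, abs(m), "right"), numeric(1))
  clusters <- data.frame(f_lo = freqs[cl$start], f_hi = freqs[cl$end],
                         mass = cl$mass, p_value = p,
                         significant = p < alpha_fw)
  structure(list(clusters = clusters, tstat = tobs, freqs = freqs,
                 alpha_fw = alpha_fw, null = null),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), alpha_fw = %g>\n",
              nrow(x$clusters), x$alpha_fw))
  if (nrow(x$clusters) > 0) print(format(x$clusters, digits = 3), row.names = FALSE)
  invisible(x)
}

.col_spearman <- function(X, y) {
  ry <- rank(y)
  RX <- apply(X, 2, rank)
  ry <- ry - mean(ry)
  RX <- sweep(RX, 2, colMeans(RX))
  num <- as.numeric(crossprod(RX, ry))
  den <- sqrt(colSums(RX^2) * sum(ry^2))
  num / den
}

#' Frequency-wise Spearman correlation with cluster correction
#'
#' Correlates power at each frequency bin with Y-BOCS across units, with a
#' percentile bootstrap band and a cluster-based permutation test: the
#' per-bin correlation is converted to a t statistic, thresholded two-sided
#' at \code{alpha_cluster}, and cluster mass compared against the maximum
#' null mass under Y-BOCS permutations.
#'
#' @param spectra Matrix, units x frequency bins.
#' @param ybocs Numeric per unit.
#' @param freqs Frequency grid (Hz).
#' @param n_boot Bootstrap resamples for the CI band (default 10000).
#' @param alpha_fw Family-wise alpha (default 0.01).
#' @param alpha_cluster Cluster-forming per-bin alpha (default 0.05).
#' @param n_perm Permutations (default 10000).
#' @param seed Integer seed.
#' @return List with \code{R} (per bin), \code{ci_lo}, \code{ci_hi},
#'   \code{clusters} (a \code{cluster_result}), \code{freqs}.
#' @export
frequencywise_correlation <- function(spectra, ybocs, freqs, n_boot = 10000,
                                      alpha_fw = 0.01, alpha_cluster = 0.05,
                                      n_perm = 10000, seed = 1) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (n < 5) stop("need at least 5 units")
  if (stats::sd(ybocs) == 0) stop("constant Y-BOCS: correlation undefined")
  R <- .col_spearman(spectra, ybocs)
  r2t <- function(r) r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  tcrit <- stats::qt(1 - alpha_cluster / 2, df = n - 2)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(freqs))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(ybocs[idx]) == 0) next
    boot[b, ] <- .col_spearman(spectra[idx, , drop = FALSE], ybocs[idx])
  }
  # ranks of a permuted vector are the permuted ranks, so the null needs a
  # single rank pass plus one matrix product
  RX <- apply(spectra, 2, rank)
  RX <- sweep(RX, 2, colMeans(RX))
  ry0 <- rank(ybocs); ry0 <- ry0 - mean(ry0)
  RY <- vapply(seq_len(n_perm), function(p) ry0[sample.int(n)],
               numeric(n))
  NUMS <- crossprod(RX, RY)
  DEN <- sqrt(colSums(RX^2) * sum(ry0^2))
  RP <- NUMS / DEN
  null <- vapply(seq_len(n_perm), function(p) {
    tp <- r2t(RP[, p])
    cl <- .find_clusters(tp, abs(tp) > tcrit)
    if (nrow(cl) == 0) 0 else max(abs(cl$mass))
  }, numeric(1))
  tobs <- r2t(R)
  cl <- .find_clusters(tobs, abs(tobs) > tcrit)
  p <- vapply(cl$mass, function(m) .perm_p(null, abs(m), "right"), numeric(1))
  clusters <- structure(list(
    clusters = data.frame(f_lo = freqs[cl$start], f_hi = freqs[cl$end],
                          mass = cl$mass, p_value = p, significant = p < alpha_fw),
    tstat = tobs, freqs = freqs, alpha_fw = alpha_fw, null = null),
    class = "cluster_result")
  list(R = R, ci_lo = apply(boot, 2, stats::quantile, 0.025, na.rm = TRUE),
       ci_hi = apply(boot, 2, stats::quantile, 0.975, na.rm = TRUE),
       clusters = clusters, freqs = freqs)
}

#' Session-to-session changes relative to S1
#'
#' For each (patient, hemisphere), the change at session s relative to the
#' first recording session: Y-BOCS as a percentage improvement
#' (100 (ybocs_S1 - ybocs_s)/ybocs_S1, so positive = clinical improvement)
#' and alpha power as a log-ratio (log(alpha_s/alpha_S1), so negative =
#' suppression). Periodic (log-residual) alpha can be nonpositive; when it
#' is, the whole alpha column is shifted to positivity before ratios and the
#' shift is recorded in the \code{"alpha_shift"} attribute.
#'
#' @param table Data frame with columns patient_id, hemisphere,
#'   session_index, ybocs, alpha.
#' @return Data frame of non-S1 rows with delta_ybocs_pct and
#'   delta_alpha_log; rows whose S1 Y-BOCS is 0 are dropped with a warning.
#' @export
session_deltas <- function(table) {
  need <- c("patient_id", "hemisphere", "session_index", "ybocs", "alpha")
  stopifnot(all(need %in% names(table)))
  alpha <- table$alpha
  shift <- 0
  if (min(alpha) <= 0) {
    rng <- diff(range(alpha))
    shift <- -min(alpha) + if (rng > 0) 1e-3 * rng else 1
    alpha <- alpha + shift
  }
  key <- interaction(table$patient_id, table$hemisphere, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    sub <- which(key == k)
    s1 <- sub[table$session_index[sub] == 1]
    if (length(s1) == 0) next
    s1 <- s1[1]
    if (table$ybocs[s1] == 0) {
      warning("S1 Y-BOCS is 0 for ", k, "; rows dropped")
      next
    }
    rest <- sub[table$session_index[sub] != 1]
    if (length(rest) == 0) next
    out[[k]] <- data.frame(
      patient_id = table$patient_id[rest], hemisphere = table$hemisphere[rest],
      session_index = table$session_index[rest],
      delta_ybocs_pct = 100 * (table$ybocs[s1] - table$ybocs[rest]) / table$ybocs[s1],
      delta_alpha_log = log(alpha[rest] / alpha[s1]),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(patient_id = character(0), hemisphere = character(0),
               session_index = integer(0), delta_ybocs_pct = numeric(0),
               delta_alpha_log = numeric(0))
  rownames(res) <- NULL
  attr(res, "alpha_shift") <- shift
  res
}

#' Linear mixed-effects model of symptom severity on alpha power
#'
#' Fits, by REML with a random intercept per patient, either the pooled
#' model \code{ybocs ~ hemisphere * alpha + stim_mA + days + (1|patient_id)}
#' or the simpler per-hemisphere model
#' \code{ybocs ~ alpha + stim_mA + days + (1|patient_id)}. Alpha and
#' stimulation amplitude are centered before fitting; hemisphere L is the
#' reference level. Inference uses Satterthwaite degree-of-freedom
#' approximation (type III F tests).
#'
#' @param table Data frame with columns patient_id, hemisphere, session_index,
#'   ybocs, alpha, stim_mA, days_since_dbs_onset.
#' @param model "pooled_interaction" or "per_hemisphere".
#' @param hemisphere For \code{model = "per_hemisphere"}, which hemisphere to
#'   fit ("L" or "R").
#' @return List with \code{fit} (the lmerTest model), \code{coefficients}
#'   (estimate, SE, df, t, p per fixed effect) and \code{anova}
#'   (Satterthwaite F tests).
#' @export
fit_lme <- function(table, model = c("pooled_interaction", "per_hemisphere"),
                    hemisphere = NULL) {
  model <- match.arg(model)
  need <- c("patient_id", "ybocs", "alpha", "stim_mA", "days_since_dbs_onset")
  stopifnot(all(need %in% names(table)))
  df <- table
  if (model == "per_hemisphere") {
    if (is.null(hemisphere)) stop("per_hemisphere model requires a hemisphere")
    df <- df[df$hemisphere == hemisphere, , drop = FALSE]
  }
  if (length(unique(df$patient_id)) < 2) stop("need at least 2 patients")
  df$alpha_c <- df$alpha - mean(df$alpha)
  df$stim_c <- df$stim_mA - mean(df$stim_mA)
  df$hemisphere <- factor(df$hemisphere, levels = c("L", "R"))
  form <- if (model == "pooled_interaction")
    ybocs ~ hemisphere * alpha_c + stim_c + days_since_dbs_onset + (1 | patient_id)
  else
    ybocs ~ alpha_c + stim_c + days_since_dbs_onset + (1 | patient_id)
  mm <- stats::model.matrix(stats::as.formula(paste(
    "~", deparse(form[[3]][[2]]))), df)
  if (qr(mm)$rank < ncol(mm)) {
    qrm <- qr(mm)
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  fit <- lmerTest::lmer(form, data = df, REML = TRUE)
  cf <- summary(fit)$coefficients
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  list(fit = fit,
       coefficients = data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                                 se = cf[, "Std. Error"], df = cf[, "df"],
                                 t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                                 row.names = NULL),
       anova = an)
}

#' Contrast the first session with the best clinical session
#'
#' Per patient, selects the session with the largest Y-BOCS reduction
#' relative to the pre-operative baseline (ties toward the earlier session)
#' and runs the paired cluster-based permutation contrast of S1 vs best
#' session spectra. Patients whose best session is S1 (or with only S1) are
#' excluded with a warning. Spectra sharing a (patient, session) key (e.g.
#' the two hemispheres) are averaged first.
#'
#' @param table Data frame with columns patient_id, session_index, ybocs,
#'   baseline_ybocs; one row per spectra row.
#' @param spectra Matrix, rows aligned with \code{table}, columns = bins.
#' @param freqs Frequency grid (Hz).
#' @param ... Passed to \code{\link{cluster_permutation_spectra}}.
#' @return A \code{cluster_result}; attribute \code{"best_session"} maps
#'   patient to chosen session.
#' @export
best_session_contrast <- function(table, spectra, freqs, ...) {
  spectra <- as.matrix(spectra)
  stopifnot(nrow(table) == nrow(spectra))
  # aggregate duplicate (patient, session) rows
  key <- paste(table$patient_id, table$session_index, sep = "|")
  agg <- rowsum(spectra, key)
  cnt <- table(key)
  agg <- agg / as.vector(cnt[rownames(agg)])
  meta <- unique(data.frame(patient_id = table$patient_id,
                            session_index = table$session_index,
                            ybocs = table$ybocs,
                            baseline_ybocs = table$baseline_ybocs,
                            key = key, stringsAsFactors = FALSE))
  agg <- agg[meta$key, , drop = FALSE]
  pats <- unique(meta$patient_id)
  A <- NULL; B <- NULL; chosen <- list()
  for (p in pats) {
    sub <- meta[meta$patient_id == p, , drop = FALSE]
    if (nrow(sub) < 2) { warning("patient ", p, " has a single session; excluded"); next }
    impr <- 100 * (sub$baseline_ybocs - sub$ybocs) / sub$baseline_ybocs
    best <- sub$session_index[order(-impr, sub$session_index)][1]
    if (best == 1) { warning("best session for ", p, " is S1; excluded"); next }
    A <- rbind(A, agg[sub$key[sub$session_index == 1], ])
    B <- rbind(B, agg[sub$key[sub$session_index == best], ])
    chosen[[p]] <- best
  }
  if (is.null(A) || nrow(A) < 2) stop("fewer than 2 patients with a usable best session")
  out <- cluster_permutation_spectra(A, B, freqs, paired = TRUE, ...)
  attr(out, "best_session") <- chosen
  out
}

#' Spearman correlation with bootstrap CI and permutation p
#'
#' @param x,y Paired numeric vectors (n >= 4).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param n_perm Permutations for the p-value (default 10000).
#' @param sidedness "two" (default), "right" or "left".
#' @param seed Integer seed.
#' @return List with \code{R}, \code{ci} (95% percentile bootstrap),
#'   \code{p_value}.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 10000, n_perm = 10000,
                               sidedness = c("two", "right", "left"), seed = 1) {
  sidedness <- match.arg(sidedness)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input: correlation undefined")
  R <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx], method = "spearman")
  }, numeric(1))
  null <- vapply(seq_len(n_perm), function(p)
    stats::cor(x, y[sample.int(n)], method = "spearman"), numeric(1))
  p <- switch(sidedness,
              right = .perm_p(null, R, "right"),
              left = .perm_p(null, R, "left"),
              two = min(1, (1 + sum(abs(null) >= abs(R))) / (1 + n_perm)))
  list(R = R, ci = unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)),
       p_value = p)
}
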
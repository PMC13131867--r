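test_that("severity stratification splits at the median or an override", {
  y <- c(P1 = 20, P2 = 25, P3 = 32, P4 = 38)
  g <- stratify_severity(y)
  expect_setequal(g$less_severe, c("P1", "P2"))
  expect_setequal(g$more_severe, c("P3", "P4"))

  g30 <- stratify_severity(c(A = 29, B = 30), threshold = 30)
  expect_equal(g30$less_severe, "A")
  expect_equal(g30$more_severe, "B")   # >= convention at the threshold

  expect_error(stratify_severity(c(A = 30, B = 30)), "identical")
})

test_that("responder rule is a 35% improvement, inclusive", {
  expect_true(classify_responder(40, 24))
  expect_true(classify_responder(40, 26))   # exactly 35%
  expect_false(classify_responder(40, 30))
  expect_error(classify_responder(0, 10), "positive")
})

test_that("cluster tests find planted band differences and nothing in nulls", {
  set.seed(30)
  fr <- fit_grid()
  A <- matrix(rnorm(12 * length(fr)), 12)
  B <- matrix(rnorm(12 * length(fr)), 12)
  sel <- fr >= 9 & fr <= 11
  B[, sel] <- B[, sel] + 2.5
  res <- cluster_permutation_spectra(A, B, fr, n_perm = 1000, seed = 9)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  expect_lte(min(sig$f_lo), 9)
  expect_gte(max(sig$f_hi), 11)

  # paired contrast of identical groups: no clusters at all
  same <- cluster_permutation_spectra(A, A + 0, fr, paired = TRUE,
                                      n_perm = 100, seed = 10)
  expect_equal(nrow(same$clusters), 0)

  expect_error(cluster_permutation_spectra(A[1, , drop = FALSE], B, fr),
               "at least 2")
})

test_that("frequency-wise correlations are rank-invariant with calibrated clusters", {
  set.seed(31)
  fr <- seq(1, 30, 0.5)
  n <- 24
  spectra <- matrix(rnorm(n * length(fr)), n)
  driver <- spectra[, fr == 10]
  ybocs <- rank(driver)  # strictly monotone in 10 Hz power, noise-free
  res <- frequencywise_correlation(spectra, ybocs, fr, n_boot = 200,
                                   n_perm = 500, seed = 11)
  expect_equal(res$R[fr == 10], 1)

  # strictly increasing transform leaves R unchanged
  res2 <- frequencywise_correlation(spectra, exp(ybocs / 10), fr, n_boot = 50,
                                    n_perm = 50, seed = 11)
  expect_equal(res2$R, res$R)

  expect_error(frequencywise_correlation(spectra, rep(5, n), fr), "constant")
})

test_that("session deltas carry the documented signs and antisymmetry", {
  tab <- data.frame(patient_id = "P1", hemisphere = "L",
                    session_index = c(1, 2, 3),
                    ybocs = c(30, 15, 30), alpha = c(2, 1, 2))
  d <- session_deltas(tab)
  expect_equal(d$delta_ybocs_pct[d$session_index == 2], 50)
  expect_equal(d$delta_alpha_log[d$session_index == 2], log(0.5))
  expect_equal(d$delta_ybocs_pct[d$session_index == 3], 0)
  expect_equal(d$delta_alpha_log[d$session_index == 3], 0)

  # swapping the roles of the two sessions negates the log-ratio exactly
  tab2 <- data.frame(patient_id = "P1", hemisphere = "L",
                     session_index = c(1, 2), ybocs = c(15, 30),
                     alpha = c(1, 2))
  d2 <- session_deltas(tab2)
  expect_equal(d2$delta_alpha_log, -d$delta_alpha_log[d$session_index == 2])

  # nonpositive periodic alpha triggers the recorded shift
  tab3 <- data.frame(patient_id = "P1", hemisphere = "L",
                     session_index = c(1, 2), ybocs = c(30, 20),
                     alpha = c(-0.1, 0.2))
  d3 <- session_deltas(tab3)
  expect_gt(attr(d3, "alpha_shift"), 0.1)
  expect_true(all(is.finite(d3$delta_alpha_log)))
})

test_that("the mixed model recovers a known alpha coefficient", {
  gen_table <- function(seed, beta = 15) {
    set.seed(seed)
    np <- 12; ns <- 4
    rows <- expand.grid(patient_id = sprintf("P%02d", 1:np),
                        hemisphere = c("L", "R"), session_index = 1:ns,
                        stringsAsFactors = FALSE)
    b <- rnorm(np, sd = 3)
    names(b) <- sprintf("P%02d", 1:np)
    rows$alpha <- rnorm(nrow(rows), sd = 0.3)
    rows$stim_mA <- runif(nrow(rows), 0, 5)
    rows$days_since_dbs_onset <- (rows$session_index - 1) * 90
    rows$ybocs <- 22 + beta * rows$alpha + b[rows$patient_id] +
      rnorm(nrow(rows), sd = 2)
    rows
  }
  fits <- lapply(1:8, function(s) fit_lme(gen_table(s), "pooled_interaction"))
  est <- vapply(fits, function(f)
    f$coefficients$estimate[f$coefficients$term == "alpha_c"], numeric(1))
  expect_lt(abs(mean(est) - 15) / 15, 0.1)

  # duplicating every row leaves point estimates essentially unchanged
  # (REML re-balances variance components, so equality is approximate)
  tab <- gen_table(99)
  f1 <- fit_lme(tab, "pooled_interaction")
  f2 <- fit_lme(rbind(tab, tab), "pooled_interaction")
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 0.05)

  # per-hemisphere model runs on a subset
  fh <- fit_lme(tab, "per_hemisphere", hemisphere = "L")
  expect_true("alpha_c" %in% fh$coefficients$term)

  # collinear design is refused with the offending column named
  bad <- tab
  bad$stim_mA <- bad$days_since_dbs_onset
  expect_error(fit_lme(bad, "pooled_interaction"), "collinear")
})

test_that("the best-session contrast picks maximal improvement with ties to earlier", {
  fr <- seq(1, 30, 0.5)
  set.seed(32)
  np <- 10
  rows <- expand.grid(patient_id = sprintf("P%d", 1:np), session_index = 1:3,
                      stringsAsFactors = FALSE)
  rows$baseline_ybocs <- 36
  rows$ybocs <- ifelse(rows$session_index == 1, 30,
                       ifelse(rows$session_index == 2, 18, 18))
  spectra <- matrix(rnorm(nrow(rows) * length(fr)), nrow(rows))
  # alpha suppression at the best session
  sel <- fr >= 9 & fr <= 11
  best_rows <- rows$session_index == 2
  spectra[best_rows, sel] <- spectra[best_rows, sel] - 3
  res <- best_session_contrast(rows, spectra, fr, n_perm = 500, seed = 12)
  # tie between sessions 2 and 3 resolved to the earlier (2)
  expect_true(all(unlist(attr(res, "best_session")) == 2))
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$f_lo <= 9 & sig$f_hi >= 11))
  # S1 minus best is positive where alpha was suppressed
  expect_gt(res$clusters$mass[which.max(abs(res$clusters$mass))], 0)
})

test_that("spearman bootstrap handles exact and null relationships", {
  x <- 1:12
  res <- spearman_bootstrap(x, x, n_boot = 200, n_perm = 200, seed = 13)
  expect_equal(res$R, 1)
  expect_equal(res$ci[2], 1)
  res2 <- spearman_bootstrap(x, -x, n_boot = 100, n_perm = 100, seed = 14)
  expect_equal(res2$R, -1)
  expect_error(spearman_bootstrap(x, rep(1, 12)), "constant")
  expect_error(spearman_bootstrap(1:3, 1:3), "at least 4")
})
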
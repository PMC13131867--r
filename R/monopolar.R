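#' Pseudo-monopolar per-contact power estimates
#'
#' Projects the six bipolar pair powers of a 4-contact lead onto per-contact
#' estimates. For each contact \eqn{c} the estimate is the maximum of two
#' quantities: (1) the mean power of the three pairs that include \eqn{c}
#' (for contact 0: pairs 0-1, 0-2, 0-3) and (2) the power of pairs that span
#' across \eqn{c} without including it (for contact 1: pair 0-2; for contact
#' 2: pair 1-3; spanning also includes 0-3 for both inner contacts). With
#' more than one spanning pair, quantity (2) takes their maximum by default
#' (consistent with the outer max rule); the mean is offered as an option.
#' Outer contacts 0 and 3 have no spanning pairs.
#'
#' @param pair_powers Named numeric vector of the 6 pair powers, names
#'   "01","02","03","12","13","23". Missing pairs (NA or absent) degrade
#'   quantity (1) to the available pairs with a warning.
#' @param spanning "max" (default) or "mean" for combining multiple spanning
#'   pairs.
#' @param lead Optional lead identity list (patient_id, hemisphere,
#'   session_index) carried through to the result.
#' @return An object of class \code{monopolar_map}: \code{estimate} (length-4
#'   numeric, contacts 0-3), \code{rule} (which quantity won per contact),
#'   \code{lead}.
#' @export
pseudo_monopolar <- function(pair_powers, spanning = c("max", "mean"), lead = NULL) {
  spanning <- match.arg(spanning)
  all_pairs <- c("01", "02", "03", "12", "13", "23")
  pw <- setNames(rep(NA_real_, 6), all_pairs)
  pw[names(pair_powers)] <- as.numeric(pair_powers)
  if (all(is.na(pw))) stop("all pairs missing")
  if (any(is.na(pw))) warning("incomplete lead: ", sum(is.na(pw)), " pair(s) missing")
  pair_idx <- rbind(c(0,1), c(0,2), c(0,3), c(1,2), c(1,3), c(2,3))
  estimate <- numeric(4); rule <- character(4)
  for (ct in 0:3) {
    incl <- pair_idx[, 1] == ct | pair_idx[, 2] == ct
    q1 <- mean(pw[incl], na.rm = TRUE)
    span <- pair_idx[, 1] < ct & pair_idx[, 2] > ct
    q2 <- if (any(span) && any(!is.na(pw[span]))) {
      if (spanning == "max") max(pw[span], na.rm = TRUE) else mean(pw[span], na.rm = TRUE)
    } else NA_real_
    if (!is.na(q2) && q2 > q1) {
      estimate[ct + 1] <- q2; rule[ct + 1] <- "spanning"
    } else {
      estimate[ct + 1] <- q1; rule[ct + 1] <- "including_mean"
    }
  }
  structure(list(estimate = estimate, rule = rule, lead = lead),
            class = "monopolar_map")
}

#' @export
print.monopolar_map <- function(x, ...) {
  cat("<monopolar_map>\n")
  for (ct in 0:3)
    cat(sprintf("  contact %d: %.4g (%s)\n", ct, x$estimate[ct + 1], x$rule[ct + 1]))
  invisible(x)
}
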
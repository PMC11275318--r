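# Internal validation: heuristic shrinkage, sliding-window concordance with
# leave-one-out cross-validation, and reverse Kaplan-Meier median follow-up.

#' Heuristic shrinkage factor
#'
#' `(chi2 - p) / chi2` with `chi2 = 2 (loglik_model - loglik_null)` the
#' likelihood-ratio chi-square of the stacked fit and `p` the number of
#' estimated coefficients. Values near 1 indicate little overfitting; the
#' value may be negative for useless models and is reported as-is.
#'
#' @param fit A [fit_supermodel()] result.
#' @return Scalar; `NA` (with a warning) when `chi2` is 0.
#' @export
heuristic_shrinkage <- function(fit) {
  chi2 <- 2 * (fit$loglik_model - fit$loglik_null)
  p <- length(coef(fit))
  if (chi2 <= 0) {
    warning("model chi-square is zero; shrinkage undefined", call. = FALSE)
    return(NA_real_)
  }
  (chi2 - p) / chi2
}

#' Windowed concordance of scores against survival times
#'
#' Harrell's rule restricted to a window: among subjects at risk at `t`
#' (`time > t`), a pair (i, j) is comparable when i dies at
#' `ti` with `t < ti <= t + w` and `tj > ti`. Concordant when the dying
#' subject has the higher score; score ties count 1/2.
#'
#' @param time,status Observed times and event indicators (1 = death).
#' @param score Risk scores (higher = predicted to die sooner).
#' @param t Landmark time.
#' @param w Window width.
#' @return List with `cindex`, `concordant` (ties counted 1/2) and `pairs`;
#'   `cindex` is `NA` when no pair is comparable.
#' @export
cindex_window <- function(time, status, score, t, w) {
  at_risk <- time > t
  time <- time[at_risk]; status <- status[at_risk]; score <- score[at_risk]
  deaths <- which(status == 1 & time <= t + w)
  pairs <- 0; conc <- 0
  for (i in deaths) {
    later <- time > time[i]
    pairs <- pairs + sum(later)
    conc <- conc + sum(score[i] > score[later]) +
      0.5 * sum(score[i] == score[later])
  }
  list(cindex = if (pairs == 0) NA_real_ else conc / pairs,
       concordant = conc, pairs = pairs)
}

# Risk score of each cohort row at landmark t under a fit: the supermodel
# linear predictor with the patient's own LR/NM status at t.
.cohort_scores <- function(fit, cohort, t) {
  x <- encode_covariates(cohort)
  beta <- coef(fit)
  val <- cbind(x,
               hist_s = x[, "hist_poor"] * t,
               hist_s2 = x[, "hist_poor"] * t^2,
               lr_status = as.numeric(!is.na(cohort$t_lr) & cohort$t_lr <= t),
               nm_status = as.numeric(!is.na(cohort$t_nm) & cohort$t_nm <= t),
               s = t, s2 = t^2)
  drop(val[, names(beta), drop = FALSE] %*% beta)
}

#' Dynamic cross-validated concordance index
#'
#' The risk score of each patient at landmark `t` is the supermodel linear
#' predictor given their covariates and LR/NM status at `t`. With
#' `loo = TRUE`, patient i's score comes from a supermodel fitted with all of
#' i's stacked rows removed (one refit per at-risk patient: the unit of
#' cross-validation is the patient). `loo = FALSE` is a fast approximation
#' that scores everyone from the single full fit; the result is flagged
#' accordingly.
#'
#' @param cohort Eligible cohort with complete covariates.
#' @param t Landmark time in years.
#' @param w Window in years.
#' @param grid [landmark_grid()] used to build the stack for fitting.
#' @param loo Leave-one-out cross-validation flag.
#' @param fit Optional pre-computed full fit (used when `loo = FALSE`).
#' @return List with `cindex`, `pairs`, `t`, `w`, `method` ("loo" or
#'   "full-fit") and `n_refits`.
#' @export
dynamic_cindex <- function(cohort, t, w = 5, grid = landmark_grid(),
                           loo = FALSE, fit = NULL) {
  stack <- build_landmark_stack(cohort, grid)
  at_risk <- cohort$t_os > t
  n_refits <- 0L
  if (loo) {
    scores <- rep(NA_real_, nrow(cohort))
    for (i in which(at_risk)) {
      sub <- stack[stack$id != cohort$id[i], , drop = FALSE]
      attr(sub, "grid") <- attr(stack, "grid")
      fit_i <- fit_supermodel(sub, robust = FALSE)
      n_refits <- n_refits + 1L
      scores[i] <- .cohort_scores(fit_i, cohort[i, , drop = FALSE], t)
    }
  } else {
    if (is.null(fit)) fit <- fit_supermodel(stack, robust = FALSE)
    scores <- .cohort_scores(fit, cohort, t)
  }
  cw <- cindex_window(cohort$t_os, cohort$os_status, scores, t, w)
  list(cindex = cw$cindex, pairs = cw$pairs, t = t, w = w,
       method = if (loo) "loo" else "full-fit", n_refits = n_refits)
}

#' Reverse Kaplan-Meier median follow-up
#'
#' Kaplan-Meier estimate with the roles of death and censoring swapped
#' (censorings are the "events"); the median of this curve estimates median
#' follow-up. The CI uses the Greenwood variance on the log(-log) scale; the
#' median CI bounds are the first times at which the upper/lower confidence
#' curves drop to 0.5 or below.
#'
#' @param cohort Cohort with `t_os` and `os_status`.
#' @param level Confidence level.
#' @return List with `median`, `lower`, `upper` (each `NA` when not
#'   reached) and the step `curve` (`time`, `surv`, `lower`, `upper`).
#' @export
reverse_km_median_followup <- function(cohort, level = 0.95) {
  time <- cohort$t_os
  event <- 1L - cohort$os_status  # censoring becomes the event
  stopifnot(!anyNA(time), !anyNA(event))
  ut <- sort(unique(time[event == 1]))
  n <- length(time)
  surv <- numeric(length(ut)); varsum <- numeric(length(ut))
  s <- 1; vs <- 0
  for (k in seq_along(ut)) {
    tk <- ut[k]
    nrisk <- sum(time >= tk)
    d <- sum(time == tk & event == 1)
    s <- s * (1 - d / nrisk)
    if (nrisk > d) vs <- vs + d / (nrisk * (nrisk - d))
    surv[k] <- s; varsum[k] <- vs
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  # log(-log S) CI; undefined where S is 0 or 1
  ok <- surv > 0 & surv < 1
  se_ll <- rep(NA_real_, length(ut))
  se_ll[ok] <- sqrt(varsum[ok]) / abs(log(surv[ok]))
  lower <- upper <- rep(NA_real_, length(ut))
  lower[ok] <- surv[ok]^exp(z * se_ll[ok])
  upper[ok] <- surv[ok]^exp(-z * se_ll[ok])
  first_below <- function(v) {
    hit <- which(!is.na(v) & v <= 0.5)
    if (!length(hit)) NA_real_ else ut[hit[1]]
  }
  list(median = first_below(surv),
       lower = first_below(lower), upper = first_below(upper),
       curve = data.frame(time = ut, surv = surv,
                          lower = lower, upper = upper))
}
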
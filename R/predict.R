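# Time-varying hazard ratio and dynamic fixed-window death probabilities.

#' Time-varying hazard-ratio effect
#'
#' Represents an effect with constant, linear and quadratic hazard-ratio
#' components: `HR(tp) = constant x linear^tp x quadratic^(tp^2)`, with `tp`
#' the prediction time in years since surgery. Used for the poor-vs-good
#' histological response effect, whose strength fades during follow-up.
#'
#' @param constant,linear,quadratic Hazard-ratio components (all > 0).
#' @param covariance Optional 3x3 covariance of the components on the log
#'   scale, ordered (constant, linear, quadratic); needed for CIs.
#' @return Object of class `tv_effect`.
#' @export
tv_effect <- function(constant, linear = 1, quadratic = 1,
                      covariance = NULL) {
  stopifnot(constant > 0, linear > 0, quadratic > 0)
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    stopifnot(all(dim(covariance) == c(3, 3)))
  }
  structure(list(constant = constant, linear = linear,
                 quadratic = quadratic, covariance = covariance),
            class = "tv_effect")
}

#' Extract the histological-response time-varying effect from a fit
#'
#' @param fit A [fit_supermodel()] result containing terms `hist_poor`,
#'   `hist_s` and `hist_s2`.
#' @param robust Use the cluster-robust covariance.
#' @return A [tv_effect()].
#' @export
tv_effect_from_fit <- function(fit, robust = TRUE) {
  terms <- c("hist_poor", "hist_s", "hist_s2")
  beta <- coef(fit)
  if (!all(terms %in% names(beta))) {
    stop("fit lacks the histology interaction terms ",
         paste(setdiff(terms, names(beta)), collapse = ", "), call. = FALSE)
  }
  v <- vcov(fit, robust = robust)[terms, terms]
  tv_effect(exp(beta[["hist_poor"]]), exp(beta[["hist_s"]]),
            exp(beta[["hist_s2"]]), covariance = v)
}

#' Evaluate a time-varying hazard ratio with pointwise CIs
#'
#' `HR(tp) = constant x linear^tp x quadratic^(tp^2)`; the CI comes from the
#' delta method on the log scale with gradient `(1, tp, tp^2)` against the
#' component covariance.
#'
#' @param effect A [tv_effect()].
#' @param tp Prediction time(s) in years since surgery (>= 0); vectorized.
#' @param level Confidence level.
#' @return `data.frame` with `tp`, `hr`, `lower`, `upper` (CI columns `NA`
#'   when the effect has no covariance).
#' @export
time_varying_hr <- function(effect, tp, level = 0.95) {
  stopifnot(inherits(effect, "tv_effect"), all(tp >= 0))
  loghr <- log(effect$constant) + tp * log(effect$linear) +
    tp^2 * log(effect$quadratic)
  if (is.null(effect$covariance)) {
    se <- rep(NA_real_, length(tp))
  } else {
    g <- cbind(1, tp, tp^2)
    se <- sqrt(rowSums((g %*% effect$covariance) * g))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(tp = tp, hr = exp(loghr),
             lower = exp(loghr - z * se), upper = exp(loghr + z * se))
}

#' First prediction time at which the HR confidence interval contains 1
#'
#' Scans a grid of prediction times; at the returned time (and possibly
#' later ones) the effect is no longer significant at the chosen level.
#'
#' @param effect A [tv_effect()] with covariance.
#' @param grid_step Scan resolution in years (default 0.25).
#' @param tmax Scan horizon in years (default 5).
#' @param level Confidence level.
#' @return Smallest grid `tp` whose CI contains 1, or `NA_real_` when the CI
#'   never contains 1 on the grid.
#' @export
hr_crossing_time <- function(effect, grid_step = 0.25, tmax = 5,
                             level = 0.95) {
  if (is.null(effect$covariance)) {
    stop("effect has no covariance; cannot form CIs", call. = FALSE)
  }
  grid <- seq(0, tmax, by = grid_step)
  ci <- time_varying_hr(effect, grid, level = level)
  hit <- which(ci$lower <= 1 & ci$upper >= 1)
  if (!length(hit)) NA_real_ else grid[hit[1]]
}

.profile_statuses <- c("none", "LR", "NM", "LR+NM")

#' Patient profile for dynamic prediction
#'
#' Baseline characteristics plus one of the four disease statuses obtained by
#' crossing the LR and NM time-varying indicators.
#'
#' @param age_group,sex,location,volume,excision,lung,other,histology
#'   Category labels; defaults give the all-reference patient (adolescent
#'   female, other location, volume <200 cm^3, wide/radical excision, no
#'   metastases, good histological response).
#' @param status One of `"none"`, `"LR"`, `"NM"`, `"LR+NM"`.
#' @param label Optional display label.
#' @return Object of class `patient_profile` holding the encoded baseline
#'   indicator vector and the status.
#' @export
patient_profile <- function(age_group = "adolescent", sex = "female",
                            location = "other", volume = "<200",
                            excision = "wide/radical", lung = "no",
                            other = "no", histology = "good",
                            status = "none", label = NULL) {
  status <- match.arg(status, .profile_statuses)
  stopifnot(age_group %in% c("child", "adolescent", "adult"),
            volume %in% c("<200", ">=200"))
  # represent the profile through a one-row cohort and the shared encoder
  bounds <- .age_bounds(age_group, match.arg(sex, c("female", "male")))
  row <- data.frame(
    id = 1L, age_years = mean(bounds), sex = sex, tumor_location = location,
    volume_cm3 = if (volume == "<200") 100 else 300, excision = excision,
    lung_mets = lung, other_mets = other, histology = histology,
    stringsAsFactors = FALSE)
  x <- drop(encode_covariates(row))
  structure(list(x = x, status = status,
                 label = if (is.null(label)) status else label),
            class = "patient_profile")
}

#' Illustrative profiles A-F
#'
#' Six baseline profiles that differ from the reference patient A (adolescent
#' female, good response, no metastases, wide/radical excision, volume
#' <200 cm^3, non-axial location) in lung metastases (B), axial location (C),
#' poor histological response (D), and combinations (E: poor + lung
#' metastases, F: poor + axial).
#'
#' @return Named list of [patient_profile()] objects with status `"none"`.
#' @export
reference_profiles <- function() {
  list(
    A = patient_profile(label = "A"),
    B = patient_profile(lung = "yes/possible", label = "B"),
    C = patient_profile(location = "axial", label = "C"),
    D = patient_profile(histology = "poor", label = "D"),
    E = patient_profile(histology = "poor", lung = "yes/possible",
                        label = "E"),
    F = patient_profile(histology = "poor", location = "axial", label = "F")
  )
}

# Linear predictor of a profile at landmark time s under a fit; only terms
# present in the fit contribute (dropped terms count as zero).
.profile_lp <- function(fit, profile, s) {
  beta <- coef(fit)
  val <- c(profile$x,
           hist_s = unname(profile$x["hist_poor"]) * s,
           hist_s2 = unname(profile$x["hist_poor"]) * s^2,
           lr_status = as.numeric(profile$status %in% c("LR", "LR+NM")),
           nm_status = as.numeric(profile$status %in% c("NM", "LR+NM")),
           s = s, s2 = s^2)
  sum(beta * val[names(beta)])
}

#' Probability of dying within the window, predicted at time tp
#'
#' Conditional on being alive at `tp` with the profile's disease status,
#' returns `1 - exp(-(H0(tp + w) - H0(tp)) * exp(lp))` where `H0` is the
#' stacked-data Breslow baseline (step-interpolated) and the linear predictor
#' `lp` includes the baseline covariates, the landmark-time effects at
#' `s = tp`, the histology interactions at `s = tp`, and the LR/NM status.
#'
#' @param fit A [fit_supermodel()] result.
#' @param profile A [patient_profile()].
#' @param tp Prediction time(s) in years since surgery; must lie within the
#'   fitted landmark range (no extrapolation).
#' @param w Prediction window in years; defaults to the fitted grid's window.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_window_death_probability <- function(fit, profile, tp, w = NULL) {
  smax <- if (!is.null(fit$grid)) max(fit$grid$times) else Inf
  if (any(tp < 0) || any(tp > smax)) {
    stop("tp must lie within the fitted landmark range [0, ",
         format(smax), "]", call. = FALSE)
  }
  if (is.null(w)) w <- if (!is.null(fit$grid)) fit$grid$window else 5
  vapply(tp, function(s) {
    dh <- .cumhaz_at(fit$baseline, s + w) - .cumhaz_at(fit$baseline, s)
    p <- 1 - exp(-dh * exp(.profile_lp(fit, profile, s)))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Dynamic prediction curves for a set of profiles
#'
#' Evaluates [predict_window_death_probability()] for each profile under all
#' four disease statuses over a grid of prediction times.
#'
#' @param fit A `supermodel_fit`.
#' @param profiles List of [patient_profile()]s (default
#'   [reference_profiles()]); each profile's own status is ignored.
#' @param tp Prediction times (default: the fitted landmark grid).
#' @param w Window in years (default: fitted grid's window).
#' @return Long-format `data.frame`: `profile`, `status`, `tp`,
#'   `probability`.
#' @export
profile_prediction_curves <- function(fit, profiles = reference_profiles(),
                                      tp = NULL, w = NULL) {
  if (is.null(tp)) tp <- fit$grid$times
  if (is.null(names(profiles))) names(profiles) <- seq_along(profiles)
  out <- list()
  for (nm in names(profiles)) {
    for (st in .profile_statuses) {
      pr <- profiles[[nm]]
      pr$status <- st
      out[[length(out) + 1]] <- data.frame(
        profile = nm, status = st, tp = tp,
        probability = predict_window_death_probability(fit, pr, tp, w),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
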
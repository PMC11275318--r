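# Proportional landmark supermodel: one Cox-type model on the stacked
# landmark rows, a common Breslow baseline across landmarks, landmark time s
# and s^2 in the linear predictor, and a cluster-robust sandwich variance by
# patient (each patient contributes up to one row per landmark).

#' Fit the proportional landmark supermodel
#'
#' Maximizes the pseudo partial likelihood over the stacked landmark rows with
#' delayed entry (risk set at event time t: rows with `entry < t <= exit`) and
#' Breslow tie handling, by Newton iteration with step halving. A model-based
#' covariance (inverse information) and a cluster-robust sandwich covariance
#' grouped by patient id are both computed; the robust one is the default for
#' all reported confidence intervals, since stacked rows of one patient are
#' strongly dependent.
#'
#' Columns in `terms` that are constant in the stack (for example `s` when the
#' grid has a single landmark) are dropped with a message.
#'
#' @param stack A [build_landmark_stack()] result, or any data frame with
#'   columns `id`, `entry`, `exit`, `event` and the model terms.
#' @param terms Character vector of design columns; defaults to all
#'   [supermodel_terms()] present in `stack`.
#' @param robust Compute the sandwich covariance (default `TRUE`).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum Newton steps.
#' @return Object of class `supermodel_fit`: `coefficients`, `var_model`,
#'   `var_robust`, `baseline` (Breslow data frame `time`, `hazard`,
#'   `cumhaz`), `terms`, `loglik_model`, `loglik_null`, `n_patients`,
#'   `n_rows`, `n_events`, `grid`.
#' @export
fit_supermodel <- function(stack, terms = NULL, robust = TRUE,
                           tol = 1e-8, max_iter = 30) {
  stopifnot(nrow(stack) > 0)
  if (sum(stack$event) < 1) stop("stack contains no events", call. = FALSE)
  if (is.null(terms)) terms <- intersect(supermodel_terms(), names(stack))
  missing_terms <- setdiff(terms, names(stack))
  if (length(missing_terms)) {
    stop("stack lacks term column(s): ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(stack[terms])
  if (anyNA(X)) {
    stop("model columns contain missing values; impute before fitting",
         call. = FALSE)
  }
  const <- apply(X, 2, function(v) max(v) - min(v)) < 1e-12
  if (any(const)) {
    message("dropping constant term(s): ",
            paste(terms[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    terms <- terms[!const]
  }
  if (!ncol(X)) stop("no non-constant model terms left", call. = FALSE)

  core <- .coxpl_fit(stack$entry, stack$exit, stack$event, X,
                     tol = tol, max_iter = max_iter)
  var_robust <- if (robust) {
    .coxpl_robust(core, stack$entry, stack$exit, stack$event, X, stack$id)
  } else NULL
  baseline <- .coxpl_breslow(core$beta, stack$entry, stack$exit,
                             stack$event, X)
  structure(list(
    coefficients = core$beta,
    var_model = core$var_model,
    var_robust = var_robust,
    baseline = baseline,
    terms = terms,
    loglik_model = core$loglik,
    loglik_null = core$loglik_null,
    score_norm = core$score_norm,
    iterations = core$iterations,
    converged = core$converged,
    n_patients = length(unique(stack$id)),
    n_rows = nrow(stack),
    n_events = sum(stack$event),
    grid = attr(stack, "grid")
  ), class = "supermodel_fit")
}

#' @export
print.supermodel_fit <- function(x, ...) {
  cat("Proportional landmark supermodel\n")
  cat(sprintf("  %d patients, %d stacked rows, %d events; loglik %.3f\n",
              x$n_patients, x$n_rows, x$n_events, x$loglik_model))
  print(hazard_ratio_table(x), digits = 3)
  invisible(x)
}

#' @export
coef.supermodel_fit <- function(object, ...) object$coefficients

#' Covariance of a supermodel fit
#'
#' @param object A `supermodel_fit`.
#' @param robust Return the cluster-robust sandwich (default, when
#'   available) or the model-based covariance.
#' @param ... Unused.
#' @export
vcov.supermodel_fit <- function(object, robust = TRUE, ...) {
  if (robust && !is.null(object$var_robust)) object$var_robust
  else object$var_model
}

#' Breslow baseline cumulative hazard of the stacked fit
#'
#' Re-derives the baseline from a stack at the fitted coefficients: the jump
#' at each distinct event time t equals (deaths at t) / sum of exp(linear
#' predictor) over rows at risk. With all coefficients zero this is the
#' Nelson-Aalen estimator of the stacked data.
#'
#' @param fit A [fit_supermodel()] result.
#' @param stack The stack the fit was (or could have been) computed on.
#' @param coefficients Optional coefficient override (e.g. all zero).
#' @return `data.frame` with `time`, `hazard` (jump) and `cumhaz`.
#' @export
breslow_baseline <- function(fit, stack, coefficients = coef(fit)) {
  X <- as.matrix(stack[fit$terms])
  .coxpl_breslow(coefficients, stack$entry, stack$exit, stack$event, X)
}

# Step-interpolated cumulative hazard H0(t); right-continuous, H0(0) = 0.
.cumhaz_at <- function(baseline, t) {
  if (!nrow(baseline)) return(rep(0, length(t)))
  idx <- findInterval(t, baseline$time)
  ifelse(idx == 0, 0, baseline$cumhaz[pmax(idx, 1)])
}

# Display labels for the hazard-ratio table, in report order. Reference rows
# carry NA term names.
.hr_layout <- function() {
  list(
    list(header = "Age", rows = list(
      c(NA, "Adolescent (ref)"), c("age_child", "Child"),
      c("age_adult", "Adult"))),
    list(header = "Sex", rows = list(
      c(NA, "Female (ref)"), c("sex_male", "Male"))),
    list(header = "Tumor location", rows = list(
      c(NA, "Other (ref)"), c("loc_axial", "Axial"),
      c("loc_proxfh", "Proximal femur/humerus"))),
    list(header = "Absolute tumor volume", rows = list(
      c(NA, "<200 cm3 (ref)"), c("vol_ge200", ">=200 cm3"))),
    list(header = "Excision", rows = list(
      c(NA, "Wide/Radical (ref)"), c("exc_marginal", "Marginal"),
      c("exc_intralesional", "Intralesional/Unknown"))),
    list(header = "Presence of lung metastases", rows = list(
      c(NA, "No (ref)"), c("lung_mets", "Yes/Possible"))),
    list(header = "Presence of other metastases", rows = list(
      c(NA, "No (ref)"), c("other_mets", "Yes/Possible"))),
    list(header = "Histological response", rows = list(
      c(NA, "Good (ref)"), c("hist_poor", "Poor - constant"),
      c("hist_s", "Poor - linear time-varying"),
      c("hist_s2", "Poor - quadratic time-varying"))),
    list(header = "Local recurrence (LR)", rows = list(
      c(NA, "No (ref)"), c("lr_status", "Yes"))),
    list(header = "New metastatic disease (NM)", rows = list(
      c(NA, "No (ref)"), c("nm_status", "Yes"))),
    list(header = "Follow-up time (ref: time of surgery)", rows = list(
      c("s", "Linear s"), c("s2", "Quadratic s2")))
  )
}

#' Hazard-ratio table of a supermodel fit
#'
#' One row per model term plus the reference categories (shown with HR 1),
#' grouped and ordered the way dynamic-prediction reports present them.
#'
#' @param fit A `supermodel_fit`.
#' @param level Confidence level (default 0.95).
#' @param robust Use the cluster-robust covariance for CIs and p-values.
#' @return `data.frame` with `group`, `label`, `term`, `HR`, `lower`,
#'   `upper`, `p_value`. Reference rows have `HR = 1` and `NA` elsewhere.
#' @export
hazard_ratio_table <- function(fit, level = 0.95, robust = TRUE) {
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit, robust = robust)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (blk in .hr_layout()) {
    for (r in blk$rows) {
      term <- r[1]
      if (is.na(term)) {
        rows[[length(rows) + 1]] <- data.frame(
          group = blk$header, label = r[2], term = NA_character_,
          HR = 1, lower = NA_real_, upper = NA_real_, p_value = NA_real_,
          stringsAsFactors = FALSE)
      } else if (term %in% names(beta)) {
        b <- beta[[term]]; s <- se[[term]]
        rows[[length(rows) + 1]] <- data.frame(
          group = blk$header, label = r[2], term = term,
          HR = exp(b), lower = exp(b - z * s), upper = exp(b + z * s),
          p_value = 2 * stats::pnorm(-abs(b / s)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
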
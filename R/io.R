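# JSON serialization of fits and generator configuration.

#' Write / read a supermodel fit as JSON
#'
#' The file holds coefficients, both covariance matrices, the Breslow
#' baseline as parallel arrays of (time, cumhaz), the landmark grid, and the
#' fit's bookkeeping scalars.
#'
#' @param fit A `supermodel_fit`.
#' @param path File path.
#' @return `read_fit()` returns the `supermodel_fit`; `write_fit()` returns
#'   `path` invisibly.
#' @export
write_fit <- function(fit, path) {
  obj <- list(
    terms = fit$terms,
    coefficients = unname(fit$coefficients),
    var_model = fit$var_model,
    var_robust = fit$var_robust,
    baseline = fit$baseline,
    grid = if (!is.null(fit$grid)) {
      list(times = fit$grid$times, window = fit$grid$window)
    },
    loglik_model = fit$loglik_model, loglik_null = fit$loglik_null,
    n_patients = fit$n_patients, n_rows = fit$n_rows,
    n_events = fit$n_events
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- obj
  fit$coefficients <- stats::setNames(obj$coefficients, obj$terms)
  as_mat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    dimnames(m) <- list(obj$terms, obj$terms)
    m
  }
  fit$var_model <- as_mat(obj$var_model)
  fit$var_robust <- as_mat(obj$var_robust)
  fit$baseline <- as.data.frame(obj$baseline)
  if (!is.null(obj$grid)) {
    fit$grid <- structure(list(times = obj$grid$times,
                               window = obj$grid$window),
                          class = "landmark_grid")
  }
  class(fit) <- "supermodel_fit"
  fit
}

#' Write / read a simulation-truth configuration as JSON
#'
#' @param truth A [simulation_truth()].
#' @param path File path.
#' @return `read_truth()` returns the `simulation_truth`; `write_truth()`
#'   returns `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist_named <- function(x) if (is.list(x)) unlist(x) else x
  do.call(simulation_truth, list(
    baseline_death_hazard = lapply(obj$baseline_death_hazard, unlist),
    log_effects = unlist_named(obj$log_effects),
    log_lr_effect = obj$log_lr_effect,
    log_nm_effect = obj$log_nm_effect,
    histology_time_effect = unlist_named(obj$histology_time_effect),
    lr_hazard = lapply(obj$lr_hazard, unlist_named),
    nm_hazard = lapply(obj$nm_hazard, unlist_named),
    censor_hazard = obj$censor_hazard,
    admin_censor_time = obj$admin_censor_time))
}
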
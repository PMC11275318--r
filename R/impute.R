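# Multiple imputation of tumor volume and histological response, and
# Rubin's-rules pooling of supermodel coefficients.
#
# The imputation engine is a deliberately simple, fully documented
# conditional model (not a reproduction of any EM-with-bootstrapping
# machinery): log-volume from a Bayesian linear regression on the complete
# covariates and the outcome, histology from a probit-style thresholded
# latent draw. Parameters are drawn from their approximate posterior for
# each imputation, so between-imputation variance is propagated.

# Predictor matrix shared by both imputation models: complete baseline
# indicators plus outcome information (event indicator and log follow-up).
.imp_predictors <- function(cohort) {
  x <- encode_covariates(cohort)
  keep <- setdiff(baseline_terms(), c("vol_ge200", "hist_poor"))
  cbind(intercept = 1, x[, keep, drop = FALSE],
        os_status = cohort$os_status, log_t_os = log(cohort$t_os))
}

# One posterior draw of (beta, sigma) for a normal linear model, then
# predictive draws for the missing rows.
.draw_normal_imputes <- function(y, X, miss) {
  obs <- !miss
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  qr_x <- qr(Xo)
  betahat <- qr.coef(qr_x, yo)
  betahat[is.na(betahat)] <- 0
  res <- yo - drop(Xo %*% betahat)
  df <- max(length(yo) - qr_x$rank, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  xtx_inv <- chol2inv(qr.R(qr_x))
  beta <- betahat + drop(t(chol(sigma2 * xtx_inv)) %*%
                           stats::rnorm(ncol(Xo)))
  mu <- drop(X[miss, , drop = FALSE] %*% beta)
  stats::rnorm(sum(miss), mu, sqrt(sigma2))
}

#' Multiply impute missing tumor volume and histology
#'
#' Produces `m` completed cohorts. Volume is imputed on the log scale from a
#' normal model given the complete covariates and the outcome; histological
#' response is imputed from a latent-normal (probit) model given the same
#' predictors plus (imputed) log-volume, thresholded to good/poor. Each
#' imputation uses a fresh posterior parameter draw. LR/NM event times and
#' all observed values are never touched.
#'
#' @param cohort Cohort with missingness only in `volume_cm3` and
#'   `histology`.
#' @param m Number of imputations (default 10).
#' @param seed Optional integer seed.
#' @return Object of class `imputation_set`: list with `cohorts` (list of m
#'   completed tables), `m`, `model` descriptor, `seed`.
#' @export
impute_missing <- function(cohort, m = 10, seed = NULL) {
  stopifnot(m >= 1)
  m <- as.integer(m)
  if (!is.null(seed)) set.seed(seed)
  needed <- setdiff(.cohort_columns, c("volume_cm3", "histology",
                                       "t_lr", "t_nm"))
  if (anyNA(cohort[needed])) {
    stop("missingness is only supported in volume_cm3 and histology",
         call. = FALSE)
  }
  miss_v <- is.na(cohort$volume_cm3)
  miss_h <- is.na(cohort$histology)
  if (all(miss_v) || all(miss_h)) {
    stop("a variable used by the imputation model is entirely missing",
         call. = FALSE)
  }
  P <- .imp_predictors(cohort)
  cohorts <- vector("list", m)
  for (k in seq_len(m)) {
    comp <- cohort
    if (any(miss_v)) {
      comp$volume_cm3[miss_v] <-
        exp(.draw_normal_imputes(log(cohort$volume_cm3), P, miss_v))
    }
    if (any(miss_h)) {
      # probit: latent = xb + N(0,1); poor when latent > 0
      Ph <- cbind(P, log_vol = log(comp$volume_cm3))
      y <- as.numeric(cohort$histology == "poor")
      obs <- !miss_h
      gfit <- suppressWarnings(
        stats::glm.fit(Ph[obs, , drop = FALSE], y[obs],
                       family = stats::binomial("probit")))
      beta <- gfit$coefficients
      beta[is.na(beta)] <- 0
      # approximate posterior draw of the probit coefficients
      vv <- tryCatch(chol2inv(chol(crossprod(
        Ph[obs, , drop = FALSE] * sqrt(pmax(gfit$weights, 1e-8))))),
        error = function(e) diag(1e-6, length(beta)))
      beta <- beta + drop(t(chol(vv)) %*% stats::rnorm(length(beta)))
      latent <- drop(Ph[miss_h, , drop = FALSE] %*% beta) +
        stats::rnorm(sum(miss_h))
      comp$histology[miss_h] <- ifelse(latent > 0, "poor", "good")
    }
    cohorts[[k]] <- comp
  }
  structure(list(cohorts = cohorts, m = m,
                 model = paste("log-volume: Bayesian normal regression;",
                               "histology: thresholded latent probit"),
                 seed = seed),
            class = "imputation_set")
}

#' Pool supermodel fits across imputations by Rubin's rules
#'
#' Pooled coefficient = mean across fits; between-imputation variance B =
#' sample variance of the coefficients; total variance
#' `T = Wbar + (1 + 1/m) B` with `Wbar` the mean within-imputation variance.
#' Confidence intervals use the Barnard-Rubin small-sample degrees of
#' freedom (complete-data df taken as events minus parameters), falling back
#' to the normal reference when B is zero.
#'
#' @param fits List of >= 2 [fit_supermodel()] results over a common term
#'   set.
#' @param level Confidence level for the pooled HR table.
#' @param robust Use each fit's cluster-robust variance as the
#'   within-imputation variance.
#' @return Object of class `pooled_fit`: `coefficients`, `within`,
#'   `between`, `total` (per-term variances), `m`, `df`, and `hr_table`.
#' @export
pool_rubin <- function(fits, level = 0.95, robust = TRUE) {
  m <- length(fits)
  stopifnot(m >= 2)
  terms <- names(coef(fits[[1]]))
  for (f in fits) {
    if (!identical(names(coef(f)), terms)) {
      stop("fits have differing term sets; cannot pool", call. = FALSE)
    }
  }
  Q <- matrix(vapply(fits, coef, numeric(length(terms))),
              nrow = length(terms), dimnames = list(terms, NULL))
  W <- matrix(vapply(fits, function(f) diag(vcov(f, robust = robust)),
                     numeric(length(terms))),
              nrow = length(terms), dimnames = list(terms, NULL))
  qbar <- rowMeans(Q)
  wbar <- rowMeans(W)
  B <- apply(Q, 1, stats::var)
  total <- wbar + (1 + 1 / m) * B

  # Barnard-Rubin df per term
  dfcom <- max(fits[[1]]$n_events - length(terms), 1)
  lambda <- (1 + 1 / m) * B / total
  lambda[total == 0] <- 0
  df_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
  df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
  df <- ifelse(is.infinite(df_old), dfcom,
               df_old * df_obs / (df_old + df_obs))

  q <- stats::qt(1 - (1 - level) / 2, df)
  se <- sqrt(total)
  hr_table <- data.frame(
    term = terms, HR = exp(qbar),
    lower = exp(qbar - q * se), upper = exp(qbar + q * se),
    p_value = 2 * stats::pt(-abs(qbar / se), df),
    stringsAsFactors = FALSE)
  structure(list(coefficients = qbar, within = wbar, between = B,
                 total = total, m = m, df = df, hr_table = hr_table),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Rubin's-rules pooled supermodel (m = %d)\n", x$m))
  print(x$hr_table, digits = 3)
  invisible(x)
}
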
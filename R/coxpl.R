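# Partial-likelihood engine for counting-process data (entry, exit].
#
# Risk set at an event time t is every row with entry < t <= exit; ties are
# handled by Breslow's approximation. The heavy risk-set sweep lives in
# src/coxpl.cpp; this file drives the Newton iteration and assembles the
# cluster-robust sandwich and the Breslow baseline.

# Log partial likelihood, score and information at beta.
.coxpl_eval <- function(beta, entry, exit, event, X, need_hess = TRUE) {
  out <- .cox_eval_cpp(as.numeric(entry), as.numeric(exit),
                       as.integer(event), X, as.numeric(beta), need_hess)
  if (!out$ok) out$loglik <- -Inf
  out
}

# Newton-Raphson with step halving. Returns beta, loglik at 0 and optimum,
# model-based covariance, and the pieces needed downstream.
.coxpl_fit <- function(entry, exit, event, X, tol = 1e-8, max_iter = 30) {
  p <- ncol(X)
  beta <- rep(0, p)
  ev <- .coxpl_eval(beta, entry, exit, event, X)
  loglik0 <- ev$loglik
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$info, ev$score), error = function(e) {
      stop("information matrix is singular (constant column or complete ",
           "separation?)", call. = FALSE)
    })
    new_beta <- beta + step
    new_ev <- .coxpl_eval(new_beta, entry, exit, event, X)
    halvings <- 0
    while ((!is.finite(new_ev$loglik) || new_ev$loglik < ev$loglik) &&
           halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_ev <- .coxpl_eval(new_beta, entry, exit, event, X)
      halvings <- halvings + 1
    }
    rel <- abs(new_ev$loglik - ev$loglik) / (abs(ev$loglik) + tol)
    beta <- new_beta
    ev <- new_ev
    trace <- c(trace, ev$loglik)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("partial-likelihood Newton iteration did not converge in ",
            max_iter, " steps (trace: ",
            paste(signif(utils::tail(trace, 3), 8), collapse = ", "), ")",
            call. = FALSE)
  }
  if (max(abs(beta)) > 20) {
    warning("very large coefficient(s); possible complete separation",
            call. = FALSE)
  }
  names(beta) <- colnames(X)
  var_model <- solve(ev$info)
  dimnames(var_model) <- list(colnames(X), colnames(X))
  list(beta = beta, loglik = ev$loglik, loglik_null = loglik0,
       var_model = var_model, eval = ev, iterations = it,
       converged = converged, score_norm = sqrt(sum(ev$score^2)))
}

# Per-cluster score sums and the sandwich covariance.
.coxpl_robust <- function(fit_core, entry, exit, event, X, id) {
  ev <- fit_core$eval
  d <- ev$d
  if (!length(d)) return(fit_core$var_model * 0)
  q <- ev$m / ev$S0
  cumQ <- cumsum(q)
  cumQX <- apply(q * ev$xbar, 2, cumsum)
  if (is.null(dim(cumQX))) cumQX <- matrix(cumQX, ncol = 1)
  hi <- findInterval(exit, d)                     # events with d <= exit
  lo <- findInterval(entry, d)                    # events with d <= entry
  at0 <- function(v, idx) ifelse(idx == 0, 0, v[pmax(idx, 1)])
  sumQ <- at0(cumQ, hi) - at0(cumQ, lo)
  pickM <- function(M, idx) {
    out <- matrix(0, length(idx), ncol(M))
    ok <- idx > 0
    out[ok, ] <- M[idx[ok], , drop = FALSE]
    out
  }
  sumQX <- pickM(cumQX, hi) - pickM(cumQX, lo)
  U <- -ev$w * (X * sumQ - sumQX)
  evr <- event == 1
  k_of_event <- match(exit[evr], d)
  U[evr, ] <- U[evr, ] + X[evr, , drop = FALSE] -
    ev$xbar[k_of_event, , drop = FALSE]
  Ug <- rowsum(U, group = id)
  meat <- crossprod(Ug)
  vr <- fit_core$var_model %*% meat %*% fit_core$var_model
  dimnames(vr) <- dimnames(fit_core$var_model)
  vr
}

# Breslow baseline cumulative hazard increments at beta.
.coxpl_breslow <- function(beta, entry, exit, event, X) {
  ev <- .coxpl_eval(beta, entry, exit, event, X, need_hess = FALSE)
  if (!length(ev$d)) {
    return(data.frame(time = numeric(), hazard = numeric(),
                      cumhaz = numeric()))
  }
  haz <- ev$m / ev$S0
  data.frame(time = ev$d, hazard = haz, cumhaz = cumsum(haz))
}
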
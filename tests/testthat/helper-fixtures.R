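# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# A hand-specifiable cohort row set. Defaults are the all-reference patient.
toy_cohort <- function(n = 1, t_os = 5, os_status = 0, t_lr = NA_real_,
                       t_nm = NA_real_, age = 15, sex = "female",
                       location = "other", volume = 100,
                       excision = "wide/radical", lung = "no", other = "no",
                       histology = "good") {
  data.frame(
    id = seq_len(n), age_years = rep_len(age, n), sex = rep_len(sex, n),
    tumor_location = rep_len(location, n),
    volume_cm3 = rep_len(volume, n), excision = rep_len(excision, n),
    lung_mets = rep_len(lung, n), other_mets = rep_len(other, n),
    histology = rep_len(histology, n), t_lr = rep_len(t_lr, n),
    t_nm = rep_len(t_nm, n), t_os = rep_len(t_os, n),
    os_status = rep_len(os_status, n), stringsAsFactors = FALSE)
}

# Truth with no intermediate events, no censoring: plain proportional
# hazards in the baseline covariates -- the landmark supermodel is then
# correctly specified and must recover the generative coefficients.
ph_only_truth <- function(rates = c(0.03, 0.05, 0.05, 0.04, 0.03),
                          admin = 10) {
  simulation_truth(
    baseline_death_hazard = list(breaks = c(0, 1, 2, 3, 4), rates = rates),
    lr_hazard = list(rate = 0), nm_hazard = list(rate = 0),
    censor_hazard = 0.10, admin_censor_time = admin)
}

# Independent brute-force log partial likelihood (Breslow ties) by explicit
# risk-set enumeration; deliberately naive, used as the oracle for the
# compiled engine.
bf_loglik <- function(beta, entry, exit, event, X) {
  lp <- drop(X %*% beta)
  d <- sort(unique(exit[event == 1]))
  ll <- 0
  for (t in d) {
    dead <- which(event == 1 & exit == t)
    risk <- which(entry < t & t <= exit)
    ll <- ll + sum(lp[dead]) - length(dead) * log(sum(exp(lp[risk])))
  }
  ll
}

# A minimal fake supermodel fit with full control over coefficients,
# covariance and baseline; used for closed-form prediction checks.
fake_fit <- function(coefficients, vcov_mat = NULL, baseline = NULL,
                     grid = landmark_grid(), n_events = 100) {
  p <- length(coefficients)
  if (is.null(vcov_mat)) {
    vcov_mat <- diag(1e-4, p)
    dimnames(vcov_mat) <- list(names(coefficients), names(coefficients))
  }
  if (is.null(baseline)) {
    tt <- seq(0.01, max(grid$times) + grid$window, by = 0.01)
    baseline <- data.frame(time = tt, hazard = 0.1 * 0.01,
                           cumhaz = 0.1 * tt)
  }
  structure(list(coefficients = coefficients, var_model = vcov_mat,
                 var_robust = vcov_mat, baseline = baseline,
                 terms = names(coefficients), grid = grid,
                 loglik_model = -100, loglik_null = -150,
                 n_patients = 100, n_rows = 100, n_events = n_events),
            class = "supermodel_fit")
}

# Generative truth values keyed by supermodel term names.
truth_beta <- function(truth = simulation_truth()) {
  c(truth$log_effects, hist_s = 0, hist_s2 = 0,
    lr_status = truth$log_lr_effect, nm_status = truth$log_nm_effect,
    s = 0, s2 = 0)
}
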
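# Supermodel estimation: engine correctness against independent oracles,
# Breslow baseline, hazard-ratio table.

test_that("single-landmark supermodel degenerates to an ordinary Cox fit", {
  skip_if_not_installed("survival")
  co <- simulate_cohort(200, seed = 30)
  st <- build_landmark_stack(co, landmark_grid(0, 0, window = 50))
  expect_message(fit <- fit_supermodel(st), "dropping constant")
  expect_setequal(names(coef(fit)), baseline_terms())

  df <- data.frame(t = co$t_os, d = co$os_status, encode_covariates(co))
  cx <- survival::coxph(
    survival::Surv(t, d) ~ age_child + age_adult + sex_male + loc_axial +
      loc_proxfh + vol_ge200 + exc_marginal + exc_intralesional +
      lung_mets + other_mets + hist_poor,
    data = df, ties = "breslow")
  expect_lt(max(abs(coef(fit)[names(coef(cx))] - coef(cx))), 1e-6)
  expect_lt(max(abs(sqrt(diag(fit$var_model))[names(coef(cx))] -
                    sqrt(diag(vcov(cx))))), 1e-6)
  expect_equal(fit$loglik_model, cx$loglik[2], tolerance = 1e-8)
})

test_that("5-row hand stack reproduces the hand-computed Breslow loglik", {
  stack <- data.frame(
    id = 1:5, s = 0, entry = c(0, 0, 0, 1, 1),
    exit = c(2, 3, 4, 3, 5), event = c(1L, 1L, 0L, 1L, 0L),
    x = c(1, 0, 1, 1, 0))
  b <- 0.3
  w <- exp(b * stack$x)
  # events at t=2 (row 1; all five rows at risk since entries are 0 or 1)
  # and t=3 (rows 2 and 4; risk set 2,3,4,5)
  hand <- b * 1 - log(sum(w)) +
    b * (0 + 1) - 2 * log(w[2] + w[3] + w[4] + w[5])
  fit <- fit_supermodel(stack, terms = "x")
  X <- matrix(stack$x, ncol = 1)
  ev <- dynosurv:::.coxpl_eval(b, stack$entry, stack$exit, stack$event, X)
  expect_equal(ev$loglik, hand, tolerance = 1e-12)
  expect_equal(ev$loglik,
               bf_loglik(b, stack$entry, stack$exit, stack$event, X),
               tolerance = 1e-12)
})

test_that("maximized loglik matches exhaustive numerical maximization", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 8
    entry <- round(stats::runif(n, 0, 1), 2)
    exit <- entry + round(stats::runif(n, 0.1, 3), 2)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 2) event[1:2] <- 1L
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    stack <- data.frame(id = 1:n, entry = entry, exit = exit,
                        event = event, X)
    fit <- fit_supermodel(stack, terms = c("a", "b"), robust = FALSE)
    opt <- stats::optim(c(0, 0), function(b) {
      -bf_loglik(b, entry, exit, event, X)
    }, method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
    expect_lt(abs(fit$loglik_model - (-opt$value)), 1e-4)
    expect_lt(max(abs(coef(fit) - opt$par)), 1e-3)
  }
})

test_that("Breslow baseline: hand jumps, zero-coefficient Nelson-Aalen", {
  skip_if_not_installed("survival")
  # single event among k at-risk rows, all coefficients 0 -> jump 1/k
  stack <- data.frame(id = 1:4, entry = 0, exit = c(2, 3, 3, 4),
                      event = c(1L, 0L, 0L, 0L), x = c(0.5, -1, 0, 2))
  fit <- fit_supermodel(stack, terms = "x", robust = FALSE)
  bl0 <- breslow_baseline(fit, stack, coefficients = 0)
  expect_equal(bl0$hazard, 1 / 4)
  expect_equal(bl0$time, 2)

  # no events -> identically zero
  stack0 <- transform(stack, event = 0L)
  expect_identical(nrow(dynosurv:::.coxpl_breslow(
    0, stack0$entry, stack0$exit, stack0$event,
    matrix(stack0$x))), 0L)

  # zero coefficients on a real stack -> Nelson-Aalen on the stacked data
  co <- simulate_cohort(150, seed = 32)
  st <- build_landmark_stack(co, landmark_grid(0, 2, 0.5))
  fit2 <- fit_supermodel(st, robust = FALSE)
  bl <- breslow_baseline(fit2, st, coefficients = rep(0, length(coef(fit2))))
  sf <- survival::survfit(
    survival::Surv(entry, exit, event) ~ 1,
    data = as.data.frame(st[c("entry", "exit", "event")]), ctype = 1)
  na_jump <- sf$cumhaz[sf$n.event > 0]
  expect_equal(bl$cumhaz, na_jump, tolerance = 1e-10)
})

test_that("full supermodel agrees with coxph on stacked data", {
  skip_if_not_installed("survival")
  co <- simulate_cohort(400, seed = 33)
  st <- build_landmark_stack(co)
  fit <- fit_supermodel(st)
  df <- as.data.frame(st)
  fml <- stats::reformulate(supermodel_terms(),
                            response = quote(survival::Surv(entry, exit,
                                                            event)))
  cx <- survival::coxph(fml, data = df, cluster = id, ties = "breslow")
  expect_lt(max(abs(coef(fit)[names(coef(cx))] - coef(cx))), 1e-8)
  expect_lt(max(abs(sqrt(diag(vcov(fit)))[names(coef(cx))] -
                    sqrt(diag(vcov(cx))))), 1e-8)
  expect_lt(max(abs(sqrt(diag(fit$var_model))[names(coef(cx))] -
                    sqrt(diag(cx$naive.var)))), 1e-8)
})

test_that("optimum diagnostics and invariances", {
  co <- simulate_cohort(150, seed = 34)
  st <- build_landmark_stack(co, landmark_grid(0, 3, 0.5))
  fit <- fit_supermodel(st)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-4)
  expect_gt(fit$loglik_model, fit$loglik_null)
  # symmetric PSD covariances
  for (v in list(fit$var_model, fit$var_robust)) {
    expect_equal(v, t(v), tolerance = 1e-10)
    expect_true(all(eigen(v, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }

  # invariance to row order and to a relabeling of patient ids
  perm <- sample(nrow(st))
  st2 <- st[perm, ]
  st2$id <- match(st2$id, unique(co$id)) + 1000L
  attr(st2, "grid") <- attr(st, "grid")
  fit2 <- fit_supermodel(st2)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-10)
  expect_equal(vcov(fit2), vcov(fit), tolerance = 1e-8)
})

test_that("robust and model-based variances agree when rows are patients", {
  # one row per patient and a correctly specified model: the sandwich is a
  # consistent estimate of the same limit as the inverse information
  truth <- ph_only_truth()
  co <- simulate_event_history(sample_baseline_covariates(600, seed = 35),
                               truth, seed = 35)
  st <- build_landmark_stack(co, landmark_grid(0, 0, window = 50))
  fit <- suppressMessages(fit_supermodel(st))
  rel <- abs(sqrt(diag(fit$var_robust)) / sqrt(diag(fit$var_model)) - 1)
  expect_lt(max(rel), 0.15)
})

test_that("supermodel recovers generative effects when correctly specified", {
  # no intermediate events, so frozen LR/NM statuses cannot bias anything:
  # stacked estimates must sit within 3 robust SE of the generative truth
  truth <- ph_only_truth()
  co <- simulate_event_history(sample_baseline_covariates(1500, seed = 36),
                               truth, seed = 36)
  st <- build_landmark_stack(co)
  fit <- suppressMessages(fit_supermodel(st))  # lr/nm columns are constant
  tb <- truth_beta(truth)[names(coef(fit))]
  z <- abs(coef(fit) - tb) / sqrt(diag(vcov(fit)))
  expect_true(all(z < 3), info = paste(names(z)[z >= 3], collapse = ", "))
})

test_that("hazard-ratio table: closed-form CI and report layout", {
  beta <- c(hist_poor = 0.5)
  v <- matrix(0.01, dimnames = list("hist_poor", "hist_poor"))
  fit <- fake_fit(beta, v)
  tab <- hazard_ratio_table(fit)
  row <- tab[!is.na(tab$term) & tab$term == "hist_poor", ]
  expect_equal(row$HR, exp(0.5), tolerance = 1e-12)
  expect_equal(row$lower, exp(0.5 - stats::qnorm(0.975) * 0.1),
               tolerance = 1e-10)
  expect_equal(row$upper, exp(0.5 + stats::qnorm(0.975) * 0.1),
               tolerance = 1e-10)

  # zero coefficient -> HR 1 and CI straddling 1
  fit0 <- fake_fit(c(sex_male = 0),
                   matrix(0.04, dimnames = list("sex_male", "sex_male")))
  r0 <- hazard_ratio_table(fit0)
  r0 <- r0[!is.na(r0$term), ]
  expect_equal(r0$HR, 1)
  expect_true(r0$lower < 1 && r0$upper > 1)

  # full fit carries every term and the reference rows
  co <- simulate_cohort(300, seed = 37)
  tab2 <- hazard_ratio_table(fit_supermodel(build_landmark_stack(co)))
  expect_setequal(tab2$term[!is.na(tab2$term)], supermodel_terms())
  refs <- tab2[is.na(tab2$term), ]
  expect_true(all(refs$HR == 1))
  expect_true("Adolescent (ref)" %in% refs$label)
})
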
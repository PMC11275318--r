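# Synthetic cohort generator: sampling, encoding, event histories,
# missingness.

test_that("baseline sampling matches requested marginals", {
  co <- sample_baseline_covariates(1965, seed = 11)
  # male frequency 0.588: binomial 3-sigma band around the expectation
  expect_lt(abs(sum(co$sex == "male") - 1965 * 0.588),
            3 * sqrt(1965 * 0.588 * 0.412))
  # volume dichotomy honored exactly by the truncated lognormal draw
  expect_lt(abs(mean(co$volume_cm3 < 200) - 1097 / 1618), 0.04)

  expect_identical(nrow(sample_baseline_covariates(0)), 0L)
  expect_named(sample_baseline_covariates(0),
               names(toy_cohort()), ignore.order = TRUE)

  freq <- default_frequencies()
  freq$tumor_location <- c(other = 0, axial = 1,
                           `proximal femur/humerus` = 0)
  co2 <- sample_baseline_covariates(50, freq, seed = 2)
  expect_true(all(co2$tumor_location == "axial"))
})

test_that("invalid frequency vectors are rejected by covariate name", {
  freq <- default_frequencies()
  freq$sex <- c(female = 0.7, male = 0.7)
  expect_error(sample_baseline_covariates(5, freq), "sex")
  freq$sex <- c(f = 0.4, m = 0.6)
  expect_error(sample_baseline_covariates(5, freq), "sex")
})

test_that("Collins age groups and reference coding", {
  co <- toy_cohort(n = 6)
  co$sex <- c("male", "male", "female", "female", "female", "male")
  co$age_years <- c(12, 13, 17, 16.9, 11, 18)
  x <- encode_covariates(co)
  expect_equal(unname(x[, "age_child"]), c(1, 0, 0, 0, 1, 0))
  expect_equal(unname(x[, "age_adult"]), c(0, 0, 1, 0, 0, 1))

  ref <- encode_covariates(toy_cohort())
  expect_true(all(ref == 0))

  bad <- toy_cohort()
  bad$excision <- "radical"
  expect_error(encode_covariates(bad), "excision")
})

test_that("null process: only administrative censoring", {
  truth <- simulation_truth(
    baseline_death_hazard = list(breaks = 0, rates = 0),
    lr_hazard = list(rate = 0), nm_hazard = list(rate = 0),
    censor_hazard = 0, admin_censor_time = 10)
  co <- simulate_event_history(sample_baseline_covariates(40, seed = 3),
                               truth, seed = 3)
  expect_true(all(co$t_os == 10))
  expect_true(all(co$os_status == 0))
  expect_true(all(is.na(co$t_lr)) && all(is.na(co$t_nm)))
})

test_that("constant hazard gives exponential death times", {
  truth <- simulation_truth(
    baseline_death_hazard = list(breaks = 0, rates = 0.2),
    log_effects = stats::setNames(numeric(0), character(0)),
    lr_hazard = list(rate = 0), nm_hazard = list(rate = 0),
    censor_hazard = 0, admin_censor_time = 1e6)
  co <- simulate_event_history(sample_baseline_covariates(4000, seed = 4),
                               truth, seed = 4)
  expect_true(all(co$os_status == 1))
  expect_lt(abs(mean(co$t_os) - 5), 4 * 5 / sqrt(4000))
})

test_that("time-varying histology multiplier shifts poor responders", {
  # decreasing effect on the event-time scale: poor responders die earlier
  # under b1 > 0 than under b1 < 0, all else equal
  mk <- function(b1) simulation_truth(
    baseline_death_hazard = list(breaks = 0, rates = 0.05),
    histology_time_effect = c(linear = b1, quadratic = 0.0),
    lr_hazard = list(rate = 0), nm_hazard = list(rate = 0),
    censor_hazard = 0, admin_censor_time = 30)
  co <- sample_baseline_covariates(1500, seed = 8)
  co$histology <- "poor"
  up <- simulate_event_history(co, mk(0.4), seed = 8)
  down <- simulate_event_history(co, mk(-0.4), seed = 8)
  # exp(0.4 t) >= exp(-0.4 t) for all t: cumulative incidence dominates
  expect_gt(mean(up$os_status), mean(down$os_status))
  expect_gt(mean(up$t_os <= 2 & up$os_status == 1),
            mean(down$t_os <= 2 & down$os_status == 1))
})

test_that("counting-process oracle recovers the LR effect", {
  skip_if_not_installed("survival")
  truth <- simulation_truth(
    baseline_death_hazard = list(breaks = 0, rates = 0.08),
    log_effects = stats::setNames(numeric(0), character(0)),
    log_lr_effect = log(2.634),
    lr_hazard = list(rate = 0.3), nm_hazard = list(rate = 0),
    censor_hazard = 0.05, admin_censor_time = 10)
  co <- simulate_event_history(sample_baseline_covariates(5000, seed = 5),
                               truth, seed = 5)
  # split each follow-up at the LR onset; LR as a true time-varying covariate
  has_lr <- !is.na(co$t_lr) & co$t_lr < co$t_os
  pre <- data.frame(start = 0,
                    stop = ifelse(has_lr, co$t_lr, co$t_os),
                    ev = ifelse(has_lr, 0L, co$os_status), lr = 0)
  post <- data.frame(start = co$t_lr[has_lr], stop = co$t_os[has_lr],
                     ev = co$os_status[has_lr], lr = 1)
  dat <- rbind(pre, post)
  cx <- survival::coxph(survival::Surv(start, stop, ev) ~ lr, data = dat,
                        ties = "breslow")
  expect_lt(abs(coef(cx)[["lr"]] - log(2.634)),
            3 * sqrt(diag(vcov(cx)))[[1]])
})

test_that("marginal survival matches the closed form without intermediates", {
  truth <- ph_only_truth()
  truth$censor_hazard <- 0
  truth$admin_censor_time <- 1e6
  co <- simulate_event_history(sample_baseline_covariates(2000, seed = 6),
                               truth, seed = 6)
  x <- encode_covariates(co)
  lp <- drop(x %*% truth$log_effects[colnames(x)])
  b <- truth$baseline_death_hazard
  H0 <- function(t) {
    ends <- c(b$breaks[-1], Inf)
    sum(pmax(pmin(t, ends) - b$breaks, 0) * b$rates)
  }
  grid <- seq(0.1, 30, by = 0.1)
  Fmix <- vapply(grid, function(t) {
    mean(1 - exp(-H0(t) * exp(lp)))
  }, numeric(1))
  emp <- stats::ecdf(co$t_os)(grid)
  expect_lt(max(abs(emp - Fmix)), 0.04)  # KS 5% crit at n=2000 is 0.030
})

test_that("event-history ordering and seed determinism", {
  co <- simulate_cohort(500, seed = 9)
  expect_true(all(co$t_os > 0))
  expect_true(all(is.na(co$t_lr) | (co$t_lr >= 0 & co$t_lr <= co$t_os)))
  expect_true(all(is.na(co$t_nm) | (co$t_nm >= 0 & co$t_nm <= co$t_os)))
  expect_identical(co, simulate_cohort(500, seed = 9))
})

test_that("missingness injection is MCAR at the stated rates", {
  co <- simulate_cohort(1965, seed = 10)
  expect_identical(inject_missingness(co, 0, 0, seed = 1), co)

  masked <- inject_missingness(co, 0.177, 0.027, seed = 1)
  expect_lt(abs(sum(is.na(masked$volume_cm3)) - 1965 * 0.177),
            3 * sqrt(1965 * 0.177 * 0.823))
  expect_lt(abs(sum(is.na(masked$histology)) - 1965 * 0.027),
            3 * sqrt(1965 * 0.027 * 0.973))
  # everything else untouched
  expect_identical(masked$t_os, co$t_os)
  expect_identical(masked$sex, co$sex)

  all_gone <- inject_missingness(co, 1, 0, seed = 2)
  expect_true(all(is.na(all_gone$volume_cm3)))
})

test_that("cohort CSV round-trips with empty-string missing values", {
  co <- simulate_cohort(40, seed = 12, rate_volume = 0.3,
                        rate_histology = 0.2)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$volume_cm3, co$volume_cm3, tolerance = 1e-12)
  expect_identical(back$histology, co$histology)
  expect_identical(is.na(back$t_lr), is.na(co$t_lr))
})
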
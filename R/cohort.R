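# Cohort container, category frequencies and reference-coded design columns.

#' Default marginal covariate frequencies
#'
#' Category probabilities used by [sample_baseline_covariates()]. The defaults
#' reproduce the marginal distribution of baseline characteristics in a large
#' multi-national high-grade osteosarcoma trial cohort (n = 1965): age group
#' per the Collins classification, sex, pooled tumor location, absolute tumor
#' volume dichotomized at 200 cm^3, surgical excision quality, presence of
#' lung and of other metastases, and histological response to neoadjuvant
#' chemotherapy (good: <10% viable tumor; poor: >=10%). Volume and histology
#' frequencies are renormalized over non-missing records, since the generator
#' produces complete data (missingness is injected separately by
#' [inject_missingness()]).
#'
#' @return Named list of named probability vectors, one per covariate.
#' @export
#' @examples
#' default_frequencies()$sex
default_frequencies <- function() {
  list(
    age_group = c(adolescent = 979, child = 441, adult = 545) / 1965,
    sex = c(female = 810, male = 1155) / 1965,
    tumor_location = c(other = 1641, axial = 64,
                       `proximal femur/humerus` = 260) / 1965,
    volume = c(`<200` = 1097, `>=200` = 521) / 1618,
    excision = c(`wide/radical` = 1606, marginal = 238,
                 `intralesional/unknown` = 121) / 1965,
    lung_mets = c(no = 1587, `yes/possible` = 378) / 1965,
    other_mets = c(no = 1889, `yes/possible` = 76) / 1965,
    histology = c(good = 996, poor = 915) / 1911
  )
}

# Category labels allowed in a cohort table.
.cohort_levels <- list(
  sex = c("female", "male"),
  tumor_location = c("other", "axial", "proximal femur/humerus"),
  excision = c("wide/radical", "marginal", "intralesional/unknown"),
  lung_mets = c("no", "yes/possible"),
  other_mets = c("no", "yes/possible"),
  histology = c("good", "poor")
)

.cohort_columns <- c("id", "age_years", "sex", "tumor_location", "volume_cm3",
                     "excision", "lung_mets", "other_mets", "histology",
                     "t_lr", "t_nm", "t_os", "os_status")

.empty_cohort <- function() {
  data.frame(id = integer(), age_years = numeric(), sex = character(),
             tumor_location = character(), volume_cm3 = numeric(),
             excision = character(), lung_mets = character(),
             other_mets = character(), histology = character(),
             t_lr = numeric(), t_nm = numeric(), t_os = numeric(),
             os_status = integer(), stringsAsFactors = FALSE)
}

.check_freq <- function(p, name, levels) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8) {
    stop("invalid probability vector for covariate '", name,
         "': entries must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(names(p)) || !setequal(names(p), levels)) {
    stop("probability vector for covariate '", name,
         "' must be named with categories: ",
         paste(levels, collapse = ", "), call. = FALSE)
  }
  p[levels]
}

# Collins age-group bounds, [low, high) in whole years at surgery.
.age_bounds <- function(group, sex) {
  lo <- c(child = 3, adolescent = 0, adult = 0)
  switch(group,
    child = if (sex == "male") c(3, 13) else c(3, 12),
    adolescent = if (sex == "male") c(13, 18) else c(12, 17),
    adult = if (sex == "male") c(18, 41) else c(17, 41),
    stop("unknown age group '", group, "'", call. = FALSE))
}

#' Sample baseline covariates for a synthetic cohort
#'
#' Draws each covariate independently from its marginal category frequencies.
#' Continuous age is drawn uniformly within the sampled Collins age-group
#' bounds (sex-specific); absolute tumor volume is drawn from a lognormal
#' (meanlog log 120, sdlog 1.1) truncated to the sampled side of the 200 cm^3
#' cut so that the dichotomized frequency is exactly the requested one.
#'
#' @param n Number of patients.
#' @param frequencies Named list of per-covariate category probabilities, as
#'   from [default_frequencies()].
#' @param seed Optional integer seed for reproducibility.
#' @return A cohort `data.frame` with covariate columns filled and event
#'   columns (`t_lr`, `t_nm`, `t_os`, `os_status`) set to `NA`.
#' @export
sample_baseline_covariates <- function(n, frequencies = default_frequencies(),
                                       seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(.empty_cohort())

  fr <- frequencies
  defaults <- default_frequencies()
  for (nm in names(defaults)) {
    if (is.null(fr[[nm]])) fr[[nm]] <- defaults[[nm]]
    fr[[nm]] <- .check_freq(fr[[nm]], nm, names(defaults[[nm]]))
  }

  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)

  sex <- draw(fr$sex)
  group <- draw(fr$age_group)
  bounds <- t(mapply(.age_bounds, group, sex))
  age <- stats::runif(n, bounds[, 1], bounds[, 2])

  vol_cat <- draw(fr$volume)
  meanlog <- log(120); sdlog <- 1.1
  p200 <- stats::plnorm(200, meanlog, sdlog)
  u <- ifelse(vol_cat == "<200",
              stats::runif(n, 0, p200),
              stats::runif(n, p200, 1))
  volume <- stats::qlnorm(u, meanlog, sdlog)

  data.frame(
    id = seq_len(n),
    age_years = age,
    sex = sex,
    tumor_location = draw(fr$tumor_location),
    volume_cm3 = volume,
    excision = draw(fr$excision),
    lung_mets = draw(fr$lung_mets),
    other_mets = draw(fr$other_mets),
    histology = draw(fr$histology),
    t_lr = NA_real_, t_nm = NA_real_, t_os = NA_real_,
    os_status = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Names of the reference-coded baseline design columns
#'
#' @return Character vector of the 11 baseline indicator columns produced by
#'   [encode_covariates()], in model order.
#' @export
baseline_terms <- function() {
  c("age_child", "age_adult", "sex_male", "loc_axial", "loc_proxfh",
    "vol_ge200", "exc_marginal", "exc_intralesional", "lung_mets",
    "other_mets", "hist_poor")
}

.check_levels <- function(x, name, levels, allow_na = FALSE) {
  bad <- !(x %in% levels)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop("unknown category label(s) for '", name, "': ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
}

#' Reference-code cohort covariates
#'
#' Builds the indicator design columns used throughout the package. Reference
#' categories: adolescent (age), female, tumor location other, volume
#' < 200 cm^3, wide/radical excision, no lung metastases, no other metastases,
#' good histological response. Age groups follow the Collins classification on
#' completed years: child (male 0--12, female 0--11), adolescent (male 13--17,
#' female 12--16), adult (male >= 18, female >= 17).
#'
#' Missing volume or histology propagates to `NA` in the corresponding
#' indicator; all other covariates must be complete.
#'
#' @param cohort Cohort `data.frame` (see [sample_baseline_covariates()]).
#' @return Numeric matrix, one row per patient, columns [baseline_terms()].
#' @export
encode_covariates <- function(cohort) {
  n <- nrow(cohort)
  if (anyNA(cohort$age_years) || anyNA(cohort$sex)) {
    stop("age_years and sex must be present for every patient", call. = FALSE)
  }
  .check_levels(cohort$sex, "sex", .cohort_levels$sex)
  .check_levels(cohort$tumor_location, "tumor_location",
                .cohort_levels$tumor_location)
  .check_levels(cohort$excision, "excision", .cohort_levels$excision)
  .check_levels(cohort$lung_mets, "lung_mets", .cohort_levels$lung_mets)
  .check_levels(cohort$other_mets, "other_mets", .cohort_levels$other_mets)
  .check_levels(cohort$histology, "histology", .cohort_levels$histology,
                allow_na = TRUE)

  a <- floor(cohort$age_years)
  male <- cohort$sex == "male"
  child <- ifelse(male, a <= 12, a <= 11)
  adult <- ifelse(male, a >= 18, a >= 17)

  x <- cbind(
    age_child = as.numeric(child),
    age_adult = as.numeric(adult),
    sex_male = as.numeric(male),
    loc_axial = as.numeric(cohort$tumor_location == "axial"),
    loc_proxfh = as.numeric(cohort$tumor_location == "proximal femur/humerus"),
    vol_ge200 = as.numeric(cohort$volume_cm3 >= 200),
    exc_marginal = as.numeric(cohort$excision == "marginal"),
    exc_intralesional =
      as.numeric(cohort$excision == "intralesional/unknown"),
    lung_mets = as.numeric(cohort$lung_mets == "yes/possible"),
    other_mets = as.numeric(cohort$other_mets == "yes/possible"),
    hist_poor = as.numeric(cohort$histology == "poor")
  )
  rownames(x) <- as.character(cohort$id)
  x
}

#' Read / write a cohort CSV
#'
#' One row per patient; empty fields encode missing values. Times are numeric
#' years since surgery. Columns: `id, age_years, sex, tumor_location,
#' volume_cm3, excision, lung_mets, other_mets, histology, t_lr, t_nm, t_os,
#' os_status`.
#'
#' @param path File path.
#' @param cohort Cohort `data.frame`.
#' @return `read_cohort()` returns the cohort `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  missing_cols <- setdiff(.cohort_columns, names(x))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x[.cohort_columns]
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[.cohort_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
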
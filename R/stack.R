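# Eligibility filtering and the stacked landmark data set.

#' Landmark grid
#'
#' @param start,end,step Landmark times in years (default 0 to 5 by 0.25,
#'   i.e. 3-month increments).
#' @param window Prediction window w in years (default 5): each landmark data
#'   set is administratively censored at s + w.
#' @return Object of class `landmark_grid` with fields `times` and `window`.
#' @export
landmark_grid <- function(start = 0, end = 5, step = 0.25, window = 5) {
  times <- seq(start, end, by = step)
  stopifnot(length(times) >= 1, all(times >= 0),
            !is.unsorted(times, strictly = TRUE), window > 0)
  structure(list(times = times, window = window), class = "landmark_grid")
}

#' Apply cohort eligibility filters
#'
#' Excludes patients with (1) LR or NM recorded at or before surgery
#' (`t_lr <= 0` or `t_nm <= 0`), (2) missing follow-up time, and (3)
#' non-positive follow-up. Exclusion counts are reported per criterion
#' (a patient can hit several); `n_excluded` counts distinct patients.
#'
#' @param cohort Cohort table.
#' @return List with `cohort` (eligible rows) and `counts` (named integer
#'   vector: `pre_surgery_event`, `missing_followup`, `nonpositive_followup`,
#'   `n_excluded`).
#' @export
apply_eligibility_filters <- function(cohort) {
  pre_event <- (!is.na(cohort$t_lr) & cohort$t_lr <= 0) |
    (!is.na(cohort$t_nm) & cohort$t_nm <= 0)
  missing_fu <- is.na(cohort$t_os) | is.na(cohort$os_status)
  nonpos_fu <- !is.na(cohort$t_os) & cohort$t_os <= 0
  drop <- pre_event | missing_fu | nonpos_fu
  list(
    cohort = cohort[!drop, , drop = FALSE],
    counts = c(pre_surgery_event = sum(pre_event),
               missing_followup = sum(missing_fu),
               nonpositive_followup = sum(nonpos_fu),
               n_excluded = sum(drop))
  )
}

#' Terms of the full landmark supermodel
#'
#' Baseline indicators, histology x landmark-time interactions, LR/NM status,
#' and the linear/quadratic landmark-time effects.
#'
#' @return Character vector of design column names, in model order.
#' @export
supermodel_terms <- function() {
  c(baseline_terms(), "hist_s", "hist_s2", "lr_status", "nm_status",
    "s", "s2")
}

#' Build the stacked landmark data set
#'
#' For each landmark time s, every patient still at risk (`t_os > s`,
#' strictly) contributes one row with delayed entry at s, exit at
#' `min(t_os, s + w)`, and event indicator 1 iff death occurred in the closed
#' window `(s, s + w]`. LR/NM status is frozen at its value at s
#' (`t_lr <= s`, inclusive); landmark-time columns `s`, `s2` and the poor
#' histology interactions `hist_s`, `hist_s2` are populated. All rows share
#' the event-time axis (years since surgery), so one Breslow baseline serves
#' every landmark.
#'
#' @param cohort Eligible cohort table with complete covariates.
#' @param grid A [landmark_grid()].
#' @return `data.frame` of class `landmark_stack` with columns `id`, `s`,
#'   `entry`, `exit`, `event` and [supermodel_terms()]; the grid is attached
#'   as attribute `grid`.
#' @export
build_landmark_stack <- function(cohort, grid = landmark_grid()) {
  stopifnot(inherits(grid, "landmark_grid"))
  x <- encode_covariates(cohort)
  w <- grid$window
  pieces <- lapply(grid$times, function(s) {
    at_risk <- cohort$t_os > s
    if (!any(at_risk)) return(NULL)
    ch <- cohort[at_risk, , drop = FALSE]
    xb <- x[at_risk, , drop = FALSE]
    exit <- pmin(ch$t_os, s + w)
    data.frame(
      id = ch$id, s = s, entry = s, exit = exit,
      event = as.integer(ch$os_status == 1 & ch$t_os <= s + w),
      xb,
      hist_s = xb[, "hist_poor"] * s,
      hist_s2 = xb[, "hist_poor"] * s^2,
      lr_status = as.numeric(!is.na(ch$t_lr) & ch$t_lr <= s),
      nm_status = as.numeric(!is.na(ch$t_nm) & ch$t_nm <= s),
      s2 = s^2,
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  stack <- do.call(rbind, pieces)
  if (is.null(stack)) {
    stack <- data.frame(id = integer(), s = numeric(), entry = numeric(),
                        exit = numeric(), event = integer())
    for (tm in supermodel_terms()) stack[[tm]] <- numeric()
  }
  stack <- stack[c("id", "s", "entry", "exit", "event", supermodel_terms())]
  attr(stack, "grid") <- grid
  class(stack) <- c("landmark_stack", "data.frame")
  stack
}

#' Risk-set counts by disease status at each landmark
#'
#' @param stack A [build_landmark_stack()] result.
#' @return `data.frame` with one row per landmark time: `s`, `n_at_risk`,
#'   `n_lr` (with local recurrence by s), `n_nm` (with new metastatic disease
#'   by s).
#' @export
risk_set_counts <- function(stack) {
  s_values <- attr(stack, "grid")$times
  out <- lapply(s_values, function(s) {
    rows <- stack$s == s
    data.frame(s = s, n_at_risk = sum(rows),
               n_lr = as.integer(sum(stack$lr_status[rows])),
               n_nm = as.integer(sum(stack$nm_status[rows])))
  })
  do.call(rbind, out)
}
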
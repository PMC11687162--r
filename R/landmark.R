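## Landmark at-risk dataset construction: time-varying features evaluated at
## the landmark time s, residual time-to-event beyond s.

#' Landmark grid
#'
#' @param landmarks landmark times s (months post-transplant), all `>= 6`;
#'   default every month from 6 to 60.
#' @param horizons prediction horizons (months ahead of s); default 12, 36
#'   and 60 months (1/3/5 years).
#' @return A `landmark_grid` list.
#' @export
landmark_grid <- function(landmarks = 6:60, horizons = c(12, 36, 60)) {
  landmarks <- sort(unique(as.numeric(landmarks)))
  horizons <- sort(unique(as.numeric(horizons)))
  if (min(landmarks) < BASELINE_MONTH)
    stop("landmarks must be at or after the baseline month (6)", call. = FALSE)
  if (any(horizons <= 0)) stop("horizons must be positive", call. = FALSE)
  structure(list(landmarks = landmarks, horizons = horizons),
            class = "landmark_grid")
}

#' At-risk subjects at a landmark time
#'
#' A recipient is at risk at landmark `s` if they are alive with a
#' functioning graft and uncensored beyond `s`, i.e. `event_time > s`
#' whatever the eventual status.
#'
#' @param cohort a `ktx_cohort`.
#' @param s landmark time (months post-transplant, `>= 6`).
#' @return Character vector of subject ids.
#' @export
at_risk_set <- function(cohort, s) {
  if (s < BASELINE_MONTH)
    stop("landmark before baseline month", call. = FALSE)
  oc <- cohort$outcomes
  oc$subject_id[oc$event_time_months > s]
}

## OLS slope and residual SD of eGFR on time over the window (s-24, s]
.egfr_window_stats <- function(times, values) {
  n <- length(times)
  if (n < 3) return(c(slope = NA_real_, volatility = NA_real_))
  tc <- times - mean(times)
  slope <- sum(tc * values) / sum(tc^2)
  fitted <- mean(values) + slope * tc
  c(slope = slope,
    volatility = sqrt(sum((values - fitted)^2) / (n - 2)))
}

#' Extract landmark features for one subject
#'
#' Evaluates the time-varying predictors at landmark `s`: the current eGFR
#' (latest thinned observation at or before `s`), the OLS slope and residual
#' SD (volatility) of eGFR over the trailing two-year window `(s-24, s]`
#' (requires at least 3 observations; otherwise slope 0 and `NA` volatility,
#' to be filled by [build_landmark_dataset()]'s training-median fallback),
#' and the hospitalization/rejection counts over `(s-12, s]`. Windows are
#' half-open on the left: an event exactly at `s` counts.
#'
#' @param cohort a `ktx_cohort` with thinned eGFR.
#' @param subject_id one subject id, at risk at `s`.
#' @param s landmark time.
#' @return One-row data frame (a landmark row without the baseline
#'   covariates), or `NULL` when the subject has no eGFR observation at or
#'   before `s`.
#' @export
extract_features <- function(cohort, subject_id, s) {
  eg <- cohort$egfr
  eg <- eg[eg$subject_id == subject_id & eg$time_months <= s, , drop = FALSE]
  if (!nrow(eg)) {
    ## thinning may have displaced the month-6 measurement past s; the
    ## baseline eGFR covariate is that measurement and stands in for it
    bl <- cohort$baseline
    bv <- bl$baseline_egfr[bl$subject_id == subject_id]
    if (!length(bv) || is.na(bv)) return(NULL)
    eg <- data.frame(subject_id = subject_id, time_months = BASELINE_MONTH,
                     egfr = bv, stringsAsFactors = FALSE)
  }
  cur <- eg$egfr[which.max(eg$time_months)]
  win <- eg[eg$time_months > s - 24, , drop = FALSE]
  st <- .egfr_window_stats(win$time_months, win$egfr)
  evs <- cohort$events
  evs <- evs[evs$subject_id == subject_id &
               evs$time_months > s - 12 & evs$time_months <= s, , drop = FALSE]
  oc <- cohort$outcomes[cohort$outcomes$subject_id == subject_id, ]
  data.frame(subject_id = subject_id, s = s,
             egfr_current = cur,
             egfr_slope = ifelse(is.na(st[["slope"]]), 0, st[["slope"]]),
             egfr_volatility = st[["volatility"]],
             n_hosp_12m = sum(evs$type == "hospitalization"),
             n_reject_12m = sum(evs$type == "rejection"),
             residual_time = oc$event_time_months - s,
             residual_status = oc$status,
             stringsAsFactors = FALSE)
}

## vectorized feature extraction for all at-risk subjects at one landmark
.features_at <- function(cohort, s, ids) {
  eg <- cohort$egfr
  eg <- eg[eg$subject_id %in% ids & eg$time_months <= s, , drop = FALSE]
  ## subjects whose only pre-s measurement was displaced by thinning fall
  ## back to the baseline eGFR covariate as a month-6 observation
  bl <- cohort$baseline
  lack <- setdiff(ids, unique(eg$subject_id))
  if (length(lack)) {
    bv <- bl$baseline_egfr[match(lack, bl$subject_id)]
    ok <- !is.na(bv)
    if (any(ok))
      eg <- rbind(eg, data.frame(subject_id = lack[ok],
                                 time_months = BASELINE_MONTH,
                                 egfr = bv[ok], stringsAsFactors = FALSE))
  }
  if (!nrow(eg)) return(NULL)
  sp <- split(eg, eg$subject_id)
  cur <- vapply(sp, function(d) d$egfr[which.max(d$time_months)], numeric(1))
  stats <- vapply(sp, function(d) {
    w <- d$time_months > s - 24
    .egfr_window_stats(d$time_months[w], d$egfr[w])
  }, numeric(2))
  evs <- cohort$events
  evs <- evs[evs$subject_id %in% ids & evs$time_months > s - 12 &
               evs$time_months <= s, , drop = FALSE]
  nh <- table(factor(evs$subject_id[evs$type == "hospitalization"],
                     levels = names(sp)))
  nr <- table(factor(evs$subject_id[evs$type == "rejection"],
                     levels = names(sp)))
  oc <- cohort$outcomes[match(names(sp), cohort$outcomes$subject_id), ]
  data.frame(subject_id = names(sp), s = s,
             egfr_current = unname(cur),
             egfr_slope = ifelse(is.na(stats["slope", ]), 0,
                                 stats["slope", ]),
             egfr_volatility = unname(stats["volatility", ]),
             n_hosp_12m = as.numeric(nh),
             n_reject_12m = as.numeric(nr),
             residual_time = oc$event_time_months - s,
             residual_status = oc$status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the stacked landmark dataset
#'
#' For each landmark `s` in the grid, forms one row per at-risk recipient:
#' baseline covariates joined to the time-varying features of
#' [extract_features()] and the residual time/status beyond `s`. Subjects
#' without any eGFR observation at or before `s` are dropped (count reported
#' via a warning). Sparse eGFR windows (fewer than 3 observations) receive
#' slope 0 and the median volatility among computable windows at the same
#' landmark (or `volatility_fallback` when supplied, e.g. frozen from a
#' training fold).
#'
#' @param cohort a `ktx_cohort`; eGFR is thinned monthly first (idempotent).
#' @param grid a [landmark_grid()].
#' @param volatility_fallback optional named numeric vector (names = landmark
#'   times as characters) of frozen fallback volatilities.
#' @return A data frame of landmark rows stacked over `s`, with attribute
#'   `volatility_fallback` (the values used).
#' @export
build_landmark_dataset <- function(cohort, grid,
                                   volatility_fallback = NULL) {
  stopifnot(inherits(grid, "landmark_grid"))
  cohort <- thin_egfr_monthly(cohort)
  out <- vector("list", length(grid$landmarks))
  fb <- numeric(0)
  dropped <- 0L
  usable <- logical(length(grid$landmarks))
  for (k in seq_along(grid$landmarks)) {
    s <- grid$landmarks[k]
    ids <- at_risk_set(cohort, s)
    if (!length(ids)) next
    ft <- .features_at(cohort, s, ids)
    if (is.null(ft)) next
    dropped <- dropped + (length(ids) - nrow(ft))
    miss <- is.na(ft$egfr_volatility)
    key <- as.character(s)
    fbv <- if (!is.null(volatility_fallback) &&
               key %in% names(volatility_fallback)) {
      volatility_fallback[[key]]
    } else if (any(!miss)) {
      median(ft$egfr_volatility[!miss])
    } else 0
    ft$egfr_volatility[miss] <- fbv
    fb[key] <- fbv
    out[[k]] <- merge(cohort$baseline, ft, by = "subject_id")
    usable[k] <- TRUE
  }
  if (dropped > 0)
    warning(sprintf("%d at-risk row(s) dropped: no eGFR at or before s",
                    dropped), call. = FALSE)
  if (!all(usable))
    warning(sprintf("empty at-risk set at landmark(s) %s; removed from grid",
                    paste(grid$landmarks[!usable], collapse = ", ")),
            call. = FALSE)
  res <- do.call(rbind, out[usable])
  rownames(res) <- NULL
  attr(res, "volatility_fallback") <- fb
  res
}

#' Expand baseline categorical covariates into indicator columns
#'
#' Turns `esrd_cause` and `donor_cod` into 0/1 dummies (reference levels
#' `other` and `living`/`other`) so that all model candidates are numeric
#' columns.
#'
#' @param df a data frame containing the baseline covariates.
#' @return The data frame with added indicator columns.
#' @export
expand_dummies <- function(df) {
  if ("esrd_cause" %in% names(df)) {
    for (lv in c("DM", "HTN", "PKD", "GN"))
      df[[paste0("esrd_", tolower(lv))]] <- as.numeric(df$esrd_cause == lv)
  }
  if ("donor_cod" %in% names(df)) {
    for (lv in c("anoxia", "CVD", "trauma", "tumor"))
      df[[paste0("cod_", tolower(lv))]] <- as.numeric(df$donor_cod == lv)
  }
  df
}

#' Default model candidate features
#'
#' The full candidate predictor set: baseline recipient, donor and
#' transplant-related covariates (categoricals as indicators) plus the five
#' time-varying landmark features.
#' @return Character vector of column names.
#' @export
candidate_features <- function() {
  c("recipient_age", "female", "black_race", "prior_tx", "pretx_hd_months",
    "esrd_dm", "esrd_htn", "esrd_pkd", "esrd_gn",
    "ims_tac", "ims_csa",
    "induction_alemtuzumab", "induction_il2", "induction_atg",
    "living_donor", "donor_age", "donor_female", "donor_black", "donor_bmi",
    "donor_dm",
    "kdpi", "hla_mismatches", "peak_pra_ge1", "dgf",
    "b2m", "mg", "ca", "ph", "baseline_hosp", "baseline_rejection",
    "egfr_current", "egfr_slope", "egfr_volatility",
    "n_hosp_12m", "n_reject_12m")
}
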
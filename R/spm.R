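## Static prediction model (SPM): the baseline-only comparator. One pair of
## cause-specific Cox models and one GEE model fitted once at baseline
## (month 6) using baseline covariates only; predictions at a later landmark
## s are obtained by analytic conditioning on being event-free at s.

#' Baseline-only predictor set for the static model
#' @return Character vector of baseline covariate columns.
#' @export
spm_features <- function() {
  setdiff(candidate_features(),
          c("egfr_current", "egfr_slope", "egfr_volatility",
            "n_hosp_12m", "n_reject_12m"))
}

#' Fit the static prediction model
#'
#' Fits one pair of cause-specific Cox models on the time from baseline
#' (month 6) to graft failure / death, and one GEE model for post-baseline
#' eGFR over `(6, 6 + max(horizons)]`, both on all recipients at baseline
#' using baseline covariates only. There is no per-landmark administrative
#' censoring: the survival models use the full residual follow-up needed to
#' condition at later prediction times.
#'
#' @param cohort a `ktx_cohort`.
#' @param horizons prediction horizons in months (default 12/36/60).
#' @param features baseline covariate columns (default [spm_features()]
#'   plus `baseline_egfr`).
#' @param max_landmark last prediction time the model must serve (months);
#'   the survival cap is `max_landmark - 6 + max(horizons)`.
#' @param corstr working correlation for the GEE part.
#' @param gee fit the GEE eGFR component (set `FALSE` when only survival
#'   predictions are needed).
#' @param ... passed to [fit_csh()].
#' @return An `spm_fit` with elements `csh`, `gee`, `features`.
#' @export
fit_spm <- function(cohort, horizons = c(12, 36, 60),
                    features = c(spm_features(), "baseline_egfr"),
                    max_landmark = 60,
                    corstr = "independence", gee = TRUE, ...) {
  cohort <- thin_egfr_monthly(cohort)
  g <- landmark_grid(landmarks = BASELINE_MONTH, horizons = horizons)
  rows <- suppressWarnings(build_landmark_dataset(cohort, g))
  rows <- expand_dummies(rows)
  features <- intersect(features, names(rows))
  cap <- (max_landmark - BASELINE_MONTH) + max(horizons)
  csh <- fit_csh(rows, features, horizon_cap = cap, ...)
  gee <- if (isTRUE(gee)) {
    fit_gee(rows, cohort, features, delta_cap = max(horizons),
            corstr = corstr)
  } else NULL
  structure(list(csh = csh, gee = gee, features = features,
                 horizons = horizons, max_landmark = max_landmark),
            class = "spm_fit")
}

#' @export
print.spm_fit <- function(x, ...) {
  cat("Static prediction model (baseline month 6):\n")
  print(x$csh)
  invisible(x)
}

#' Predict from the static model at a later landmark
#'
#' For a recipient event-free at prediction time `s`, the conditional
#' cumulative incidence over the next `delta` months is
#' `(Fk(s - 6 + delta | Z) - Fk(s - 6 | Z)) / S(s - 6 | Z)`, the analytic
#' conditioning of the baseline-time model on event-free status at `s`.
#' The eGFR prediction is the baseline GEE marginal mean at elapsed time
#' `(s - 6) + delta` (not conditioned on survival).
#'
#' @param spm an `spm_fit`.
#' @param newdata baseline features, one row per subject.
#' @param s prediction time (months post-transplant, `>= 6`).
#' @param delta horizon in months beyond `s`.
#' @return Data frame with `cif_graft_failure`, `cif_death`, `event_free`
#'   (conditional on being event-free at `s`) and `egfr_pred`.
#' @export
predict_spm <- function(spm, newdata, s, delta) {
  stopifnot(inherits(spm, "spm_fit"))
  if (s < BASELINE_MONTH) stop("s before baseline", call. = FALSE)
  a <- s - BASELINE_MONTH
  pa <- predict_cif(spm$csh, newdata, a)
  pad <- predict_cif(spm$csh, newdata, a + delta)
  Sa <- pa$event_free
  if (any(Sa <= 0))
    stop("event-free probability zero at s; conditional risk undefined",
         call. = FALSE)
  out <- data.frame(
    cif_graft_failure = (pad$cif_graft_failure - pa$cif_graft_failure) / Sa,
    cif_death = (pad$cif_death - pa$cif_death) / Sa,
    event_free = pad$event_free / Sa)
  if (!is.null(spm$gee))
    out$egfr_pred <- predict_egfr(spm$gee, newdata, a + delta,
                                  extrapolate = TRUE)
  if ("subject_id" %in% names(newdata))
    out <- cbind(subject_id = newdata$subject_id, out)
  out
}
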
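## Accuracy machinery: IPCW time-dependent AUC and Brier score under
## competing risks, eGFR RMSE/P30/P50, repeated cross-validation and
## bootstrap comparison of the landmark model against the static comparator.

## Kaplan-Meier of the censoring distribution evaluated at `at`
## (left limit when minus = TRUE)
.censor_km <- function(time, status, at, minus = FALSE) {
  sf <- survival::survfit(survival::Surv(time, status == 0) ~ 1)
  tt <- sf$time[sf$n.event > 0]
  ss <- sf$surv[sf$n.event > 0]
  vapply(at, function(a) {
    if (minus) j <- sum(tt < a) else j <- sum(tt <= a)
    if (j == 0) 1 else ss[j]
  }, numeric(1))
}

#' Inverse-probability-of-censoring weights at a landmark
#'
#' Weights correcting Delta-horizon accuracy metrics for right censoring,
#' computed within the at-risk set at the landmark (residual time scale).
#' The censoring survivor function G is the Kaplan-Meier estimate treating
#' censoring as the event. Subjects with any event at residual time
#' `T <= delta` get `1/G(T-)`; subjects event-free at `delta` get
#' `1/G(delta)`; subjects censored before `delta` get 0.
#'
#' @param time residual times (months beyond the landmark).
#' @param status residual status (0 censored, 1 graft failure, 2 death).
#' @param delta horizon (months).
#' @return Numeric weight vector.
#' @export
ipcw_weights <- function(time, status, delta) {
  Gd <- .censor_km(time, status, delta)
  if (Gd <= 0)
    stop("censoring survival zero at the horizon; delta beyond follow-up support",
         call. = FALSE)
  w <- numeric(length(time))
  ev <- status > 0 & time <= delta
  fr <- time > delta
  w[ev] <- 1 / .censor_km(time, status, time[ev], minus = TRUE)
  w[fr] <- 1 / Gd
  w
}

## weighted Mann-Whitney with ties counted 1/2 (sort-based)
.weighted_auc <- function(risk_case, w_case, risk_ctrl, w_ctrl) {
  o <- order(risk_ctrl)
  rc <- risk_ctrl[o]; wc <- w_ctrl[o]
  cw <- c(0, cumsum(wc))
  lt <- cw[findInterval(risk_case, rc, left.open = TRUE) + 1]  # ctrl < case
  le <- cw[findInterval(risk_case, rc) + 1]                    # ctrl <= case
  num <- sum(w_case * (lt + 0.5 * (le - lt)))
  num / (sum(w_case) * sum(w_ctrl))
}

#' Time-dependent AUC for competing risks
#'
#' Discrimination of predicted Delta-horizon cause-k risks among the at-risk
#' set at the landmark. Cases are subjects with a cause-k event in
#' `(0, delta]` (residual scale); controls are subjects event-free at `delta`
#' together with subjects who had the competing event by `delta` (they
#' verifiably lack the index event). The AUC is the IPCW-weighted
#' Mann-Whitney probability that a random case's predicted risk exceeds a
#' random control's, ties counted one half.
#'
#' @param risk predicted cause-k cumulative incidence at `delta`.
#' @param time,status residual time and status.
#' @param delta horizon (months).
#' @param cause index cause (1 graft failure, 2 death).
#' @return List with `value` and `n_effective` (subjects with positive
#'   weight among cases and controls); `value` is `NA` with zero cases or
#'   zero controls.
#' @export
td_auc <- function(risk, time, status, delta, cause = 1) {
  w <- ipcw_weights(time, status, delta)
  is_case <- status == cause & time <= delta
  is_ctrl <- time > delta | (status > 0 & status != cause & time <= delta)
  ok_case <- is_case & w > 0
  ok_ctrl <- is_ctrl & w > 0
  if (!any(ok_case) || !any(ok_ctrl))
    return(list(value = NA_real_, n_effective = sum(ok_case | ok_ctrl)))
  list(value = .weighted_auc(risk[ok_case], w[ok_case],
                             risk[ok_ctrl], w[ok_ctrl]),
       n_effective = sum(ok_case | ok_ctrl))
}

#' Time-dependent Brier score for competing risks
#'
#' IPCW-weighted mean squared error of the predicted cause-k cumulative
#' incidence against the 0/1 indicator of a cause-k event by the horizon:
#' `BS = sum(w (D - Fhat)^2) / sum(w)`.
#'
#' @inheritParams td_auc
#' @return List with `value` and `n_effective`.
#' @export
td_brier <- function(risk, time, status, delta, cause = 1) {
  w <- ipcw_weights(time, status, delta)
  D <- as.numeric(status == cause & time <= delta)
  if (sum(w) == 0) return(list(value = NA_real_, n_effective = 0L))
  list(value = sum(w * (D - risk)^2) / sum(w),
       n_effective = sum(w > 0))
}

#' eGFR prediction accuracy at the horizon
#'
#' For each subject event-free at `s + delta`, the observed value is the
#' thinned eGFR measurement closest to `s + delta` within two months (ties
#' toward the earlier measurement); subjects without such a measurement are
#' excluded. Returns the RMSE over included subjects and the fractions
#' within 30% (P30) and 50% (P50) of the observed value.
#'
#' @param predictions data frame with `subject_id` and `egfr_pred`.
#' @param cohort a `ktx_cohort` (thinned).
#' @param s landmark time; `delta` horizon (months).
#' @param delta horizon (months).
#' @param window matching half-width in months (default 2).
#' @return List with `rmse`, `p30`, `p50`, `n_effective`.
#' @export
egfr_accuracy <- function(predictions, cohort, s, delta, window = 2) {
  target <- s + delta
  oc <- cohort$outcomes
  free <- oc$subject_id[oc$event_time_months > target]
  pr <- predictions[predictions$subject_id %in% free, , drop = FALSE]
  eg <- cohort$egfr
  eg <- eg[eg$subject_id %in% pr$subject_id &
             abs(eg$time_months - target) <= window, , drop = FALSE]
  if (!nrow(eg) || !nrow(pr))
    return(list(rmse = NA_real_, p30 = NA_real_, p50 = NA_real_,
                n_effective = 0L))
  o <- order(eg$subject_id, abs(eg$time_months - target), eg$time_months)
  eg <- eg[o, , drop = FALSE]
  eg <- eg[!duplicated(eg$subject_id), , drop = FALSE]
  m <- merge(pr, eg[, c("subject_id", "egfr")], by = "subject_id")
  err <- m$egfr_pred - m$egfr
  list(rmse = sqrt(mean(err^2)),
       p30 = mean(abs(err) <= 0.30 * m$egfr),
       p50 = mean(abs(err) <= 0.50 * m$egfr),
       n_effective = nrow(m))
}

## evaluate fitted LM + SPM on a test cohort over (s, delta) combinations;
## returns tidy rows
.evaluate_fits <- function(lm_fits, gee_fits, spm, test_lm, test_cohort,
                           grid) {
  out <- list()
  for (s in grid$landmarks) {
    key <- as.character(s)
    rows <- test_lm[test_lm$s == s, , drop = FALSE]
    if (!nrow(rows) || is.null(lm_fits[[key]])) next
    for (d in grid$horizons) {
      lm_ci <- tryCatch(predict_cif(lm_fits[[key]], rows, d),
                        error = function(e) NULL)
      sp_ci <- tryCatch(predict_spm(spm, rows, s, d),
                        error = function(e) NULL)
      tt <- rows$residual_time
      ss <- rows$residual_status
      for (model in c("LM", "SPM")) {
        ci <- if (model == "LM") lm_ci else sp_ci
        if (is.null(ci)) next
        for (cz in 1:2) {
          rk <- if (cz == 1) ci$cif_graft_failure else ci$cif_death
          a <- tryCatch(td_auc(rk, tt, ss, d, cz), error = function(e)
            list(value = NA_real_, n_effective = 0L))
          b <- tryCatch(td_brier(rk, tt, ss, d, cz), error = function(e)
            list(value = NA_real_, n_effective = 0L))
          cname <- c("graft_failure", "death")[cz]
          out[[length(out) + 1]] <- data.frame(
            model = model, metric = c("AUC", "BS"), cause = cname,
            s = s, delta = d, value = c(a$value, b$value),
            n_effective = c(a$n_effective, b$n_effective),
            stringsAsFactors = FALSE)
        }
        ## eGFR accuracy
        ep <- if (model == "LM") {
          gk <- gee_fits[[key]][[as.character(d)]]
          if (is.null(gk)) NULL else
            data.frame(subject_id = rows$subject_id,
                       egfr_pred = predict_egfr(gk, rows, d))
        } else {
          data.frame(subject_id = rows$subject_id, egfr_pred = sp_ci$egfr_pred)
        }
        if (!is.null(ep)) {
          ea <- egfr_accuracy(ep, test_cohort, s, d)
          out[[length(out) + 1]] <- data.frame(
            model = model, metric = c("RMSE", "P30", "P50"), cause = "none",
            s = s, delta = d,
            value = c(ea$rmse, ea$p30, ea$p50),
            n_effective = ea$n_effective, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

## fit LM (per-landmark CSH + per-(s,delta) GEE) and SPM on a training cohort
.fit_both_models <- function(train, grid, lm_feats, spm_feats,
                             corstr = "independence", min_events = 10,
                             with_gee = TRUE) {
  train <- thin_egfr_monthly(train)
  lmdata <- suppressWarnings(build_landmark_dataset(train, grid))
  lmdata <- expand_dummies(lmdata)
  lm_feats <- intersect(lm_feats, names(lmdata))
  fits <- fit_landmark_csh(lmdata, grid, lm_feats,
                           horizon_cap = max(grid$horizons),
                           min_events = min_events)
  gee_fits <- NULL
  if (with_gee) {
    gee_fits <- lapply(grid$landmarks, function(s) {
      rows <- lmdata[lmdata$s == s, , drop = FALSE]
      if (!nrow(rows)) return(NULL)
      gl <- lapply(grid$horizons, function(d) {
        tryCatch(fit_gee(rows, train, lm_feats, delta_cap = d,
                         corstr = corstr),
                 error = function(e) NULL)
      })
      names(gl) <- as.character(grid$horizons)
      gl
    })
    names(gee_fits) <- as.character(grid$landmarks)
  }
  spm <- fit_spm(train, horizons = grid$horizons,
                 features = spm_feats, max_landmark = max(grid$landmarks),
                 corstr = corstr, min_events = min_events, gee = with_gee)
  list(csh = fits, gee = gee_fits, spm = spm,
       volatility_fallback = attr(lmdata, "volatility_fallback"))
}

#' Repeated cross-validated accuracy curves
#'
#' Subject-level k-fold cross-validation repeated `repeats` times: the
#' landmark model (per-landmark cause-specific Cox pair plus per-(s, delta)
#' GEE) and the static comparator are fitted on the training folds
#' (including imputation, frozen for the held-out fold) and evaluated on the
#' held-out fold with the IPCW competing-risks AUC/Brier and the eGFR
#' RMSE/P30/P50; results are averaged over folds, then over repeats.
#'
#' @param cohort a `ktx_cohort`.
#' @param grid a [landmark_grid()].
#' @param lm_features landmark-model predictors (default
#'   [candidate_features()]).
#' @param spm_feats static-model predictors.
#' @param folds number of folds (default 3). `repeats` number of repeated
#'   splits (default 5).
#' @param repeats number of repeated splits.
#' @param seed RNG seed; the same seed reproduces the curves exactly.
#' @param corstr GEE working correlation.
#' @param min_events per-cause event floor for the Cox fits.
#' @return List with `curves` (mean value per model/metric/cause/s/delta and
#'   mean effective n) and `raw` (per repeat and fold).
#' @export
cross_validate <- function(cohort, grid, lm_features = candidate_features(),
                           spm_feats = c(spm_features(), "baseline_egfr"),
                           folds = 3, repeats = 5, seed = 1,
                           corstr = "independence", min_events = 10) {
  set.seed(seed)
  ids <- cohort_subjects(cohort)
  raw <- list()
  for (r in seq_len(repeats)) {
    fold_of <- sample(rep(seq_len(folds), length.out = length(ids)))
    for (f in seq_len(folds)) {
      train <- cohort_subset(cohort, ids[fold_of != f])
      test <- cohort_subset(cohort, ids[fold_of == f])
      imp <- impute_baseline(train)
      train <- imp$cohort
      test <- impute_baseline(test, values = imp$values)$cohort
      mods <- .fit_both_models(train, grid, lm_features, spm_feats,
                               corstr = corstr, min_events = min_events)
      test <- thin_egfr_monthly(test)
      test_lm <- suppressWarnings(
        build_landmark_dataset(test, grid,
                               volatility_fallback = mods$volatility_fallback))
      test_lm <- expand_dummies(test_lm)
      ev <- .evaluate_fits(mods$csh, mods$gee, mods$spm, test_lm, test, grid)
      if (!is.null(ev)) {
        ev$rep <- r; ev$fold <- f
        raw[[length(raw) + 1]] <- ev
      }
    }
  }
  raw <- do.call(rbind, raw)
  agg <- aggregate(cbind(value, n_effective) ~ model + metric + cause +
                     s + delta,
                   data = raw[!is.na(raw$value), ], FUN = mean)
  agg <- agg[order(agg$metric, agg$cause, agg$model, agg$delta, agg$s), ]
  rownames(agg) <- NULL
  list(curves = agg, raw = raw)
}

#' Bootstrap comparison of landmark vs static model at one (s, delta)
#'
#' Resamples the training set at subject level `B` times; for each resample
#' both models are refitted and the chosen accuracy metric recomputed on the
#' fixed test set; returns the percentile confidence interval of the LM
#' minus SPM difference and a significance flag (interval excludes zero).
#'
#' @param train,test `ktx_cohort` training and test sets.
#' @param s landmark time; `delta` horizon (months).
#' @param delta horizon (months).
#' @param metric `"auc"` or `"brier"`.
#' @param cause index cause (1 or 2).
#' @param lm_features,spm_feats predictor sets.
#' @param B number of bootstrap resamples (>= 2; 500 in full-scale use).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @param min_events per-cause event floor.
#' @return List with `diff_obs`, `ci` (length 2), `significant`, `diffs`
#'   (the B resampled differences, NA where undefined) and `unstable`
#'   (TRUE when the metric was undefined in more than half the resamples).
#' @export
bootstrap_compare <- function(train, test, s, delta, metric = c("auc", "brier"),
                              cause = 1,
                              lm_features = candidate_features(),
                              spm_feats = c(spm_features(), "baseline_egfr"),
                              B = 500, level = 0.95, seed = 1,
                              min_events = 10) {
  metric <- match.arg(metric)
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  set.seed(seed)
  grid <- landmark_grid(landmarks = s, horizons = delta)
  test <- thin_egfr_monthly(test)

  ## the test-set landmark rows are fixed across resamples (the training
  ## volatility fallback is frozen from the observed training fit)
  obs_mods <- tryCatch(
    .fit_both_models(train, grid, lm_features, spm_feats,
                     min_events = min_events, with_gee = FALSE),
    error = function(e) NULL)
  if (is.null(obs_mods))
    stop("models cannot be fitted on the observed training set", call. = FALSE)
  test_lm <- suppressWarnings(
    build_landmark_dataset(test, grid,
                           volatility_fallback = obs_mods$volatility_fallback))
  test_lm <- expand_dummies(test_lm)
  rows <- test_lm[test_lm$s == s, , drop = FALSE]
  if (!nrow(rows)) stop("empty test at-risk set at s", call. = FALSE)

  one_diff <- function(mods) {
    if (is.null(mods)) return(NA_real_)
    fitL <- mods$csh[[as.character(s)]]
    if (is.null(fitL)) return(NA_real_)
    lm_ci <- tryCatch(predict_cif(fitL, rows, delta), error = function(e) NULL)
    sp_ci <- tryCatch(predict_spm(mods$spm, rows, s, delta),
                      error = function(e) NULL)
    if (is.null(lm_ci) || is.null(sp_ci)) return(NA_real_)
    rkL <- if (cause == 1) lm_ci$cif_graft_failure else lm_ci$cif_death
    rkS <- if (cause == 1) sp_ci$cif_graft_failure else sp_ci$cif_death
    fun <- if (metric == "auc") td_auc else td_brier
    vL <- tryCatch(fun(rkL, rows$residual_time, rows$residual_status,
                       delta, cause)$value, error = function(e) NA_real_)
    vS <- tryCatch(fun(rkS, rows$residual_time, rows$residual_status,
                       delta, cause)$value, error = function(e) NA_real_)
    vL - vS
  }

  diff_obs <- one_diff(obs_mods)
  ids <- cohort_subjects(train)
  eg_sp <- split(train$egfr, factor(train$egfr$subject_id, levels = ids))
  ev_sp <- split(train$events, factor(train$events$subject_id, levels = ids))
  oc_sp <- split(train$outcomes, factor(train$outcomes$subject_id,
                                        levels = ids))
  diffs <- vapply(seq_len(B), function(b) {
    bid <- sample(ids, replace = TRUE)
    ## subject-level resample: duplicated subjects get fresh ids so all of a
    ## subject's rows are carried together
    bl <- train$baseline[match(bid, train$baseline$subject_id), , drop = FALSE]
    new_id <- sprintf("B%05d", seq_along(bid))
    remap <- function(sp) {
      k <- sp[bid]
      d <- do.call(rbind, k)
      d$subject_id <- rep(new_id, vapply(k, nrow, integer(1)))
      d
    }
    bl$subject_id <- new_id
    tr <- suppressWarnings(ktx_cohort(bl, remap(eg_sp), remap(ev_sp),
                                      remap(oc_sp)))
    m <- tryCatch(
      .fit_both_models(tr, grid, lm_features, spm_feats,
                       min_events = min_events, with_gee = FALSE),
      error = function(e) NULL)
    one_diff(m)
  }, numeric(1))
  ok <- diffs[!is.na(diffs)]
  unstable <- length(ok) < B / 2
  ci <- if (length(ok) >= 2) {
    unname(quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
  } else c(NA_real_, NA_real_)
  list(diff_obs = diff_obs, ci = ci,
       significant = !unstable && !anyNA(ci) && (ci[1] > 0 || ci[2] < 0),
       diffs = diffs, unstable = unstable)
}
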
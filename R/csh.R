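## Paired cause-specific proportional-hazards models at a landmark, and the
## conversion of the fitted pair into predicted cumulative incidence
## functions.
##
## Each cause is fitted by partial likelihood (the competing cause treated as
## censoring); the baseline cumulative hazard is the Breslow estimator
## evaluated at covariates centered on the training means, so the baseline
## refers to an average at-risk recipient. Predicted cumulative incidences
## use the discrete product-limit construction
##   S(u) = prod_{v <= u} (1 - dL1(v|Z) - dL2(v|Z)),
##   Fk(t) = sum_{u <= t} S(u-) dLk(u|Z),
## which guarantees F1 + F2 + S = 1 exactly and reduces to the
## Aalen-Johansen estimator when there are no covariates.

#' Fit the paired cause-specific Cox models at one landmark
#'
#' Residual times are administratively censored at `horizon_cap` before
#' fitting (the standard landmark device). Features are centered at their
#' training means; constant columns are dropped. The Breslow baseline
#' cumulative-hazard increments are computed at the centered covariates.
#'
#' @param rows landmark rows at one landmark (from
#'   [build_landmark_dataset()]), expanded with [expand_dummies()] as needed.
#' @param features character vector of predictor columns; may be empty for
#'   the null (covariate-free) model.
#' @param horizon_cap administrative censoring time on the residual scale
#'   (months), typically `max(horizons)`.
#' @param ties tie handling passed to the partial likelihood
#'   (`"breslow"` default, `"efron"` optional).
#' @param min_events minimum events required per cause (default 10).
#' @return A `csh_fit` with per-cause coefficients, robust-free model-based
#'   covariance, Breslow baseline hazard step functions, centering values and
#'   convergence info.
#' @export
fit_csh <- function(rows, features = character(0), horizon_cap = 60,
                    ties = c("breslow", "efron"), min_events = 10) {
  ties <- match.arg(ties)
  rt <- pmin(rows$residual_time, horizon_cap)
  st <- ifelse(rows$residual_time > horizon_cap, 0L,
               as.integer(rows$residual_status))
  n_ev <- c(sum(st == 1), sum(st == 2))
  if (any(n_ev < min_events))
    stop(sprintf("too few events within the horizon cap (%d graft failures, %d deaths; need >= %d per cause)",
                 n_ev[1], n_ev[2], min_events), call. = FALSE)

  features <- unique(features)
  X <- NULL; center <- numeric(0)
  if (length(features)) {
    miss <- setdiff(features, names(rows))
    if (length(miss))
      stop("features not in data: ", paste(miss, collapse = ", "),
           call. = FALSE)
    X <- as.matrix(rows[, features, drop = FALSE])
    if (anyNA(X)) stop("missing values in features", call. = FALSE)
    keep <- apply(X, 2, function(x) diff(range(x)) > 0)
    ## a binary indicator with a zero-event level gives a monotone partial
    ## likelihood (infinite coefficient); drop such columns up front
    for (j in which(keep)) {
      x <- X[, j]
      if (length(unique(x)) == 2) {
        for (cz in 1:2) {
          ev <- st == cz
          if (any(tapply(ev, x, sum) == 0)) { keep[j] <- FALSE; break }
        }
      }
    }
    ## near-collinear pairs (|cor| > 0.95) destabilize the partial
    ## likelihood; keep the earlier-listed feature of each such pair
    ki <- which(keep)
    if (length(ki) > 1) {
      cm <- suppressWarnings(abs(stats::cor(X[, ki, drop = FALSE])))
      for (a in seq_along(ki)) for (b in seq_len(a - 1)) {
        if (keep[ki[a]] && keep[ki[b]] && is.finite(cm[a, b]) &&
            cm[a, b] > 0.95)
          keep[ki[a]] <- FALSE
      }
    }
    if (any(!keep))
      warning("dropped unusable feature(s): ",
              paste(features[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    features <- features[keep]
    center <- colMeans(X)
    X <- sweep(X, 2, center)
  }

  fit1core <- function(cause) {
    y <- survival::Surv(rt, st == cause)
    if (!length(features)) {
      sf <- survival::survfit(y ~ 1)
      ## Nelson-Aalen increments of this cause
      dh <- sf$n.event / sf$n.risk
      keep <- sf$n.event > 0
      return(list(beta = numeric(0), vcov = matrix(0, 0, 0),
                  base = data.frame(time = sf$time[keep], dhaz = dh[keep]),
                  iter = 0L, loglik = NA_real_))
    }
    cf <- survival::coxph(y ~ X, ties = ties,
                          control = survival::coxph.control(eps = 1e-10,
                                                            iter.max = 100))
    beta <- coef(cf)
    if (anyNA(beta))
      stop("singular design in cause-specific fit; remove collinear features",
           call. = FALSE)
    if (any(abs(beta) > 15))
      stop(sprintf("apparent separation (|coef| > 15) for: %s; remove the feature",
                   paste(features[abs(beta) > 15], collapse = ", ")),
           call. = FALSE)
    names(beta) <- features
    lp <- drop(X %*% beta)
    ## Breslow baseline increments at the centered covariates
    o <- order(rt)
    rs <- rev(cumsum(rev(exp(lp[o]))))   # risk-set sums at sorted times
    tt <- rt[o]; ss <- (st == cause)[o]
    ut <- unique(tt[ss])
    dh <- vapply(ut, function(u) {
      i <- which(tt >= u)[1]
      sum(ss & tt == u) / rs[i]
    }, numeric(1))
    vc <- cf$var
    dimnames(vc) <- list(features, features)
    list(beta = beta, vcov = vc,
         base = data.frame(time = ut, dhaz = dh),
         iter = cf$iter, loglik = cf$loglik[2])
  }

  f1 <- fit1core(1)
  f2 <- fit1core(2)
  structure(list(s = if ("s" %in% names(rows)) rows$s[1] else NA_real_,
                 features = features, center = center,
                 cause1_coefs = f1$beta, cause2_coefs = f2$beta,
                 cause1_vcov = f1$vcov, cause2_vcov = f2$vcov,
                 cause1_baseline = f1$base, cause2_baseline = f2$base,
                 loglik = c(graft_failure = f1$loglik, death = f2$loglik),
                 horizon_cap = horizon_cap, ties = ties,
                 n = length(rt), n_events = setNames(n_ev,
                   c("graft_failure", "death")),
                 convergence = c(iter1 = f1$iter, iter2 = f2$iter)),
            class = "csh_fit")
}

#' @export
print.csh_fit <- function(x, ...) {
  cat(sprintf("Cause-specific hazards fit at landmark s = %s (n = %d; %d graft failures, %d deaths within cap %s)\n",
              format(x$s), x$n, x$n_events[1], x$n_events[2],
              format(x$horizon_cap)))
  if (length(x$features)) {
    tab <- data.frame(graft_failure = x$cause1_coefs,
                      death = x$cause2_coefs)
    print(round(tab, 4))
  } else cat("  (null model: Nelson-Aalen baselines only)\n")
  invisible(x)
}

.lp_for <- function(fit, newdata, cause) {
  if (!length(fit$features)) return(rep(0, nrow(newdata)))
  miss <- setdiff(fit$features, names(newdata))
  if (length(miss))
    stop("newdata lacks feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[, fit$features, drop = FALSE])
  if (anyNA(X)) stop("missing values in newdata features", call. = FALSE)
  X <- sweep(X, 2, fit$center)
  beta <- if (cause == 1) fit$cause1_coefs else fit$cause2_coefs
  drop(X %*% beta)
}

#' Predict cumulative incidence from a cause-specific hazards fit
#'
#' Combines both fitted cause-specific hazards into the cumulative incidence
#' of each cause at horizon `delta` (months beyond the landmark) and the
#' event-free probability, via the product-limit construction, so that
#' `cif_graft_failure + cif_death + event_free = 1` exactly.
#'
#' @param fit a `csh_fit`.
#' @param newdata data frame with the fit's feature columns (ignored for a
#'   null fit); one row per subject.
#' @param delta horizon(s) on the residual scale, each `<= horizon_cap`.
#' @return Data frame with columns `delta`, `cif_graft_failure`, `cif_death`,
#'   `event_free` (and `subject_id` when present in `newdata`), one row per
#'   subject and horizon.
#' @export
predict_cif <- function(fit, newdata, delta) {
  stopifnot(inherits(fit, "csh_fit"))
  if (any(delta > fit$horizon_cap + 1e-9))
    stop("delta beyond the fitted horizon cap", call. = FALSE)
  if (any(delta < 0)) stop("delta must be nonnegative", call. = FALSE)
  lp1 <- .lp_for(fit, newdata, 1)
  lp2 <- .lp_for(fit, newdata, 2)
  b1 <- fit$cause1_baseline; b2 <- fit$cause2_baseline
  u <- sort(unique(c(b1$time, b2$time)))
  dh1 <- numeric(length(u)); dh1[match(b1$time, u)] <- b1$dhaz
  dh2 <- numeric(length(u)); dh2[match(b2$time, u)] <- b2$dhaz
  m <- length(lp1)
  D1 <- outer(exp(lp1), dh1)            # m x J per-subject hazard increments
  D2 <- outer(exp(lp2), dh2)
  fac <- pmax(1 - D1 - D2, 0)
  Scum <- t(apply(fac, 1, cumprod))
  Sprev <- cbind(rep(1, m), Scum[, -ncol(Scum), drop = FALSE])
  res <- lapply(delta, function(d) {
    inh <- u <= d + 1e-12
    F1 <- as.numeric((Sprev * D1)[, inh, drop = FALSE] %*% rep(1, sum(inh)))
    F2 <- as.numeric((Sprev * D2)[, inh, drop = FALSE] %*% rep(1, sum(inh)))
    out <- data.frame(delta = d, cif_graft_failure = F1, cif_death = F2,
                      event_free = 1 - F1 - F2)
    if ("subject_id" %in% names(newdata))
      out <- cbind(subject_id = newdata$subject_id, out)
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fit cause-specific models at every landmark of a grid
#'
#' One [fit_csh()] per landmark. Landmarks with too few events fall back to
#' the nearest earlier landmark's fit (recorded in the result); landmarks
#' with no usable fit at all are dropped with a warning.
#'
#' @param lmdata stacked landmark dataset (with dummies expanded).
#' @param grid a [landmark_grid()].
#' @param features predictor columns.
#' @param horizon_cap administrative cap on the residual scale; default
#'   `max(grid$horizons)`.
#' @param ... passed to [fit_csh()].
#' @return Named list (by landmark) of `csh_fit` objects; attribute
#'   `fallback_from` names landmarks served by an earlier fit.
#' @export
fit_landmark_csh <- function(lmdata, grid, features,
                             horizon_cap = max(grid$horizons), ...) {
  fits <- list(); fellback <- character(0)
  last <- NULL
  for (s in grid$landmarks) {
    rows <- lmdata[lmdata$s == s, , drop = FALSE]
    key <- as.character(s)
    f <- if (nrow(rows) >= 2) {
      tryCatch(fit_csh(rows, features, horizon_cap, ...),
               error = function(e) NULL)
    } else NULL
    if (is.null(f)) {
      if (!is.null(last)) {
        fits[[key]] <- last
        fellback <- c(fellback, key)
      }
    } else {
      fits[[key]] <- f
      last <- f
    }
  }
  if (!length(fits)) stop("no landmark could be fitted", call. = FALSE)
  if (length(fellback))
    warning("fallback to an earlier landmark fit at s = ",
            paste(fellback, collapse = ", "), call. = FALSE)
  attr(fits, "fallback_from") <- fellback
  fits
}

#' Coefficient trajectories over landmark time
#'
#' Collects each feature's fitted log hazard ratio and 95% Wald confidence
#' interval across a collection of per-landmark fits, for plotting
#' coefficient curves against landmark time.
#'
#' @param fits named list of `csh_fit` (as from [fit_landmark_csh()]).
#' @return Data frame with columns `s`, `cause`, `feature`, `coef`, `se`,
#'   `lower`, `upper`.
#' @export
coefficient_curves <- function(fits) {
  out <- lapply(fits, function(f) {
    if (!length(f$features)) return(NULL)
    do.call(rbind, lapply(1:2, function(k) {
      beta <- if (k == 1) f$cause1_coefs else f$cause2_coefs
      vc <- if (k == 1) f$cause1_vcov else f$cause2_vcov
      se <- sqrt(diag(vc))
      data.frame(s = f$s,
                 cause = c("graft_failure", "death")[k],
                 feature = f$features, coef = unname(beta), se = unname(se),
                 lower = unname(beta - qnorm(0.975) * se),
                 upper = unname(beta + qnorm(0.975) * se),
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
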
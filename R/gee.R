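## Marginal (GEE) model for eGFR observed between the landmark and the
## horizon. Mean model: E[eGFR(t)] = a'X + g (t - s) on the window
## (s, s + delta_cap]. Working correlation: independence (default) or
## exchangeable; inference always uses the robust sandwich covariance, so the
## mean coefficients are consistent regardless of the true correlation.

.gee_solve <- function(Zs, ys, corstr, tol = 1e-8, maxit = 50) {
  Z <- do.call(rbind, Zs)
  y <- unlist(ys, use.names = FALSE)
  p <- ncol(Z)
  qrz <- qr(Z)
  if (qrz$rank < p) {
    bad <- colnames(Z)[qrz$pivot[(qrz$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrz, y)
  rho <- 0
  N <- length(y)
  if (corstr == "exchangeable") {
    for (it in seq_len(maxit)) {
      e <- y - drop(Z %*% beta)
      phi <- sum(e^2) / (N - p)
      es <- split(e, rep(seq_along(ys), lengths(ys)))
      num <- sum(vapply(es, function(ei) (sum(ei)^2 - sum(ei^2)) / 2,
                        numeric(1)))
      npair <- sum(vapply(lengths(ys), function(m) m * (m - 1) / 2,
                          numeric(1)))
      rho <- if (npair > p) num / ((npair - p) * phi) else 0
      rho <- max(min(rho, 0.99), -0.99)
      A <- matrix(0, p, p); b <- numeric(p)
      for (i in seq_along(Zs)) {
        Zi <- Zs[[i]]; m <- nrow(Zi)
        ## inverse of exchangeable correlation, closed form
        c1 <- 1 / (1 - rho)
        c2 <- -rho / ((1 - rho) * (1 + (m - 1) * rho))
        ZtR <- c1 * t(Zi) + c2 * tcrossprod(colSums(Zi), rep(1, m))
        A <- A + ZtR %*% Zi
        b <- b + drop(ZtR %*% ys[[i]])
      }
      beta_new <- solve(A, b)
      if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
      beta <- beta_new
    }
  }
  e <- y - drop(Z %*% beta)
  phi <- sum(e^2) / (N - p)
  ## sandwich: Binv %*% M %*% Binv with the working-model bread
  if (corstr == "independence") {
    B <- crossprod(Z)
    es <- split(seq_len(N), rep(seq_along(ys), lengths(ys)))
    M <- matrix(0, p, p)
    for (ii in es) {
      u <- drop(crossprod(Z[ii, , drop = FALSE], e[ii]))
      M <- M + tcrossprod(u)
    }
  } else {
    B <- matrix(0, p, p); M <- matrix(0, p, p)
    start <- cumsum(c(1, lengths(ys)))
    for (i in seq_along(Zs)) {
      Zi <- Zs[[i]]; m <- nrow(Zi)
      ei <- e[start[i]:(start[i] + m - 1)]
      c1 <- 1 / (1 - rho)
      c2 <- -rho / ((1 - rho) * (1 + (m - 1) * rho))
      ZtR <- c1 * t(Zi) + c2 * tcrossprod(colSums(Zi), rep(1, m))
      B <- B + ZtR %*% Zi
      u <- drop(ZtR %*% ei)
      M <- M + tcrossprod(u)
    }
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  V <- (V + t(V)) / 2
  list(beta = beta, vcov = V, scale = phi, rho = rho)
}

#' Fit the landmark GEE model for eGFR
#'
#' Joins the at-risk landmark rows at `s` to their eGFR observations in the
#' window `(s, s + delta_cap]` and fits the marginal mean model
#' `E[eGFR(t)] = a'X + g (t - s)` by generalized estimating equations with
#' the chosen working correlation and robust sandwich covariance. Subjects
#' with no observation in the window are excluded. Subjects who fail or die
#' within the window contribute their observations up to the event.
#'
#' @param rows landmark rows at one landmark (features evaluated at `s`).
#' @param cohort the `ktx_cohort` supplying the (thinned) eGFR observations.
#' @param features predictor columns of `rows` entering the mean model.
#' @param delta_cap window end (months beyond `s`).
#' @param corstr working correlation, `"independence"` (default) or
#'   `"exchangeable"`.
#' @return A `gee_fit` with `coefs` (intercept, features, `time_since_s`),
#'   `robust_cov`, `scale`, `rho`, and window metadata.
#' @export
fit_gee <- function(rows, cohort, features, delta_cap,
                    corstr = c("independence", "exchangeable")) {
  corstr <- match.arg(corstr)
  s <- rows$s[1]
  eg <- cohort$egfr
  eg <- eg[eg$subject_id %in% rows$subject_id &
             eg$time_months > s & eg$time_months <= s + delta_cap, ,
           drop = FALSE]
  if (!nrow(eg)) stop("no eGFR observations in the window", call. = FALSE)
  rows <- rows[match(unique(eg$subject_id), rows$subject_id), , drop = FALSE]
  sp <- split(eg, eg$subject_id)
  sp <- sp[rows$subject_id]
  X <- as.matrix(rows[, features, drop = FALSE])
  if (anyNA(X)) stop("missing values in features", call. = FALSE)
  Zs <- lapply(seq_along(sp), function(i) {
    m <- nrow(sp[[i]])
    cbind(`(Intercept)` = rep(1, m),
          matrix(X[i, ], m, ncol(X), byrow = TRUE,
                 dimnames = list(NULL, features)),
          time_since_s = sp[[i]]$time_months - s)
  })
  ys <- lapply(sp, function(d) d$egfr)
  sol <- .gee_solve(Zs, ys, corstr)
  nm <- c("(Intercept)", features, "time_since_s")
  names(sol$beta) <- nm
  dimnames(sol$vcov) <- list(nm, nm)
  structure(list(s = s, delta_cap = delta_cap, features = features,
                 coefs = sol$beta, robust_cov = sol$vcov,
                 scale = sol$scale, rho = sol$rho, corstr = corstr,
                 n_subjects = length(sp),
                 n_obs = sum(lengths(ys))),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE eGFR fit at s = %s, window (s, s+%s] (%d subjects, %d observations, %s working correlation)\n",
              format(x$s), format(x$delta_cap), x$n_subjects, x$n_obs,
              x$corstr))
  se <- sqrt(diag(x$robust_cov))
  print(round(data.frame(coef = x$coefs, robust_se = se), 4))
  invisible(x)
}

#' Predict eGFR at the horizon
#'
#' Returns the marginal mean `a'X + g * delta`, the model's prediction of
#' eGFR at `s + delta` given the landmark features, reported as-is (no
#' floor or ceiling).
#'
#' @param fit a `gee_fit`.
#' @param newdata data frame with the fit's feature columns.
#' @param delta months beyond the landmark; `delta <= delta_cap` unless
#'   `extrapolate = TRUE`.
#' @param extrapolate allow predicting beyond the fitted window (used by the
#'   static comparator).
#' @return Numeric vector of predicted eGFR values.
#' @export
predict_egfr <- function(fit, newdata, delta, extrapolate = FALSE) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!extrapolate && any(delta > fit$delta_cap + 1e-9))
    stop("delta beyond the fitted window", call. = FALSE)
  miss <- setdiff(fit$features, names(newdata))
  if (length(miss))
    stop("newdata lacks feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[, fit$features, drop = FALSE])
  if (anyNA(X)) stop("missing values in newdata features", call. = FALSE)
  unname(drop(cbind(1, X) %*% fit$coefs[seq_len(ncol(X) + 1)]) +
           fit$coefs[["time_since_s"]] * delta)
}
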
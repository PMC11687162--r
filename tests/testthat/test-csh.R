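# helper: minimal landmark-row frame for direct fitting
csh_rows <- function(time, status, x = NULL) {
  d <- data.frame(s = 6, residual_time = time, residual_status = status)
  if (!is.null(x)) d$x <- x
  d$subject_id <- sprintf("S%03d", seq_along(time))
  d
}

test_that("the partial likelihood matches hand-enumerated risk sets", {
  # six subjects, one binary covariate, no ties; cause-1 events at times 1
  # and 3, cause-2 events at 2 and 2.5 leave the risk set like censorings
  d <- csh_rows(time = c(1, 2, 2.5, 3, 4, 5), status = c(1, 2, 2, 1, 0, 0),
                x = c(1, 0, 1, 0, 1, 0))
  f <- fit_csh(d, "x", horizon_cap = 10, min_events = 1)
  b <- f$cause1_coefs[["x"]]
  xc <- d$x - mean(d$x)
  # log PL(b) = sum over cause-1 events of [b x_i - log sum_{risk} exp(b x_j)]
  logpl <- function(b) {
    (b * xc[1] - log(sum(exp(b * xc[1:6])))) +
      (b * xc[4] - log(sum(exp(b * xc[4:6]))))
  }
  expect_equal(f$loglik[["graft_failure"]], logpl(b), tolerance = 1e-8)
  # the fitted value maximizes the hand-computed curve
  expect_gt(logpl(b), logpl(b - 0.1))
  expect_gt(logpl(b), logpl(b + 0.1))
})

test_that("the null-model baseline equals the hand-computed Nelson-Aalen", {
  set.seed(5)
  n <- 60
  time <- round(rexp(n, 0.1), 1) + 0.5
  status <- sample(0:2, n, replace = TRUE)
  f <- fit_csh(csh_rows(time, status), character(0), horizon_cap = 100,
               min_events = 1)
  # hand Nelson-Aalen for cause 1
  ut <- sort(unique(time[status == 1]))
  na <- vapply(ut, function(u) sum(time == u & status == 1) / sum(time >= u),
               numeric(1))
  expect_equal(f$cause1_baseline$time, ut)
  expect_equal(f$cause1_baseline$dhaz, na, tolerance = 1e-12)
})

test_that("treating the competing cause as censoring is exactly equivalent", {
  sim <- simulate_cohort(recovery_scenario(800, 21))
  rows <- recovery_rows(sim)
  f1 <- fit_csh(rows, recovery_truth$features, horizon_cap = 120,
                min_events = 5)
  # censoring any subset of the competing deaths must leave the cause-1
  # partial likelihood untouched (they enter risk sets identically up to
  # their event times); keep half so the cause-2 fit stays estimable
  rows2 <- rows
  i2 <- which(rows2$residual_status == 2)
  rows2$residual_status[i2[seq_len(length(i2) / 2)]] <- 0
  f2 <- fit_csh(rows2, recovery_truth$features, horizon_cap = 120,
                min_events = 5)
  expect_equal(f1$cause1_coefs, f2$cause1_coefs, tolerance = 1e-10)
  expect_equal(f1$cause1_baseline, f2$cause1_baseline, tolerance = 1e-10)
})

test_that("generative log hazard ratios are recovered without bias", {
  est1 <- est2 <- NULL
  for (sd in 1:5) {
    sim <- simulate_cohort(recovery_scenario(1500, 300 + sd))
    f <- fit_csh(recovery_rows(sim), recovery_truth$features,
                 horizon_cap = 130)
    est1 <- rbind(est1, f$cause1_coefs)
    est2 <- rbind(est2, f$cause2_coefs)
  }
  expect_true(all(abs(colMeans(est1) - recovery_truth$cause1) < 0.12))
  expect_true(all(abs(colMeans(est2) - recovery_truth$cause2) < 0.12))
})

test_that("predicted CIFs reproduce the Aalen-Johansen estimator exactly", {
  sim <- simulate_cohort(boosted_null_scenario(800, 15))
  oc <- sim$cohort$outcomes
  rows <- csh_rows(oc$event_time_months - 6, oc$status)
  f <- fit_csh(rows, character(0), horizon_cap = 60, min_events = 1)
  aj <- aj_cif(oc$event_time_months - 6, oc$status, cap = 60)
  mine <- predict_cif(f, rows[1, ], aj$time)
  expect_lt(max(abs(mine$cif_graft_failure - aj$cif1)), 1e-10)
  expect_lt(max(abs(mine$cif_death - aj$cif2)), 1e-10)
})

test_that("CIF components are proper and additive", {
  sim <- simulate_cohort(recovery_scenario(900, 44))
  rows <- recovery_rows(sim)
  f <- fit_csh(rows, recovery_truth$features, horizon_cap = 60)
  pr0 <- predict_cif(f, rows[1:5, ], 0)
  expect_equal(pr0$cif_graft_failure, rep(0, 5))
  expect_equal(pr0$event_free, rep(1, 5))
  set.seed(1)
  idx <- sample(nrow(rows), 50)
  for (d in c(6, 24, 48, 60)) {
    pr <- predict_cif(f, rows[idx, ], d)
    expect_lt(max(abs(pr$cif_graft_failure + pr$cif_death +
                        pr$event_free - 1)), 1e-8)
    expect_true(all(pr$cif_graft_failure >= 0 & pr$cif_graft_failure <= 1))
  }
  # monotone in the horizon
  pr_all <- predict_cif(f, rows[idx[1], ], c(6, 24, 48, 60))
  expect_true(all(diff(pr_all$cif_graft_failure) >= 0))
  expect_true(all(diff(pr_all$cif_death) >= 0))
  # horizons beyond the cap are refused
  expect_error(predict_cif(f, rows[1, ], 61), "horizon cap")
})

test_that("risk is monotone in the cause-1 linear predictor", {
  set.seed(2)
  d <- csh_rows(time = rexp(300, 0.05), status = sample(0:2, 300, TRUE),
                x = rnorm(300))
  f <- fit_csh(d, "x", horizon_cap = 30, min_events = 1)
  sgn <- sign(f$cause1_coefs[["x"]])
  lo <- data.frame(x = -2 * sgn); hi <- data.frame(x = 2 * sgn)
  plo <- predict_cif(f, lo, 24); phi <- predict_cif(f, hi, 24)
  expect_gt(phi$cif_graft_failure, plo$cif_graft_failure)
  expect_lt(phi$event_free + phi$cif_death, 1)
})

test_that("predictions are invariant to feature centering conventions", {
  sim <- simulate_cohort(recovery_scenario(700, 50))
  rows <- recovery_rows(sim)
  f <- fit_csh(rows, recovery_truth$features, horizon_cap = 60)
  rows_shift <- rows
  rows_shift$age_std <- rows_shift$age_std + 5  # shift train and test alike
  f2 <- fit_csh(rows_shift, recovery_truth$features, horizon_cap = 60)
  p1 <- predict_cif(f, rows[1:10, ], 36)
  p2 <- predict_cif(f2, rows_shift[1:10, ], 36)
  expect_equal(p1$cif_graft_failure, p2$cif_graft_failure, tolerance = 1e-8)
})

test_that("degenerate fits are refused with informative errors", {
  d <- csh_rows(time = c(1, 2, 3, 4), status = c(1, 2, 1, 0))
  expect_error(fit_csh(d, character(0), min_events = 10), "too few events")
  set.seed(3)
  n <- 80
  d2 <- csh_rows(time = rexp(n, 0.1), status = sample(0:2, n, TRUE),
                 x = rnorm(n))
  d2$y <- d2$x  # exact duplicate column is dropped by the collinearity guard
  expect_warning(f <- fit_csh(d2, c("x", "y"), horizon_cap = 50,
                              min_events = 1),
                 "dropped unusable")
  expect_equal(f$features, "x")
})

test_that("coefficient curves track a strengthening eGFR effect", {
  sc <- scenario_preset("time_varying_effect", n = 2500, seed = 60)
  sim <- simulate_cohort(sc)
  co <- thin_egfr_monthly(sim$cohort)
  g <- landmark_grid(c(6, 24, 48), 36)
  lmdata <- expand_dummies(suppressWarnings(build_landmark_dataset(co, g)))
  fits <- suppressWarnings(
    fit_landmark_csh(lmdata, g, c("egfr_current", "recipient_age")))
  cc <- coefficient_curves(fits)
  eg <- cc[cc$cause == "graft_failure" & cc$feature == "egfr_current", ]
  eg <- eg[order(eg$s), ]
  # the generative effect goes from -0.012 at baseline to about -0.05 at
  # s = 48; the fitted coefficient magnitude must increase with s
  expect_equal(nrow(eg), 3)
  expect_lt(eg$coef[3], eg$coef[1])
  expect_true(all(c("s", "cause", "feature", "coef", "lower", "upper")
                  %in% names(cc)))
})
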
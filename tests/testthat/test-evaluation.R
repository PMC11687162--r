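test_that("IPCW weights are 1 without censoring and 0 after early censoring", {
  time <- c(3, 8, 14, 20, 30, 40)
  status <- c(1, 2, 1, 2, 1, 2)
  expect_equal(ipcw_weights(time, status, 24), rep(1, 6))
  # censored before the horizon contributes weight zero; censored after the
  # horizon is an observed event-free subject and keeps positive weight
  status2 <- c(1, 0, 1, 2, 0, 0)
  w <- ipcw_weights(time, status2, 24)
  expect_equal(w[2], 0)
  expect_gt(w[5], 0)
})

test_that("IPCW weights match a hand-computed censoring Kaplan-Meier", {
  # six subjects, censorings at 5 and 15; the event at 2 has left the risk
  # set, so G drops to 4/5 after 5 (5 at risk) and to 4/5 * 2/3 after 15
  # (3 at risk)
  time <- c(2, 5, 10, 15, 20, 30)
  status <- c(1, 0, 2, 0, 1, 0)
  w <- ipcw_weights(time, status, 24)
  G5 <- 4 / 5; G15 <- 4 / 5 * 2 / 3
  expect_equal(w[1], 1)            # event before any censoring
  expect_equal(w[2], 0)            # censored before horizon
  expect_equal(w[3], 1 / G5)       # event at 10: G(10-) = G after 5
  expect_equal(w[4], 0)
  expect_equal(w[5], 1 / G15)      # event at 20
  expect_equal(w[6], 1 / G15)      # event-free at 24: 1 / G(24)
})

test_that("the AUC equals a brute-force weighted pair loop", {
  set.seed(11)
  n <- 300
  time <- rexp(n, 0.05)
  status <- sample(1:2, n, replace = TRUE)   # no censoring
  risk <- round(runif(n), 2)                 # rounding forces ties
  a <- td_auc(risk, time, status, delta = 15, cause = 1)
  is_case <- status == 1 & time <= 15
  is_ctrl <- time > 15 | (status == 2 & time <= 15)
  num <- 0; den <- 0
  for (i in which(is_case)) for (j in which(is_ctrl)) {
    num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    den <- den + 1
  }
  expect_equal(a$value, num / den, tolerance = 1e-12)

  # with censoring: brute force with the IPCW weight products
  status_c <- sample(0:2, n, replace = TRUE)
  w <- ipcw_weights(time, status_c, 15)
  a2 <- td_auc(risk, time, status_c, delta = 15, cause = 1)
  ic <- which(status_c == 1 & time <= 15 & w > 0)
  ik <- which((time > 15 | (status_c == 2 & time <= 15)) & w > 0)
  num <- 0; den <- 0
  for (i in ic) for (j in ik) {
    ww <- w[i] * w[j]
    num <- num + ww * ((risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j]))
    den <- den + ww
  }
  expect_equal(a2$value, num / den, tolerance = 1e-12)
})

test_that("degenerate AUC cases behave as specified", {
  time <- c(5, 8, 30, 40); status <- c(1, 1, 2, 0)
  # perfect separation
  a <- td_auc(c(0.9, 0.8, 0.1, 0.2), time, status, 24, cause = 1)
  expect_equal(a$value, 1)
  # no cases of the index cause: flagged missing
  expect_true(is.na(td_auc(runif(4), time, rep(1, 4), 24, cause = 2)$value))
  # permuted predictions hover near 1/2
  set.seed(8)
  n <- 2000
  tme <- rexp(n, 0.05); st <- sample(1:2, n, TRUE)
  av <- td_auc(sample(runif(n)), tme, st, 15, cause = 1)$value
  expect_lt(abs(av - 0.5), 0.05)
})

test_that("the Brier score reduces to the plain MSE without censoring", {
  set.seed(13)
  n <- 200
  time <- rexp(n, 0.05); status <- sample(1:2, n, TRUE)
  risk <- runif(n)
  b <- td_brier(risk, time, status, 15, cause = 1)
  D <- as.numeric(status == 1 & time <= 15)
  expect_equal(b$value, mean((D - risk)^2), tolerance = 1e-15)
  # perfect 0/1 predictions score zero
  expect_equal(td_brier(D, time, status, 15, cause = 1)$value, 0)
  # constant prediction p: closed form mean(D)(1-p)^2 + (1-mean(D))p^2
  p <- 0.3
  expect_equal(td_brier(rep(p, n), time, status, 15, cause = 1)$value,
               mean(D) * (1 - p)^2 + (1 - mean(D)) * p^2)
})

test_that("a hand-built censored Brier example matches the weighted sum", {
  time <- c(2, 5, 10, 15, 20, 30)
  status <- c(1, 0, 2, 0, 1, 0)
  risk <- c(0.8, 0.5, 0.4, 0.3, 0.6, 0.1)
  w <- ipcw_weights(time, status, 24)
  D <- as.numeric(status == 1 & time <= 24)
  expect_equal(td_brier(risk, time, status, 24, cause = 1)$value,
               sum(w * (D - risk)^2) / sum(w))
})

test_that("eGFR accuracy applies the 30%/50% bands and the matching window", {
  bl <- tiny_baseline(3)
  eg <- data.frame(subject_id = rep(bl$subject_id, each = 2),
                   time_months = rep(c(6, 47.5), 3),
                   egfr = c(55, 50, 55, 50, 55, 50))
  # third subject's only near-horizon measurement is 2.5 months away
  eg$time_months[6] <- 50.5
  oc <- data.frame(subject_id = bl$subject_id, event_time_months = 90,
                   status = 0)
  co <- ktx_cohort(bl, eg, data.frame(subject_id = character(0),
                                      time_months = numeric(0),
                                      type = character(0)), oc)
  pred <- data.frame(subject_id = bl$subject_id,
                     egfr_pred = c(64, 66, 50))
  acc <- egfr_accuracy(pred, co, s = 12, delta = 36)  # horizon at 48
  expect_equal(acc$n_effective, 2)                    # subject 3 unmatched
  # obs 50: |64-50| = 14 <= 15 inside P30; |66-50| = 16 > 15 outside
  expect_equal(acc$p30, 0.5)
  expect_equal(acc$p50, 1)
  expect_equal(acc$rmse, sqrt(mean(c(14, 16)^2)))
  # perfect prediction
  acc2 <- egfr_accuracy(data.frame(subject_id = bl$subject_id[1:2],
                                   egfr_pred = c(50, 50)), co, 12, 36)
  expect_equal(acc2$rmse, 0)
  expect_equal(acc2$p30, 1)
})

test_that("cross-validation is reproducible and yields defined curves", {
  sim <- simulate_cohort(boosted_null_scenario(500, 27))
  g <- landmark_grid(c(6, 12, 24), 24)
  feats <- c("recipient_age", "dgf", "egfr_current")
  cv1 <- suppressWarnings(cross_validate(sim$cohort, g, lm_features = feats,
                                         folds = 3, repeats = 1, seed = 5,
                                         min_events = 5))
  cv2 <- suppressWarnings(cross_validate(sim$cohort, g, lm_features = feats,
                                         folds = 3, repeats = 1, seed = 5,
                                         min_events = 5))
  expect_identical(cv1$curves, cv2$curves)
  expect_true(all(c("LM", "SPM") %in% cv1$curves$model))
  expect_true(all(c("AUC", "BS", "RMSE", "P30", "P50") %in%
                    cv1$curves$metric))
  expect_setequal(unique(cv1$curves$s), c(6, 12, 24))
  auc <- cv1$curves[cv1$curves$metric == "AUC", ]
  expect_true(all(auc$value >= 0 & auc$value <= 1))
  expect_true(all(cv1$curves$n_effective[cv1$curves$metric == "AUC"] > 0))
  p <- cv1$curves[cv1$curves$metric %in% c("P30", "P50"), ]
  p30 <- p$value[p$metric == "P30"]
  p50 <- p$value[p$metric == "P50"]
  expect_true(all(p30 <= p50 + 1e-12))
})

test_that("bootstrap comparison handles degenerate B and flags instability", {
  sim <- simulate_cohort(boosted_null_scenario(400, 29))
  ids <- cohort_subjects(sim$cohort)
  set.seed(2)
  tr <- sample(ids, 260)
  feats <- c("recipient_age", "dgf", "baseline_egfr")
  expect_error(bootstrap_compare(cohort_subset(sim$cohort, tr),
                                 cohort_subset(sim$cohort, setdiff(ids, tr)),
                                 s = 12, delta = 36, B = 1), "at least 2")
  bs <- suppressWarnings(bootstrap_compare(
    cohort_subset(sim$cohort, tr),
    cohort_subset(sim$cohort, setdiff(ids, tr)),
    s = 12, delta = 36, metric = "auc", cause = 1,
    lm_features = feats, spm_feats = feats, B = 2, seed = 4,
    min_events = 5))
  expect_length(bs$diffs, 2)
  expect_length(bs$ci, 2)
  expect_true(is.finite(bs$diff_obs))
})
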
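test_that("the at-risk set keeps everyone with follow-up beyond s", {
  co <- tiny_cohort()
  # event-free at baseline: everyone
  expect_setequal(at_risk_set(co, 6), co$baseline$subject_id)
  # a graft-failure case at 40 is still at risk at 39 but not at 40
  expect_true("S01" %in% at_risk_set(co, 39))
  expect_false("S01" %in% at_risk_set(co, 40))
  # early event excluded later regardless of status
  expect_false("S04" %in% at_risk_set(co, 31))
  # a subject failing at 54.5 remains at risk at s = 48
  co$outcomes$event_time_months[1] <- 54.5
  expect_true("S01" %in% at_risk_set(cohort_subset(co, co$baseline$subject_id),
                                     48))
})

test_that("at-risk size is non-increasing in s", {
  sim <- simulate_cohort(scenario_preset("wisard_like", n = 600, seed = 3))
  sizes <- vapply(c(6, 12, 24, 36, 48, 60),
                  function(s) length(at_risk_set(sim$cohort, s)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  lmdata <- suppressWarnings(
    build_landmark_dataset(sim$cohort, landmark_grid(c(6, 12, 24, 36, 48, 60))))
  counts <- table(lmdata$s)
  expect_true(all(diff(as.numeric(counts)) <= 0))
})

test_that("eGFR window features reproduce the closed-form OLS", {
  s <- 30
  bl <- tiny_baseline(1)
  eg <- data.frame(subject_id = "S01",
                   time_months = c(s - 4, s - 2, s), egfr = c(60, 50, 58))
  oc <- data.frame(subject_id = "S01", event_time_months = 90, status = 0)
  co <- ktx_cohort(bl, eg, data.frame(subject_id = character(0),
                                      time_months = numeric(0),
                                      type = character(0)), oc)
  ft <- extract_features(co, "S01", s)
  # hand OLS: centered times (-2, 0, 2); slope = (-2*60 + 2*58)/8 = -0.5
  expect_equal(ft$egfr_slope, -0.5)
  # residuals (3, -6, 3); volatility = sqrt(54 / (3 - 2))
  expect_equal(ft$egfr_volatility, sqrt(54))
  expect_equal(ft$egfr_current, 58)
  # an exact line has zero volatility and the line's slope
  eg2 <- data.frame(subject_id = "S01",
                    time_months = c(s - 2, s - 1, s), egfr = c(50, 52, 54))
  co2 <- ktx_cohort(bl, eg2, co$events, oc)
  ft2 <- extract_features(co2, "S01", s)
  expect_equal(ft2$egfr_slope, 2)
  expect_equal(ft2$egfr_volatility, 0)
})

test_that("recurrent-event windows are half-open (s-12, s]", {
  s <- 30
  bl <- tiny_baseline(1)
  eg <- data.frame(subject_id = "S01", time_months = c(6, 20, 30),
                   egfr = c(55, 54, 53))
  ev <- data.frame(subject_id = "S01",
                   time_months = c(s - 13, s - 11, s),
                   type = rep("hospitalization", 3))
  oc <- data.frame(subject_id = "S01", event_time_months = 90, status = 0)
  co <- ktx_cohort(bl, eg, ev, oc)
  ft <- extract_features(co, "S01", s)
  # s-13 is outside, s-11 inside, an event exactly at s counts
  expect_equal(ft$n_hosp_12m, 2)
  expect_equal(ft$n_reject_12m, 0)
})

test_that("features at s never depend on data after s", {
  sim <- simulate_cohort(scenario_preset("wisard_like", n = 120, seed = 8))
  co <- thin_egfr_monthly(sim$cohort)
  s <- 24
  ids <- intersect(at_risk_set(co, s), unique(co$egfr$subject_id))
  id <- ids[1]
  ft0 <- extract_features(co, id, s)
  co2 <- co
  late <- co2$egfr$subject_id == id & co2$egfr$time_months > s
  co2$egfr$egfr[late] <- co2$egfr$egfr[late] + 100
  expect_equal(extract_features(co2, id, s), ft0)
  # permuting event types outside the window leaves counts unchanged
  co3 <- co
  out <- co3$events$subject_id == id & co3$events$time_months <= s - 12
  co3$events$type[out] <- rev(co3$events$type[out])
  expect_equal(extract_features(co3, id, s)[c("n_hosp_12m", "n_reject_12m")],
               ft0[c("n_hosp_12m", "n_reject_12m")])
})

test_that("a subject contributes landmark rows only while at risk", {
  bl <- tiny_baseline(1)
  eg <- data.frame(subject_id = "S01", time_months = seq(6, 29.5, by = 1),
                   egfr = 55)
  oc <- data.frame(subject_id = "S01", event_time_months = 30, status = 1)
  co <- ktx_cohort(bl, eg, data.frame(subject_id = character(0),
                                      time_months = numeric(0),
                                      type = character(0)), oc)
  lmdata <- suppressWarnings(build_landmark_dataset(co, landmark_grid(6:60)))
  expect_setequal(lmdata$s, 6:29)
  # single-landmark grid: just the at-risk rows at that s
  one <- suppressWarnings(build_landmark_dataset(co, landmark_grid(12)))
  expect_equal(nrow(one), 1)
  expect_equal(one$residual_time, 18)
})

test_that("sparse eGFR windows get slope 0 and the training median volatility", {
  sim <- simulate_cohort(scenario_preset("wisard_like", n = 200, seed = 12))
  co <- thin_egfr_monthly(sim$cohort)
  lmdata <- suppressWarnings(build_landmark_dataset(co, landmark_grid(7)))
  # at s = 7 most subjects have < 3 observations: fallback must be finite
  expect_false(anyNA(lmdata$egfr_volatility))
  fb <- attr(lmdata, "volatility_fallback")
  expect_true(is.finite(fb[["7"]]))
  # frozen fallback is reused verbatim
  lmdata2 <- suppressWarnings(
    build_landmark_dataset(co, landmark_grid(7),
                           volatility_fallback = c("7" = 99)))
  expect_true(any(lmdata2$egfr_volatility == 99))
})
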
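# Fixture builders: small cohorts constructed in code, plus the simulation
# scenarios shared by the recovery and null-coverage checks.

# baseline table with valid defaults; override any column by name
tiny_baseline <- function(n, ...) {
  df <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    recipient_age = 50, female = 0, black_race = 0, prior_tx = 0,
    pretx_hd_months = 10, esrd_cause = "GN",
    ims_tac = 1, ims_csa = 0,
    induction_alemtuzumab = 0, induction_il2 = 1, induction_atg = 0,
    living_donor = 0, donor_age = 40, donor_female = 0, donor_black = 0,
    donor_bmi = 27, donor_dm = 0, donor_cod = "trauma",
    kdpi = 40, hla_mismatches = 3, peak_pra_ge1 = 0, dgf = 0,
    baseline_egfr = 55, b2m = 1.3, mg = 1.8, ca = 9.4, ph = 2.7,
    baseline_hosp = 0, baseline_rejection = 0,
    stringsAsFactors = FALSE)
  ov <- list(...)
  for (nm in names(ov)) df[[nm]] <- ov[[nm]]
  df
}

# 10-subject cohort with simple eGFR series and a few recurrent events
tiny_cohort <- function() {
  n <- 10
  bl <- tiny_baseline(n)
  eg <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- seq(6, 30, by = 1) + 0.3
    data.frame(subject_id = bl$subject_id[i], time_months = tt,
               egfr = 55 - 0.2 * (tt - 6) + i, stringsAsFactors = FALSE)
  }))
  oc <- data.frame(subject_id = bl$subject_id,
                   event_time_months = c(40, 50, 60, 31, 35, 45, 55, 65, 75, 85),
                   status = c(1, 2, 0, 1, 2, 0, 1, 2, 0, 0),
                   stringsAsFactors = FALSE)
  eg <- eg[eg$time_months <= oc$event_time_months[
    match(eg$subject_id, oc$subject_id)], ]
  ev <- data.frame(subject_id = c("S01", "S01", "S02", "S05"),
                   time_months = c(3, 20, 25, 10),
                   type = c("hospitalization", "rejection",
                            "hospitalization", "hospitalization"),
                   stringsAsFactors = FALSE)
  ktx_cohort(bl, eg, ev, oc)
}

# scenario with balanced covariates, flat trajectories and no frailty, so the
# fitted cause-specific models are correctly specified and the generative
# coefficients are recoverable from the latent covariates
recovery_scenario <- function(n, seed) {
  sc <- scenario_preset("wisard_like", n = n, seed = seed)
  sc$event_model$coefs1 <- c(age_std = -0.2, female = 0.35, esrd_dm = 0.4)
  sc$event_model$coefs2 <- c(age_std = 0.5, female = -0.2, esrd_dm = 0.3)
  sc$event_model$scale <- c(graft_failure = 330, death = 260)
  sc$event_model$egfr_coef1 <- 0
  sc$event_model$egfr_coef2 <- 0
  sc$event_model$recurrent_coef1[] <- 0
  sc$event_model$recurrent_coef2[] <- 0
  sc$recurrent_model$frailty_sd <- 0
  sc$event_model$frailty_coef <- 0
  sc
}

recovery_truth <- list(
  features = c("age_std", "female", "esrd_dm"),
  cause1 = c(-0.2, 0.35, 0.4),
  cause2 = c(0.5, -0.2, 0.3))

# landmark rows for a recovery cohort using the latent generative covariates
recovery_rows <- function(sim) {
  b <- expand_dummies(sim$cohort$baseline)
  b$age_std <- (b$recipient_age - 51.1) / 12.9
  oc <- sim$cohort$outcomes
  cbind(b, s = 6, residual_time = oc$event_time_months - 6,
        residual_status = oc$status)
}

# covariate-free competing-risks scenario with enough events at modest n for
# bootstrap and oracle experiments
boosted_null_scenario <- function(n, seed) {
  sc <- scenario_preset("null_covariates", n = n, seed = seed)
  sc$event_model$scale <- c(graft_failure = 330, death = 260)
  sc
}

# Aalen-Johansen cause-1/2 CIF via the independent multi-state Kaplan-Meier
# machinery in the survival package
aj_cif <- function(time, status, cap = Inf) {
  rt <- pmin(time, cap)
  st <- ifelse(time > cap, 0L, as.integer(status))
  sf <- survival::survfit(survival::Surv(rt, factor(st, 0:2)) ~ 1)
  data.frame(time = sf$time, cif1 = sf$pstate[, 2], cif2 = sf$pstate[, 3])
}
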
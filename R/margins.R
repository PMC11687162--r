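#' Published registry margins used to calibrate the simulator
#'
#' Baseline characteristics of the 3,893-recipient transplant registry cohort
#' the simulator emulates: overall counts for the categorical covariates,
#' means/SDs for the continuous ones, and the outcome mix at data extraction.
#' These margins are the calibration targets of [scenario_preset()]'s
#' `wisard_like` scenario and the inputs to the printed-percentage arithmetic
#' in `scripts/acceptance.R`.
#'
#' @return A list with components `n_total`, `outcome_counts` (censored /
#'   graft_failure / death), `proportions` (event counts over `n_total` for
#'   binary covariates), `continuous` (mean, sd) and `quantiles`
#'   (median, q25, q75).
#' @export
registry_margins <- function() {
  list(
    n_total = 3893,
    outcome_counts = c(censored = 2587, graft_failure = 532, death = 774),
    counts = c(
      female = 1535, black_race = 377, prior_tx = 848,
      esrd_dm = 978, esrd_htn = 432, esrd_pkd = 529, esrd_gn = 966,
      ims_tac = 2671, ims_csa = 927,
      induction_alemtuzumab = 736, induction_il2 = 2175, induction_atg = 815,
      living_donor = 1528, donor_female = 1807, donor_black = 290,
      donor_dm = 180,
      cod_anoxia = 654, cod_cvd = 810, cod_trauma = 800, cod_tumor = 20,
      peak_pra_ge1 = 1595, dgf = 678,
      baseline_hosp = 1521, baseline_rejection = 657
    ),
    continuous = list(
      recipient_age = c(mean = 51.1, sd = 12.9),
      donor_age     = c(mean = 43.2, sd = 14.6),
      donor_bmi     = c(mean = 27.7, sd = 6.53),
      kdpi          = c(mean = 45.5, sd = 26.6),
      baseline_egfr = c(mean = 55.6, sd = 18.6),
      b2m           = c(mean = 1.29, sd = 0.49),
      mg            = c(mean = 1.79, sd = 0.29),
      ca            = c(mean = 9.43, sd = 0.68),
      ph            = c(mean = 2.75, sd = 0.88)
    ),
    quantiles = list(
      pretx_hd_months = c(q25 = 1, median = 14, q75 = 34),
      hla_mismatches  = c(q25 = 3, median = 4, q75 = 5)
    )
  )
}
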
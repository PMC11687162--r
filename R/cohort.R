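#' @importFrom stats median sd lm coef qnorm pnorm rnorm runif rbinom rexp
#'   rpois rlnorm quantile complete.cases aggregate setNames approx predict
#' @importFrom utils read.csv write.csv head tail
NULL

## Column schemas for the four cohort tables. All times are months since
## transplantation; baseline is fixed at month 6.
.baseline_numeric <- c(
  "recipient_age", "pretx_hd_months", "donor_age", "donor_bmi", "kdpi",
  "hla_mismatches", "baseline_egfr", "b2m", "mg", "ca", "ph"
)
.baseline_binary <- c(
  "female", "black_race", "prior_tx", "ims_tac", "ims_csa",
  "induction_alemtuzumab", "induction_il2", "induction_atg", "living_donor",
  "donor_female", "donor_black", "donor_dm", "peak_pra_ge1", "dgf",
  "baseline_hosp", "baseline_rejection"
)
.baseline_factor <- list(
  esrd_cause = c("DM", "HTN", "PKD", "GN", "other"),
  donor_cod  = c("anoxia", "CVD", "trauma", "tumor", "other", "living")
)
.baseline_cols <- c("subject_id", .baseline_numeric, .baseline_binary,
                    names(.baseline_factor))

.egfr_cols    <- c("subject_id", "time_months", "egfr")
.events_cols  <- c("subject_id", "time_months", "type")
.event_types  <- c("hospitalization", "rejection")
.outcome_cols <- c("subject_id", "event_time_months", "status")

#' Baseline month on the post-transplant clock
#'
#' Recipients enter the cohort with a functioning graft 6 months after
#' transplantation; all landmark arithmetic is anchored here.
#' @export
BASELINE_MONTH <- 6

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Assemble a validated cohort object
#'
#' Bundles the four cohort tables (baseline covariates, longitudinal eGFR,
#' recurrent hospitalization/rejection events, and competing-risk outcomes)
#' into a single validated container sharing one time convention (months since
#' transplantation, baseline at month 6).
#'
#' Validation enforces: one outcome row per subject with `status` in
#' \{0 = censored, 1 = graft failure, 2 = death with functioning graft\} and
#' `event_time_months > 6`; identical subject sets across tables (rows of the
#' auxiliary tables with unknown subjects are rejected); eGFR values positive
#' at times `>= 6`; eGFR observations strictly after a subject's event time
#' are dropped with a warning carrying the count.
#'
#' @param baseline,egfr,events,outcomes data frames matching the documented
#'   CSV schemas (see [read_cohort()]).
#' @return An object of class `ktx_cohort`: a list with elements `baseline`,
#'   `egfr`, `events`, `outcomes`.
#' @export
ktx_cohort <- function(baseline, egfr, events, outcomes) {
  .require_cols(baseline, .baseline_cols, "baseline")
  .require_cols(egfr, .egfr_cols, "egfr")
  .require_cols(events, .events_cols, "events")
  .require_cols(outcomes, .outcome_cols, "outcomes")

  baseline$subject_id <- as.character(baseline$subject_id)
  egfr$subject_id     <- as.character(egfr$subject_id)
  events$subject_id   <- as.character(events$subject_id)
  outcomes$subject_id <- as.character(outcomes$subject_id)

  if (anyDuplicated(baseline$subject_id))
    stop("baseline: duplicated subject_id", call. = FALSE)
  if (anyDuplicated(outcomes$subject_id))
    stop("outcomes: more than one outcome row for some subject", call. = FALSE)

  ids <- baseline$subject_id
  if (!setequal(ids, outcomes$subject_id))
    stop("baseline and outcomes must cover the same subjects", call. = FALSE)

  bad <- !(egfr$subject_id %in% ids)
  if (any(bad))
    stop(sprintf("egfr: %d row(s) with unknown subject_id", sum(bad)),
         call. = FALSE)
  bad <- !(events$subject_id %in% ids)
  if (any(bad))
    stop(sprintf("events: %d row(s) with unknown subject_id", sum(bad)),
         call. = FALSE)

  if (!all(outcomes$status %in% 0:2))
    stop("outcomes: status must be 0 (censored), 1 (graft failure) or 2 (death)",
         call. = FALSE)
  if (any(outcomes$event_time_months <= BASELINE_MONTH))
    stop("outcomes: event_time_months must exceed the baseline month (6)",
         call. = FALSE)
  if (!all(events$type %in% .event_types))
    stop(sprintf("events: type must be one of {%s}",
                 paste(.event_types, collapse = ", ")), call. = FALSE)
  if (any(events$time_months < 0))
    stop("events: negative time_months", call. = FALSE)
  if (any(egfr$egfr <= 0, na.rm = TRUE))
    stop("egfr: values must be positive", call. = FALSE)
  if (any(egfr$time_months < BASELINE_MONTH))
    stop("egfr: observations before the baseline month (6)", call. = FALSE)
  for (v in .baseline_binary) {
    x <- baseline[[v]]
    if (!all(x[!is.na(x)] %in% 0:1))
      stop(sprintf("baseline: %s must be 0/1", v), call. = FALSE)
  }
  for (v in names(.baseline_factor)) {
    x <- baseline[[v]]
    if (!all(x[!is.na(x)] %in% .baseline_factor[[v]]))
      stop(sprintf("baseline: %s has levels outside {%s}", v,
                   paste(.baseline_factor[[v]], collapse = ", ")),
           call. = FALSE)
  }
  hla <- baseline$hla_mismatches
  if (any(hla[!is.na(hla)] < 0 | hla[!is.na(hla)] > 6))
    stop("baseline: hla_mismatches outside [0, 6]", call. = FALSE)
  if (any(baseline$pretx_hd_months < 0, na.rm = TRUE))
    stop("baseline: negative pretx_hd_months", call. = FALSE)
  liv <- baseline$living_donor == 1 & !is.na(baseline$living_donor)
  if (any(baseline$kdpi[liv] != 0, na.rm = TRUE))
    stop("baseline: kdpi must be 0 for living donors", call. = FALSE)

  ## eGFR observations after the subject's event time carry no information for
  ## prediction at risk and are removed.
  et <- setNames(outcomes$event_time_months, outcomes$subject_id)
  late <- egfr$time_months > et[egfr$subject_id]
  if (any(late)) {
    warning(sprintf("dropped %d eGFR observation(s) recorded after event time",
                    sum(late)), call. = FALSE)
    egfr <- egfr[!late, , drop = FALSE]
  }

  egfr   <- egfr[order(egfr$subject_id, egfr$time_months), , drop = FALSE]
  events <- events[order(events$subject_id, events$time_months), , drop = FALSE]
  rownames(baseline) <- rownames(egfr) <- rownames(events) <-
    rownames(outcomes) <- NULL

  structure(list(baseline = baseline, egfr = egfr, events = events,
                 outcomes = outcomes),
            class = "ktx_cohort")
}

#' @export
print.ktx_cohort <- function(x, ...) {
  n <- nrow(x$baseline)
  st <- table(factor(x$outcomes$status, levels = 0:2))
  cat("Kidney-transplant cohort:", n, "recipients\n")
  cat(sprintf("  outcomes: %d censored, %d graft failure, %d death with functioning graft\n",
              st[["0"]], st[["1"]], st[["2"]]))
  cat(sprintf("  eGFR observations: %d (%.1f per recipient)\n",
              nrow(x$egfr), nrow(x$egfr) / n))
  cat(sprintf("  recurrent events: %d hospitalization, %d rejection\n",
              sum(x$events$type == "hospitalization"),
              sum(x$events$type == "rejection")))
  invisible(x)
}

#' Subjects in a cohort
#' @param cohort a `ktx_cohort`.
#' @return Character vector of subject ids.
#' @export
cohort_subjects <- function(cohort) cohort$baseline$subject_id

#' Restrict a cohort to a subject subset
#' @param cohort a `ktx_cohort`.
#' @param ids subject ids to keep.
#' @return A `ktx_cohort` restricted to `ids`.
#' @export
cohort_subset <- function(cohort, ids) {
  ktx_cohort(
    baseline = cohort$baseline[cohort$baseline$subject_id %in% ids, , drop = FALSE],
    egfr     = cohort$egfr[cohort$egfr$subject_id %in% ids, , drop = FALSE],
    events   = cohort$events[cohort$events$subject_id %in% ids, , drop = FALSE],
    outcomes = cohort$outcomes[cohort$outcomes$subject_id %in% ids, , drop = FALSE]
  )
}

#' Read a cohort from four CSV files
#'
#' The files use UTF-8 with a header row; missing values are empty cells.
#' Schemas: `baseline.csv` (subject_id plus the documented covariates),
#' `egfr.csv` (`subject_id,time_months,egfr`), `events.csv`
#' (`subject_id,time_months,type`), `outcomes.csv`
#' (`subject_id,event_time_months,status`).
#'
#' @param baseline_path,egfr_path,events_path,outcomes_path file paths.
#' @return A validated [ktx_cohort()].
#' @export
read_cohort <- function(baseline_path, egfr_path, events_path, outcomes_path) {
  rd <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    read.csv(p, stringsAsFactors = FALSE, na.strings = "")
  }
  ktx_cohort(rd(baseline_path), rd(egfr_path), rd(events_path),
             rd(outcomes_path))
}

#' Write a cohort to four CSV files
#' @param cohort a `ktx_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("baseline.csv", "egfr.csv", "events.csv",
                            "outcomes.csv"))
  write.csv(cohort$baseline, paths[1], row.names = FALSE, na = "")
  write.csv(cohort$egfr, paths[2], row.names = FALSE, na = "")
  write.csv(cohort$events, paths[3], row.names = FALSE, na = "")
  write.csv(cohort$outcomes, paths[4], row.names = FALSE, na = "")
  invisible(paths)
}

#' Monthly thinning of eGFR series
#'
#' Retains at most one eGFR observation per recipient per month since
#' baseline: within each month bin `[6+k, 6+k+1)` the observation closest to
#' the bin mid-point `6+k+0.5` is kept, ties broken toward the earlier
#' observation. Avoids over-weighting recipients measured very frequently.
#'
#' @param egfr an eGFR data frame (`subject_id,time_months,egfr`) or a
#'   `ktx_cohort` (thinned in place).
#' @return Object of the same type with thinned eGFR.
#' @export
thin_egfr_monthly <- function(egfr) {
  if (inherits(egfr, "ktx_cohort")) {
    if (isTRUE(attr(egfr, "thinned"))) return(egfr)
    egfr$egfr <- thin_egfr_monthly(egfr$egfr)
    attr(egfr, "thinned") <- TRUE
    return(egfr)
  }
  if (!nrow(egfr)) return(egfr)
  id   <- match(egfr$subject_id, unique(egfr$subject_id))
  bin  <- floor(egfr$time_months - BASELINE_MONTH)
  key  <- id * (max(bin) + 2) + bin
  dist <- abs(egfr$time_months - (BASELINE_MONTH + bin + 0.5))
  ## order by distance then time: first row per (subject, bin) is the keeper,
  ## with ties resolved toward the earlier observation
  o <- order(key, dist, egfr$time_months)
  x <- egfr[o, , drop = FALSE]
  kid <- id[o]
  keep <- !duplicated(key[o])
  x <- x[keep, , drop = FALSE]
  x <- x[order(kid[keep], x$time_months), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Default baseline imputation rules
#'
#' Single-value imputation statistic per field with sporadic missingness:
#' mean for roughly symmetric continuous labs, median for skewed counts,
#' mode for binaries/categoricals.
#' @return Named character vector mapping field to statistic.
#' @export
default_imputation_rules <- function() {
  c(donor_bmi = "mean", b2m = "mean", ca = "mean", mg = "mean", ph = "mean",
    pretx_hd_months = "median", hla_mismatches = "median",
    donor_dm = "mode", peak_pra_ge1 = "mode", esrd_cause = "mode")
}

.impute_stat <- function(x, rule) {
  obs <- x[!is.na(x)]
  if (!length(obs)) stop("no observed values to fit imputation", call. = FALSE)
  switch(rule,
         mean   = mean(obs),
         median = median(obs),
         mode   = {
           tt <- table(obs)
           names(tt)[which.max(tt)]
         },
         stop("unknown imputation rule: ", rule, call. = FALSE))
}

#' Impute baseline covariates
#'
#' Replaces missing values in the listed baseline fields by a single statistic
#' (mean, median or mode) computed on the `fit_on` subjects only — typically
#' the training fold — so that held-out folds reuse frozen values and
#' cross-validation stays honest.
#'
#' @param cohort a `ktx_cohort`.
#' @param rules named character vector field -> statistic
#'   (default [default_imputation_rules()]).
#' @param fit_on subject ids on which the statistics are computed (default all).
#' @param values optional previously fitted values (as returned in `$values`);
#'   when given, `rules`/`fit_on` are ignored and the frozen values are applied.
#' @return List with `cohort` (imputed) and `values` (named list of fitted
#'   imputation values).
#' @export
impute_baseline <- function(cohort, rules = default_imputation_rules(),
                            fit_on = cohort_subjects(cohort), values = NULL) {
  b <- cohort$baseline
  if (is.null(values)) {
    if (!length(fit_on)) stop("fit_on must be nonempty", call. = FALSE)
    tr <- b[b$subject_id %in% fit_on, , drop = FALSE]
    values <- lapply(names(rules), function(v) {
      if (!v %in% names(b)) stop("unknown field in rules: ", v, call. = FALSE)
      s <- .impute_stat(tr[[v]], rules[[v]])
      if (is.numeric(b[[v]])) as.numeric(s) else s
    })
    names(values) <- names(rules)
  }
  for (v in names(values)) {
    miss <- is.na(b[[v]])
    if (any(miss)) b[[v]][miss] <- values[[v]]
  }
  cohort$baseline <- b
  list(cohort = cohort, values = values)
}
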
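## End-to-end pipeline: a single configuration drives simulation (or CSV
## input), landmark construction, optional backward selection, model
## fitting, cross-validated evaluation, and optional bootstrap comparison.
## One top-level seed determines every stochastic step (derived sub-seeds
## are seed + fixed small offsets).

#' Default pipeline configuration
#'
#' @param seed top-level seed; every stochastic stage derives its seed from
#'   it.
#' @param out_dir output directory for CSV artifacts.
#' @return A configuration list; fields may be edited before
#'   [run_pipeline()].
#' @export
default_config <- function(seed = 1, out_dir = "graftland-out") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(preset = "wisard_like", n = 3893),
    input = NULL,  # list(baseline=, egfr=, events=, outcomes=) CSV paths
    grid = list(landmarks = c(6, 12, 24, 36, 48, 60),
                horizons = c(12, 36, 60)),
    selection = NULL,  # list(rule = "conservative", alpha = 0.05)
    cv = list(folds = 3, repeats = 5),
    bootstrap = NULL,  # list(B = 500, s = 24, delta = 36, metric = "auc")
    min_events = 10
  )
}

#' Run the full pipeline from a configuration
#'
#' Loads or simulates the cohort, builds the landmark dataset, optionally
#' runs backward selection, cross-validates the landmark and static models,
#' and optionally bootstraps their difference at one (s, delta). Artifacts
#' (cohort CSVs when simulated, `landmarks.csv`, `selected.csv`,
#' `accuracy_curves.csv`, `bootstrap.csv`) are written under
#' `config$out_dir`. Identical configurations produce identical artifacts.
#'
#' @param config a configuration list (see [default_config()]).
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- landmark_grid(cfg$grid$landmarks, cfg$grid$horizons)

  if (!is.null(cfg$input)) {
    for (p in unlist(cfg$input))
      if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    cohort <- read_cohort(cfg$input$baseline, cfg$input$egfr,
                          cfg$input$events, cfg$input$outcomes)
    truth <- NULL
  } else {
    sc <- scenario_preset(cfg$simulate$preset, n = cfg$simulate$n,
                          seed = cfg$seed)
    sim <- simulate_cohort(sc)
    cohort <- sim$cohort
    truth <- sim$truth
    write_cohort(cohort, cfg$out_dir)
    write.csv(truth, file.path(cfg$out_dir, "truth.csv"), row.names = FALSE)
  }
  cohort <- impute_baseline(cohort)$cohort
  cohort <- thin_egfr_monthly(cohort)

  lmdata <- suppressWarnings(build_landmark_dataset(cohort, grid))
  write.csv(lmdata, file.path(cfg$out_dir, "landmarks.csv"),
            row.names = FALSE)

  features <- candidate_features()
  sel <- NULL
  if (!is.null(cfg$selection)) {
    sel <- backward_select(cohort, grid, candidates = features,
                           rule = cfg$selection$rule,
                           alpha = cfg$selection$alpha,
                           forced = "egfr_current")
    features <- sel$selected
    write.csv(data.frame(feature = sel$selected),
              file.path(cfg$out_dir, "selected.csv"), row.names = FALSE)
  }

  cv <- NULL
  if (!is.null(cfg$cv)) {
    cv <- cross_validate(cohort, grid, lm_features = features,
                         folds = cfg$cv$folds, repeats = cfg$cv$repeats,
                         seed = cfg$seed + 101L,
                         min_events = cfg$min_events)
    write.csv(cv$curves, file.path(cfg$out_dir, "accuracy_curves.csv"),
              row.names = FALSE)
  }

  bs <- NULL
  if (!is.null(cfg$bootstrap)) {
    set.seed(cfg$seed + 202L)
    ids <- cohort_subjects(cohort)
    tr_ids <- sample(ids, floor(2 * length(ids) / 3))
    bs <- bootstrap_compare(cohort_subset(cohort, tr_ids),
                            cohort_subset(cohort, setdiff(ids, tr_ids)),
                            s = cfg$bootstrap$s, delta = cfg$bootstrap$delta,
                            metric = cfg$bootstrap$metric %||% "auc",
                            lm_features = features,
                            B = cfg$bootstrap$B, seed = cfg$seed + 203L,
                            min_events = cfg$min_events)
    write.csv(data.frame(diff_obs = bs$diff_obs, ci_lo = bs$ci[1],
                         ci_hi = bs$ci[2], significant = bs$significant),
              file.path(cfg$out_dir, "bootstrap.csv"), row.names = FALSE)
  }

  invisible(list(cohort = cohort, truth = truth, landmarks = lmdata,
                 selection = sel, cv = cv, bootstrap = bs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
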
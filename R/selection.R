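## Backward selection of a common predictor set across the three sub-models
## (two cause-specific Cox models and the GEE eGFR model) and a set of
## landmark times.

.wald_p <- function(beta, vc) {
  se <- sqrt(diag(vc))
  p <- 2 * pnorm(-abs(beta / se))
  setNames(p, names(beta))
}

## p-value matrix: rows = features, cols = (landmark x sub-model)
.selection_pvalues <- function(lmdata, cohort, landmarks, features,
                               delta_cap, min_events) {
  P <- NULL
  for (s in landmarks) {
    rows <- lmdata[lmdata$s == s, , drop = FALSE]
    if (!nrow(rows)) next
    cf <- tryCatch(fit_csh(rows, features, horizon_cap = delta_cap,
                           min_events = min_events),
                   error = function(e) NULL)
    gf <- tryCatch(fit_gee(rows, cohort, features, delta_cap = delta_cap),
                   error = function(e) NULL)
    if (is.null(cf) || is.null(gf)) next
    p1 <- .wald_p(cf$cause1_coefs, cf$cause1_vcov)[features]
    p2 <- .wald_p(cf$cause2_coefs, cf$cause2_vcov)[features]
    pg <- .wald_p(gf$coefs, gf$robust_cov)[features]
    block <- cbind(p1, p2, pg)
    colnames(block) <- paste0("s", s, c("_gf", "_death", "_egfr"))
    P <- if (is.null(P)) block else cbind(P, block)
  }
  if (is.null(P)) stop("no landmark usable for selection", call. = FALSE)
  rownames(P) <- features
  P
}

#' Backward selection of a common predictor set
#'
#' Iteratively removes the single candidate with the weakest evidence across
#' the three sub-models (graft-failure hazard, death hazard, eGFR mean) over
#' the selection landmarks, until no candidate qualifies for removal.
#'
#' Under the `conservative` rule a candidate qualifies for removal only when
#' its Wald p-value exceeds `alpha` in all three sub-models at every
#' landmark (i.e. it is kept if significant anywhere). Under the
#' `parsimonious` rule it qualifies when its p-values exceed `alpha` in all
#' three sub-models at at least half the landmarks. Among qualifying
#' candidates, the one whose smallest p-value (over all sub-models and
#' landmarks) is largest is removed; constant or collinear candidates are
#' removed first. Features in `forced` are never removed.
#'
#' @param cohort a `ktx_cohort` (thinned internally).
#' @param grid a [landmark_grid()]; the selection landmarks default to the
#'   grid's landmarks (use a coarse subsample such as `c(6,12,24,36,48,60)`
#'   to bound cost).
#' @param candidates candidate feature columns (>= 2).
#' @param rule `"conservative"` (default) or `"parsimonious"`.
#' @param alpha Wald level in (0, 1), default 0.05.
#' @param forced features never removed (e.g. `"egfr_current"`).
#' @param min_events per-cause event floor for the Cox fits.
#' @return List with `selected`, `removed`, and `trace` (one entry per
#'   removal with the supporting p-value summary).
#' @export
backward_select <- function(cohort, grid, candidates = candidate_features(),
                            rule = c("conservative", "parsimonious"),
                            alpha = 0.05, forced = character(0),
                            min_events = 10) {
  rule <- match.arg(rule)
  if (length(candidates) < 2)
    stop("need at least 2 candidates", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  cohort <- thin_egfr_monthly(cohort)
  lmdata <- suppressWarnings(build_landmark_dataset(cohort, grid))
  lmdata <- expand_dummies(lmdata)
  candidates <- intersect(candidates, names(lmdata))
  current <- candidates
  trace <- list()
  delta_cap <- max(grid$horizons)

  repeat {
    ## drop constant/collinear candidates outright
    X <- as.matrix(lmdata[, current, drop = FALSE])
    const <- apply(X, 2, function(x) diff(range(x)) == 0)
    if (any(const & !(current %in% forced))) {
      drop1 <- current[const & !(current %in% forced)][1]
      trace[[length(trace) + 1]] <- list(feature = drop1,
                                         reason = "constant column")
      current <- setdiff(current, drop1)
      next
    }
    if (length(current) < 2) break
    P <- .selection_pvalues(lmdata, cohort, grid$landmarks, current,
                            delta_cap, min_events)
    nlm <- ncol(P) / 3
    qual <- vapply(current, function(f) {
      pv <- matrix(P[f, ], nrow = 3)  # sub-models x landmarks
      if (anyNA(pv)) return(FALSE)
      if (rule == "conservative") all(pv > alpha)
      else sum(apply(pv, 2, function(x) all(x > alpha))) >= nlm / 2
    }, logical(1))
    qual[current %in% forced] <- FALSE
    if (!any(qual)) break
    minp <- apply(P[current, , drop = FALSE], 1, min, na.rm = TRUE)
    weakest <- current[qual][which.max(minp[qual])]
    trace[[length(trace) + 1]] <- list(
      feature = weakest, reason = "qualifies under rule",
      min_p = unname(minp[weakest]),
      pvalues = P[weakest, ])
    current <- setdiff(current, weakest)
  }
  list(selected = current, removed = setdiff(candidates, current),
       trace = trace, rule = rule, alpha = alpha)
}
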
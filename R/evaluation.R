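# Split-half accuracy/consistency harness and grouping sensitivity.
#
# A confidence-limit method is accurate if, on data it was not fitted to,
# close to 5% of ears fall below its curve; it is consistent if that
# percentage varies little across random half-samples. Both are summarised
# through DEV = 5 - (percent below): mean DEV over draws measures accuracy,
# SD of DEV measures consistency, and negative DEV means the curve sits too
# high (too many ears flagged).

#' Percentage of ears falling below a curve
#'
#' Strictly below: an ear whose score equals the curve value at its PTA is
#' not counted (scores are discrete, so ties happen).
#'
#' @param records Cohort data.frame (`pta`, `pbmax`).
#' @param curve A [cl_curve()], a `"cl_fit"`, or a function mapping PTA to a
#'   curve value (e.g. an oracle quantile).
#' @return Percentage in \[0, 100\].
#' @export
percent_below <- function(records, curve) {
  stopifnot(nrow(records) > 0)
  lim <- if (is.function(curve)) curve(records$pta)
  else if (inherits(curve, "cl_fit")) eval_curve(curve$curve, records$pta)
  else eval_curve(curve, records$pta)
  100 * mean(records$pbmax < lim)
}

#' Deviation of observed coverage from the 5% target
#'
#' `DEV = 5 - percent_below`; negative values mean more than 5% of ears fell
#' below the estimated limit (the curve is too high).
#'
#' @param percent_below Percentage in \[0, 100\].
#' @return DEV in percentage points.
#' @examples
#' dev_from_percent(8.2)  # -3.2
#' @export
dev_from_percent <- function(percent_below) {
  stopifnot(all(percent_below >= 0 & percent_below <= 100))
  5 - percent_below
}

#' Random participant-level 50/50 split
#'
#' Splits a cohort into a fitting set and a test set by participant, so both
#' ears of a participant always land on the same side (splitting by ear
#' would leak paired information across the split).
#'
#' @param records Cohort data.frame with a `participant_id` column.
#' @param fraction Fraction of participants in the fitting set; the fitting
#'   set has `round(fraction * n_participants)` participants. Degenerate
#'   splits (an empty side) are rejected.
#' @param seed Integer seed.
#' @return List with elements `fitting` and `test` (data.frames).
#' @export
split_draw <- function(records, fraction = 0.5, seed = 1L) {
  if (!"participant_id" %in% names(records))
    records$participant_id <- seq_len(nrow(records))
  ids <- unique(records$participant_id)
  n <- length(ids)
  if (n < 2) stop("need at least 2 participants to split")
  k <- round(fraction * n)
  if (k < 1 || k >= n)
    stop("degenerate split: fitting set would have ", k, " of ", n,
         " participants")
  set.seed(seed)
  fit_ids <- sample(ids, k)
  infit <- records$participant_id %in% fit_ids
  list(fitting = records[infit, , drop = FALSE],
       test = records[!infit, , drop = FALSE])
}

# Fit one method's 95% CL curve on a fitting set. `method` may also be a
# function(records, tau) returning something percent_below() accepts, which
# lets tests plug in the generator's exact quantile as an oracle "method".
.fit_method_curve <- function(records, method, scheme, tau = 0.05,
                              n_sims = 50000, seed = 1L) {
  if (is.function(method)) return(method(records, tau))
  switch(method,
    nqr = fit_nqr(records, tau),
    hd = method2_curve(records, scheme, seed = seed)$cl_curve,
    simulation = method1_curve(records, scheme, n_sims = n_sims,
                               seed = seed)$cl_curve,
    stop("unknown method: ", method))
}

#' Split-half accuracy and consistency of a confidence-limit method
#'
#' Repeats `n_draws` times: split the cohort 50/50 by participant, fit the
#' method's 95% confidence-limit curve on the fitting half, measure the
#' percentage of test-half ears falling below it (overall and within each
#' test-half PTA sub-group), and convert to DEV = 5 - percent-below. The
#' mean of DEV across draws measures accuracy, its SD consistency.
#'
#' @param records Cohort data.frame (typically one ear's records; see
#'   [split_draw()] for the participant-level split).
#' @param method `"nqr"`, `"hd"`, `"simulation"`, or a function
#'   `(records, tau) ->` curve for oracle checks.
#' @param scheme [pta_scheme()] for the sub-group methods and for stratified
#'   reporting (the `"nqr"` fit itself ignores it).
#' @param n_draws Number of random splits (default 25).
#' @param master_seed Integer; per-draw seeds are derived from it, so the
#'   whole evaluation is reproducible.
#' @param tau Quantile level of the fitted limit (default 0.05).
#' @param n_sims Monte-Carlo draws per sub-group for `"simulation"`.
#' @param max_failures Abort if more than this many draws fail to fit.
#' @return Object of class `"cl_eval"`: `per_draw` (data.frame of DEV values,
#'   one row per draw, columns `overall` plus one per sub-group; `NA` where a
#'   draw emptied a bin), `mean_dev`, `sd_dev`, and bookkeeping fields.
#' @export
evaluate_method <- function(records, method = "nqr",
                            scheme = pta_scheme("group1"), n_draws = 25,
                            master_seed = 1L, tau = 0.05, n_sims = 50000,
                            max_failures = 5L) {
  if (!"participant_id" %in% names(records))
    records$participant_id <- seq_len(nrow(records))
  set.seed(master_seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  strata <- c("overall", as.character(scheme$labels))
  per_draw <- matrix(NA_real_, n_draws, length(strata),
                     dimnames = list(NULL, strata))
  failed <- 0L
  for (d in seq_len(n_draws)) {
    halves <- split_draw(records, 0.5, seed = draw_seeds[d])
    curve <- try(suppressMessages(suppressWarnings(
      .fit_method_curve(halves$fitting, method, scheme, tau = tau,
                        n_sims = n_sims, seed = draw_seeds[d]))),
      silent = TRUE)
    if (inherits(curve, "try-error")) {
      failed <- failed + 1L
      if (failed > max_failures)
        stop("more than ", max_failures, " draws failed to fit")
      next
    }
    test <- halves$test
    per_draw[d, "overall"] <- dev_from_percent(percent_below(test, curve))
    g <- assign_subgroup(test$pta, scheme)
    for (lab in levels(g)) {
      sub <- test[g == lab, , drop = FALSE]
      if (nrow(sub) > 0)
        per_draw[d, lab] <- dev_from_percent(percent_below(sub, curve))
    }
  }
  per_draw <- as.data.frame(per_draw)
  structure(list(
    method = if (is.function(method)) "custom" else method,
    tau = tau, n_draws = n_draws, failed = failed,
    scheme = scheme, per_draw = per_draw,
    mean_dev = vapply(per_draw, function(v) mean(v, na.rm = TRUE), 0),
    sd_dev = vapply(per_draw, function(v) stats::sd(v[!is.na(v)]), 0)
  ), class = "cl_eval")
}

#' @export
print.cl_eval <- function(x, digits = 3, ...) {
  cat("Split-half evaluation of the '", x$method, "' method (tau = ",
      x$tau, ", ", x$n_draws, " draws", sep = "")
  if (x$failed > 0) cat(", ", x$failed, " failed", sep = "")
  cat(")\n")
  cat("  accuracy   (mean DEV, overall): ",
      signif(x$mean_dev[["overall"]], digits), "\n", sep = "")
  cat("  consistency (SD of DEV, overall): ",
      signif(x$sd_dev[["overall"]], digits), "\n", sep = "")
  invisible(x)
}

#' Sensitivity of the fitted confidence limit to the sub-grouping scheme
#'
#' The sub-group methods depend on an arbitrary choice of PTA bins. This
#' fits the method's 95% CL curve on the full cohort once per scheme and
#' reports, for each scheme against the first, the RMS and extreme signed
#' differences of the curves over a PTA grid.
#'
#' @param records Cohort data.frame.
#' @param schemes List of [pta_scheme()] objects (>= 2; first is reference).
#' @param method `"simulation"` or `"hd"`.
#' @param pta_grid PTA values at which curves are compared (default 0-90 dB
#'   in 1-dB steps).
#' @param n_sims,seed Passed to the simulation method.
#' @return Data.frame with one row per non-reference scheme: `scheme`, `rms`,
#'   `min_diff`, `max_diff` (percentage points). The fitted curves and the
#'   grid are attached as attributes `"curves"` and `"pta_grid"`.
#' @export
grouping_sensitivity <- function(records, schemes,
                                 method = c("simulation", "hd"),
                                 pta_grid = 0:90, n_sims = 50000,
                                 seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(schemes) >= 2)
  curves <- lapply(schemes, function(sc) suppressMessages(
    .fit_method_curve(records, method, sc, n_sims = n_sims, seed = seed)))
  vals <- vapply(curves, eval_curve, numeric(length(pta_grid)),
                 pta = pta_grid)
  ref <- vals[, 1]
  out <- data.frame(
    scheme = vapply(schemes[-1], function(s) s$name, ""),
    rms = apply(vals[, -1, drop = FALSE], 2,
                function(v) sqrt(mean((v - ref)^2))),
    min_diff = apply(vals[, -1, drop = FALSE], 2, function(v) min(v - ref)),
    max_diff = apply(vals[, -1, drop = FALSE], 2, function(v) max(v - ref))
  )
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  attr(out, "pta_grid") <- pta_grid
  out
}
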
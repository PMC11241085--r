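#' Fit a lower confidence-limit curve for PBmax against PTA
#'
#' The central fitting function of the package. Estimates the conditional
#' tau-quantile of the maximum speech identification score (PBmax, percent)
#' as a function of the pure-tone average (PTA, dB HL), expressed as the
#' three-parameter link curve of [cl_curve()], by one of three methods:
#'
#' * `"nqr"`: nonlinear quantile regression on the raw per-ear records by
#'   check-loss minimisation ([fit_nqr()]); needs no sub-grouping.
#' * `"hd"`: Harrell-Davis quantile estimate within each PTA sub-group
#'   ([hd_quantile()]), then a least-squares fit of the link curve to the
#'   per-bin estimates.
#' * `"simulation"`: censored-normal Monte-Carlo estimate within each
#'   sub-group ([simulate_cl_s()]), then the same least-squares curve fit.
#'
#' With `tau = 0.05` (the default) the fitted curve is the one-tailed lower
#' 95% confidence limit: a patient whose score falls below the curve at their
#' PTA is in the worst 5% and may be flagged as disproportionately poor. The
#' sub-group methods support only `tau` 0.05 (confidence limit) and 0.5
#' (median for `"hd"`, simulated mean curve for `"simulation"`).
#'
#' @param formula Model formula, `pbmax ~ pta`, naming the score and
#'   predictor columns of `data`.
#' @param data Data.frame of per-ear records (e.g. from [read_cohort()] or
#'   [gen_cohort()]).
#' @param method `"nqr"`, `"hd"`, or `"simulation"`.
#' @param tau Quantile level in (0, 1).
#' @param scheme [pta_scheme()] used by the sub-group methods (ignored by
#'   `"nqr"`).
#' @param n_sims Monte-Carlo draws per sub-group (`"simulation"` only).
#' @param n_boot Bootstrap resamples for Harrell-Davis bin SEs (`"hd"` with
#'   `boot_se = TRUE`).
#' @param boot_se Also compute per-bin bootstrap SEs for `"hd"`.
#' @param seed Integer master seed for the stochastic methods.
#' @return An object of class `"cl_fit"`: a list with the fitted `curve`
#'   (a [cl_curve()]), the companion central-tendency `center_curve` for the
#'   sub-group methods, the per-bin `subgroups` table, the `data`, the
#'   `percent_below` coverage on the fitting data, and the call.
#' @seealso [predict.cl_fit()], [plot.cl_fit()], [evaluate_method()]
#' @examples
#' coh <- gen_cohort(300, cohort_model(), seed = 7)
#' fit <- fit_cl(pbmax ~ pta, coh[coh$ear == "R", ], method = "nqr")
#' coef(fit)
#' predict(fit, newdata = data.frame(pta = c(0, 40, 70)))
#' @export
fit_cl <- function(formula = pbmax ~ pta, data,
                   method = c("nqr", "hd", "simulation"),
                   tau = 0.05, scheme = pta_scheme("group1"),
                   n_sims = 50000, n_boot = 1000, boot_se = FALSE,
                   seed = 1L) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  records <- data.frame(pbmax = mf[[1L]], pta = mf[[2L]])
  if ("participant_id" %in% names(data) && nrow(mf) == nrow(data))
    records$participant_id <- data$participant_id
  validate_records(records)
  obj <- list(call = match.call(), method = method, tau = tau,
              scheme = scheme, data = records)
  if (method == "nqr") {
    obj$curve <- fit_nqr(records, tau)
    obj$subgroups <- subgroup_table(records, scheme)
  } else {
    if (!isTRUE(all.equal(tau, 0.05)) && !isTRUE(all.equal(tau, 0.5)))
      stop("sub-group methods support only tau = 0.05 or 0.5")
    parts <- if (method == "hd")
      method2_curve(records, scheme, n_boot = n_boot, seed = seed,
                    boot_se = boot_se)
    else
      method1_curve(records, scheme, n_sims = n_sims, seed = seed)
    obj$subgroups <- parts$subgroups
    if (isTRUE(all.equal(tau, 0.05))) {
      obj$curve <- parts$cl_curve
      obj$center_curve <- if (method == "hd") parts$median_curve else
        parts$mean_curve
    } else {
      obj$curve <- if (method == "hd") parts$median_curve else
        parts$mean_curve
      obj$center_curve <- obj$curve
    }
    obj$curve$tau <- tau
  }
  obj$percent_below <- percent_below(records, obj$curve)
  class(obj) <- "cl_fit"
  obj
}

#' @export
print.cl_fit <- function(x, digits = 4, ...) {
  cat("Lower confidence-limit fit for PBmax vs PTA\n")
  cat("  method: ", x$method, ", tau = ", x$tau, ", n = ", nrow(x$data),
      " ears\n", sep = "")
  b <- coef(x)
  cat("  curve:  beta1 = ", signif(b[1], digits), ", beta2 = ",
      signif(b[2], digits), ", beta3 = ", signif(b[3], digits), "\n",
      sep = "")
  cat("  ", format(100 * x$tau), "% of ears expected below the curve; ",
      signif(x$percent_below, 3), "% observed below\n", sep = "")
  invisible(x)
}

#' @export
coef.cl_fit <- function(object, ...)
  c(beta1 = object$curve$beta1, beta2 = object$curve$beta2,
    beta3 = object$curve$beta3)

#' Predict the fitted confidence-limit curve at new PTA values
#'
#' @param object A `"cl_fit"`.
#' @param newdata Data.frame with a `pta` column, a bare numeric vector of
#'   PTA values, or missing (predictions at the fitting records).
#' @param ... Unused.
#' @return Numeric vector of curve values (percent).
#' @export
predict.cl_fit <- function(object, newdata = NULL, ...) {
  pta <- if (is.null(newdata)) object$data$pta
  else if (is.numeric(newdata)) newdata
  else newdata$pta
  eval_curve(object$curve, pta)
}

#' @export
fitted.cl_fit <- function(object, ...) predict(object)

#' @export
residuals.cl_fit <- function(object, ...)
  object$data$pbmax - predict(object)

#' @export
summary.cl_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cl_fit")
}

#' @export
print.summary.cl_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f)
  cat("\nLink curve detail:\n")
  print(f$curve, digits = digits)
  if (!is.null(f$subgroups)) {
    cat("\nPTA sub-groups (scheme '", f$scheme$name, "'):\n", sep = "")
    tab <- f$subgroups
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(col) signif(col, digits))
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a fitted confidence-limit curve over the cohort
#'
#' Scatter of PBmax against PTA with the fitted curve; ears falling below the
#' curve (the flagged ones) are drawn filled.
#'
#' @param x A `"cl_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cl_fit <- function(x, ...) {
  d <- x$data
  below <- d$pbmax < predict(x)
  graphics::plot(d$pta, d$pbmax, pch = ifelse(below, 17, 1),
                 col = ifelse(below, "darkgreen", "grey40"),
                 xlab = "PTA (dB HL)", ylab = "PBmax (%)",
                 ylim = c(0, 100), ...)
  grid_pta <- seq(0, max(d$pta), length.out = 200)
  graphics::lines(grid_pta, eval_curve(x$curve, grid_pta), lwd = 2)
  if (!is.null(x$center_curve))
    graphics::lines(grid_pta, eval_curve(x$center_curve, grid_pta),
                    lty = 2)
  invisible(x)
}
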
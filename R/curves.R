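#' Three-parameter link curve for PBmax as a function of PTA
#'
#' All three estimation methods summarise the lower confidence limit (or the
#' central tendency) of PBmax as a continuous function of PTA with the same
#' three-parameter form,
#' \deqn{PB_{max}(PTA) = \beta_1 (2 - e^{\beta_2\, PTA^{\beta_3}}),}
#' where `beta1` is the PBmax value at PTA = 0 dB HL and `beta2`, `beta3`
#' control slope and curvature. Two clamping rules make it a valid percent
#' score: for PTA < 0 the value is `beta1`, and negative values are set to 0.
#' `0^beta3` is taken as 0 (also when `beta3 = 0`), so the curve always equals
#' `beta1` exactly at PTA = 0.
#'
#' @param beta1 Value at PTA = 0, in percent; must lie in (0, 110].
#' @param beta2 Non-negative slope constant (at most 1).
#' @param beta3 Non-negative curvature exponent (at most 5).
#' @param tau The quantile the curve describes (e.g. 0.05 or 0.5), or `NA`
#'   for a least-squares fit to sub-group points.
#' @param se Optional named numeric of parameter standard errors.
#' @param gof Optional goodness of fit (R-squared for least-squares fits,
#'   R1(tau) for quantile fits).
#' @return Object of class `"cl_curve"`.
#' @examples
#' eval_curve(cl_curve(88.8, 0.00216, 1.29), 0)   # 88.8
#' eval_curve(cl_curve(88.8, 0.00216, 1.29), -10) # 88.8 (clamped)
#' @export
cl_curve <- function(beta1, beta2, beta3, tau = NA_real_, se = NULL,
                     gof = NA_real_) {
  stopifnot(is.finite(beta1), is.finite(beta2), is.finite(beta3))
  if (beta1 <= 0 || beta1 > 110) stop("beta1 must be in (0, 110]")
  if (beta2 < 0 || beta3 < 0) stop("beta2 and beta3 must be >= 0")
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3, tau = tau,
                 se = se, gof = gof),
            class = "cl_curve")
}

#' @export
print.cl_curve <- function(x, digits = 4, ...) {
  what <- if (is.na(x$tau)) "least-squares" else
    sprintf("tau = %g quantile", x$tau)
  cat("PBmax link curve (", what, "):\n", sep = "")
  b <- c(beta1 = x$beta1, beta2 = x$beta2, beta3 = x$beta3)
  print(signif(b, digits))
  if (!is.null(x$se)) {
    cat("SEs:\n"); print(signif(x$se, digits))
  }
  if (!is.na(x$gof))
    cat(if (is.na(x$tau)) "R-squared: " else "R1(tau): ",
        signif(x$gof, digits), "\n", sep = "")
  invisible(x)
}

#' @rdname cl_curve
#' @param params A `"cl_curve"` (or bare list with `beta1..beta3`).
#' @param pta Numeric vector of PTA values (dB HL).
#' @export
eval_curve <- function(params, pta) {
  pta <- as.numeric(pta)
  x <- pmax(pta, 0)
  xp <- x^params$beta3
  xp[x == 0] <- 0  # anchor: curve equals beta1 at PTA = 0 for any beta3
  val <- params$beta1 * (2 - exp(params$beta2 * xp))
  val[pta < 0] <- params$beta1
  pmax(val, 0)
}

#' Check (pinball) loss
#'
#' The asymmetric absolute loss whose expected minimiser is the tau-quantile:
#' `residual * (tau - 1[residual < 0])`. Positive residuals (observation above
#' the curve) cost `tau` per unit; negative residuals cost `1 - tau` per unit.
#'
#' @param residual Numeric vector of residuals (observed minus predicted).
#' @param tau Quantile level in (0, 1).
#' @return Numeric vector of losses.
#' @export
check_loss <- function(residual, tau) {
  stopifnot(tau > 0, tau < 1)
  residual * (tau - (residual < 0))
}

# Parameter transform: unconstrained theta <-> bounded (beta1, beta2, beta3).
# Logistic maps keep beta1 in (0,110), beta2 in (0,1), beta3 in (0,5) and give
# the optimizer a log-like scale for the tiny beta2 values the data demand.
.b2theta <- function(b)
  c(stats::qlogis(b[1] / 110), stats::qlogis(b[2]), stats::qlogis(b[3] / 5))
.theta2b <- function(theta)
  c(110 * stats::plogis(theta[1]), stats::plogis(theta[2]),
    5 * stats::plogis(theta[3]))

# Fixed multi-start grid spanning the parameter range seen in practice.
.start_grid <- function() {
  g <- expand.grid(b1 = c(80, 90, 100), b2 = c(1e-5, 1e-3, 1e-2),
                   b3 = c(1.0, 1.5, 2.2))
  lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
}

# Multi-start Nelder-Mead on the transformed scale: a cheap exploration pass
# from every start, then a long polish (with one restart) from the best.
.minimize_curve <- function(obj, explore_maxit = 300, polish_maxit = 4000) {
  best <- NULL
  for (b0 in .start_grid()) {
    fit <- try(stats::optim(.b2theta(b0), obj, method = "Nelder-Mead",
                            control = list(maxit = explore_maxit,
                                           reltol = 1e-7)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("curve fit failed from every start")
  for (i in 1:2) {
    best2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                          control = list(maxit = polish_maxit,
                                         reltol = 1e-12))
    if (best2$value <= best$value) best <- best2
  }
  best
}

#' Least-squares fit of the link curve to sub-group points
#'
#' Fits the three-parameter link curve to `(PTA, value)` points (typically a
#' sub-group's mean PTA against its estimated confidence limit, mean or
#' median) by unweighted least squares. The primary optimiser is bounded
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) from a fixed grid of starting
#' values; a derivative-free fallback handles degenerate inputs (e.g. flat
#' data) where the Jacobian is singular.
#'
#' @param points Data.frame with columns `pta` and `value`, or a two-column
#'   matrix. At least 4 points spanning at least 30 dB are recommended; fewer
#'   triggers a warning.
#' @return A [cl_curve()] with `tau = NA`, least-squares standard errors when
#'   available, and `gof` set to R-squared.
#' @export
fit_curve_ls <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("pta", "value") %in% names(points)))
    names(points)[1:2] <- c("pta", "value")
  points <- points[is.finite(points$pta) & is.finite(points$value), ]
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points to fit the link curve")
  if (n < 4 || diff(range(points$pta)) < 30)
    warning("fewer than 4 points or PTA span < 30 dB; fit may be unstable")
  sstot <- sum((points$value - mean(points$value))^2)
  best <- NULL; best_se <- NULL
  for (b0 in .start_grid()) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      value ~ pmax(b1 * (2 - exp(b2 * pta^b3)), 0),
      data = points,
      start = list(b1 = b0[1], b2 = b0[2], b3 = b0[3]),
      lower = c(1e-6, 0, 0), upper = c(110, 1, 5),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    dev <- sum(stats::residuals(fit)^2)
    if (is.null(best) || dev < best$dev) {
      cf <- stats::coef(fit)
      se <- try(summary(fit)$coefficients[, "Std. Error"], silent = TRUE)
      best <- list(dev = dev, coef = cf)
      best_se <- if (inherits(se, "try-error")) NULL else
        stats::setNames(as.numeric(se), c("beta1", "beta2", "beta3"))
    }
  }
  if (is.null(best)) {
    y <- points$value; x <- points$pta
    obj <- function(theta) {
      b <- .theta2b(theta)
      sum((y - eval_curve(list(beta1 = b[1], beta2 = b[2], beta3 = b[3]),
                          x))^2)
    }
    opt <- .minimize_curve(obj)
    b <- .theta2b(opt$par)
    best <- list(dev = opt$value, coef = c(b1 = b[1], b2 = b[2], b3 = b[3]))
  }
  r2 <- if (sstot > 0) 1 - best$dev / sstot else NA_real_
  cl_curve(beta1 = min(unname(best$coef[1]), 110),
           beta2 = unname(best$coef[2]),
           beta3 = unname(best$coef[3]),
           tau = NA_real_, se = best_se, gof = r2)
}

#' Nonlinear quantile regression of the link curve
#'
#' Estimates the conditional tau-quantile of PBmax given PTA by minimising the
#' total check loss of the link curve over `(beta1, beta2, beta3)`, directly
#' on per-ear records and without any sub-grouping. The objective is
#' non-smooth, so a derivative-free multi-start Nelder-Mead search on a
#' bounded, log-like transformed parameter scale is used; the start grid is
#' fixed, making the fit deterministic.
#'
#' @param records Cohort data.frame with `pta` and `pbmax` columns.
#' @param tau Quantile level in (0, 1): 0.05 for the lower 95% confidence
#'   limit, 0.5 for the median curve.
#' @return A [cl_curve()] with `gof` set to the R1(tau) goodness of fit.
#' @examples
#' d <- data.frame(pta = rep(seq(0, 80, 10), 4))
#' d$pbmax <- eval_curve(cl_curve(90, 1e-3, 1.5), d$pta)
#' coef_fit <- fit_nqr(d, tau = 0.5)
#' @export
fit_nqr <- function(records, tau = 0.05) {
  stopifnot(tau > 0, tau < 1)
  y <- records$pbmax; x <- records$pta
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("too few records to fit a quantile curve")
  if (n < 50 || diff(range(x)) < 40)
    warning("fewer than 50 records or PTA span < 40 dB; quantile fit may be unstable")
  if (stats::sd(y) == 0) {
    warning("all scores identical; returning a flat curve")
    return(cl_curve(beta1 = max(y[1], 1e-6), beta2 = 0, beta3 = 1,
                    tau = tau, gof = NA_real_))
  }
  xc <- pmax(x, 0)
  zero <- xc == 0
  obj <- function(theta) {
    b1 <- 110 * stats::plogis(theta[1])
    b2 <- stats::plogis(theta[2])
    b3 <- 5 * stats::plogis(theta[3])
    xp <- xc^b3
    if (any(zero)) xp[zero] <- 0
    pred <- pmax(b1 * (2 - exp(b2 * xp)), 0)
    r <- y - pred
    sum(r * (tau - (r < 0)))
  }
  opt <- .minimize_curve(obj)
  b <- .theta2b(opt$par)
  fit <- cl_curve(beta1 = b[1], beta2 = b[2], beta3 = b[3], tau = tau)
  fit$gof <- r1_goodness(data.frame(pta = x, pbmax = y), fit, tau)
  fit$loss <- opt$value
  fit
}

#' Goodness of fit for quantile regression, R1(tau)
#'
#' The quantile-regression analogue of R-squared: one minus the ratio of the
#' fitted model's total check loss to that of the null model which predicts
#' the constant sample tau-quantile. 1 means a perfect fit; 0 means the curve
#' does no better than the constant quantile.
#'
#' @param records Cohort data.frame (`pta`, `pbmax`).
#' @param params A [cl_curve()] fitted at the same `tau`.
#' @param tau Quantile level in (0, 1).
#' @return A number in \[0, 1\] (can be slightly negative for a curve worse
#'   than the null model); `NA` if the scores have zero spread.
#' @export
r1_goodness <- function(records, params, tau) {
  y <- records$pbmax
  num <- sum(check_loss(y - eval_curve(params, records$pta), tau))
  q0 <- stats::quantile(y, tau, names = FALSE)
  den <- sum(check_loss(y - q0, tau))
  if (den == 0) return(NA_real_)
  1 - num / den
}

#' Bootstrap standard errors of nonlinear quantile-regression parameters
#'
#' Resamples participants (both ears of a resampled participant enter
#' together, preserving the pairing) with replacement, refits the quantile
#' curve on each resample, and reports the standard deviation of each
#' parameter across resamples.
#'
#' @param records Cohort data.frame; a `participant_id` column defines the
#'   resampling unit (rows are resampled independently if it is absent).
#' @param tau Quantile level.
#' @param n_boot Number of bootstrap resamples (>= 200 recommended for stable
#'   SEs; smaller values error).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Named numeric: `se_beta1`, `se_beta2`, `se_beta3`.
#' @export
nqr_param_se <- function(records, tau = 0.05, n_boot = 200, seed = 1L) {
  if (n_boot < 200) stop("n_boot must be at least 200")
  unit <- if ("participant_id" %in% names(records))
    records$participant_id else seq_len(nrow(records))
  ids <- unique(unit)
  idx <- split(seq_len(nrow(records)), match(unit, ids))
  set.seed(seed)
  fits <- matrix(NA_real_, n_boot, 3)
  fails <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample.int(length(ids), replace = TRUE)
    rows <- unlist(idx[take], use.names = FALSE)
    fit <- try(suppressWarnings(fit_nqr(records[rows, , drop = FALSE], tau)),
               silent = TRUE)
    if (inherits(fit, "try-error")) fails <- fails + 1L
    else fits[b, ] <- c(fit$beta1, fit$beta2, fit$beta3)
  }
  if (fails > 0.2 * n_boot)
    stop("more than 20% of bootstrap refits failed (", fails, "/", n_boot, ")")
  se <- apply(fits, 2, stats::sd, na.rm = TRUE)
  stats::setNames(se, c("se_beta1", "se_beta2", "se_beta3"))
}
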
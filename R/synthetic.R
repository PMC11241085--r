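# Synthetic cohorts with analytically known conditional quantiles.
#
# Real per-ear norms data are rarely shareable, so the package carries a
# generator whose conditional law of PBmax given PTA is fully specified:
# every downstream estimator can be checked against the generator's exact
# quantiles. The default calibration follows the distributional summaries of
# a large sensorineural-loss clinic cohort: mean score falling and SD growing
# with PTA, a hard ceiling at 100, strong left skew at low PTA, scores on the
# 4% lattice, and bin occupancies dominated by mild losses.

# Default tabulated conditioning curves: sub-group mean PTA against the
# measured mean and SD of PBmax (right-ear values), plus the 10-dB-bin
# participant counts used as sampling weights.
.default_mean_points <- function()
  data.frame(pta = c(10.2, 20.8, 30.1, 40.8, 50.7, 60.2, 70.8, 81.3, 91.2),
             value = c(96.2, 93.0, 89.9, 84.3, 81.2, 72.3, 50.8, 44.6, 21.6))
.default_sd_points <- function()
  data.frame(pta = c(10.2, 20.8, 30.1, 40.8, 50.7, 60.2, 70.8, 81.3, 91.2),
             value = c(5.6, 8.9, 8.4, 13.2, 14.4, 15.3, 21.7, 23.5, 20.5))
.default_weights <- function()
  c(151, 115, 96, 91, 69, 58, 32, 14, 16)

#' Specify a synthetic-cohort model
#'
#' Defines the conditional law of PBmax given PTA from which [gen_cohort()]
#' samples and for which [true_quantile()] returns exact quantiles.
#'
#' The latent score at a given PTA has mean `mu(PTA)` and SD `sigma(PTA)`,
#' linearly interpolated from `mean_points` / `sd_points` (held constant
#' beyond the tabulated range). Two families are available:
#'
#' * `"skewed_beta"` (default): a Beta distribution rescaled to \[0, 100\]
#'   and moment-matched to `(mu, sigma)`. High-mean sub-groups come out
#'   left-skewed with a soft ceiling, like real score distributions.
#' * `"censored_normal"`: Normal(`mu`, `sigma`) clamped into \[0, 100\] -- the
#'   very assumption the Monte-Carlo method makes, so that method is unbiased
#'   by construction under this family (a useful null check).
#'
#' PTA is drawn by choosing a bin with probability proportional to
#' `pta_weights`, then uniformly within the bin, snapped to the 1.25-dB grid
#' of clinical audiometry. With `discretize = TRUE` scores are rounded to
#' multiples of 4, as 25-item lists produce.
#'
#' @param mean_points,sd_points Data.frames (`pta`, `value`) tabulating
#'   `mu(PTA)` and `sigma(PTA)`; all SDs must be positive.
#' @param family `"skewed_beta"` or `"censored_normal"`.
#' @param scheme A [pta_scheme()] whose bins carry the sampling weights.
#' @param pta_weights Non-negative weights, one per scheme bin.
#' @param discretize Round scores to multiples of 4 (default `TRUE`).
#' @param ear_correlation Gaussian-copula correlation between the two ears of
#'   one participant (default 0: ears independent).
#' @return Object of class `"cohort_model"`.
#' @export
cohort_model <- function(mean_points = .default_mean_points(),
                         sd_points = .default_sd_points(),
                         family = c("skewed_beta", "censored_normal"),
                         scheme = pta_scheme("group1"),
                         pta_weights = .default_weights(),
                         discretize = TRUE,
                         ear_correlation = 0) {
  family <- match.arg(family)
  stopifnot(all(sd_points$value > 0),
            length(pta_weights) == length(scheme$labels),
            all(pta_weights >= 0), any(pta_weights > 0),
            ear_correlation >= -1, ear_correlation <= 1)
  structure(list(mean_points = mean_points, sd_points = sd_points,
                 family = family, scheme = scheme,
                 pta_weights = pta_weights, discretize = discretize,
                 ear_correlation = ear_correlation),
            class = "cohort_model")
}

#' @export
print.cohort_model <- function(x, ...) {
  cat("Synthetic cohort model: family '", x$family, "', ",
      length(x$scheme$labels), " PTA bins, scores ",
      if (x$discretize) "on the 4% lattice" else "continuous", "\n", sep = "")
  invisible(x)
}

.model_mu <- function(model, pta)
  stats::approx(model$mean_points$pta, model$mean_points$value,
                xout = pta, rule = 2)$y
.model_sigma <- function(model, pta)
  stats::approx(model$sd_points$pta, model$sd_points$value,
                xout = pta, rule = 2)$y

# Moment-matched Beta shape parameters on the [0, 100] scale; the variance is
# capped just under the Bernoulli bound m(1-m) where matching is impossible.
.beta_shapes <- function(mu, sigma) {
  m <- pmin(pmax(mu / 100, 1e-4), 1 - 1e-4)
  v <- pmin((sigma / 100)^2, 0.98 * m * (1 - m))
  k <- m * (1 - m) / v - 1
  list(a = m * k, b = (1 - m) * k)
}

#' Exact conditional quantile of a synthetic-cohort model
#'
#' The tau-quantile of the latent-then-censored score law at a given PTA,
#' before any lattice discretization: for `"censored_normal"`,
#' `clamp(mu + sigma * qnorm(tau), 0, 100)`; for `"skewed_beta"`, the scaled
#' Beta inverse CDF. This is the oracle every estimator in the package can be
#' benchmarked against.
#'
#' @param model A [cohort_model()].
#' @param pta PTA value(s), dB HL.
#' @param tau Quantile level in (0, 1).
#' @return Quantile(s) in percent.
#' @examples
#' m <- cohort_model(family = "censored_normal")
#' true_quantile(m, 10.2, 0.05)  # 96.2 + 5.6 * qnorm(0.05) = 86.99
#' @export
true_quantile <- function(model, pta, tau) {
  stopifnot(inherits(model, "cohort_model"), tau > 0, tau < 1)
  mu <- .model_mu(model, pta)
  sigma <- .model_sigma(model, pta)
  if (model$family == "censored_normal") {
    pmin(pmax(mu + sigma * stats::qnorm(tau), 0), 100)
  } else {
    sh <- .beta_shapes(mu, sigma)
    100 * stats::qbeta(tau, sh$a, sh$b)
  }
}

#' Generate a synthetic per-ear cohort
#'
#' Draws `n_participants` participants, two ears each (left and right), from
#' a [cohort_model()]. Each ear gets a PTA from the bin-weighted mixture
#' (uniform within bin, snapped to 1.25-dB steps) and a score from the
#' family's conditional law at that PTA, clamped into \[0, 100\] and, if the
#' model discretizes, rounded to the 4% lattice. Ears are independent unless
#' the model sets `ear_correlation`, which links the two latent scores by a
#' Gaussian copula.
#'
#' @param n_participants Number of participants (>= 1); the cohort has twice
#'   as many records.
#' @param model A [cohort_model()].
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return Cohort data.frame: `participant_id`, `ear`, `pta`, `pbmax`.
#' @examples
#' coh <- gen_cohort(100, cohort_model(), seed = 1)
#' nrow(coh)  # 200
#' @export
gen_cohort <- function(n_participants, model = cohort_model(), seed = 1L) {
  stopifnot(inherits(model, "cohort_model"), n_participants >= 1)
  set.seed(seed)
  n_ears <- 2L * n_participants
  br <- model$scheme$breaks
  bin <- sample.int(length(model$pta_weights), n_ears, replace = TRUE,
                    prob = model$pta_weights)
  lo <- br[bin]; hi <- br[bin + 1L]
  pta <- lo + stats::runif(n_ears) * (hi - lo)
  # snap to the 1.25-dB audiometric grid, clipped to the scheme's range
  pta <- pmin(pmax(round(pta / 1.25) * 1.25, br[1]), br[length(br)])
  rng <- range(c(model$mean_points$pta, model$sd_points$pta))
  # conditioning curves are extended flat outside their tabulated range, so
  # any sampled PTA is supported; warn if extrapolating far
  if (any(pta < rng[1] - 20) || any(pta > rng[2] + 30))
    warning("sampled PTA far outside the tabulated curve range [",
            rng[1], ", ", rng[2], "]")
  u <- matrix(stats::runif(n_ears), ncol = 2)
  if (model$ear_correlation != 0) {
    rho <- model$ear_correlation
    z1 <- stats::qnorm(u[, 1]); z2 <- stats::qnorm(u[, 2])
    u[, 2] <- stats::pnorm(rho * z1 + sqrt(1 - rho^2) * z2)
  }
  u <- as.vector(u)
  mu <- .model_mu(model, pta)
  sigma <- .model_sigma(model, pta)
  score <- if (model$family == "censored_normal") {
    mu + sigma * stats::qnorm(u)
  } else {
    sh <- .beta_shapes(mu, sigma)
    100 * stats::qbeta(u, sh$a, sh$b)
  }
  score <- pmin(pmax(score, 0), 100)
  if (model$discretize) score <- round_to_step(score, 4)
  data.frame(
    participant_id = rep(seq_len(n_participants), 2L),
    ear = rep(c("L", "R"), each = n_participants),
    pta = pta,
    pbmax = score
  )
}
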
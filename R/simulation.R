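# Method 1: censored-normal Monte-Carlo estimation of the lower 95% CL.
#
# Each PTA sub-group's scores are modelled as Normal(mean, SD) with the
# moments measured in that sub-group; simulated scores outside [0, 100] are
# clamped (not resampled), and the 5th percentile of the censored draws,
# rounded onto the 4% score lattice, is the confidence limit.

#' Censored-normal Monte-Carlo lower 95% confidence limit for one sub-group
#'
#' Draws `n_sims` scores from Normal(`mean`, `sd`), sets values above 100 to
#' 100 and below 0 to 0, and takes the value below which 5% of the censored
#' draws fall (the order statistic at rank `ceiling(0.05 * n_sims)`), rounded
#' to the nearest multiple of `score_step`.
#'
#' `sd_mode = "binomial_x1.62"` replaces the measured SD by 1.62 times the
#' binomial SD of a 25-item list at the sub-group's mean score, a historical
#' variant retained for comparison only.
#'
#' @param mean,sd Measured mean and SD of the sub-group's scores (percent).
#' @param n_sims Number of Monte-Carlo draws (>= 1000; default 50000).
#' @param seed Integer seed (optional); fixes the draw.
#' @param sd_mode `"measured"` (default) or `"binomial_x1.62"`.
#' @param score_step Score lattice step, default 4 (percent).
#' @return List: `sim_mean`, `sim_sd` (moments of the censored draws),
#'   `cl_raw` (unrounded 5th percentile), `cl_s` (rounded confidence limit).
#' @examples
#' simulate_cl_s(96.2, 5.6, seed = 1)$cl_s  # 88
#' @export
simulate_cl_s <- function(mean, sd, n_sims = 50000, seed = NULL,
                          sd_mode = c("measured", "binomial_x1.62"),
                          score_step = 4) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n_sims >= 1000)
  if (sd_mode == "binomial_x1.62") {
    p <- mean / 100
    sd <- 1.62 * sqrt(p * (1 - p) / 25) * 100
  }
  if (sd == 0) {
    message("zero SD: degenerate sub-group, CL equals the (rounded) mean")
    m <- min(max(mean, 0), 100)
    return(list(sim_mean = m, sim_sd = 0, cl_raw = m,
                cl_s = round_to_step(m, score_step)))
  }
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n_sims, mean, sd)
  x[x > 100] <- 100
  x[x < 0] <- 0
  q <- sort(x, partial = ceiling(0.05 * n_sims))[ceiling(0.05 * n_sims)]
  list(sim_mean = base::mean(x), sim_sd = stats::sd(x), cl_raw = q,
       cl_s = round_to_step(q, score_step))
}

#' Asymptotic standard error of an estimated quantile (order-statistic form)
#'
#' The large-sample SE of the p-quantile estimated from a sub-group of
#' `n_group` ears, `sqrt(p (1 - p) / n_group) / f(q_p)`, with `f` the
#' Normal(`mean`, `sd`) density evaluated at that distribution's p-quantile.
#' Note the SE reflects the sub-group's own sample size, not the number of
#' Monte-Carlo draws.
#'
#' @param p Quantile level in (0, 1) (0.05 for the lower 95% CL).
#' @param n_group Number of ears in the sub-group (>= 2).
#' @param mean,sd Normal parameters fitted to the sub-group (percent; sd > 0).
#' @return The SE in percent.
#' @examples
#' quantile_se(0.05, 96, 89.9, 8.4)  # about 1.8
#' @export
quantile_se <- function(p, n_group, mean, sd) {
  stopifnot(p > 0, p < 1, n_group >= 2, sd > 0)
  qp <- stats::qnorm(p, mean, sd)
  f <- stats::dnorm(qp, mean, sd)
  if (f < .Machine$double.xmin * 1e10)
    stop("density underflow at the requested quantile; SE undefined")
  sqrt(p * (1 - p) / n_group) / f
}

# Per-bin simulation estimates plus fitted link curves; shared backend of
# fit_cl(method = "simulation"). Per-bin seeds are master seed + bin index so
# adding a bin does not perturb the others.
method1_curve <- function(records, scheme = pta_scheme("group1"),
                          n_sims = 50000, seed = 1L,
                          sd_mode = "measured", score_step = 4) {
  tab <- subgroup_table(records, scheme)
  usable <- tab$n >= 2
  if (any(!usable))
    warning("dropping sub-group(s) with n < 2: ",
            paste(tab$label[!usable], collapse = ", "))
  sim_mean <- sim_sd <- cl <- se <- rep(NA_real_, nrow(tab))
  for (i in which(usable)) {
    s <- simulate_cl_s(tab$mean_pbmax[i], tab$sd_pbmax[i], n_sims = n_sims,
                       seed = seed + i, sd_mode = sd_mode,
                       score_step = score_step)
    sim_mean[i] <- s$sim_mean
    sim_sd[i] <- s$sim_sd
    cl[i] <- s$cl_s
    if (tab$sd_pbmax[i] > 0)
      se[i] <- quantile_se(0.05, tab$n[i], tab$mean_pbmax[i], tab$sd_pbmax[i])
  }
  tab$sim_mean <- sim_mean
  tab$sim_sd <- sim_sd
  tab$cl_value <- cl
  tab$cl_se <- se
  ok <- usable & is.finite(cl)
  list(
    subgroups = tab,
    cl_curve = fit_curve_ls(data.frame(pta = tab$mean_pta[ok],
                                       value = cl[ok])),
    mean_curve = fit_curve_ls(data.frame(pta = tab$mean_pta[ok],
                                         value = sim_mean[ok]))
  )
}
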
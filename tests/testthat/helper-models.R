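# Shared fixtures, all built in code.

# A generator whose exact 0.05-quantile curve lies in the link-curve family
# by construction: the conditional mean and the conditional 0.05 quantile are
# both link curves, and sigma(PTA) is their gap divided by qnorm(0.95).
# Recovery tests against true_quantile() then measure estimator error only,
# not curve-family misspecification.
link_calibrated_model <- function(discretize = FALSE) {
  mu_curve <- cl_curve(96, 1e-4, 2.0)
  q_curve <- cl_curve(88, 8e-4, 1.6)
  grid <- seq(0, 119, 2.5)
  mu <- eval_curve(mu_curve, grid)
  sigma <- pmax((mu - eval_curve(q_curve, grid)) / stats::qnorm(0.95), 0.5)
  cohort_model(mean_points = data.frame(pta = grid, value = mu),
               sd_points = data.frame(pta = grid, value = sigma),
               family = "censored_normal", discretize = discretize)
}

# Records lying exactly on a known link curve, PTA spread over [0, 90].
on_curve_records <- function(n, curve = cl_curve(90, 0.001, 1.5),
                             seed = 1L) {
  set.seed(seed)
  pta <- stats::runif(n, 0, 90)
  data.frame(pta = pta, pbmax = eval_curve(curve, pta))
}

# Write a small cohort CSV and return its path.
write_cohort_csv <- function(df, file = tempfile(fileext = ".csv")) {
  utils::write.csv(df, file, row.names = FALSE)
  file
}

# Mean (percent) of a Normal(mean, sd) clamped into [0, 100]: closed form,
# used as an independent oracle for the censored-normal family.
censored_normal_mean <- function(mean, sd, lo = 0, hi = 100) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    mean * (stats::pnorm(b) - stats::pnorm(a)) -
    sd * (stats::dnorm(b) - stats::dnorm(a))
}
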
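test_that("eval_curve anchors at beta1 and applies both clamping rules", {
  p <- cl_curve(88.8, 0.00216, 1.29)
  expect_equal(eval_curve(p, 0), 88.8)       # exact anchor at PTA = 0
  expect_equal(eval_curve(p, -10), 88.8)     # negative PTA clamps to beta1
  # hand evaluation of the published-form curve
  p2 <- cl_curve(96.3, 0.0000312, 2.17)
  expect_equal(eval_curve(p2, 10.2),
               96.3 * (2 - exp(0.0000312 * 10.2^2.17)), tolerance = 1e-12)
  expect_equal(round(eval_curve(p2, 10.2), 1), 95.8)
  # floor clamp: far out the curve would go negative
  expect_equal(eval_curve(cl_curve(90, 0.01, 2), 120), 0)
  # beta3 = 0 edge: still beta1 at PTA = 0
  expect_equal(eval_curve(cl_curve(90, 0.5, 0), 0), 90)
})

test_that("eval_curve is continuous and non-increasing for positive shape", {
  g <- seq(-5, 119, by = 0.25)
  for (p in list(cl_curve(96, 1e-4, 2), cl_curve(88, 8e-4, 1.6),
                 cl_curve(91.8, 0.00182, 1.33))) {
    v <- eval_curve(p, g)
    expect_true(all(diff(v) <= 1e-9))
    expect_true(all(abs(diff(v)) < 1.5))  # no jumps on a 0.25-dB grid
  }
})

test_that("least-squares fit recovers exact curves and flags perturbations", {
  truth <- cl_curve(90, 0.001, 1.5)
  pts <- data.frame(pta = c(10, 25, 40, 55, 70, 85))
  pts$value <- eval_curve(truth, pts$pta)
  fit <- fit_curve_ls(pts)
  expect_lt(abs(fit$beta1 - 90) / 90, 1e-4)
  expect_lt(abs(fit$beta2 - 0.001) / 0.001, 1e-4)
  expect_lt(abs(fit$beta3 - 1.5) / 1.5, 1e-4)
  expect_equal(fit$gof, 1, tolerance = 1e-9)

  pts2 <- pts; pts2$value[3] <- pts2$value[3] + 1
  fit2 <- fit_curve_ls(pts2)
  expect_lt(fit2$gof, 1)
  expect_lt(abs(fit2$beta1 - 90), 2)

  flat <- data.frame(pta = c(10, 30, 50, 70), value = 100)
  fit3 <- suppressWarnings(fit_curve_ls(flat))
  expect_equal(eval_curve(fit3, c(0, 40, 80)), rep(100, 3), tolerance = 1e-3)
  expect_equal(fit3$beta1, 100, tolerance = 1e-3)
})

test_that("check loss is the standard pinball loss", {
  expect_equal(check_loss(1, 0.05), 0.05)
  expect_equal(check_loss(-1, 0.05), 0.95)
  expect_equal(check_loss(0, 0.37), 0)
  expect_equal(check_loss(c(2, -2), 0.5), c(1, 1))
  expect_true(all(check_loss(rnorm(100), 0.2) >= 0))
})

test_that("quantile regression interpolates noise-free curves at any tau", {
  truth <- cl_curve(90, 0.001, 1.5)
  rec <- on_curve_records(300, truth, seed = 5)
  for (tau in c(0.05, 0.5)) {
    fit <- fit_nqr(rec, tau)
    expect_lt(fit$loss, 1e-6)
    expect_lt(abs(fit$beta1 - 90) / 90, 1e-3)
    expect_lt(abs(fit$beta2 - 0.001) / 0.001, 1e-3)
    expect_lt(abs(fit$beta3 - 1.5) / 1.5, 1e-3)
  }
})

test_that("fitted 5% curve leaves 3-7% of fitting records strictly below", {
  coh <- gen_cohort(1200, cohort_model(family = "skewed_beta"), seed = 17)
  rec <- coh[coh$ear == "L", ]
  fit <- fit_nqr(rec, 0.05)
  pb <- percent_below(rec, fit)
  expect_gt(pb, 3); expect_lt(pb, 7)
})

test_that("the 5% curve never exceeds the median curve", {
  coh <- gen_cohort(800, cohort_model(), seed = 23)
  rec <- coh[coh$ear == "R", ]
  lo <- fit_nqr(rec, 0.05)
  med <- fit_nqr(rec, 0.5)
  g <- seq(min(rec$pta), max(rec$pta), length.out = 200)
  expect_true(all(eval_curve(lo, g) <= eval_curve(med, g) + 1e-6))
})

test_that("check-loss minimum is a local optimum and beats coarse grid search", {
  set.seed(41)
  rec <- data.frame(pta = runif(12, 0, 80))
  rec$pbmax <- round_to_step(pmin(pmax(
    eval_curve(cl_curve(92, 5e-4, 1.7), rec$pta) + rnorm(12, 0, 8), 0), 100))
  tau <- 0.05
  fit <- suppressWarnings(fit_nqr(rec, tau))
  loss_of <- function(b1, b2, b3)
    sum(check_loss(rec$pbmax -
                     eval_curve(list(beta1 = b1, beta2 = b2, beta3 = b3),
                                rec$pta), tau))
  # exhaustive coarse grid as an independent oracle
  grid <- expand.grid(b1 = seq(50, 105, 5), b2 = 10^seq(-5, -1, 0.5),
                      b3 = seq(0.5, 3, 0.25))
  gmin <- min(mapply(loss_of, grid$b1, grid$b2, grid$b3))
  expect_lte(fit$loss, gmin + 1e-6)
  # +/-1% parameter perturbations never help beyond tolerance
  for (d in c(-0.01, 0.01)) {
    expect_gte(loss_of(fit$beta1 * (1 + d), fit$beta2, fit$beta3),
               fit$loss - 1e-6)
    expect_gte(loss_of(fit$beta1, fit$beta2 * (1 + d), fit$beta3),
               fit$loss - 1e-6)
    expect_gte(loss_of(fit$beta1, fit$beta2, fit$beta3 * (1 + d)),
               fit$loss - 1e-6)
  }
})

test_that("R1 is 1 for a perfect fit, 0 for the null model, plausible between", {
  truth <- cl_curve(90, 0.001, 1.5)
  rec <- on_curve_records(120, truth, seed = 2)
  expect_equal(r1_goodness(rec, truth, 0.05), 1)
  q0 <- quantile(rec$pbmax, 0.05, names = FALSE)
  # constant curve at the sample tau-quantile (bare list: q0 may be 0)
  null_curve <- list(beta1 = q0, beta2 = 0, beta3 = 1)
  expect_equal(r1_goodness(rec, null_curve, 0.05), 0, tolerance = 1e-12)

  coh <- gen_cohort(642, cohort_model(family = "skewed_beta"), seed = 19)
  fit <- fit_nqr(coh[coh$ear == "R", ], 0.05)
  expect_gt(fit$gof, 0.5); expect_lt(fit$gof, 0.95)
  flat <- data.frame(pta = 1:10, pbmax = 80)
  expect_true(is.na(r1_goodness(flat, truth, 0.05)))
})

test_that("bootstrap parameter SEs are reproducible and sane", {
  truth <- cl_curve(90, 0.001, 1.5)
  rec <- on_curve_records(60, truth, seed = 3)
  rec$participant_id <- rep(1:30, each = 2)
  se <- suppressWarnings(nqr_param_se(rec, 0.05, n_boot = 200, seed = 9))
  expect_lt(se[["se_beta1"]], 0.2)  # noise-free data: nearly no spread
  se2 <- suppressWarnings(nqr_param_se(rec, 0.05, n_boot = 200, seed = 9))
  expect_identical(se, se2)
  expect_error(nqr_param_se(rec, 0.05, n_boot = 50), "at least 200")
})

test_that("bootstrap beta1 SE agrees with a jackknife to within a factor 2", {
  set.seed(13)
  n <- 60
  rec <- data.frame(pta = runif(n, 0, 85), participant_id = 1:n)
  # continuous scores: lattice rounding makes tiny-sample quantile fits
  # jumpy, which is not what this cross-method sanity check is about
  rec$pbmax <- pmin(pmax(
    eval_curve(cl_curve(92, 5e-4, 1.7), rec$pta) + rnorm(n, 0, 6), 0), 100)
  boot <- suppressWarnings(nqr_param_se(rec, 0.5, n_boot = 200, seed = 2))
  jack <- vapply(seq_len(n), function(i)
    suppressWarnings(fit_nqr(rec[-i, ], 0.5))$beta1, numeric(1))
  jack_se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  ratio <- boot[["se_beta1"]] / jack_se
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
})
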
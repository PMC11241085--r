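test_that("PTA is the arithmetic mean of the four thresholds", {
  expect_equal(compute_pta(10, 10, 10, 10), 10)
  expect_equal(compute_pta(20, 30, 40, 50), 35)
  expect_equal(compute_pta(0, 5, 5, 10), 5)
  expect_equal(compute_pta(c(10, 20), c(10, 30), c(10, 40), c(10, 50)),
               c(10, 35))
  expect_error(compute_pta(10, NA, 10, 10), "finite")
})

test_that("conductive flag requires a >=15 dB air-bone gap at >=2 frequencies", {
  expect_false(flag_conductive(c(40, 40, 40), c(20, 30, 40)))  # one gap
  expect_true(flag_conductive(c(40, 40, 40), c(20, 20, 40)))   # two gaps
  expect_false(flag_conductive(c(40, 40, 40), c(40, 40, 40)))  # no gap
  expect_warning(res <- flag_conductive(c(40, 40, 40), NULL), "absent")
  expect_false(res)
})

test_that("round_to_step snaps to the score lattice, ties away from zero", {
  expect_equal(round_to_step(86.99), 88)
  expect_equal(round_to_step(78.36), 80)
  expect_equal(round_to_step(76.0), 76)
  expect_equal(round_to_step(86), 88)  # exact half-distance rounds up
  # idempotent and never further than half a step... 2 for step 4
  x <- seq(-10, 110, by = 0.37)
  r <- round_to_step(x)
  expect_equal(round_to_step(r), r)
  expect_true(all(abs(r - x) <= 2))
  expect_true(all(r %% 4 == 0))
})

test_that("read_cohort validates rows and computes PTA from thresholds", {
  good <- data.frame(participant_id = 1:3, ear = "R",
                     pta = c(10, 20, 30), pbmax = c(96, 88, 80))
  expect_equal(nrow(read_cohort(write_cohort_csv(good))), 3)

  bad <- good; bad$pbmax[2] <- 103
  expect_warning(res <- read_cohort(write_cohort_csv(bad)), "rejected")
  expect_equal(nrow(res), 2)

  thr <- data.frame(participant_id = 1:2, ear = c("L", "R"),
                    htl_500 = c(20, 0), htl_1000 = c(30, 5),
                    htl_2000 = c(40, 5), htl_4000 = c(50, 10),
                    pbmax = c(84, 100))
  res <- read_cohort(write_cohort_csv(thr))
  expect_equal(res$pta, c(35, 5))

  off <- good; off$pbmax[1] <- 93  # not a multiple of 4
  expect_warning(read_cohort(write_cohort_csv(off)), "multiple of 4")
  expect_error(suppressWarnings(read_cohort(write_cohort_csv(off),
                                            strict = TRUE)))
})

test_that("read_cohort applies the conductive exclusion when bone data exist", {
  d <- data.frame(participant_id = 1:2, ear = "R",
                  htl_500 = c(40, 40), htl_1000 = c(40, 40),
                  htl_2000 = c(40, 40), htl_4000 = c(40, 40),
                  bone_500 = c(20, 35), bone_1000 = c(20, 35),
                  bone_2000 = c(40, 35), pbmax = c(80, 80))
  expect_message(res <- read_cohort(write_cohort_csv(d)), "conductive")
  expect_equal(res$participant_id, 2)
})

test_that("sub-group assignment is total on all four schemes", {
  set.seed(4)
  pta <- sample(seq(0, 120, by = 1.25), 500, replace = TRUE)
  for (nm in c("group1", "group2", "group3", "group4")) {
    g <- assign_subgroup(pta, pta_scheme(nm))
    expect_false(anyNA(g))
  }
  sc <- pta_scheme("group1")
  expect_equal(as.character(assign_subgroup(10.2, sc)), "<15")
  expect_equal(as.character(assign_subgroup(60.2, sc)), "56-65")
  # boundary convention: cut point at the label midpoint 15.5
  expect_equal(as.character(assign_subgroup(15.5, sc)), "<15")
  expect_equal(as.character(assign_subgroup(16.25, sc)), "16-25")
  expect_error(assign_subgroup(130, sc), "outside")
})

test_that("sub-group summaries use sample SD and non-excess kurtosis", {
  flat <- data.frame(pta = c(10, 11, 12), pbmax = c(96, 96, 96))
  s <- summarize_subgroup(flat)
  expect_equal(s$mean_pbmax, 96)
  expect_equal(s$sd_pbmax, 0)
  expect_true(is.na(s$skewness) && is.na(s$kurtosis))

  two <- data.frame(pta = c(10, 20), pbmax = c(0, 100))
  expect_equal(summarize_subgroup(two)$sd_pbmax, sqrt(2) * 50)  # 70.71, n-1

  set.seed(1)
  z <- data.frame(pta = 0, pbmax = rnorm(1e5))
  s <- summarize_subgroup(z)
  expect_lt(abs(s$skewness), 0.05)
  expect_lt(abs(s$kurtosis - 3), 0.1)  # normal law -> kurtosis 3, not 0
})

test_that("pooled mean of merged sub-groups is the weighted average", {
  set.seed(7)
  a <- data.frame(pta = runif(11, 0, 15), pbmax = sample(0:25, 11, TRUE) * 4)
  b <- data.frame(pta = runif(17, 16, 25), pbmax = sample(0:25, 17, TRUE) * 4)
  pooled <- summarize_subgroup(rbind(a, b))
  brute <- sum(c(a$pbmax, b$pbmax)) / (nrow(a) + nrow(b))
  expect_equal(pooled$mean_pbmax, brute)
  expect_equal(pooled$mean_pbmax,
               (11 * mean(a$pbmax) + 17 * mean(b$pbmax)) / 28)
})

test_that("subgroup_table mirrors per-bin summaries", {
  coh <- gen_cohort(200, cohort_model(), seed = 3)
  tab <- subgroup_table(coh, pta_scheme("group1"))
  expect_equal(sum(tab$n), nrow(coh))
  g <- assign_subgroup(coh$pta, pta_scheme("group1"))
  lab <- as.character(tab$label[1])
  expect_equal(tab$mean_pbmax[1], mean(coh$pbmax[g == lab]))
})
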
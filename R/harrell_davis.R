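# Method 2: the Harrell-Davis quantile estimator.
#
# A distribution-free estimator of the q-quantile that weights every order
# statistic by an increment of a Beta distribution function, which smooths
# across observations and behaves well for extreme quantiles in small
# sub-groups where a single order statistic would be noisy.

# Weight cache: weights depend only on (n, q).
.hd_cache <- new.env(parent = emptyenv())

#' Harrell-Davis order-statistic weights
#'
#' Weight `i` is the mass the Beta((n+1)q, (n+1)(1-q)) distribution assigns
#' to the interval \[(i-1)/n, i/n\]; the estimator is the weighted sum of the
#' ascending order statistics. Weights are non-negative and sum to 1; they
#' are cached per `(n, q)`.
#'
#' @param n Sample size (>= 1).
#' @param q Quantile level in (0, 1).
#' @return Numeric weight vector of length `n`.
#' @examples
#' hd_weights(3, 0.5)  # symmetric: w[1] == w[3]
#' @export
hd_weights <- function(n, q) {
  stopifnot(n >= 1, q > 0, q < 1)
  key <- paste(n, q, sep = "|")
  w <- .hd_cache[[key]]
  if (!is.null(w)) return(w)
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  edges <- stats::pbeta((0:n) / n, a, b)
  w <- diff(edges)
  .hd_cache[[key]] <- w
  w
}

#' Harrell-Davis quantile estimate
#'
#' @param sample Numeric vector of scores (percent); must be non-empty.
#' @param q Quantile level in (0, 1): 0.05 gives the lower 95% confidence
#'   limit, 0.5 the median.
#' @return The estimate, always within `range(sample)`.
#' @examples
#' hd_quantile(c(1, 2, 3), 0.5)  # 2
#' @export
hd_quantile <- function(sample, q) {
  sample <- sample[is.finite(sample)]
  if (!length(sample)) stop("empty sample")
  sum(hd_weights(length(sample), q) * sort(sample))
}

#' Bootstrap standard error of a Harrell-Davis quantile
#'
#' Draws `n_boot` resamples of the same size with replacement, re-estimates
#' the quantile on each, and reports the SD (n-1 denominator) across
#' resamples.
#'
#' @param sample Numeric vector (length >= 2).
#' @param q Quantile level in (0, 1).
#' @param n_boot Number of resamples (>= 100).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return The bootstrap SE (percent).
#' @export
hd_bootstrap_se <- function(sample, q, n_boot = 1000, seed = 1L) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  stopifnot(n >= 2, n_boot >= 100)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i)
    hd_quantile(sample[sample.int(n, replace = TRUE)], q), numeric(1))
  stats::sd(reps)
}

# Per-bin Harrell-Davis estimates plus fitted link curves; shared backend of
# fit_cl(method = "hd").
method2_curve <- function(records, scheme = pta_scheme("group1"),
                          n_boot = 1000, seed = 1L, boot_se = FALSE) {
  tab <- subgroup_table(records, scheme)
  small <- tab$n < 10
  if (any(small))
    message("sub-group(s) with n < 10 (", paste(tab$label[small],
            collapse = ", "), "): quantile estimates may be unstable")
  usable <- tab$n >= 2
  if (any(!usable))
    warning("dropping sub-group(s) with n < 2: ",
            paste(tab$label[!usable], collapse = ", "))
  g <- assign_subgroup(records$pta, scheme)
  cl <- med <- se <- rep(NA_real_, nrow(tab))
  for (i in which(usable)) {
    y <- records$pbmax[g == tab$label[i]]
    cl[i] <- hd_quantile(y, 0.05)
    med[i] <- hd_quantile(y, 0.5)
    if (boot_se)
      se[i] <- hd_bootstrap_se(y, 0.05, n_boot = n_boot, seed = seed + i)
  }
  tab$median_hd <- med
  tab$cl_value <- cl
  tab$cl_se <- se
  ok <- usable & is.finite(cl)
  list(
    subgroups = tab,
    cl_curve = fit_curve_ls(data.frame(pta = tab$mean_pta[ok],
                                       value = cl[ok])),
    median_curve = fit_curve_ls(data.frame(pta = tab$mean_pta[ok],
                                           value = med[ok]))
  )
}
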
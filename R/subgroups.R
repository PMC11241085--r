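#' PTA sub-grouping schemes
#'
#' The simulation and Harrell-Davis methods require dividing ears into PTA
#' sub-groups. Four conventional schemes are built in:
#'
#' * `"group1"`: nine 10-dB bins, `<15`, `16-25`, ..., `86-120`;
#' * `"group2"`: nine 10-dB bins shifted by 5 dB, `<10`, `11-20`, ..., `81-120`;
#' * `"group3"`: fourteen 5-dB bins up to 60 dB HL, then `61-70`, `71-80`,
#'   `81-120`;
#' * `"group4"`: six 15-dB bins, `<15`, `16-30`, ..., `76-120`.
#'
#' Because the conventional labels leave gaps (a label of `16-25` says nothing
#' about a PTA of 15.5), bins are implemented as contiguous intervals with cut
#' points at label midpoints: `<15` means PTA <= 15.5, `16-25` means
#' 15.5 < PTA <= 25.5, and so on. PTAs are multiples of 1.25 dB, so no
#' observable value ever falls on a cut point, and every value in \[0, 120\]
#' is assignable.
#'
#' @param name One of `"group1"`, `"group2"`, `"group3"`, `"group4"`, or a
#'   label for a custom scheme built from `breaks`.
#' @param breaks For a custom scheme: increasing cut points including both
#'   endpoints (first bin is `[breaks[1], breaks[2]]`, later bins are
#'   half-open on the left).
#' @param labels Optional bin labels for a custom scheme.
#' @return An object of class `"pta_scheme"` with elements `name`, `breaks`,
#'   `labels`.
#' @examples
#' pta_scheme("group1")$labels
#' @export
pta_scheme <- function(name = "group1", breaks = NULL, labels = NULL) {
  if (is.null(breaks)) {
    builtin <- list(
      group1 = c(0, 15.5, 25.5, 35.5, 45.5, 55.5, 65.5, 75.5, 85.5, 120),
      group2 = c(0, 10.5, 20.5, 30.5, 40.5, 50.5, 60.5, 70.5, 80.5, 120),
      group3 = c(0, 10.5, 15.5, 20.5, 25.5, 30.5, 35.5, 40.5, 45.5, 50.5,
                 55.5, 60.5, 70.5, 80.5, 120),
      group4 = c(0, 15.5, 30.5, 45.5, 60.5, 75.5, 120)
    )
    lab <- list(
      group1 = c("<15", "16-25", "26-35", "36-45", "46-55", "56-65", "66-75",
                 "76-85", "86-120"),
      group2 = c("<10", "11-20", "21-30", "31-40", "41-50", "51-60", "61-70",
                 "71-80", "81-120"),
      group3 = c("<10", "11-15", "16-20", "21-25", "26-30", "31-35", "36-40",
                 "41-45", "46-50", "51-55", "56-60", "61-70", "71-80",
                 "81-120"),
      group4 = c("<15", "16-30", "31-45", "46-60", "61-75", "76-120")
    )
    name <- match.arg(name, names(builtin))
    breaks <- builtin[[name]]
    labels <- lab[[name]]
  } else {
    if (is.unsorted(breaks, strictly = TRUE))
      stop("breaks must be strictly increasing")
    if (is.null(labels))
      labels <- paste(utils::head(breaks, -1L), breaks[-1L], sep = "-")
    if (length(labels) != length(breaks) - 1L)
      stop("need one label per bin")
  }
  structure(list(name = name, breaks = breaks, labels = labels),
            class = "pta_scheme")
}

#' @export
print.pta_scheme <- function(x, ...) {
  cat("PTA sub-grouping scheme '", x$name, "': ", length(x$labels),
      " bins over [", x$breaks[1], ", ", max(x$breaks), "] dB HL\n", sep = "")
  cat("  ", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

#' Assign ears to PTA sub-groups
#'
#' @param pta Numeric vector of PTA values (dB HL), or a cohort data.frame
#'   with a `pta` column.
#' @param scheme A [pta_scheme()].
#' @return Factor of bin labels, one per ear, levels in scheme order.
#' @examples
#' assign_subgroup(c(10.2, 60.2), pta_scheme("group1"))
#' @export
assign_subgroup <- function(pta, scheme = pta_scheme("group1")) {
  if (is.data.frame(pta)) pta <- pta$pta
  stopifnot(inherits(scheme, "pta_scheme"))
  out <- cut(pta, breaks = scheme$breaks, labels = scheme$labels,
             include.lowest = TRUE, right = TRUE)
  if (anyNA(out) && !anyNA(pta))
    stop("PTA value(s) outside the scheme's range [",
         scheme$breaks[1], ", ", max(scheme$breaks), "]: ",
         paste(utils::head(pta[is.na(out)], 5L), collapse = ", "))
  out
}

# Third and fourth standardized moments (moment estimators; kurtosis is
# non-excess, i.e. a normal law gives 3).
.skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}
.kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^4) / s2^2
}

#' Distribution summary of one PTA sub-group
#'
#' Computes, for the PBmax scores of one sub-group: n, mean PTA, mean, SD
#' (n-1 denominator), skewness and kurtosis (third and fourth standardized
#' moments; kurtosis is non-excess so a normal sample gives about 3), and the
#' sample median. With zero variance the shape statistics are undefined and
#' reported as `NA`.
#'
#' @param records Cohort data.frame with `pta` and `pbmax` columns.
#' @return One-row data.frame: `n`, `mean_pta`, `mean_pbmax`, `sd_pbmax`,
#'   `skewness`, `kurtosis`, `median_pbmax`.
#' @export
summarize_subgroup <- function(records) {
  y <- records$pbmax
  n <- length(y)
  data.frame(
    n = n,
    mean_pta = mean(records$pta),
    mean_pbmax = mean(y),
    sd_pbmax = if (n >= 2) stats::sd(y) else NA_real_,
    skewness = if (n >= 3) .skewness(y) else NA_real_,
    kurtosis = if (n >= 3) .kurtosis(y) else NA_real_,
    median_pbmax = stats::median(y)
  )
}

#' Per-bin distribution summaries for a whole cohort
#'
#' @param records Cohort data.frame (`pta`, `pbmax`).
#' @param scheme A [pta_scheme()]; empty bins are dropped.
#' @return Data.frame with one row per occupied bin, a `label` column plus the
#'   [summarize_subgroup()] columns.
#' @export
subgroup_table <- function(records, scheme = pta_scheme("group1")) {
  g <- assign_subgroup(records$pta, scheme)
  parts <- split(records, g, drop = FALSE)
  parts <- parts[vapply(parts, nrow, 0L) > 0L]
  out <- do.call(rbind, lapply(parts, summarize_subgroup))
  out <- cbind(label = factor(names(parts), levels = scheme$labels), out)
  rownames(out) <- NULL
  out
}
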
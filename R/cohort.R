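#' Pure-tone average of the four standard audiometric frequencies
#'
#' The PTA is the arithmetic mean of the air-conduction hearing threshold
#' levels at 0.5, 1, 2 and 4 kHz, computed separately for each ear. It is the
#' standard single-number index of peripheral hearing loss and the predictor
#' variable for every confidence-limit curve in this package.
#'
#' @param htl_500,htl_1000,htl_2000,htl_4000 Air-conduction thresholds in
#'   dB HL at 0.5, 1, 2 and 4 kHz. Vectorised; recycled to a common length.
#' @return Numeric vector of PTA values in dB HL.
#' @examples
#' compute_pta(20, 30, 40, 50)  # 35
#' @export
compute_pta <- function(htl_500, htl_1000, htl_2000, htl_4000) {
  htl <- cbind(htl_500, htl_1000, htl_2000, htl_4000)
  if (anyNA(htl) || any(!is.finite(htl)))
    stop("all four thresholds must be finite to compute a PTA")
  rowMeans(htl)
}

#' Flag a conductive hearing-loss component from the air-bone gap
#'
#' An ear is flagged as having a conductive component (and is excluded from
#' the sensorineural norms) when the air-bone gap is at least 15 dB at two or
#' more of the frequencies 0.5, 1 and 2 kHz.
#'
#' @param air_htls,bone_htls Numeric vectors of length 3 giving air- and
#'   bone-conduction thresholds (dB HL) at 0.5, 1 and 2 kHz, in that order.
#'   `bone_htls = NULL` (or all-`NA`) means bone conduction was not measured:
#'   the rule cannot be applied, the ear passes, and a warning is issued.
#' @return `TRUE` if the ear should be excluded as conductive, else `FALSE`.
#' @examples
#' flag_conductive(c(40, 40, 40), c(20, 20, 40))  # TRUE: two 20-dB gaps
#' flag_conductive(c(40, 40, 40), c(20, 30, 40))  # FALSE: one gap >= 15
#' @export
flag_conductive <- function(air_htls, bone_htls) {
  if (is.null(bone_htls) || all(is.na(bone_htls))) {
    warning("bone-conduction thresholds absent; conductive rule not applied")
    return(FALSE)
  }
  if (length(air_htls) != 3L || length(bone_htls) != 3L)
    stop("air_htls and bone_htls must each give thresholds at 0.5, 1, 2 kHz")
  gap <- air_htls - bone_htls
  sum(gap >= 15, na.rm = TRUE) >= 2L
}

#' Round a score to the nearest multiple of a step
#'
#' Speech identification scores from 25-item lists are integer multiples of
#' 4 percent; continuous quantities (simulated scores, estimated confidence
#' limits) are mapped back onto that lattice. Exact half-distances round away
#' from zero.
#'
#' @param value Numeric vector, in percent.
#' @param step Positive lattice step, default 4 (percent).
#' @return `value` rounded to the nearest integer multiple of `step`.
#' @examples
#' round_to_step(86.99)  # 88
#' round_to_step(78.36)  # 80
#' @export
round_to_step <- function(value, step = 4) {
  stopifnot(is.numeric(step), length(step) == 1L, step > 0)
  sign(value) * floor(abs(value) / step + 0.5) * step
}

# Validate a cohort data.frame of per-ear records; returns it invisibly or
# stops with row-numbered messages. Used by read_cohort() and the fitters.
validate_records <- function(records, strict_step = FALSE) {
  need <- c("pta", "pbmax")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort records lack required column(s): ", paste(miss, collapse = ", "))
  bad <- !is.finite(records$pta) | !is.finite(records$pbmax) |
    records$pbmax < 0 | records$pbmax > 100
  if (any(bad))
    stop("invalid cohort rows (missing PTA/PBmax or PBmax outside [0,100]): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  off <- abs(records$pbmax - round_to_step(records$pbmax, 4)) > 1e-8
  if (any(off)) {
    msg <- paste0(sum(off), " row(s) have PBmax not a multiple of 4 (rows ",
                  paste(utils::head(which(off), 10L), collapse = ", "), ")")
    if (strict_step) stop(msg) else warning(msg)
  }
  invisible(records)
}

#' Read a per-ear audiometric cohort from CSV
#'
#' Expected columns: `participant_id`, `ear` (`"L"`/`"R"`), a `pbmax` score in
#' percent, and either a precomputed `pta` column or the four air-conduction
#' threshold columns `htl_500`, `htl_1000`, `htl_2000`, `htl_4000` (dB HL).
#' Optional bone-conduction columns `bone_500`, `bone_1000`, `bone_2000`
#' trigger the conductive-loss exclusion rule (see [flag_conductive()]);
#' flagged ears are dropped with a message.
#'
#' Rows with missing PTA/PBmax or PBmax outside \[0, 100\] are rejected and
#' reported with their row numbers. Scores that are not multiples of 4 warn by
#' default (`strict = TRUE` rejects the file instead), since 25-item lists
#' can only produce multiples of 4.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict Reject (rather than warn about) scores off the 4% lattice.
#' @return A data.frame with columns `participant_id`, `ear`, `pta`, `pbmax`.
#' @export
read_cohort <- function(path, strict = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"pbmax" %in% names(raw)) stop("cohort file has no 'pbmax' column")
  if (!"pta" %in% names(raw)) {
    thr <- c("htl_500", "htl_1000", "htl_2000", "htl_4000")
    if (!all(thr %in% names(raw)))
      stop("cohort file needs a 'pta' column or all of: ",
           paste(thr, collapse = ", "))
    ok <- stats::complete.cases(raw[thr])
    if (!all(ok))
      stop("missing threshold(s) in rows: ",
           paste(utils::head(which(!ok), 10L), collapse = ", "),
           if ("participant_id" %in% names(raw))
             paste0(" (participants ",
                    paste(utils::head(raw$participant_id[!ok], 10L),
                          collapse = ", "), ")") else "")
    raw$pta <- compute_pta(raw$htl_500, raw$htl_1000, raw$htl_2000,
                           raw$htl_4000)
  }
  keep <- is.finite(raw$pta) & is.finite(raw$pbmax) &
    raw$pbmax >= 0 & raw$pbmax <= 100
  if (!all(keep)) {
    warning("rejected ", sum(!keep), " invalid row(s): ",
            paste(utils::head(which(!keep), 10L), collapse = ", "))
    raw <- raw[keep, , drop = FALSE]
  }
  bone <- c("bone_500", "bone_1000", "bone_2000")
  if (all(bone %in% names(raw))) {
    air <- c("htl_500", "htl_1000", "htl_2000")
    if (all(air %in% names(raw))) {
      cond <- vapply(seq_len(nrow(raw)), function(i) {
        b <- as.numeric(raw[i, bone])
        if (all(is.na(b))) FALSE
        else flag_conductive(as.numeric(raw[i, air]), b)
      }, logical(1))
      if (any(cond)) {
        message("excluded ", sum(cond), " ear(s) with a conductive component")
        raw <- raw[!cond, , drop = FALSE]
      }
    }
  }
  if (!"participant_id" %in% names(raw))
    raw$participant_id <- seq_len(nrow(raw))
  if (!"ear" %in% names(raw)) raw$ear <- "R"
  out <- raw[c("participant_id", "ear", "pta", "pbmax")]
  rownames(out) <- NULL
  validate_records(out, strict_step = strict)
  out
}
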
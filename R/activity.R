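# Reporter-activity and binding-titration statistics: percent-of-reference
# normalization with SEM, fold-range, additivity of combined mutations, and
# titration-threshold relative affinity.

#' Replicate reporter-intensity measurements for one construct
#'
#' @param construct_id Construct identifier.
#' @param intensities Positive replicate intensities (arbitrary
#'   fluorescence units), `n >= 1`.
#' @param segment Body-segment label the measurements were taken in
#'   (default `"A6"`).
#' @param sex Sex label (default `"female"`).
#' @return An object of class `activity_measurements`.
#' @export
activity_measurements <- function(construct_id, intensities,
                                  segment = "A6", sex = "female") {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 1L || any(!is.finite(intensities)) ||
      any(intensities <= 0))
    stop("intensities must be positive and non-empty")
  structure(list(construct_id = construct_id, intensities = intensities,
                 segment = segment, sex = sex),
            class = "activity_measurements")
}

#' Normalize a construct's activity to a reference
#'
#' `percent = 100 * mean(test) / mean(ref)`; the SEM is the test sample SEM
#' (n-1 standard deviation over sqrt(n)) on the same percent scale. The
#' reference's own uncertainty is not propagated, matching the per-construct
#' "mean +/- SEM" reporting convention; the reference normalized to itself
#' is 100%.
#'
#' @param test,ref [activity_measurements()] with matching segment and sex
#'   labels.
#' @return An object of class `normalized_activity`: `construct_id`,
#'   `percent`, `sem_percent`, `n`.
#' @export
normalize_activity <- function(test, ref) {
  stopifnot(inherits(test, "activity_measurements"),
            inherits(ref, "activity_measurements"))
  if (test$segment != ref$segment || test$sex != ref$sex)
    stop("segment/sex label mismatch between test and reference")
  mref <- mean(ref$intensities)
  if (mref == 0) stop("zero reference mean")
  n <- length(test$intensities)
  sem <- if (n > 1L) stats::sd(test$intensities) / sqrt(n) else 0
  structure(list(construct_id = test$construct_id,
                 percent = 100 * mean(test$intensities) / mref,
                 sem_percent = 100 * sem / mref,
                 n = n),
            class = "normalized_activity")
}

#' @export
print.normalized_activity <- function(x, ...) {
  cat(sprintf("<normalized_activity> %s: %.1f +/- %.1f%% (n = %d)\n",
              x$construct_id, x$percent, x$sem_percent, x$n))
  invisible(x)
}

#' Fold-range across allele activities
#'
#' @param percents Positive activity means.
#' @return `max(percents) / min(percents)` (always >= 1).
#' @export
fold_range <- function(percents) {
  percents <- as.numeric(percents)
  if (length(percents) < 1L || any(percents <= 0))
    stop("percents must be positive and non-empty")
  max(percents) / min(percents)
}

#' Additivity analysis for combined mutations
#'
#' On a percent-of-reference scale where the reference is 100, the additive
#' expectation for a combination is `100 + sum(single_i - 100)`; the
#' deviation is `observed - expected`.
#'
#' @param singles Percent means of the single-mutation constructs.
#' @param combined_observed Percent mean of the combined construct.
#' @return A list with `expected` and `deviation`.
#' @export
additivity <- function(singles, combined_observed) {
  singles <- as.numeric(singles)
  if (length(singles) < 1L) stop("empty singles")
  expected <- 100 + sum(singles - 100)
  list(expected = expected, deviation = combined_observed - expected)
}

#' A binding titration series
#'
#' Ordered protein amounts with a per-lane detection call. Detection must be
#' monotone: once a shift is detected it must stay detected at every higher
#' amount (violations are validation errors, not smoothed over).
#'
#' @param probe_id Probe identifier.
#' @param amounts_ng Strictly increasing protein amounts (ng).
#' @param detected Logical vector, one call per amount.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(probe_id, amounts_ng, detected) {
  amounts_ng <- as.numeric(amounts_ng)
  detected <- as.logical(detected)
  if (length(amounts_ng) != length(detected) || length(amounts_ng) < 1L)
    stop("amounts and detection calls must be non-empty and equal length")
  if (any(diff(amounts_ng) <= 0)) stop("amounts must be strictly increasing")
  if (any(diff(detected) < 0))
    stop("detection must be monotone non-decreasing once true")
  structure(list(probe_id = probe_id, amounts_ng = amounts_ng,
                 detected = detected), class = "titration_series")
}

#' Relative binding affinity from titration detection thresholds
#'
#' `100 * (minimal detected amount in the reference) / (minimal detected
#' amount in the variant)`. The estimate's granularity is that of the
#' titration step (no interpolation); a variant never detected is an error.
#'
#' @param reference,variant [titration_series()] objects.
#' @return Relative affinity in percent.
#' @export
relative_affinity <- function(reference, variant) {
  stopifnot(inherits(reference, "titration_series"),
            inherits(variant, "titration_series"))
  thr <- function(ts, who) {
    i <- which(ts$detected)
    if (!length(i)) stop("undetectable affinity: ", who,
                         " series has no detected amount")
    ts$amounts_ng[i[1L]]
  }
  100 * thr(reference, "reference") / thr(variant, "variant")
}

#' Read a replicate-measurements TSV
#'
#' Expected columns: `construct_id`, `segment`, `sex`, `replicate`,
#' `intensity`.
#'
#' @param path TSV path with a header row.
#' @return Named list of [activity_measurements()], one per
#'   (construct, segment, sex) combination, named by construct id.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "segment", "sex", "intensity")
  if (!all(need %in% names(tab)))
    stop("measurements TSV must have columns: ", paste(need, collapse = ", "))
  sp <- split(tab, list(tab$construct_id, tab$segment, tab$sex), drop = TRUE)
  out <- lapply(sp, function(d)
    activity_measurements(d$construct_id[1], d$intensity,
                          segment = d$segment[1], sex = d$sex[1]))
  names(out) <- vapply(out, function(x) x$construct_id, character(1))
  out
}
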
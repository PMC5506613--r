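#' Segment a global impedance curve into breaths
#'
#' End-expiration points are local minima of the (cardiac-filtered) global
#' curve and end-inspiration is the unique local maximum between consecutive
#' minima. Noise-born extrema are suppressed with a minimum-prominence rule:
#' alternating extrema whose swing is below `prominence_fraction` of the
#' median peak-to-trough swing are merged away. Partial breaths at both ends
#' of the recording are discarded, and the longest run of consecutive
#' artifact-free breaths (earliest on ties) is marked as the analysis
#' selection; a breath is artifact-free when its inspiratory swing is at
#' least half the median swing and its duration within 0.5-2 times the
#' median duration.
#'
#' @param curve an `eit_curve`, already low-pass filtered.
#' @param min_breaths minimum number of selected breaths (default 10; a
#'   sequence yielding fewer is rejected).
#' @param prominence_fraction swing threshold as a fraction of the median
#'   peak-to-trough swing (default 0.10).
#' @return object of class `breath_seg`: data frame `breaths` with columns
#'   `start` (end-expiration index opening the breath), `peak`
#'   (end-inspiration index), `end` (closing end-expiration index, shared
#'   with the next breath) and `selected`; plus `sampling_rate`. Indices are
#'   1-based frame indices.
#' @export
detect_breaths <- function(curve, min_breaths = 10,
                           prominence_fraction = 0.10) {
  stopifnot(inherits(curve, "eit_curve"))
  x <- curve$values
  ext <- alternating_extrema(x)
  ext <- prune_extrema(x, ext, prominence_fraction)
  kinds <- ext$kind
  idx <- ext$index
  mins <- idx[kinds == "min"]
  if (length(mins) < 2L)
    stop("insufficient breaths: no complete breathing cycle found", call. = FALSE)
  breaths <- data.frame(start = mins[-length(mins)], end = mins[-1])
  breaths$peak <- vapply(seq_len(nrow(breaths)), function(i) {
    span <- breaths$start[i]:breaths$end[i]
    span[which.max(x[span])]
  }, numeric(1))
  breaths <- breaths[, c("start", "peak", "end")]

  swing <- x[breaths$peak] - x[breaths$start]
  dur <- breaths$end - breaths$start
  ok <- swing >= 0.5 * stats::median(swing) &
    dur >= 0.5 * stats::median(dur) & dur <= 2 * stats::median(dur)
  breaths$selected <- in_longest_run(ok)
  if (sum(breaths$selected) < min_breaths)
    stop(sprintf(
      "insufficient breaths: %d artifact-free consecutive cycles, %d required",
      sum(breaths$selected), min_breaths), call. = FALSE)
  structure(list(breaths = breaths, sampling_rate = curve$sampling_rate),
            class = "breath_seg")
}

#' Respiratory rate from a breath segmentation
#'
#' @param seg a `breath_seg` from [detect_breaths()].
#' @param sampling_rate sampling rate in Hz; defaults to the rate stored in
#'   `seg`.
#' @return breaths per minute: `60 / mean selected breath duration`.
#' @export
respiratory_rate <- function(seg, sampling_rate = seg$sampling_rate) {
  sel <- seg$breaths[seg$breaths$selected, ]
  if (nrow(sel) < 2L)
    stop("need >= 2 selected breaths for a respiratory rate", call. = FALSE)
  60 / mean((sel$end - sel$start) / sampling_rate)
}

# strictly alternating interior extrema of x (plateau-tolerant)
alternating_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) stop("insufficient breaths: curve is constant", call. = FALSE)
  # carry the previous nonzero slope through plateaus
  run <- s
  last <- 0
  for (i in seq_along(run)) {
    if (run[i] == 0) run[i] <- last else last <- run[i]
  }
  turns <- which(diff(run) != 0 & run[-length(run)] != 0) + 1L
  if (length(turns) == 0L)
    stop("insufficient breaths: curve is monotone (no cycles)", call. = FALSE)
  kind <- ifelse(run[turns - 1L] > 0, "max", "min")
  list(index = turns, kind = kind)
}

# iteratively merge alternating extrema with sub-threshold swings
prune_extrema <- function(x, ext, prominence_fraction) {
  repeat {
    idx <- ext$index; kind <- ext$kind
    if (length(idx) < 3L) break
    swing <- abs(diff(x[idx]))
    thr <- prominence_fraction * stats::median(swing)
    bad <- which(swing < thr)
    if (length(bad) == 0L) break
    # drop the extremum pair with the smallest swing, then re-alternate
    j <- bad[which.min(swing[bad])]
    keep <- setdiff(seq_along(idx), c(j, j + 1L))
    idx <- idx[keep]; kind <- kind[keep]
    # enforce alternation: among same-kind neighbours keep the more extreme
    i <- 2L
    while (i <= length(idx)) {
      if (kind[i] == kind[i - 1L]) {
        better_prev <- if (kind[i] == "max") x[idx[i - 1L]] >= x[idx[i]]
                       else x[idx[i - 1L]] <= x[idx[i]]
        drop_i <- if (better_prev) i else i - 1L
        idx <- idx[-drop_i]; kind <- kind[-drop_i]
      } else i <- i + 1L
    }
    ext <- list(index = idx, kind = kind)
  }
  ext
}

# logical vector marking the longest TRUE run (earliest on ties)
in_longest_run <- function(ok) {
  r <- rle(ok)
  out <- rep(FALSE, length(ok))
  true_runs <- which(r$values)
  if (length(true_runs) == 0L) return(out)
  best <- true_runs[which.max(r$lengths[true_runs])]
  start <- sum(r$lengths[seq_len(best - 1L)]) + 1L
  out[start:(start + r$lengths[best] - 1L)] <- TRUE
  out
}
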
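#' Tidal impedance variation (TIV)
#'
#' Mean over the selected breaths of the global-curve difference between
#' end-inspiration and the end-expiration opening each breath, expressed in
#' AU and as a percentage of a baseline session's TIV (the baseline itself
#' is 100%).
#'
#' @param curve the masked global `eit_curve` of the session.
#' @param seg its `breath_seg`; at least 10 selected breaths are required.
#' @param baseline_tiv_au baseline TIV in AU, or `NULL` when this session is
#'   the baseline.
#' @param min_breaths minimum selected breaths (default 10).
#' @return list with `tiv_au` and `tiv_percent`.
#' @export
tiv <- function(curve, seg, baseline_tiv_au = NULL, min_breaths = 10) {
  stopifnot(inherits(curve, "eit_curve"), inherits(seg, "breath_seg"))
  sel <- seg$breaths[seg$breaths$selected, ]
  if (nrow(sel) < min_breaths)
    stop(sprintf("TIV needs >= %d selected breaths, got %d",
                 min_breaths, nrow(sel)), call. = FALSE)
  x <- curve$values
  tiv_au <- mean(x[sel$peak] - x[sel$start])
  if (tiv_au <= 0)
    stop("invalid breath landmarks: non-positive tidal swing", call. = FALSE)
  pct <- if (is.null(baseline_tiv_au)) 100 else 100 * tiv_au / baseline_tiv_au
  list(tiv_au = tiv_au, tiv_percent = pct)
}

#' End-expiratory lung impedance change (dEELI)
#'
#' The session EELI is the mean of the global curve at the selected
#' end-expiration minima (the same preselected breaths used for TIV). Its
#' change from baseline is normalized by the baseline TIV, so -65% means a
#' baseline shift equal to 0.65 baseline tidal swings — AU offsets are not
#' comparable across sessions, a tidal-swing yardstick is.
#'
#' @param curve the masked global `eit_curve`.
#' @param seg its `breath_seg`.
#' @param baseline_eeli_au baseline session EELI, AU (`NULL` for the
#'   baseline session itself).
#' @param baseline_tiv_au baseline TIV, AU (the normalizer).
#' @return list with `eeli_au` and `delta_eeli_percent` (0 for the
#'   baseline session).
#' @export
delta_eeli <- function(curve, seg, baseline_eeli_au = NULL,
                       baseline_tiv_au = NULL) {
  stopifnot(inherits(curve, "eit_curve"), inherits(seg, "breath_seg"))
  sel <- seg$breaths[seg$breaths$selected, ]
  eeli_au <- mean(curve$values[sel$start])
  if (is.null(baseline_eeli_au))
    return(list(eeli_au = eeli_au, delta_eeli_percent = 0))
  if (is.null(baseline_tiv_au) || baseline_tiv_au <= 0)
    stop("baseline TIV (positive, AU) required to normalize dEELI", call. = FALSE)
  list(eeli_au = eeli_au,
       delta_eeli_percent = 100 * (eeli_au - baseline_eeli_au) / baseline_tiv_au)
}

#' Global inhomogeneity index (GI)
#'
#' Sum over lung-mask pixels of the absolute deviation of each pixel's DI
#' from the median lung DI, normalized by the total lung DI:
#' `GI = sum(|DI_xy - median(DI_lung)|) / sum(DI_xy)`. Zero for perfectly
#' homogeneous ventilation; it grows with spatial heterogeneity. The raw
#' value lies near 0-1; clinical reports print it scaled by 100, so both
#' scales are returned.
#'
#' @param img a [tidal_image()].
#' @param mask a [build_lung_mask()] result (median and sums run over mask
#'   pixels only).
#' @return list with `gi` (raw) and `gi_reported` (`100 * gi`).
#' @export
gi_index <- function(img, mask) {
  stopifnot(inherits(img, "tidal_image"), inherits(mask, "lung_mask"))
  if (!any(mask$member)) stop("empty lung mask", call. = FALSE)
  di <- img$di[mask$member]
  tot <- sum(di)
  if (tot <= 0) stop("GI undefined: total lung DI is non-positive", call. = FALSE)
  g <- sum(abs(di - stats::median(di))) / tot
  list(gi = g, gi_reported = 100 * g)
}

#' Regional ventilation delay under spontaneous breathing (spRVD)
#'
#' For each selected breath and lung pixel, the delay between the global
#' inspiration onset (the end-expiration minimum of the global curve) and
#' the moment the pixel's impedance rise first reaches `threshold_percent`
#' of that pixel's tidal amplitude for the breath, as a percentage of the
#' global inspiration duration:
#' `RVD_i = dt_i / (tmax - tmin) * 100`, clamped to `[0, 100]`. A pixel that
#' never reaches its threshold during inspiration is assigned 100 (the
#' latest possible delay) and counted as a warning. Pixel values are
#' summarized per breath by the across-pixel standard deviation (the
#' heterogeneity reading; `summary = "mean"` gives the average delay) and
#' then averaged over the selected breaths.
#'
#' @param seq the *filtered* [frame_sequence()].
#' @param seg its `breath_seg`.
#' @param mask a [build_lung_mask()] result.
#' @param threshold_percent amplitude threshold, one of 40, 60, 80.
#' @param summary `"sd"` (default) or `"mean"`.
#' @return list with `value` (%), `summary`, `threshold_percent`, and
#'   `n_unreached` (clamp warnings counted across breaths and pixels).
#' @export
sp_rvd <- function(seq, seg, mask, threshold_percent = 40,
                   summary = c("sd", "mean")) {
  stopifnot(inherits(seq, "eit_frames"), inherits(seg, "breath_seg"),
            inherits(mask, "lung_mask"))
  summary <- match.arg(summary)
  if (!threshold_percent %in% c(40, 60, 80))
    stop("threshold_percent must be 40, 60 or 80", call. = FALSE)
  sel <- seg$breaths[seg$breaths$selected, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no selected breaths", call. = FALSE)
  mat <- as_pixel_matrix(seq)
  px <- which(as.vector(mask$member))
  thr <- threshold_percent / 100
  per_breath <- numeric(nrow(sel))
  n_unreached <- 0L
  for (b in seq_len(nrow(sel))) {
    tmin <- sel$start[b]; tmax <- sel$peak[b]
    win <- mat[tmin:tmax, px, drop = FALSE]
    base <- win[1L, ]
    amp <- apply(win, 2L, max) - base
    target <- base + thr * amp
    nwin <- nrow(win)
    cross <- vapply(seq_along(px), function(j) {
      k <- which(win[, j] >= target[j])[1L]
      if (is.na(k)) NA_integer_ else k
    }, integer(1))
    miss <- is.na(cross) | amp <= 0
    n_unreached <- n_unreached + sum(miss)
    dt <- (cross - 1L) / (nwin - 1L)  # fraction of inspiration
    dt[miss] <- 1
    rvd <- pmin(pmax(100 * dt, 0), 100)
    per_breath[b] <- if (summary == "sd") stats::sd(rvd) else mean(rvd)
  }
  if (n_unreached > 0L)
    warning(sprintf("spRVD: %d pixel-breaths never reached %d%% during inspiration (clamped to 100)",
                    n_unreached, threshold_percent), call. = FALSE)
  list(value = mean(per_breath), summary = summary,
       threshold_percent = threshold_percent, n_unreached = n_unreached)
}

#' EIT-derived rapid shallow breathing index
#'
#' Respiratory rate over normalized tidal impedance variation,
#' `RR / (TIV% / 100)`. With TIV as the tidal-volume surrogate the index
#' rises under rapid shallow breathing, mirroring the bedside RSBI
#' (= RR / VT).
#'
#' @param rr respiratory rate, breaths per minute.
#' @param tiv_percent TIV as % of baseline (> 0).
#' @return unitless index (equals `rr` at baseline where TIV = 100%).
#' @export
rsbi_eit <- function(rr, tiv_percent) {
  if (tiv_percent <= 0) stop("tiv_percent must be > 0", call. = FALSE)
  rr / (tiv_percent / 100)
}
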
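#' Analysis configuration
#'
#' Bundles the tunable pipeline parameters with their documented defaults.
#'
#' @param cutoff_per_min low-pass cutoff, min^-1 (default 50, between the
#'   respiratory and cardiac bands).
#' @param filter_order Butterworth order of the one-way filter (default 4).
#' @param pixelwise filter every pixel trace (default `TRUE`); if `FALSE`
#'   only the global curve is filtered.
#' @param mask_threshold lung-mask threshold fraction of the maximum DI
#'   (default 0.20).
#' @param rvd_thresholds amplitude thresholds for spRVD, % (default
#'   `c(40, 60, 80)`).
#' @param rvd_summary `"sd"` (default) or `"mean"` as the primary spRVD
#'   summary; both are always emitted.
#' @param min_breaths minimum selected breaths per session (default 10).
#' @param prominence_fraction swing threshold for breath detection
#'   (default 0.10).
#' @param roc_cutoff GI cutoff (reported scale) for the default operating
#'   point (default 41.5).
#' @param seed integer seed recorded in provenance output.
#' @return a named list of class `eit_config`.
#' @export
eit_config <- function(cutoff_per_min = 50, filter_order = 4,
                       pixelwise = TRUE, mask_threshold = 0.20,
                       rvd_thresholds = c(40, 60, 80),
                       rvd_summary = "sd", min_breaths = 10,
                       prominence_fraction = 0.10, roc_cutoff = 41.5,
                       seed = 1L) {
  structure(list(cutoff_per_min = cutoff_per_min, filter_order = filter_order,
                 pixelwise = pixelwise, mask_threshold = mask_threshold,
                 rvd_thresholds = rvd_thresholds, rvd_summary = rvd_summary,
                 min_breaths = min_breaths,
                 prominence_fraction = prominence_fraction,
                 roc_cutoff = roc_cutoff, seed = as.integer(seed)),
            class = "eit_config")
}

# filter + provisional segmentation + tidal image for one session
prepare_session <- function(seq, config = eit_config()) {
  filt <- lowpass_filter(seq, config$cutoff_per_min, config$filter_order,
                         pixelwise = config$pixelwise)
  curve_all <- compute_global_curve(filt)
  if (!config$pixelwise)
    curve_all <- lowpass_filter_curve(curve_all, config$cutoff_per_min,
                                      config$filter_order)
  seg <- detect_breaths(curve_all, config$min_breaths,
                        config$prominence_fraction)
  list(seq = filt, seg = seg, tidal = tidal_image(filt, seg))
}

#' Analyze one EIT session
#'
#' Runs the full per-session pipeline — low-pass filter, global curve,
#' breath segmentation, tidal image — and computes the index set: TIV (%
#' of baseline), dEELI (% of baseline TIV), IR and IR_adapt, GI, spRVD at
#' 40/60/80% thresholds (sd and mean summaries), respiratory rate, and
#' RSBI_EIT. Non-baseline sessions need `baseline` references from the t0
#' session.
#'
#' @param seq a [frame_sequence()].
#' @param mask a [build_lung_mask()] covering the study's ventilated extent,
#'   or `NULL` to build one from this session alone.
#' @param baseline `NULL` for the baseline session, else
#'   `list(tiv_au =, eeli_au =)` from the baseline's indices.
#' @param config an [eit_config()].
#' @param prepared internal: a precomputed [prepare_session()] result.
#' @return one-row data frame of class `session_indices`.
#' @export
analyze_session <- function(seq, mask = NULL, baseline = NULL,
                            config = eit_config(), prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_session(seq, config)
  if (seq$session_label != "t0" && is.null(baseline))
    stop(sprintf("session %s requires baseline references (tiv_au, eeli_au) from t0",
                 seq$session_label), call. = FALSE)
  if (is.null(mask))
    mask <- build_lung_mask(prepared$tidal, config$mask_threshold)
  filt <- prepared$seq
  seg <- prepared$seg
  curve <- compute_global_curve(filt, mask$member)
  if (!config$pixelwise)
    curve <- lowpass_filter_curve(curve, config$cutoff_per_min,
                                  config$filter_order)

  tv <- tiv(curve, seg, baseline$tiv_au, config$min_breaths)
  de <- delta_eeli(curve, seg, baseline$eeli_au, baseline$tiv_au)
  rr <- respiratory_rate(seg)
  g <- gi_index(prepared$tidal, mask)
  ir <- impedance_ratio(prepared$tidal, roi_partition(nrow(prepared$tidal$di)))
  ira <- impedance_ratio(prepared$tidal, adapted_partition(mask))

  out <- data.frame(subject_id = seq$subject_id,
                    session_label = seq$session_label,
                    tiv_au = tv$tiv_au, tiv_percent = tv$tiv_percent,
                    eeli_au = de$eeli_au,
                    delta_eeli_percent = de$delta_eeli_percent,
                    ir = ir, ir_adapt = ira,
                    gi = g$gi, gi_reported = g$gi_reported,
                    rr = rr, rsbi_eit = rsbi_eit(rr, tv$tiv_percent),
                    n_breaths_selected = sum(seg$breaths$selected),
                    stringsAsFactors = FALSE)
  n_unreached <- 0L
  for (thr in config$rvd_thresholds) {
    for (sm in c("sd", "mean")) {
      r <- withCallingHandlers(
        sp_rvd(filt, seg, mask, thr, sm),
        warning = function(w) invokeRestart("muffleWarning"))
      out[[sprintf("sp_rvd_%s_%d", sm, thr)]] <- r$value
      if (sm == "sd") n_unreached <- n_unreached + r$n_unreached
    }
  }
  out$rvd_unreached <- n_unreached
  class(out) <- c("session_indices", "data.frame")
  out
}

#' Analyze a full patient study (t0, t1, t2)
#'
#' Builds the lung mask from the maximum ventilated extent across all
#' supplied sessions, analyzes t0 as the baseline, and references t1/t2
#' to it.
#'
#' @param sessions named list of [frame_sequence()] objects; `t0` is
#'   mandatory, `t1`/`t2` optional.
#' @param config an [eit_config()].
#' @return data frame with one `session_indices` row per session.
#' @export
analyze_patient <- function(sessions, config = eit_config()) {
  if (is.null(sessions$t0))
    stop("a t0 baseline session is mandatory", call. = FALSE)
  labs <- intersect(c("t0", "t1", "t2"), names(sessions))
  prepared <- lapply(sessions[labs], prepare_session, config = config)
  mask <- build_lung_mask(lapply(prepared, `[[`, "tidal"),
                          config$mask_threshold)
  base_row <- analyze_session(sessions$t0, mask, NULL, config, prepared$t0)
  baseline <- list(tiv_au = base_row$tiv_au, eeli_au = base_row$eeli_au)
  rows <- list(base_row)
  for (lab in setdiff(labs, "t0"))
    rows[[lab]] <- analyze_session(sessions[[lab]], mask, baseline, config,
                                   prepared[[lab]])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
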
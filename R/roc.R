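#' Ventilatory deterioration label
#'
#' A patient deteriorates when the tidal volume after the T-piece trial
#' (t2) has dropped by at least `delta_ml` compared with baseline (t0);
#' the 20 ml default guards against measurement error, and the boundary is
#' inclusive ("at least").
#'
#' @param vt_t0,vt_t2 tidal volumes in ml (> 0).
#' @param delta_ml drop threshold in ml (default 20).
#' @return logical.
#' @export
deterioration_label <- function(vt_t0, vt_t2, delta_ml = 20) {
  if (any(vt_t0 <= 0) || any(vt_t2 <= 0))
    stop("tidal volumes must be positive", call. = FALSE)
  (vt_t0 - vt_t2) >= delta_ml
}

#' ROC curve for a deterioration predictor
#'
#' Sweeps candidate cutoffs (midpoints between sorted distinct scores plus
#' +/-Inf) with the classification rule `score > cutoff` is positive —
#' matching the convention that a *high* baseline GI predicts
#' deterioration. The AUC is the normalized Mann-Whitney statistic: the
#' fraction of (positive, negative) score pairs ranked correctly, ties
#' counting one half.
#'
#' @param scores numeric predictor (baseline GI, reported scale).
#' @param labels logical outcome (TRUE = deteriorated).
#' @return object of class `roc_result`: data frame `sweep` with
#'   `threshold`, `sensitivity`, `specificity`; plus `auc`, `n_pos`,
#'   `n_neg`, and the input `scores`/`labels` (for [operating_point()]).
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1 || n_neg < 1)
    stop("ROC needs at least one positive and one negative label", call. = FALSE)
  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sweep <- data.frame(threshold = thresholds)
  sweep$sensitivity <- vapply(thresholds, function(th)
    sum(scores[labels] > th) / n_pos, numeric(1))
  sweep$specificity <- vapply(thresholds, function(th)
    sum(scores[!labels] <= th) / n_neg, numeric(1))
  # Mann-Whitney with half weight for ties
  pos <- scores[labels]; neg <- scores[!labels]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  structure(list(sweep = sweep, auc = u / (n_pos * n_neg),
                 n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d positive / %d negative, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$sweep)))
  invisible(x)
}

#' Operating point at a given cutoff
#'
#' Confusion counts for the rule `score > cutoff` is positive, returned as
#' exact fractions with the underlying counts.
#'
#' @param roc a [roc_curve()] result.
#' @param cutoff predictor cutoff (e.g. a GI of 41.5 on the reported
#'   scale).
#' @return list with `sensitivity`, `specificity`, `tp`, `fn`, `tn`, `fp`,
#'   `cutoff`.
#' @export
operating_point <- function(roc, cutoff) {
  stopifnot(inherits(roc, "roc_result"))
  pred <- roc$scores > cutoff
  tp <- sum(pred & roc$labels); fn <- sum(!pred & roc$labels)
  tn <- sum(!pred & !roc$labels); fp <- sum(pred & !roc$labels)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp, cutoff = cutoff)
}

#' Cohort summary tables (median and IQR per session)
#'
#' Median and interquartile range (25th/75th percentile, linear
#' interpolation) of every index at each time point, optionally split by
#' deterioration group — the shape of a subgroup table comparing patients
#' with and without tidal-volume decrease.
#'
#' @param sessions stacked `session_indices` rows (from
#'   [analyze_cohort()]`$sessions`).
#' @param patients optional per-patient data frame with `subject_id` and
#'   `deteriorated`; required for `group_by = "deterioration"`.
#' @param group_by `"none"` (default) or `"deterioration"`.
#' @param log_gi also include the natural-log-transformed GI column
#'   (default `FALSE`).
#' @return data frame with columns `group`, `session_label`, `index`,
#'   `median`, `q25`, `q75`, `n`.
#' @export
cohort_summary <- function(sessions, patients = NULL,
                           group_by = c("none", "deterioration"),
                           log_gi = FALSE) {
  group_by <- match.arg(group_by)
  if (nrow(sessions) < 2) stop("need >= 2 session rows", call. = FALSE)
  num_cols <- setdiff(names(sessions)[vapply(sessions, is.numeric, logical(1))],
                      c("n_breaths_selected", "rvd_unreached"))
  if (log_gi) {
    sessions$log_gi <- log(sessions$gi_reported)
    num_cols <- c(num_cols, "log_gi")
  }
  if (group_by == "deterioration") {
    if (is.null(patients))
      stop("`patients` with a `deteriorated` column is required", call. = FALSE)
    sessions$group <- ifelse(
      patients$deteriorated[match(sessions$subject_id, patients$subject_id)],
      "deterioration", "no_deterioration")
  } else sessions$group <- "all"
  out <- list()
  for (g in unique(sessions$group)) {
    for (lab in unique(sessions$session_label)) {
      sub <- sessions[sessions$group == g & sessions$session_label == lab, ]
      if (nrow(sub) == 0) stop("empty group in summary", call. = FALSE)
      for (cn in num_cols) {
        q <- stats::quantile(sub[[cn]], c(0.25, 0.5, 0.75), type = 7,
                             names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          group = g, session_label = lab, index = cn,
          median = q[2], q25 = q[1], q75 = q[3], n = nrow(sub),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
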
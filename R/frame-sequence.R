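#' EIT frame sequence
#'
#' Container for a reconstructed EIT movie: relative impedance per pixel per
#' frame at a fixed sampling rate. Frames are stored as a numeric array with
#' dimensions `time x rows x cols`; row 0 of the image (R index 1) is the
#' most ventral pixel row, following the usual display convention for a
#' supine patient.
#'
#' @param frames numeric array `n_frames x n_rows x n_cols`, relative
#'   impedance in arbitrary units (AU). All values must be finite.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param session_label one of `"t0"`, `"t1"`, `"t2"` (baseline on pressure
#'   support, end of T-piece trial, after return to pressure support).
#' @param subject_id opaque subject identifier.
#' @return object of class `eit_frames`.
#' @export
frame_sequence <- function(frames, sampling_rate,
                           session_label = "t0", subject_id = "anon") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-d array (time x rows x cols)", call. = FALSE)
  if (!all(is.finite(frames)))
    stop("`frames` contains non-finite values", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  session_label <- match.arg(session_label, c("t0", "t1", "t2"))
  structure(
    list(frames = frames,
         sampling_rate = as.numeric(sampling_rate),
         session_label = session_label,
         subject_id = as.character(subject_id)),
    class = "eit_frames")
}

#' @export
print.eit_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<eit_frames> subject %s, session %s: %d frames of %dx%d @ %g Hz (%.1f s)\n",
              x$subject_id, x$session_label, d[1], d[2], d[3],
              x$sampling_rate, d[1] / x$sampling_rate))
  invisible(x)
}

n_frames <- function(seq) dim(seq$frames)[1]
grid_shape <- function(seq) dim(seq$frames)[2:3]

# time x pixel matrix view (pixels in column-major image order)
as_pixel_matrix <- function(seq) {
  d <- dim(seq$frames)
  matrix(seq$frames, nrow = d[1], ncol = d[2] * d[3])
}

pixel_matrix_to_frames <- function(mat, shape) {
  array(mat, dim = c(nrow(mat), shape[1], shape[2]))
}

#' Global impedance curve
#'
#' Sums each frame over a pixel mask, yielding the global impedance curve
#' whose local minima mark end-expiration and whose peaks mark
#' end-inspiration.
#'
#' @param seq an [frame_sequence()] object.
#' @param mask logical matrix with the grid shape of `seq`, or `NULL` to sum
#'   over all pixels.
#' @return object of class `eit_curve`: list with `values` (AU per frame),
#'   `sampling_rate`, and `mask_id` (`"all"` or `"masked:<n>"`).
#' @export
compute_global_curve <- function(seq, mask = NULL) {
  stopifnot(inherits(seq, "eit_frames"))
  shape <- grid_shape(seq)
  if (is.null(mask)) {
    idx <- seq_len(prod(shape))
    mask_id <- "all"
  } else {
    if (!is.logical(mask) || !identical(dim(mask), as.integer(shape)) &&
        !identical(dim(mask), shape))
      stop("`mask` must be a logical matrix matching the grid shape", call. = FALSE)
    if (!any(mask)) stop("mask is empty", call. = FALSE)
    idx <- which(as.vector(mask))
    mask_id <- sprintf("masked:%d", length(idx))
  }
  mat <- as_pixel_matrix(seq)
  vals <- if (length(idx) == 1L) mat[, idx] else rowSums(mat[, idx, drop = FALSE])
  structure(list(values = as.numeric(vals),
                 sampling_rate = seq$sampling_rate,
                 mask_id = mask_id),
            class = "eit_curve")
}
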
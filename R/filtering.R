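#' Zero-phase low-pass filtering of an EIT movie
#'
#' Removes cardiac-related impedance variations with a low-pass filter whose
#' cutoff sits between the respiratory and cardiac frequency bands
#' (default 50 min^-1). A Butterworth design (default order 4) is applied
#' forward and backward, so the net filter has zero phase shift — breath
#' landmark times are preserved — and unit DC gain.
#'
#' Filtering is applied to every pixel trace by default, so downstream tidal
#' images and regional delay measurements also use cardiac-free signals; set
#' `pixelwise = FALSE` to leave pixels untouched (filter only where a global
#' curve is later computed from the result, which is then *not* filtered —
#' the flag exists for comparing both conventions).
#'
#' @param seq an [frame_sequence()].
#' @param cutoff_per_min cutoff frequency in min^-1 (default 50).
#' @param order Butterworth order of the one-way filter (default 4; applied
#'   twice, the magnitude response is squared).
#' @param pixelwise logical; filter each pixel trace (default `TRUE`).
#' @return a filtered copy of `seq`.
#' @export
lowpass_filter <- function(seq, cutoff_per_min = 50, order = 4,
                           pixelwise = TRUE) {
  stopifnot(inherits(seq, "eit_frames"))
  fc <- cutoff_per_min / 60
  nyq <- seq$sampling_rate / 2
  if (fc >= nyq)
    stop(sprintf(
      "cutoff %.3g Hz (%.4g min^-1) is at/above the Nyquist frequency %.3g Hz of the %.3g Hz sampling rate",
      fc, cutoff_per_min, nyq, seq$sampling_rate), call. = FALSE)
  if (!pixelwise) return(seq)
  bf <- signal::butter(order, fc / nyq, type = "low")
  mat <- filtfilt_matrix(bf$b, bf$a, as_pixel_matrix(seq))
  out <- seq
  out$frames <- pixel_matrix_to_frames(mat, grid_shape(seq))
  out
}

#' Zero-phase filtering of a global curve
#'
#' Same forward-backward Butterworth filter as [lowpass_filter()], applied
#' to a single global impedance curve.
#'
#' @param curve an `eit_curve`.
#' @inheritParams lowpass_filter
#' @return a filtered copy of `curve`.
#' @export
lowpass_filter_curve <- function(curve, cutoff_per_min = 50, order = 4) {
  stopifnot(inherits(curve, "eit_curve"))
  fc <- cutoff_per_min / 60
  nyq <- curve$sampling_rate / 2
  if (fc >= nyq)
    stop(sprintf(
      "cutoff %.4g min^-1 is at/above the Nyquist frequency of the %.3g Hz sampling rate",
      cutoff_per_min, curve$sampling_rate), call. = FALSE)
  bf <- signal::butter(order, fc / nyq, type = "low")
  out <- curve
  out$values <- as.numeric(filtfilt_matrix(bf$b, bf$a,
                                           matrix(curve$values, ncol = 1)))
  out
}

# Forward-backward IIR filtering of every column of X, with odd-reflection
# padding at both ends to suppress edge transients. Direct-form II
# transposed recursion, vectorized across columns; only the time loop runs
# in R, so filtering all 1024 pixel traces costs the same order of time as
# one signal::filtfilt call.
filtfilt_matrix <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  npad <- 3L * (max(length(a), length(b)) - 1L)
  n <- nrow(X)
  if (n <= npad + 1L)
    stop("signal too short for the filter's edge padding", call. = FALSE)
  head_pad <- 2 * X[rep(1L, npad), , drop = FALSE] -
    X[(npad + 1L):2L, , drop = FALSE]
  tail_pad <- 2 * X[rep(n, npad), , drop = FALSE] -
    X[(n - 1L):(n - npad), , drop = FALSE]
  Y <- rbind(head_pad, X, tail_pad)
  zi <- steady_state_zi(b, a)
  Y <- iir_pass(b, a, Y, zi)
  Y <- iir_pass(b, a, Y[nrow(Y):1L, , drop = FALSE], zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(npad + 1L):(npad + n), , drop = FALSE]
}

# steady-state direct-form-II-transposed state for unit constant input, so
# each pass starts settled (scaled by the first padded sample per column);
# a constant signal then passes through exactly unchanged
steady_state_zi <- function(b, a) {
  ns <- max(length(a), length(b)) - 1L
  b <- c(b, numeric(ns + 1L - length(b)))
  a <- c(a, numeric(ns + 1L - length(a)))
  M <- diag(ns)
  rhs <- numeric(ns)
  for (j in seq_len(ns)) {
    if (j < ns) M[j, j + 1L] <- -1
    M[j, 1L] <- M[j, 1L] + a[j + 1L]
    rhs[j] <- b[j + 1L] - a[j + 1L] * b[1L]
  }
  solve(M, rhs)
}

iir_pass <- function(b, a, X, zi = NULL) {
  n <- nrow(X); k <- ncol(X)
  nb <- length(b); na <- length(a)
  ns <- max(nb, na) - 1L
  b <- c(b, numeric(ns + 1L - nb))
  a <- c(a, numeric(ns + 1L - na))
  Y <- matrix(0, n, k)
  state <- if (is.null(zi)) matrix(0, ns, k) else zi %o% X[1L, ]
  for (tt in seq_len(n)) {
    xt <- X[tt, ]
    yt <- b[1] * xt + state[1L, ]
    if (ns > 1L)
      for (j in seq_len(ns - 1L))
        state[j, ] <- state[j + 1L, ] + b[j + 1L] * xt - a[j + 1L] * yt
    state[ns, ] <- b[ns + 1L] * xt - a[ns + 1L] * yt
    Y[tt, ] <- yt
  }
  Y
}
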
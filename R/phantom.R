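#' Two-ellipse lung field mask
#'
#' Boolean pixel map of two elliptical lung fields on the EIT grid, the
#' spatial support used by the synthetic thorax phantom. Rows run ventral to
#' dorsal, columns right to left lung.
#'
#' @param n_rows,n_cols grid dimensions (default 32 x 32).
#' @param semi_row,semi_col ellipse semi-axes in pixels (row and column
#'   direction).
#' @return logical `n_rows x n_cols` matrix.
#' @export
lung_ellipses <- function(n_rows = 32, n_cols = 32,
                          semi_row = 9, semi_col = 5.5) {
  r <- matrix(seq_len(n_rows) - 1, n_rows, n_cols)
  cc <- matrix(rep(seq_len(n_cols) - 1, each = n_rows), n_rows, n_cols)
  cr <- (n_rows - 1) / 2
  c1 <- (n_cols - 1) / 4
  c2 <- 3 * (n_cols - 1) / 4
  e1 <- ((r - cr) / semi_row)^2 + ((cc - c1) / semi_col)^2 <= 1
  e2 <- ((r - cr) / semi_row)^2 + ((cc - c2) / semi_col)^2 <= 1
  e1 | e2
}

#' Synthetic thorax phantom specification
#'
#' Parameters of the forward model used to generate phantom EIT movies with
#' analytically known ground truth. Each pixel's trace is
#' `eeli(t) + A_xy * w(t - tau_xy) + cardiac(t) + noise`, where `w` is a
#' periodic raised-cosine breath waveform rising from 0 to 1 over the
#' inspiratory fraction of the breath period and returning to 0 over
#' expiration. Smooth extrema keep peak detection well-posed.
#'
#' @param grid_shape integer vector `c(rows, cols)`.
#' @param lung_amplitude_map per-pixel tidal amplitude (AU, >= 0), nonzero
#'   only inside the lung fields. Default: uniform 1 AU on [lung_ellipses()].
#' @param delay_map per-pixel inspiratory delay in seconds (>= 0, zero where
#'   the amplitude is zero). Delays are pure phase shifts of the breath
#'   waveform, so expiration shifts together with inspiration.
#' @param respiratory_rate breaths per minute (> 0). Default 23.5, a typical
#'   baseline rate in prolonged-weaning patients on pressure support.
#' @param inspiration_fraction fraction of the breath period spent in
#'   inspiration, in (0, 1). At the default 0.5 the waveform is a single
#'   spectral line at the respiratory rate, so the cardiac filter's rolloff
#'   does not touch it; asymmetric fractions add harmonics (realistic, but
#'   they shave the tidal swing once they approach the cutoff).
#' @param eeli_trajectory per-breath end-expiratory baseline offset, AU per
#'   lung pixel: a single number, or a vector indexed by breath (recycled to
#'   the breath count). Piecewise constant within each breath.
#' @param cardiac_rate cardiac oscillation rate, min^-1. Must exceed the
#'   50 min^-1 respiratory band so the low-pass filter can remove it.
#' @param cardiac_amplitude cardiac oscillation amplitude, AU (>= 0), added
#'   to every pixel.
#' @param noise_sd additive white-noise standard deviation, AU (>= 0).
#' @param sampling_rate frame rate in Hz.
#' @param duration recording length in seconds; must cover at least 12 full
#'   breaths so that >= 10 complete cycles remain selectable.
#' @param seed integer seed for the noise generator.
#' @param mask_threshold fraction of the maximum amplitude used when the
#'   ground-truth lung mask is derived (mirrors [build_lung_mask()]).
#' @return object of class `phantom_spec` (validated list of the above).
#' @export
phantom_spec <- function(grid_shape = c(32, 32),
                         lung_amplitude_map = NULL,
                         delay_map = NULL,
                         respiratory_rate = 23.5,
                         inspiration_fraction = 0.5,
                         eeli_trajectory = 0,
                         cardiac_rate = 90,
                         cardiac_amplitude = 0,
                         noise_sd = 0,
                         sampling_rate = 20,
                         duration = 36,
                         seed = 1L,
                         mask_threshold = 0.20) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(lung_amplitude_map)) {
    lung_amplitude_map <- matrix(0, grid_shape[1], grid_shape[2])
    lung_amplitude_map[lung_ellipses(grid_shape[1], grid_shape[2])] <- 1
  }
  if (is.null(delay_map))
    delay_map <- matrix(0, grid_shape[1], grid_shape[2])
  stopifnot(identical(dim(lung_amplitude_map), dim(delay_map)))
  if (!identical(as.integer(dim(lung_amplitude_map)), grid_shape))
    stop("amplitude map shape does not match grid_shape", call. = FALSE)
  if (any(lung_amplitude_map < 0))
    stop("negative amplitudes in lung_amplitude_map", call. = FALSE)
  if (any(delay_map < 0))
    stop("negative delays in delay_map", call. = FALSE)
  if (any(delay_map[lung_amplitude_map == 0] != 0))
    stop("delay_map must be zero where the amplitude is zero", call. = FALSE)
  if (respiratory_rate <= 0 || inspiration_fraction <= 0 ||
      inspiration_fraction >= 1)
    stop("respiratory_rate must be > 0 and inspiration_fraction in (0,1)",
         call. = FALSE)
  if (cardiac_amplitude < 0 || noise_sd < 0 || sampling_rate <= 0 ||
      duration <= 0)
    stop("cardiac_amplitude/noise_sd must be >= 0; sampling_rate/duration > 0",
         call. = FALSE)
  period <- 60 / respiratory_rate
  if (duration < 12 * period)
    stop(sprintf(
      "duration %.1f s covers only %.1f breaths at %.1f min^-1; >= 12 required",
      duration, duration / period, respiratory_rate), call. = FALSE)
  structure(list(grid_shape = grid_shape,
                 lung_amplitude_map = lung_amplitude_map,
                 delay_map = delay_map,
                 respiratory_rate = respiratory_rate,
                 inspiration_fraction = inspiration_fraction,
                 eeli_trajectory = eeli_trajectory,
                 cardiac_rate = cardiac_rate,
                 cardiac_amplitude = cardiac_amplitude,
                 noise_sd = noise_sd,
                 sampling_rate = sampling_rate,
                 duration = duration,
                 seed = as.integer(seed),
                 mask_threshold = mask_threshold),
            class = "phantom_spec")
}

#' Raised-cosine breath waveform
#'
#' Periodic waveform rising 0 -> 1 over the inspiratory fraction of the
#' period and falling 1 -> 0 over the remainder, evaluated at times `t`.
#'
#' @param t times in seconds (any real values; the waveform is periodic).
#' @param period breath period, s.
#' @param inspiration_fraction inspiratory fraction of the period, in (0,1).
#' @return numeric vector in `[0, 1]`.
#' @export
breath_waveform <- function(t, period, inspiration_fraction) {
  ti <- inspiration_fraction * period
  u <- t %% period
  ifelse(u <= ti,
         (1 - cos(pi * u / ti)) / 2,
         (1 + cos(pi * (u - ti) / (period - ti))) / 2)
}

#' Generate a phantom EIT movie with analytic ground truth
#'
#' Runs the forward model of [phantom_spec()] and returns both the frame
#' sequence and a `GroundTruth` list computed analytically from the spec
#' (never from the generated movie).
#'
#' Ground-truth regional ventilation delay is the programmed per-pixel phase
#' delay as a percentage of the inspiratory time, `100 * tau_xy / T_insp`;
#' since a phase delay postpones every threshold crossing by exactly
#' `tau_xy`, the map is the same for any amplitude threshold.
#'
#' @param spec a [phantom_spec()].
#' @param session_label,subject_id metadata for the returned sequence.
#' @return list with elements `frames` ([frame_sequence()]) and `truth`:
#'   `lung_mask` (threshold-rule mask on the amplitude map),
#'   `expected_tiv` (global tidal swing over the mask, AU),
#'   `expected_gi` (raw scale), `expected_ir`, `expected_ir_adapt`,
#'   `expected_rvd_map` (%, NA outside the mask),
#'   `expected_eeli_offsets` (per breath, global AU over the mask),
#'   `expected_rr` (min^-1), `n_breaths`.
#' @export
generate_phantom <- function(spec, session_label = "t0", subject_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  fs <- spec$sampling_rate
  nt <- floor(spec$duration * fs)
  t <- (seq_len(nt) - 1) / fs
  period <- 60 / spec$respiratory_rate
  n_breaths <- floor(spec$duration / period)
  ti <- spec$inspiration_fraction * period

  shape <- spec$grid_shape
  npx <- prod(shape)
  amp <- as.vector(spec$lung_amplitude_map)
  tau <- as.vector(spec$delay_map)
  lung <- amp > 0

  eeli_breath <- rep_len(spec$eeli_trajectory, n_breaths)
  breath_of_t <- pmin(floor(t / period) + 1L, n_breaths)
  eeli_t <- eeli_breath[breath_of_t]

  cardiac_t <- if (spec$cardiac_amplitude > 0)
    spec$cardiac_amplitude * sin(2 * pi * (spec$cardiac_rate / 60) * t)
  else numeric(nt)

  mat <- matrix(0, nt, npx)
  # evaluate the waveform once per distinct delay, then scale per pixel
  for (d in unique(tau[lung])) {
    w <- breath_waveform(t - d, period, spec$inspiration_fraction)
    px <- which(lung & tau == d)
    mat[, px] <- w %o% amp[px]
  }
  mat[, lung] <- mat[, lung] + eeli_t  # baseline shifts act on lung pixels
  mat <- mat + cardiac_t               # cardiac oscillation on every pixel
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    mat <- mat + matrix(stats::rnorm(nt * npx, sd = spec$noise_sd), nt, npx)
  }

  frames <- frame_sequence(pixel_matrix_to_frames(mat, shape), fs,
                           session_label, subject_id)

  # analytic ground truth from the spec alone
  mask <- spec$lung_amplitude_map >=
    spec$mask_threshold * max(spec$lung_amplitude_map)
  di <- spec$lung_amplitude_map
  gi_true <- sum(abs(di[mask] - stats::median(di[mask]))) / sum(di[mask])
  rvd_map <- matrix(NA_real_, shape[1], shape[2])
  rvd_map[mask] <- 100 * spec$delay_map[mask] / ti
  truth <- list(
    lung_mask = mask,
    expected_tiv = sum(di[mask]),
    expected_gi = gi_true,
    expected_ir = ir_of_map(di, roi_partition(shape[1], mode = "static")),
    expected_ir_adapt = ir_of_map(di, adapted_partition_rows(mask)),
    expected_rvd_map = rvd_map,
    expected_eeli_offsets = eeli_breath * sum(mask),
    expected_rr = spec$respiratory_rate,
    n_breaths = n_breaths)
  list(frames = frames, truth = truth)
}

# IR of a DI map under a row partition (internal; shared with ground truth)
ir_of_map <- function(di, part) {
  s <- vapply(part$bands, function(rows) sum(di[rows, , drop = FALSE]),
              numeric(1))
  if (s[3] + s[4] <= 0) stop("IR undefined: dorsal DI sum is zero", call. = FALSE)
  (s[1] + s[2]) / (s[3] + s[4])
}
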
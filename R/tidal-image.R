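#' Tidal image (per-pixel inspiratory impedance change)
#'
#' For each selected breath, the tidal image is the per-pixel impedance at
#' end-inspiration minus the impedance at the end-expiration opening the
#' breath (DI per pixel); the returned image is the mean over the selected
#' breaths.
#'
#' @param seq a (filtered) [frame_sequence()].
#' @param seg a `breath_seg` from [detect_breaths()].
#' @return object of class `tidal_image`: list with `di` (matrix, AU) and
#'   `breath_ids` (row indices of the averaged breaths).
#' @export
tidal_image <- function(seq, seg) {
  stopifnot(inherits(seq, "eit_frames"), inherits(seg, "breath_seg"))
  sel <- which(seg$breaths$selected)
  if (length(sel) == 0L) stop("no selected breaths", call. = FALSE)
  shape <- grid_shape(seq)
  di <- matrix(0, shape[1], shape[2])
  for (i in sel) {
    di <- di + (seq$frames[seg$breaths$peak[i], , ] -
                  seq$frames[seg$breaths$start[i], , ])
  }
  structure(list(di = di / length(sel), breath_ids = sel),
            class = "tidal_image")
}

#' Functional lung mask from tidal images
#'
#' A pixel belongs to the lung mask when its maximum DI across the supplied
#' tidal images (typically the three study sessions, so the mask covers the
#' maximum ventilated extent of the entire study) is at least
#' `threshold_fraction` of the overall maximum DI. The boundary is
#' inclusive.
#'
#' @param tidal_images a single [tidal_image()] or a list of them.
#' @param threshold_fraction fraction of the maximum DI (default 0.20, the
#'   common functional-EIT convention).
#' @return object of class `lung_mask`: list with `member` (logical matrix),
#'   `threshold_fraction` and `source_sessions` (count of images used).
#' @export
build_lung_mask <- function(tidal_images, threshold_fraction = 0.20) {
  if (inherits(tidal_images, "tidal_image")) tidal_images <- list(tidal_images)
  stopifnot(length(tidal_images) >= 1L,
            all(vapply(tidal_images, inherits, logical(1), "tidal_image")))
  dis <- lapply(tidal_images, `[[`, "di")
  maxdi <- Reduce(pmax, dis)
  gmax <- max(maxdi)
  if (gmax <= 0) stop("all tidal images are non-positive; no ventilated region",
                      call. = FALSE)
  member <- maxdi >= threshold_fraction * gmax
  structure(list(member = member,
                 threshold_fraction = threshold_fraction,
                 source_sessions = length(tidal_images)),
            class = "lung_mask")
}

#' Horizontal ROI partition of the pixel grid
#'
#' Four horizontal bands numbered 1 to 4 from ventral to dorsal. In static
#' mode each band spans 25% of the grid rows.
#'
#' @param n_rows number of grid rows (default 32).
#' @param mode `"static"` (the only mode built here; see
#'   [adapted_partition()] for the patient-adapted variant).
#' @return object of class `roi_partition`: list with `bands` (list of four
#'   row-index vectors) and `mode`.
#' @export
roi_partition <- function(n_rows = 32, mode = "static") {
  mode <- match.arg(mode, "static")
  if (n_rows %% 4 != 0)
    stop("static partition requires a row count divisible by 4", call. = FALSE)
  h <- n_rows / 4
  bands <- lapply(0:3, function(k) (k * h + 1L):((k + 1L) * h))
  structure(list(bands = bands, mode = "static"), class = "roi_partition")
}

#' Patient-adapted ROI partition
#'
#' Splits the row range actually containing lung-mask pixels into four
#' contiguous bands of equal height; when the extent is not divisible by 4,
#' the remainder rows are assigned to the dorsal-most bands.
#'
#' @param mask a [build_lung_mask()] result.
#' @return an `roi_partition` with `mode = "adapted"`.
#' @export
adapted_partition <- function(mask) {
  stopifnot(inherits(mask, "lung_mask"))
  adapted_partition_rows(mask$member)
}

adapted_partition_rows <- function(member) {
  rows <- which(rowSums(member) > 0)
  if (length(rows) == 0L) stop("empty lung mask", call. = FALSE)
  first <- min(rows); last <- max(rows)
  extent <- last - first + 1L
  if (extent < 4L)
    stop(sprintf("ventilated extent spans only %d rows; 4 required", extent),
         call. = FALSE)
  h <- rep(extent %/% 4L, 4L)
  extra <- extent %% 4L
  if (extra > 0L) h[(4L - extra + 1L):4L] <- h[(4L - extra + 1L):4L] + 1L
  stops <- first - 1L + cumsum(h)
  starts <- c(first, stops[-4L] + 1L)
  bands <- Map(function(s, e) s:e, starts, stops)
  structure(list(bands = bands, mode = "adapted"), class = "roi_partition")
}

#' Impedance ratio (ventral over dorsal ventilation)
#'
#' Ratio of the summed tidal impedance change in the two ventral bands
#' (ROI1 + ROI2) to the two dorsal bands (ROI3 + ROI4). A falling IR
#' accompanies recruitment of dorsal (dependent) lung.
#'
#' @param img a [tidal_image()].
#' @param part an `roi_partition` covering the image rows.
#' @return unitless ratio.
#' @export
impedance_ratio <- function(img, part) {
  stopifnot(inherits(img, "tidal_image"), inherits(part, "roi_partition"))
  if (max(unlist(part$bands)) > nrow(img$di))
    stop("partition rows exceed image rows", call. = FALSE)
  ir_of_map(img$di, part)
}
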
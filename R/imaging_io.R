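# Loading, calibration and preprocessing of time-lapse sequences.

#' Construct a calibrated frame sequence
#'
#' A `frame_sequence` is the raw observable of every analysis in this
#' package: a list of same-sized grayscale frames in `[0, 1]`, their
#' acquisition times in seconds, the pixel size in micrometres per pixel and
#' the index of the reference frame against which displacements are
#' measured.
#'
#' @param frames list of numeric matrices, all with identical dimensions,
#'   intensities in `[0, 1]` (values outside are clipped with a warning).
#' @param pixel_size micrometres per pixel, positive scalar.
#' @param times acquisition time of each frame in seconds, strictly
#'   increasing; mutually exclusive with `frame_interval`.
#' @param frame_interval seconds between consecutive frames; `times` is then
#'   `frame_interval * (0, 1, 2, ...)`.
#' @param reference_index 1-based index of the reference frame (default 1).
#' @return An object of class `frame_sequence` with elements `frames`,
#'   `times`, `pixel_size`, `reference_index`.
#' @export
frame_sequence <- function(frames, pixel_size, times = NULL,
                           frame_interval = NULL, reference_index = 1L) {
  if (!is.list(frames) || length(frames) < 2L)
    stopf("a frame sequence needs at least 2 frames, got %d", length(frames))
  dims <- lapply(frames, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stopf("all frames must be 2-D matrices")
  d0 <- dims[[1]]
  ok <- vapply(dims, function(d) length(d) == 2 && all(d == d0), logical(1))
  if (!all(ok))
    stopf("frame dimension mismatch: frame 1 is %dx%d but frame %d is %s",
          d0[1], d0[2], which(!ok)[1],
          paste(dims[[which(!ok)[1]]], collapse = "x"))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stopf("pixel_size must be a positive scalar (um/px)")
  if (is.null(times)) {
    if (is.null(frame_interval))
      stopf("provide either times or frame_interval")
    times <- frame_interval * (seq_along(frames) - 1)
  }
  if (length(times) != length(frames))
    stopf("times length (%d) != number of frames (%d)",
          length(times), length(frames))
  if (any(diff(times) <= 0))
    stopf("times must be strictly increasing")
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(frames))
    stopf("reference_index %d out of range [1, %d]",
          reference_index, length(frames))
  rng <- range(unlist(lapply(frames, range), use.names = FALSE))
  if (rng[1] < 0 || rng[2] > 1) {
    warnf("frame intensities outside [0,1] were clipped")
    frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  }
  structure(list(frames = frames, times = as.numeric(times),
                 pixel_size = pixel_size,
                 reference_index = reference_index),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(paste0("<frame_sequence> %d frames of %d x %d px ",
                     "(%.3g um/px), t = %.4g..%.4g s, reference #%d\n"),
              length(x$frames), d[2], d[1], x$pixel_size,
              min(x$times), max(x$times), x$reference_index))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Shape (rows, cols) of the frames in a sequence
#' @param x a `frame_sequence`
#' @return integer vector `c(rows, cols)`
#' @export
frame_shape <- function(x) dim(x$frames[[1]])

.to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  d <- dim(a)
  if (length(d) == 3L) {
    nc <- min(d[3], 3L)          # average RGB, drop alpha
    m <- a[, , 1]
    if (nc > 1) for (k in 2:nc) m <- m + a[, , k]
    return(m / nc)
  }
  stopf("unsupported image array with %d dimensions", length(d))
}

.read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pages <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path, all = TRUE, info = FALSE),
    "png" = list(png::readPNG(path)),
    stopf("unsupported image format '%s' (use TIFF or PNG): %s", ext, path))
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, .to_gray)
}

#' Load an image sequence from disk
#'
#' Reads either a single multipage TIFF or an ordered vector of PNG/TIFF
#' file paths (lexicographic file order is temporal order) and assembles a
#' calibrated [frame_sequence]. RGB images are converted to grayscale by
#' channel averaging; all frames end up on a common `[0, 1]` intensity
#' scale.
#'
#' @param source a single multipage TIFF path, a directory containing the
#'   frames, or a character vector of image paths.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames (frame `i` is at
#'   `(i-1) * frame_interval` s).
#' @param reference_index 1-based reference frame index.
#' @return a [frame_sequence]
#' @export
load_sequence <- function(source, pixel_size, frame_interval,
                          reference_index = 1L) {
  if (length(source) == 1L && dir.exists(source)) {
    source <- sort(list.files(source, full.names = TRUE,
                              pattern = "\\.(tiff?|png)$", ignore.case = TRUE))
    if (length(source) == 0L) stopf("no TIFF/PNG frames found in directory")
  }
  missing <- source[!file.exists(source)]
  if (length(missing) > 0)
    stopf("cannot read input file(s): %s", paste(missing, collapse = ", "))
  frames <- unlist(lapply(source, .read_frame_file), recursive = FALSE)
  if (length(frames) < 2L)
    stopf("need at least 2 frames, found %d", length(frames))
  frame_sequence(frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 reference_index = reference_index)
}

#' Percentile contrast stretching
#'
#' Linearly rescales intensities so the `p_low` percentile maps to 0 and the
#' `p_high` percentile maps to 1, clipping outside `[0, 1]`.  Used to make
#' the speckle features of the slice more prominent before displacement
#' tracking.  A constant frame (zero percentile span) yields an all-zero
#' frame with a warning rather than an error.
#'
#' @param frame numeric matrix of intensities.
#' @param p_low,p_high percentiles in `[0, 100]` with `p_low < p_high`.
#' @return rescaled matrix in `[0, 1]`.
#' @export
stretch_contrast <- function(frame, p_low = 2, p_high = 98) {
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stopf("need 0 <= p_low < p_high <= 100 (got %g, %g)", p_low, p_high)
  q <- quantile(frame, probs = c(p_low, p_high) / 100, names = FALSE,
                na.rm = TRUE)
  span <- q[2] - q[1]
  if (span <= 0) {
    warnf("contrast stretch on a constant frame: returning all zeros")
    return(array(0, dim(frame)))
  }
  pmin(pmax((frame - q[1]) / span, 0), 1)
}

#' Local-variance tissue mask
#'
#' Separates textured tissue from smooth non-tissue regions (lumen
#' interior, agarose voids, empty background).  Intensity alone cannot do
#' this — agarose and lumen can both be bright — but tissue carries a
#' speckle texture, so a local-standard-deviation map thresholded with
#' Otsu's criterion isolates it.  The thresholded map is closed
#' morphologically to bridge low-contrast speckle gaps, eroded to undo the
#' outward bleed of the SD estimator across texture edges, and cleaned of
#' small components and holes.  Because both the SD map and the Otsu split
#' are normalised, the mask is invariant to global intensity scaling of
#' the frame.
#'
#' @param frame preprocessed intensity matrix.
#' @param sd_sigma Gaussian sigma (px) of the local-variance estimator
#'   (small, so texture edges stay sharp).
#' @param close_radius disc radius (px) of the morphological closing that
#'   bridges gaps between speckle features.
#' @param erode_radius disc radius (px) of the erosion compensating the
#'   SD estimator's support beyond texture edges.
#' @param min_area connected tissue components smaller than this (px) are
#'   dropped.
#' @param max_hole holes smaller than this (px) are filled.
#' @param threshold optional fixed threshold on the normalised local-SD map
#'   in `[0, 1]`; default `NULL` uses Otsu's criterion.
#' @return logical matrix, `TRUE` where tissue is present.
#' @export
tissue_mask <- function(frame, sd_sigma = 2, close_radius = 5,
                        erode_radius = 3, min_area = 100, max_hole = 200,
                        threshold = NULL) {
  mu <- .gsmooth(frame, sd_sigma)
  mu2 <- .gsmooth(frame^2, sd_sigma)
  lsd <- sqrt(pmax(mu2 - mu^2, 0))
  rng <- range(lsd)
  # a (numerically) constant frame has no texture anywhere
  if (rng[2] - rng[1] <= 1e-6 * max(abs(frame), 1)) {
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  # normalising by the range makes the Otsu split invariant to global
  # intensity scaling of the input frame
  lsdn <- (lsd - rng[1]) / (rng[2] - rng[1])
  th <- if (is.null(threshold)) EBImage::otsu(lsdn, range = c(0, 1)) else threshold
  m <- lsdn > th
  if (!any(m)) return(m)
  # Otsu assumes two classes; on a frame that is textured everywhere it
  # splits the texture itself.  If the "background" class is not markedly
  # smoother than the "tissue" class, the whole frame is tissue.
  if (mean(lsdn[!m]) > 0.3 * mean(lsdn[m]))
    return(matrix(TRUE, nrow(frame), ncol(frame)))
  if (close_radius > 0)
    m <- EBImage::closing(m * 1,
                          EBImage::makeBrush(2 * close_radius + 1,
                                             "disc")) > 0
  if (erode_radius > 0)
    m <- EBImage::erode(m * 1,
                        EBImage::makeBrush(2 * erode_radius + 1,
                                           "disc")) > 0
  m <- .fill_small_holes(m, max_hole)
  m <- .drop_small_components(m, min_area)
  m
}

.drop_small_components <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

.fill_small_holes <- function(mask, max_hole) {
  if (!any(mask)) return(mask)
  filled <- EBImage::fillHull(mask * 1) > 0
  holes <- filled & !mask
  if (!any(holes)) return(mask)
  lab <- EBImage::bwlabel(holes * 1)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < max_hole)
  mask | matrix(lab %in% small, nrow(mask), ncol(mask))
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices of equal dimension
#' @return scalar IoU in `[0, 1]` (1 if both are empty)
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
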
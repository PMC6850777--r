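#' Estimate the per-pixel camera bias from a dark stack
#'
#' The bias map is the per-pixel arithmetic mean over frames acquired with no
#' illumination.
#'
#' @param dark_stack numeric array x * y * n (n >= 2) of dark frames.
#' @return bias map matrix.
#' @export
estimateBias <- function(dark_stack) {
  d <- dim(dark_stack)
  if (length(d) != 3L || d[3] < 2L)
    stop("dark_stack must be an x*y*n array with at least 2 frames")
  apply(dark_stack, c(1, 2), mean)
}

#' Estimate the flat-field correction from a dye stack
#'
#' Each bias-subtracted dye frame is grayscale-dilated with a disk of radius
#' `dilation_radius` (removing narrow dark device features), the per-pixel
#' median across frames is taken as the illumination field, and the correction
#' is the inverse field renormalized to mean 1, so corrected images stay on
#' the raw intensity scale.
#'
#' @param dye_stack numeric array x * y * n (n >= 3) of bias-subtracted frames.
#' @param params a [QuantParams-class].
#' @return flat-field correction matrix (mean 1).
#' @export
estimateFlatfield <- function(dye_stack, params = quantParams()) {
  validObject(params)
  d <- dim(dye_stack)
  if (length(d) != 3L || d[3] < 3L)
    stop("dye_stack must be an x*y*n array with at least 3 frames")
  brush <- EBImage::makeBrush(2L * params@dilation_radius + 1L, "disc")
  dil <- array(0, d)
  for (k in seq_len(d[3]))
    dil[, , k] <- as.matrix(EBImage::dilate(EBImage::Image(dye_stack[, , k]), brush))
  field <- apply(dil, c(1, 2), stats::median)
  if (any(field <= 0))
    stop("nonpositive field values after dilation; cannot invert")
  # inverse field, renormalized so the correction has mean exactly 1 (the
  # naive mean(field)/field has mean slightly above 1 by Jensen's inequality)
  flat <- 1 / field
  flat / mean(flat)
}

#' Apply bias subtraction and flat-field correction to an image
#'
#' `corrected = (raw - bias) * flat_correction`, clipped at zero.
#'
#' @param raw image matrix.
#' @param calib a [CalibrationSet-class].
#' @return corrected image matrix.
#' @export
correctImage <- function(raw, calib) {
  validObject(calib)
  if (!identical(dim(raw), dim(calib@bias_map)))
    stop("image shape does not match calibration maps")
  pmax((raw - calib@bias_map) * calib@flat_correction, 0)
}

#' Top-fraction asymmetry score of a cell's pixels
#'
#' Mean of the brightest `top_fraction` of the pixels (count `ceil(fraction *
#' n)`, at least one pixel) divided by the median of all mask pixels. The
#' median normalization makes the score invariant to multiplicative rescaling,
#' e.g. photobleaching. High scores indicate a concentrated (nucleolar /
#' nuclear) signal; a uniform cell scores exactly 1.
#'
#' @param pixels numeric vector of pixel values inside one cell mask.
#' @param params a [QuantParams-class].
#' @return scalar score.
#' @examples
#' nucleolarAsymmetry(c(rep(1, 980), rep(11, 20)), quantParams())  # 11
#' @export
nucleolarAsymmetry <- function(pixels, params = quantParams()) {
  validObject(params)
  n <- length(pixels)
  if (n < params@min_mask_pixels)
    stop(sprintf("mask has %d pixels; minimum is %d", n, params@min_mask_pixels))
  med <- stats::median(pixels)
  if (med == 0)
    stop("median pixel value is zero; score undefined")
  k <- max(1L, as.integer(ceiling(params@top_fraction * n)))
  top <- sort(pixels, decreasing = TRUE)[seq_len(k)]
  mean(top) / med
}

#' Extract mother/daughter compartment signals from an image series
#'
#' Sums the corrected intensity within each mask per frame, producing the raw
#' material of a [TraceSet-class] trace pair.
#'
#' @param stack numeric array x * y * n of (corrected) frames.
#' @param mother_mask,daughter_mask logical or 0/1 matrices; must be disjoint.
#' @param times_min frame times (minutes); defaults to 5-minute cadence.
#' @return list with `time_min`, `mother`, `daughter` summed series.
#' @export
extractCompartmentSignal <- function(stack, mother_mask, daughter_mask,
                                     times_min = NULL) {
  d <- dim(stack)
  mm <- mother_mask != 0; dm <- daughter_mask != 0
  if (!any(mm) || !any(dm)) stop("empty compartment mask")
  if (any(mm & dm)) stop("mother and daughter masks overlap")
  if (is.null(times_min)) times_min <- (seq_len(d[3]) - 1L) * 5
  mother <- vapply(seq_len(d[3]), function(k) sum(stack[, , k][mm]), numeric(1))
  daughter <- vapply(seq_len(d[3]), function(k) sum(stack[, , k][dm]), numeric(1))
  list(time_min = times_min, mother = mother, daughter = daughter)
}
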
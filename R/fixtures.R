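#' Generate synthetic microscopy image fixtures with ground truth
#'
#' Three scenarios mirror the calibration and quantification inputs of a
#' microfluidic aging run:
#' \describe{
#'   \item{dark}{frames with no illumination: a fixed per-pixel bias pattern
#'     plus Gaussian read noise. Ground truth: the bias map.}
#'   \item{dye}{a fluorescent dye imaged through the device: smooth
#'     multiplicative vignette times a dye level, with small per-frame x/y
#'     offsets and narrow dark device features (1-2 px lines). Ground truth:
#'     the vignette map and the feature mask.}
#'   \item{cells}{disk-shaped cells containing bright nuclear foci on a dark
#'     background. Ground truth: the label mask and the true top-2%/median
#'     asymmetry score of each noiseless cell.}
#' }
#'
#' @param shape integer length-2 pixel dimensions (>= 64 each).
#' @param n_frames number of frames (>= 1).
#' @param scenario one of `"dark"`, `"dye"`, `"cells"`.
#' @param seed integer seed.
#' @param read_noise_sd dark-scenario read noise SD (AU).
#' @param bias_level mean dark bias (AU).
#' @param vignette_amplitude fractional center-to-corner falloff of the dye
#'   vignette (0 = flat field).
#' @param dye_level mean dye intensity (AU).
#' @param noise_cv multiplicative shot-noise CV for dye/cells frames.
#' @return list with `stack` (x * y * n_frames array) and scenario-specific
#'   ground truth (`bias_map`; or `vignette`, `feature_mask`, `offsets`; or
#'   `mask`, `true_scores`, `noiseless`).
#' @export
generateImageFixtures <- function(shape = c(64L, 64L), n_frames = 8L,
                                  scenario = c("dark", "dye", "cells"),
                                  seed = 1L,
                                  read_noise_sd = 2, bias_level = 100,
                                  vignette_amplitude = 0.3, dye_level = 1000,
                                  noise_cv = 0.02) {
  scenario <- match.arg(scenario)
  if (length(shape) != 2L || any(shape < 64))
    stop("shape must be two dimensions, each >= 64")
  if (n_frames < 1) stop("n_frames must be >= 1")
  shape <- as.integer(shape)
  set.seed(as.integer(seed))
  nx <- shape[1]; ny <- shape[2]
  xs <- seq_len(nx); ys <- seq_len(ny)

  vignetteMap <- function(amp) {
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    r2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    v <- 1 - amp * r2 / max(r2)
    v / mean(v)
  }

  if (scenario == "dark") {
    bias <- bias_level + 5 * matrix(stats::rnorm(nx * ny), nx, ny) +
      2 * sin(outer(xs / 7, ys / 11, "+"))
    stack <- array(0, c(nx, ny, n_frames))
    for (k in seq_len(n_frames))
      stack[, , k] <- bias +
        if (read_noise_sd > 0) matrix(stats::rnorm(nx * ny, 0, read_noise_sd), nx, ny) else 0
    return(list(stack = stack, bias_map = bias))
  }

  if (scenario == "dye") {
    vig <- vignetteMap(vignette_amplitude)
    feat <- matrix(FALSE, nx, ny)
    fx <- sort(sample(seq(8L, nx - 8L), 2))
    feat[fx, ] <- TRUE         # narrow vertical device walls
    fy <- sample(seq(8L, ny - 8L), 1)
    feat[, fy] <- TRUE         # one horizontal channel edge
    offsets <- cbind(x = sample(-2:2, n_frames, replace = TRUE),
                     y = sample(-2:2, n_frames, replace = TRUE))
    stack <- array(0, c(nx, ny, n_frames))
    base <- dye_level * vig
    for (k in seq_len(n_frames)) {
      fr <- base
      shf <- feat
      shf <- shiftMatrix(feat, offsets[k, 1], offsets[k, 2])
      fr[shf] <- fr[shf] * 0.15
      if (noise_cv > 0)
        fr <- fr * (1 + noise_cv * matrix(stats::rnorm(nx * ny), nx, ny))
      stack[, , k] <- pmax(fr, 0)
    }
    return(list(stack = stack, vignette = vig, feature_mask = feat,
                offsets = offsets))
  }

  # cells: disks with bright nuclear foci; one label per cell
  mask <- matrix(0L, nx, ny)
  noiseless <- matrix(10, nx, ny)       # dim background
  # jittered grid placement keeps cell disks disjoint
  gx <- seq(16, nx - 16, by = 32)
  gy <- seq(16, ny - 16, by = 32)
  centers <- as.matrix(expand.grid(gx, gy))
  centers <- centers + matrix(stats::runif(length(centers), -3, 3),
                              nrow(centers))
  n_cells <- nrow(centers)
  radius <- 9
  true_scores <- numeric(n_cells)
  for (c in seq_len(n_cells)) {
    d2 <- outer((xs - centers[c, 1])^2, (ys - centers[c, 2])^2, "+")
    disk <- d2 <= radius^2 & mask == 0L
    cyto <- stats::runif(1, 80, 140)
    noiseless[disk] <- cyto
    # nuclear focus: small bright blob near center
    f2 <- outer((xs - centers[c, 1] + stats::runif(1, -2, 2))^2,
                (ys - centers[c, 2] + stats::runif(1, -2, 2))^2, "+")
    focus <- f2 <= 2.5^2 & disk
    noiseless[focus] <- cyto * stats::runif(1, 5, 9)
    mask[disk] <- c
    true_scores[c] <- nucleolarAsymmetry(noiseless[mask == c], quantParams())
  }
  stack <- array(0, c(nx, ny, n_frames))
  for (k in seq_len(n_frames)) {
    fr <- noiseless
    if (noise_cv > 0)
      fr <- fr * (1 + noise_cv * matrix(stats::rnorm(nx * ny), nx, ny))
    stack[, , k] <- pmax(fr, 0)
  }
  list(stack = stack, mask = mask, true_scores = true_scores,
       noiseless = noiseless)
}

# integer shift with edge replication (for per-frame stage offsets)
shiftMatrix <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  xi <- pmin(pmax(seq_len(nx) - dx, 1L), nx)
  yi <- pmin(pmax(seq_len(ny) - dy, 1L), ny)
  m[xi, yi, drop = FALSE]
}
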
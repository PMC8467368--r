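#' Shift-and-add back projection
#'
#' Reconstructs in-focus plane images: the plane at height h (mm from the
#' isocenter, along the source-detector axis) is the mean over views of
#' each projection shifted by `-tan(theta_v) * h / pitch` pixels along the
#' sweep axis (subpixel linear interpolation, replicate-edge padding), so
#' structures at that height align across views. Deterministic.
#'
#' @param projections a [ProjectionSet-class] (or plain array with
#'   `geometry` supplied).
#' @param planeHeights plane heights in mm, strictly increasing.
#' @param geometry required when `projections` is a bare array.
#' @param filtered internal: apply the sweep-axis ramp filter first.
#' @return A [ReconVolume-class].
#' @export
backproject <- function(projections, planeHeights = NULL, geometry = NULL,
                        filtered = FALSE) {
  if (is(projections, "ProjectionSet")) {
    geometry <- projections@geometry
    imgs <- projections@images
    dom <- projections@domain
  } else {
    if (is.null(geometry)) stop("geometry required for a bare array")
    imgs <- asStack(projections)
    dom <- "intermediate"
  }
  if (is.null(planeHeights)) planeHeights <- defaultPlaneHeights(geometry)
  if (is.unsorted(planeHeights, strictly = TRUE))
    stop("planeHeights must be strictly increasing")
  if (filtered) {
    for (v in seq_len(dim(imgs)[3]))
      imgs[, , v] <- fbpFilter(imgs[, , v])
  }
  angles <- viewAngles(geometry) * pi / 180
  nv <- dim(imgs)[3]
  out <- array(0, c(dim(imgs)[1], dim(imgs)[2], length(planeHeights)))
  for (p in seq_along(planeHeights)) {
    acc <- matrix(0, dim(imgs)[1], dim(imgs)[2])
    for (v in seq_len(nv)) {
      s <- -tan(angles[v]) * planeHeights[p] / geometry@detectorPitch
      acc <- acc + shiftRows(imgs[, , v], s, "replicate")
    }
    out[, , p] <- acc / nv
  }
  new("ReconVolume", planes = out, planeHeights = as.numeric(planeHeights),
      pixelSize = geometry@detectorPitch,
      algorithm = if (filtered) "FBP" else "BP", sourceDomain = dom)
}

#' Filtered back projection for linear tomosynthesis
#'
#' Applies a 1-D ramp filter apodized by a Hann window (cutoff at Nyquist)
#' along the sweep axis of every projection, then backprojects with
#' [backproject()]. The ramp nulls the DC component, so constant
#' projections reconstruct to approximately zero in the plane interior.
#'
#' @inheritParams backproject
#' @return A [ReconVolume-class] with algorithm tag `"FBP"`.
#' @export
fbpReconstruct <- function(projections, planeHeights = NULL,
                           geometry = NULL) {
  backproject(projections, planeHeights, geometry, filtered = TRUE)
}

#' Ramp-Hann filtering along the sweep axis
#'
#' Filters each column of `m` (the sweep axis runs along rows) with the
#' apodized ramp `H(f) = (|f| / f_N) * 0.5 * (1 + cos(pi f / f_N))`,
#' evaluated on a zero-padded FFT grid. Exposed so the filter kernel
#' itself can be inspected: filtering an impulse returns the kernel.
#'
#' @param m matrix (one projection image).
#' @return Filtered matrix of the same size.
#' @export
fbpFilter <- function(m) {
  n <- nrow(m)
  nfft <- 2^ceiling(log2(2 * n))
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) / nfft  # cycles/sample
  H <- (abs(f) / 0.5) * 0.5 * (1 + cos(pi * abs(f) / 0.5))
  H[abs(f) > 0.5] <- 0
  pad <- matrix(0, nfft, ncol(m))
  pad[seq_len(n), ] <- m
  ft <- stats::mvfft(pad) * H
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / nfft
  out[seq_len(n), , drop = FALSE]
}

#' Weighted DT-MAR combination of filtered and unfiltered reconstructions
#'
#' The DT-MAR baseline blends the filtered and plain back projections:
#' `(1 - w) * FBP + w * BP` elementwise, with the standard DT-MAR weighting
#' factor w = 0.6, i.e. `FBP * 0.4 + BP * 0.6`.
#'
#' @param fbp FBP plane image (matrix/array) or [ReconVolume-class].
#' @param bp back-projection plane of the same shape.
#' @param w back-projection weight in `[0, 1]` (default 0.6).
#' @return Same type as the inputs; for [ReconVolume-class] inputs a
#'   volume tagged `"DT-MAR"`.
#' @export
dtmarCombine <- function(fbp, bp, w = 0.6) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (is(fbp, "ReconVolume") && is(bp, "ReconVolume")) {
    if (!identical(dim(fbp@planes), dim(bp@planes)))
      stop("shape mismatch")
    out <- fbp
    out@planes <- (1 - w) * fbp@planes + w * bp@planes
    out@algorithm <- "DT-MAR"
    return(out)
  }
  if (!identical(dim(fbp), dim(bp))) stop("shape mismatch")
  (1 - w) * fbp + w * bp
}

#' Default reconstruction plane heights
#'
#' Nine planes spanning the implant region, spaced one detector pitch
#' apart and centred on the isocenter plane.
#'
#' @param geometry an [AcquisitionGeometry-class].
#' @param n number of planes.
#' @return Numeric vector of heights in mm.
#' @export
defaultPlaneHeights <- function(geometry, n = 9L) {
  geometry@detectorPitch * (seq_len(n) - (n + 1) / 2)
}
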
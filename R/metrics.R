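#' Mean squared error between two images
#'
#' @param ref,test images (matrices or arrays) of identical shape.
#' @return Mean of squared differences over all pixels.
#' @export
mse <- function(ref, test) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  mean((ref - test)^2)
}

#' Structural-similarity parameters
#'
#' Unit luminance/contrast/structure exponents, a `window` x `window`
#' uniform local window, and the standard small stabilizing constants
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, `C3 = C2 / 2` relative to the data
#' range L.
#'
#' @param omega,xi,psi exponents of the luminance, contrast and structure
#'   terms (all 1 by default).
#' @param window local window size in pixels.
#' @param K1,K2 stabilizing-constant factors.
#' @return A list of SSIM parameters.
#' @export
ssimParams <- function(omega = 1, xi = 1, psi = 1, window = 8L,
                       K1 = 0.01, K2 = 0.03) {
  stopifnot(K1 > 0, K2 > 0, window >= 2L)
  list(omega = omega, xi = xi, psi = psi, window = as.integer(window),
       K1 = K1, K2 = K2)
}

#' Mean structural similarity (MSSIM)
#'
#' Local SSIM maps `l^omega * c^xi * s^psi` computed over a sliding
#' uniform window, averaged over all window positions. With unit
#' exponents this is the standard SSIM product
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' split into its luminance, contrast and structure factors. The data
#' range L defaults to the joint range of both images.
#'
#' @param ref,test images of identical shape.
#' @param params from [ssimParams()].
#' @param dataRange value range L for the stabilizing constants; `NULL`
#'   uses the observed joint range.
#' @return MSSIM value in `[-1, 1]`.
#' @export
mssim <- function(ref, test, params = ssimParams(), dataRange = NULL) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  w <- params$window
  if (w > min(dim(ref)[1:2])) stop("window larger than image")
  if (is.null(dataRange)) {
    dataRange <- max(max(ref), max(test)) - min(min(ref), min(test))
    if (dataRange == 0) dataRange <- 1
  }
  C1 <- (params$K1 * dataRange)^2
  C2 <- (params$K2 * dataRange)^2
  C3 <- C2 / 2
  mux <- boxMean(ref, w); muy <- boxMean(test, w)
  sxx <- pmax(boxMean(ref * ref, w) - mux^2, 0)
  syy <- pmax(boxMean(test * test, w) - muy^2, 0)
  sxy <- boxMean(ref * test, w) - mux * muy
  sx <- sqrt(sxx); sy <- sqrt(syy)
  l <- (2 * mux * muy + C1) / (mux^2 + muy^2 + C1)
  cc <- (2 * sx * sy + C2) / (sxx + syy + C2)
  s <- (sxy + C3) / (sx * sy + C3)
  mean(l^params$omega * cc^params$xi * s^params$psi)
}

roiSlice <- function(plane, roi) {
  r <- roi@row + seq_len(roi@height)      # 0-based top-left
  cl <- roi@col + seq_len(roi@width)
  if (max(r) > nrow(plane) || max(cl) > ncol(plane) ||
      min(r) < 1L || min(cl) < 1L)
    stop("ROI '", roi@label, "' outside the plane")
  plane[r, cl]
}

#' Artifact index of an in-focus plane
#'
#' For each artifact ROI, the relative standard deviation (coefficient of
#' variation, SD/mean) is compared with that of the background ROI:
#' `AI_n = |rSD_artifact_n - rSD_background|`. Reports per-ROI values and
#' the group mean with its standard error. Lower AI means fewer artifacts.
#'
#' @param plane matrix (one in-focus plane) or [ReconVolume-class] (uses
#'   the central plane).
#' @param rois list of [ROISpec-class]: exactly one with group
#'   `"background"`, at least one artifact ROI.
#' @return An [AIResult-class].
#' @export
artifactIndex <- function(plane, rois) {
  if (is(plane, "ReconVolume"))
    plane <- plane@planes[, , ceiling(dim(plane@planes)[3] / 2)]
  groups <- vapply(rois, function(r) r@group, character(1))
  bg <- rois[groups == "background"]
  art <- rois[groups != "background"]
  if (length(bg) != 1L) stop("exactly one background ROI required")
  if (length(art) < 1L) stop("at least one artifact ROI required")
  relSD <- function(roi) {
    vals <- roiSlice(plane, roi)
    m <- mean(vals)
    if (abs(m) < 1e-12 * max(1, stats::sd(vals)))
      stop("ROI '", roi@label, "' has mean ~ 0; relative SD undefined")
    stats::sd(vals) / m
  }
  bgRSD <- relSD(bg[[1]])
  perROI <- data.frame(
    label = vapply(art, function(r) r@label, character(1)),
    group = vapply(art, function(r) r@group, character(1)),
    rSD = vapply(art, relSD, numeric(1))
  )
  perROI$AI <- abs(perROI$rSD - bgRSD)
  new("AIResult", perROI = perROI, backgroundRSD = bgRSD,
      mean = mean(perROI$AI),
      se = if (nrow(perROI) > 1L) standardError(perROI$AI) else NA_real_)
}

#' Extract parallel-line profiles from a measurement window
#'
#' Places a rectangular window on the plane (length axis along the sweep
#' direction, i.e. image rows) and samples `nProfiles` parallel lines at
#' 1-pixel intervals, each of `length` positions. Per profile the sample
#' series is the adjacent-position differences, so a 24-position profile
#' yields 23 samples. The canonical protocol uses 23 profiles of sampling
#' size 23; `nProfiles = 8` (one line per window-width pixel) and
#' `nProfiles = 48` are alternative readings selectable here.
#'
#' @param plane matrix or [ReconVolume-class] (central plane).
#' @param row,col 0-based top-left corner of the window.
#' @param length profile length in pixels along the sweep axis.
#' @param nProfiles number of parallel lines (window width).
#' @return Matrix `nProfiles x (length - 1)` of adjacent differences.
#' @export
extractProfiles <- function(plane, row = 0L, col = 0L, length = 24L,
                            nProfiles = 23L) {
  if (is(plane, "ReconVolume"))
    plane <- plane@planes[, , ceiling(dim(plane@planes)[3] / 2)]
  rows <- row + seq_len(length)
  cols <- col + seq_len(nProfiles)
  if (max(rows) > nrow(plane) || max(cols) > ncol(plane))
    stop("window outside plane")
  win <- plane[rows, cols, drop = FALSE]
  t(apply(win, 2, diff))
}

#' Gumbel largest-variation analysis
#'
#' Per profile, the largest variation is the maximum absolute difference
#' between adjacent pixel values. The sorted largest variations x_delta
#' receive symmetry-rank plotting positions
#' `Gamma(x_delta) = (delta - 0.5) / q` and reduced variates
#' `-log(-log(Gamma))`; for Gumbel-distributed variations the plot of
#' x against the reduced variate is linear, which the Pearson correlation
#' between the two quantifies.
#'
#' @param profiles matrix of adjacent differences (rows = profiles), as
#'   returned by [extractProfiles()], or a numeric vector of
#'   precomputed largest variations.
#' @return A [GumbelSample-class].
#' @export
gumbelAnalysis <- function(profiles) {
  x <- if (is.matrix(profiles)) apply(abs(profiles), 1, max)
       else as.numeric(profiles)
  q <- length(x)
  if (q < 3L) stop("need at least 3 profiles (Pearson r undefined)")
  xs <- sort(x)
  gamma <- gumbelPlottingPositions(q)
  red <- -log(-log(gamma))
  new("GumbelSample", x = xs, gamma = gamma, q = as.integer(q),
      reducedVariate = red, pearsonR = pearsonR(xs, red))
}

#' Symmetry-rank plotting positions
#'
#' `Gamma(delta) = (delta - 0.5) / q` for `delta = 1, ..., q`; depends
#' only on the sample size, never on the data.
#'
#' @param q sample size.
#' @return Numeric vector of length q, strictly increasing in (0, 1).
#' @examples
#' gumbelPlottingPositions(4)  # 0.125 0.375 0.625 0.875
#' @export
gumbelPlottingPositions <- function(q) {
  (seq_len(q) - 0.5) / q
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length series of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance")
  stats::cor(x, y)
}
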
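#' Segment the metal trace in projection space
#'
#' Per view, pixels with projection value at or above the threshold are
#' labelled metal (the implant attenuates strictly more than any tissue,
#' so its trace occupies the top of the post-log value histogram). When no
#' threshold is given, Otsu's method restricted to the upper decile of the
#' values picks one. The mask is then dilated (default 1 pixel) to guard
#' against partial-volume rims at the trace boundary. An acquisition with
#' no metal yields an all-zero mask with the empty flag set (and a
#' warning), never an error.
#'
#' @param projections a [ProjectionSet-class] or projection array.
#' @param threshold projection-value threshold; `NULL` for automatic.
#' @param dilation dilation radius in pixels (0 disables).
#' @return A [MetalMask-class].
#' @export
extractMetalMask <- function(projections, threshold = NULL, dilation = 1L) {
  imgs <- asStack(projections)
  if (is.null(threshold)) threshold <- otsuThreshold(imgs)
  masks <- array(0, dim(imgs))
  for (v in seq_len(dim(imgs)[3])) {
    m <- (imgs[, , v] >= threshold) * 1
    if (dilation >= 1L && any(m == 1)) m <- dilateMask(m, dilation)
    masks[, , v] <- m
  }
  empty <- !any(masks == 1)
  if (empty) warning("no metal found: mask is empty in every view")
  new("MetalMask", masks = masks, threshold = as.numeric(threshold),
      dilation = as.integer(dilation), empty = empty)
}

#' Remove the metal trace from a projection stack
#'
#' Pixels under the mask are replaced by NA (treated as missing by the
#' downstream interpolation); all other pixels are copied unchanged.
#'
#' @param projections a [ProjectionSet-class] or array.
#' @param mask a [MetalMask-class] (or 0/1 array) of the same shape.
#' @return Array of the same shape with NA inside the trace.
#' @export
removeMetal <- function(projections, mask) {
  imgs <- asStack(projections)
  m <- if (is(mask, "MetalMask")) mask@masks else mask
  if (!identical(dim(imgs), dim(m))) stop("shape mismatch")
  imgs[m == 1] <- NA_real_
  imgs
}

#' Linear interpolation across the metal trace
#'
#' Per view and per detector row (the interpolation axis runs across the
#' sweep axis, so rows cross the metal trace transversally), every
#' contiguous missing run is replaced by the straight line between its
#' flanking valid values. Runs touching the detector border replicate the
#' single available flank; a fully missing row falls back to the nearest
#' row with valid pixels (with a warning); a fully missing view is an
#' error. Valid pixels are copied bit-exactly.
#'
#' @param pTemp metal-removed stack from [removeMetal()] (NA = missing).
#' @param mask the [MetalMask-class] (or 0/1 array) used for removal.
#' @return Array of the same shape with no missing values.
#' @export
linearInterpolate <- function(pTemp, mask) {
  imgs <- asStack(pTemp)
  m <- if (is(mask, "MetalMask")) mask@masks else mask
  if (!identical(dim(imgs), dim(m))) stop("shape mismatch")
  warnedRow <- FALSE
  for (v in seq_len(dim(imgs)[3])) {
    mv <- matrix(m[, , v], dim(m)[1], dim(m)[2])
    if (all(mv == 1)) stop("view ", v, " is fully masked; nothing to ",
                           "interpolate from")
    if (!any(mv == 1)) next
    plane <- matrix(imgs[, , v], dim(imgs)[1], dim(imgs)[2])
    fullRows <- which(apply(mv == 1, 1, all))
    partRows <- which(apply(mv, 1, function(r) any(r == 1) && !all(r == 1)))
    for (r in partRows) {
      plane[r, ] <- interpRow(plane[r, ], mv[r, ] == 1)
    }
    if (length(fullRows)) {
      if (!warnedRow) {
        warning("fully masked detector row(s): nearest valid row used")
        warnedRow <- TRUE
      }
      validRows <- setdiff(seq_len(nrow(plane)), fullRows)
      for (r in fullRows) {
        nearest <- validRows[which.min(abs(validRows - r))]
        plane[r, ] <- plane[nearest, ]
      }
    }
    imgs[, , v] <- plane
  }
  imgs
}

# One detector row: straight-line fill of masked runs from the flanking
# unmasked values; border runs replicate the single flank (rule = 2).
interpRow <- function(x, masked) {
  keep <- which(!masked)
  fill <- which(masked)
  x[fill] <- stats::approx(keep, x[keep], xout = fill, method = "linear",
                           rule = 2)$y
  x
}
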
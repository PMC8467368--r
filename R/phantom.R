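#' Specification of a synthetic prosthesis phantom
#'
#' The phantom volume is a `rows x cols x depth` voxel grid (rows = sweep
#' axis, depth = source-detector axis). Materials are `air`, `water`,
#' `bone` and `metal`, each with one linear attenuation coefficient
#' (mm^-1) per spectral energy bin. Shapes are cylinders with axis along
#' the rows (a water bath, a bone shaft, a metal intramedullary nail);
#' painting precedence is metal > bone > water > air, so overlapping
#' shapes voxelize the way the physical phantom nests.
#'
#' @slot dim integer (rows, cols, depth) voxel counts.
#' @slot voxelSize voxel edge length in mm.
#' @slot spectrum relative fluence per energy bin (sums to 1).
#' @slot attenuation matrix materials x bins (mm^-1); row names
#'   `air`, `water`, `bone`, `metal`. Metal must attenuate strictly most
#'   in every bin.
#' @slot shapes list of cylinder specs: each a list with `material`,
#'   `centerCol`, `centerDepth`, `radius` (all in voxel units) and
#'   `rowRange` (inclusive, 1-based).
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(dim = "integer", voxelSize = "numeric",
                 spectrum = "numeric", attenuation = "matrix",
                 shapes = "list")
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@attenuation < 0))
    msg <- c(msg, "attenuation must be >= 0 everywhere")
  if (abs(sum(object@spectrum) - 1) > 1e-8)
    msg <- c(msg, "spectrum weights must sum to 1")
  need <- c("air", "water", "bone", "metal")
  if (!all(need %in% rownames(object@attenuation)))
    msg <- c(msg, "attenuation needs rows air, water, bone, metal")
  else {
    mu <- object@attenuation
    others <- mu[setdiff(rownames(mu), "metal"), , drop = FALSE]
    if (!all(mu["metal", ] > apply(others, 2, max)))
      msg <- c(msg, "metal attenuation must be strictly greatest per bin")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param dim integer (rows, cols, depth).
#' @param voxelSize voxel size in mm.
#' @param spectrum relative fluence per bin (normalized to sum 1).
#' @param attenuation materials x bins matrix (mm^-1), rows
#'   air/water/bone/metal.
#' @param shapes list of cylinder shape specs (see [PhantomSpec-class]).
#' @return A [PhantomSpec-class].
#' @export
PhantomSpec <- function(dim, voxelSize, spectrum, attenuation, shapes) {
  new("PhantomSpec", dim = as.integer(dim), voxelSize = voxelSize,
      spectrum = spectrum / sum(spectrum), attenuation = attenuation,
      shapes = shapes)
}

#' Default attenuation table and spectrum
#'
#' Three energy bins representing a filtered 80 kVp tungsten-anode beam
#' (soft / middle / hard components), with tabulated linear attenuation
#' coefficients (mm^-1) for water, cortical-bone-like material and
#' titanium alloy. Values are simulator parameters chosen to reproduce
#' the qualitative physics (beam hardening, photon starvation behind the
#' implant), not measured data.
#'
#' @return A list with `spectrum` and `attenuation`.
#' @export
defaultMaterials <- function() {
  att <- rbind(
    air   = c(0,     0,     0),
    water = c(0.027, 0.021, 0.018),
    bone  = c(0.090, 0.045, 0.032),
    metal = c(0.450, 0.200, 0.130)
  )
  colnames(att) <- c("soft", "mid", "hard")
  list(spectrum = c(soft = 0.35, mid = 0.45, hard = 0.20),
       attenuation = att)
}

#' Default desk-scale prosthesis phantom
#'
#' A 64^3 voxel volume (3 mm voxels): a water bath cylinder, a bone shaft
#' and a titanium-alloy nail inside the shaft, all with axis along the
#' sweep direction (image rows); the nail is shorter than the bone, as in
#' an intramedullary fixation.
#'
#' @param n cube edge in voxels.
#' @param voxelSize voxel size in mm.
#' @return A [PhantomSpec-class].
#' @export
defaultPhantom <- function(n = 64L, voxelSize = 3) {
  mat <- defaultMaterials()
  cc <- (n + 1) / 2
  PhantomSpec(
    dim = c(n, n, n), voxelSize = voxelSize,
    spectrum = mat$spectrum, attenuation = mat$attenuation,
    shapes = list(
      list(material = "water", centerCol = cc, centerDepth = cc,
           radius = 0.44 * n, rowRange = c(1L, n)),
      list(material = "bone", centerCol = cc, centerDepth = cc,
           radius = 0.08 * n, rowRange = c(1L, n)),
      list(material = "metal", centerCol = cc, centerDepth = cc,
           radius = 0.04 * n, rowRange = c(round(0.16 * n),
                                           round(0.84 * n)))
    )
  )
}

#' Voxelize a phantom specification
#'
#' Paints the shapes into the voxel grid with precedence
#' metal > bone > water (a lower-precedence shape can never overwrite a
#' higher one), then tabulates per-bin attenuation volumes. Deterministic
#' for a given spec.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with `labels` (integer array, 0 = air, 1 = water,
#'   2 = bone, 3 = metal), `mu` (list of per-bin attenuation arrays,
#'   mm^-1), `spec`.
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  d <- spec@dim
  labels <- array(0L, d)
  rank <- c(air = 0L, water = 1L, bone = 2L, metal = 3L)
  colIdx <- matrix(rep(seq_len(d[2]), d[3]), d[2], d[3])
  depIdx <- matrix(rep(seq_len(d[3]), each = d[2]), d[2], d[3])
  for (lv in 1:3) {  # paint in precedence order: water, bone, metal
    for (sh in spec@shapes) {
      if (rank[[sh$material]] != lv) next
      inside <- (colIdx - sh$centerCol)^2 + (depIdx - sh$centerDepth)^2 <=
        sh$radius^2
      rows <- seq(max(1L, sh$rowRange[1]), min(d[1], sh$rowRange[2]))
      sel <- which(inside, arr.ind = TRUE)  # (col, depth) pairs
      if (nrow(sel)) {
        lin0 <- (sel[, 1] - 1L) * d[1] + (sel[, 2] - 1L) * d[1] * d[2]
        for (r in rows) labels[r + lin0] <- lv
      }
    }
  }
  bins <- colnames(spec@attenuation)
  mu <- lapply(seq_along(bins), function(bidx) {
    lut <- spec@attenuation[c("air", "water", "bone", "metal"), bidx]
    array(lut[labels + 1L], d)
  })
  names(mu) <- bins
  list(labels = labels, mu = mu, spec = spec)
}
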
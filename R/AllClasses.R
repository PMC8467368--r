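#' @import methods
#' @importFrom stats cor rnorm runif rpois rbinom sd median
#' @importFrom utils modifyList
#' @importFrom tools file_path_sans_ext
#' @useDynLib dtmar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Acquisition geometry of a linear-sweep tomosynthesis scan
#'
#' Describes the linear source sweep: number of views, total sweep angle,
#' source-isocenter and source-detector distances, detector pitch and shape.
#' The sweep axis is the image axis along which the source motion displaces
#' structures (axis 1 = image rows by convention; row 0 at top).
#'
#' @slot nViews number of projection views.
#' @slot sweepAngle total sweep angle in degrees.
#' @slot sourceIsocenter source-to-isocenter distance in mm.
#' @slot sourceDetector source-to-detector distance in mm.
#' @slot detectorPitch detector element pitch in mm.
#' @slot detectorShape integer (rows, cols) of the detector matrix.
#' @slot sweepAxis image axis index of the sweep direction (1 = rows).
#'
#' @exportClass AcquisitionGeometry
setClass("AcquisitionGeometry",
  representation(
    nViews = "integer",
    sweepAngle = "numeric",
    sourceIsocenter = "numeric",
    sourceDetector = "numeric",
    detectorPitch = "numeric",
    detectorShape = "integer",
    sweepAxis = "integer"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  if (object@nViews < 1L) msg <- c(msg, "nViews must be >= 1")
  if (object@sweepAngle <= 0) msg <- c(msg, "sweepAngle must be > 0")
  if (!(object@sourceDetector > object@sourceIsocenter &&
        object@sourceIsocenter > 0))
    msg <- c(msg, "need sourceDetector > sourceIsocenter > 0")
  if (object@detectorPitch <= 0) msg <- c(msg, "detectorPitch must be > 0")
  if (length(object@detectorShape) != 2L || any(object@detectorShape < 1L))
    msg <- c(msg, "detectorShape must be two positive integers")
  if (!object@sweepAxis %in% c(1L, 2L))
    msg <- c(msg, "sweepAxis must be 1 (rows) or 2 (cols)")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionGeometry
#'
#' @param nViews number of views.
#' @param sweepAngle total sweep angle (degrees).
#' @param sourceIsocenter source-isocenter distance (mm).
#' @param sourceDetector source-detector distance (mm).
#' @param detectorPitch detector pitch (mm).
#' @param detectorShape integer vector (rows, cols).
#' @param sweepAxis sweep axis index (1 = image rows).
#' @return An [AcquisitionGeometry-class] object.
#' @export
AcquisitionGeometry <- function(nViews, sweepAngle, sourceIsocenter,
                                sourceDetector, detectorPitch, detectorShape,
                                sweepAxis = 1L) {
  new("AcquisitionGeometry",
    nViews = as.integer(nViews), sweepAngle = as.numeric(sweepAngle),
    sourceIsocenter = as.numeric(sourceIsocenter),
    sourceDetector = as.numeric(sourceDetector),
    detectorPitch = as.numeric(detectorPitch),
    detectorShape = as.integer(detectorShape),
    sweepAxis = as.integer(sweepAxis)
  )
}

#' Dose level of an acquisition
#'
#' A dose level is identified by its per-view exposure time; the relative
#' fluence is the exposure time divided by the reference exposure time
#' (20 ms/view), so the reference level has relative fluence 1.
#'
#' @slot label short label, e.g. `"reference"` or `"55pct_reduced"`.
#' @slot msPerView exposure time per view in ms.
#' @slot relativeFluence fluence relative to the reference level, in (0, 1].
#' @exportClass DoseLevel
setClass("DoseLevel",
  representation(label = "character", msPerView = "numeric",
                 relativeFluence = "numeric")
)

setValidity("DoseLevel", function(object) {
  if (object@relativeFluence <= 0 || object@relativeFluence > 1)
    "relativeFluence must be in (0, 1]" else TRUE
})

#' Construct a DoseLevel
#'
#' @param label text label.
#' @param msPerView exposure time per view (ms).
#' @param referenceMsPerView reference exposure time (ms); the relative
#'   fluence is `msPerView / referenceMsPerView`.
#' @return A [DoseLevel-class] object.
#' @export
DoseLevel <- function(label, msPerView, referenceMsPerView = 20) {
  new("DoseLevel", label = label, msPerView = as.numeric(msPerView),
      relativeFluence = as.numeric(msPerView) / referenceMsPerView)
}

#' A stack of post-log projection images
#'
#' Images are stored as a `rows x cols x nViews` numeric array of post-log
#' line integrals (single-precision on disk). The domain tag distinguishes
#' the low-dose domain A, the reference-dose domain B, and pipeline
#' intermediates.
#'
#' @slot images numeric array, `rows x cols x nViews`.
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot dose a [DoseLevel-class].
#' @slot domain one of `"low"`, `"reference"`, `"intermediate"`.
#' @exportClass ProjectionSet
setClass("ProjectionSet",
  representation(images = "array", geometry = "AcquisitionGeometry",
                 dose = "DoseLevel", domain = "character")
)

setValidity("ProjectionSet", function(object) {
  d <- dim(object@images)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "images must be a 3-d array")
  else {
    if (d[3] != object@geometry@nViews)
      msg <- c(msg, "one image per view required")
    if (!all(d[1:2] == object@geometry@detectorShape))
      msg <- c(msg, "image shape inconsistent with detectorShape")
  }
  if (!all(is.finite(object@images)))
    msg <- c(msg, "all projection values must be finite")
  if (!object@domain %in% c("low", "reference", "intermediate"))
    msg <- c(msg, "domain must be low/reference/intermediate")
  if (length(msg)) msg else TRUE
})

#' Construct a ProjectionSet
#'
#' @param images `rows x cols x nViews` array of post-log projections.
#' @param geometry an [AcquisitionGeometry-class].
#' @param dose a [DoseLevel-class].
#' @param domain `"low"`, `"reference"` or `"intermediate"`.
#' @return A [ProjectionSet-class].
#' @export
ProjectionSet <- function(images, geometry, dose, domain = "intermediate") {
  new("ProjectionSet", images = images, geometry = geometry, dose = dose,
      domain = domain)
}

#' Per-view binary metal-trace masks
#'
#' @slot masks 0/1 array with the shape of the source projection stack.
#' @slot threshold projection-value threshold used for segmentation.
#' @slot dilation dilation radius (pixels) applied after thresholding.
#' @slot empty TRUE when no metal was found in any view.
#' @exportClass MetalMask
setClass("MetalMask",
  representation(masks = "array", threshold = "numeric",
                 dilation = "integer", empty = "logical")
)

setValidity("MetalMask", function(object) {
  if (!all(object@masks %in% c(0, 1)))
    return("mask values must be 0 or 1")
  if (length(dim(object@masks)) != 3L)
    return("masks must be a 3-d array")
  TRUE
})

#' Named intermediate stacks of the MAR pipeline
#'
#' Holds the six named stacks produced by a full pipeline run:
#' `translated` (stage-1 output), `metalRemoved`, `liCorrected`,
#' `prior` (conditional-GAN refinement), `composite` (mask-composited
#' completion) and `completed` (the final projections fed to FBP).
#'
#' @slot stacks named list of `rows x cols x nViews` arrays.
#' @slot mask the [MetalMask-class] used by the run.
#' @exportClass StageProjections
setClass("StageProjections",
  representation(stacks = "list", mask = "MetalMask")
)

setValidity("StageProjections", function(object) {
  dims <- lapply(object@stacks, dim)
  if (length(dims) > 1L &&
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    return("all stacks must share one shape")
  TRUE
})

#' Reconstructed in-focus plane images
#'
#' @slot planes numeric array, `rows x cols x nPlanes`.
#' @slot planeHeights plane heights in mm relative to the isocenter,
#'   strictly increasing.
#' @slot pixelSize in-plane pixel size in mm.
#' @slot algorithm reconstruction tag, e.g. `"originalFBP"`, `"referenceFBP"`,
#'   `"DT-MAR"`, `"CGpM-MAR"`, `"BP"`.
#' @slot sourceDomain domain tag of the source projections.
#' @exportClass ReconVolume
setClass("ReconVolume",
  representation(planes = "array", planeHeights = "numeric",
                 pixelSize = "numeric", algorithm = "character",
                 sourceDomain = "character")
)

setValidity("ReconVolume", function(object) {
  msg <- character()
  d <- dim(object@planes)
  if (length(d) != 3L || d[3] < 1L) msg <- c(msg, "need >= 1 plane")
  else if (d[3] != length(object@planeHeights))
    msg <- c(msg, "one height per plane required")
  if (length(object@planeHeights) > 1L &&
      any(diff(object@planeHeights) <= 0))
    msg <- c(msg, "planeHeights must be strictly increasing")
  if (!all(is.finite(object@planes)))
    msg <- c(msg, "all plane values must be finite")
  if (length(msg)) msg else TRUE
})

#' Gumbel largest-variation sample
#'
#' Largest variations (per line profile, the maximum absolute difference
#' between adjacent pixel values) sorted ascending, with symmetry-rank
#' plotting positions `(delta - 0.5) / q` and reduced variates
#' `-log(-log(Gamma))`. `pearsonR` measures linearity of the Gumbel plot.
#'
#' @slot x sorted largest variations (length q).
#' @slot gamma plotting positions in (0, 1), strictly increasing.
#' @slot q sample size.
#' @slot reducedVariate `-log(-log(gamma))`.
#' @slot pearsonR Pearson correlation between `x` and the reduced variates.
#' @exportClass GumbelSample
setClass("GumbelSample",
  representation(x = "numeric", gamma = "numeric", q = "integer",
                 reducedVariate = "numeric", pearsonR = "numeric")
)

setValidity("GumbelSample", function(object) {
  msg <- character()
  if (length(object@x) != object@q) msg <- c(msg, "length(x) must equal q")
  if (any(diff(object@x) < 0)) msg <- c(msg, "x must be non-decreasing")
  if (any(object@gamma <= 0 | object@gamma >= 1) ||
      any(diff(object@gamma) <= 0))
    msg <- c(msg, "gamma must be strictly increasing in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Artifact-index result
#'
#' Per-ROI artifact indices `AI_n = |rSD_artifact_n - rSD_background|`
#' where rSD is the relative standard deviation (coefficient of variation,
#' SD/mean) inside the ROI, with the group mean and standard error.
#'
#' @slot perROI data.frame with columns `label`, `group`, `rSD`, `AI`.
#' @slot backgroundRSD relative SD of the background ROI.
#' @slot mean mean AI over the artifact ROIs.
#' @slot se standard error of the AI values.
#' @exportClass AIResult
setClass("AIResult",
  representation(perROI = "data.frame", backgroundRSD = "numeric",
                 mean = "numeric", se = "numeric")
)

setValidity("AIResult", function(object) {
  if (any(object@perROI$AI < 0)) "AI values must be >= 0" else TRUE
})

#' Rectangular region of interest on an in-focus plane
#'
#' @slot label ROI label (`"artifact_1"`, ..., or `"background"`).
#' @slot row 0-based top row.
#' @slot col 0-based left column.
#' @slot height ROI height in pixels.
#' @slot width ROI width in pixels.
#' @slot group `"location_1"` (streak area, 3 x 9 ROIs), `"location_2"`
#'   (dark area, 3 x 7 ROIs) or `"background"`.
#' @exportClass ROISpec
setClass("ROISpec",
  representation(label = "character", row = "integer", col = "integer",
                 height = "integer", width = "integer", group = "character")
)

#' Construct an ROISpec
#'
#' @param label,row,col,height,width,group see [ROISpec-class]; `row`/`col`
#'   are 0-based.
#' @return An [ROISpec-class].
#' @export
ROISpec <- function(label, row, col, height, width, group) {
  new("ROISpec", label = label, row = as.integer(row), col = as.integer(col),
      height = as.integer(height), width = as.integer(width), group = group)
}

#' Loss weights and optimizer hyperparameters for the adversarial stages
#'
#' @slot lambda cycle-consistency weight (default 10).
#' @slot gamma conditional-GAN L1 weight (default 100).
#' @slot eta mask-fusion content weight (default 100).
#' @slot lr Adam learning rate (default 2e-4).
#' @slot beta1,beta2 Adam momentum pair (0.5, 0.999).
#' @slot batchSize training batch size (1).
#' @exportClass LossWeights
setClass("LossWeights",
  representation(lambda = "numeric", gamma = "numeric", eta = "numeric",
                 lr = "numeric", beta1 = "numeric", beta2 = "numeric",
                 batchSize = "integer")
)

setValidity("LossWeights", function(object) {
  if (object@lambda <= 0 || object@gamma <= 0 || object@eta <= 0)
    "lambda, gamma and eta must be > 0" else TRUE
})

#' Construct a LossWeights object
#'
#' Defaults are the method's training settings: cycle weight 10,
#' conditional L1 weight 100, mask-fusion content weight 100, Adam with
#' learning rate 2e-4, beta1 = 0.5, beta2 = 0.999 and batch size 1.
#'
#' @param lambda,gamma,eta,lr,beta1,beta2,batchSize see [LossWeights-class].
#' @return A [LossWeights-class].
#' @export
LossWeights <- function(lambda = 10, gamma = 100, eta = 100, lr = 2e-4,
                        beta1 = 0.5, beta2 = 0.999, batchSize = 1L) {
  new("LossWeights", lambda = lambda, gamma = gamma, eta = eta, lr = lr,
      beta1 = beta1, beta2 = beta2, batchSize = as.integer(batchSize))
}

#' Bookkeeping for one training stage
#'
#' @slot stage `"cycle_gan"`, `"pix2pix"` or `"mpn"`.
#' @slot epochs number of epochs trained.
#' @slot mseCurve per-epoch MSE against the reference stack.
#' @slot mssimCurve per-epoch mean SSIM against the reference stack.
#' @slot selectedEpoch epoch chosen by the rank-sum rule over MSE and MSSIM.
#' @slot checkpoint generator checkpoint(s) at the selected epoch (a list).
#' @slot nTrainingImages number of images in the assembled training set.
#' @slot seed RNG seed of the run.
#' @exportClass StageRun
setClass("StageRun",
  representation(stage = "character", epochs = "integer",
                 mseCurve = "numeric", mssimCurve = "numeric",
                 selectedEpoch = "integer", checkpoint = "list",
                 nTrainingImages = "integer", seed = "integer")
)

setValidity("StageRun", function(object) {
  msg <- character()
  if (length(object@mseCurve) != object@epochs ||
      length(object@mssimCurve) != object@epochs)
    msg <- c(msg, "curves must have one entry per epoch")
  if (object@selectedEpoch < 1L || object@selectedEpoch > object@epochs)
    msg <- c(msg, "selectedEpoch out of range")
  if (length(msg)) msg else TRUE
})
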
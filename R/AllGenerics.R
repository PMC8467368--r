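#' @describeIn AcquisitionGeometry-class number of views.
#' @param object an object.
#' @export
setGeneric("nViews", function(object) standardGeneric("nViews"))

#' @export
setMethod("nViews", "AcquisitionGeometry", function(object) object@nViews)

#' @export
setMethod("nViews", "ProjectionSet", function(object) object@geometry@nViews)

#' Accessors for projection stacks and derived objects
#'
#' `projImages`, `geometry`, `doseLevel` and `projDomain` access the image
#' array, acquisition geometry, dose level and domain tag of a
#' [ProjectionSet-class]. `maskArray` returns the 0/1 array of a
#' [MetalMask-class]; `planes` and `planeHeights` access a
#' [ReconVolume-class]; `stageStack` pulls one named intermediate out of a
#' [StageProjections-class].
#'
#' @param object the object to access.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("projImages", function(object) standardGeneric("projImages"))
#' @rdname accessors
#' @export
setMethod("projImages", "ProjectionSet", function(object) object@images)

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "ProjectionSet", function(object) object@geometry)

#' @rdname accessors
#' @export
setGeneric("doseLevel", function(object) standardGeneric("doseLevel"))
#' @rdname accessors
#' @export
setMethod("doseLevel", "ProjectionSet", function(object) object@dose)

#' @rdname accessors
#' @export
setGeneric("projDomain", function(object) standardGeneric("projDomain"))
#' @rdname accessors
#' @export
setMethod("projDomain", "ProjectionSet", function(object) object@domain)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "MetalMask", function(object) object@masks)

#' @rdname accessors
#' @export
setGeneric("isEmptyMask", function(object) standardGeneric("isEmptyMask"))
#' @rdname accessors
#' @export
setMethod("isEmptyMask", "MetalMask", function(object) object@empty)

#' @rdname accessors
#' @export
setGeneric("planes", function(object) standardGeneric("planes"))
#' @rdname accessors
#' @export
setMethod("planes", "ReconVolume", function(object) object@planes)

#' @rdname accessors
#' @export
setGeneric("planeHeights", function(object) standardGeneric("planeHeights"))
#' @rdname accessors
#' @export
setMethod("planeHeights", "ReconVolume", function(object) object@planeHeights)

#' @rdname accessors
#' @param name name of the stack: one of `"translated"`, `"metalRemoved"`,
#'   `"liCorrected"`, `"prior"`, `"composite"`, `"completed"`.
#' @export
setGeneric("stageStack", function(object, name) standardGeneric("stageStack"))
#' @rdname accessors
#' @export
setMethod("stageStack", "StageProjections", function(object, name) {
  if (!name %in% names(object@stacks))
    stop("no stack named '", name, "'; available: ",
         paste(names(object@stacks), collapse = ", "))
  object@stacks[[name]]
})

#' @rdname accessors
#' @export
setGeneric("stageNames", function(object) standardGeneric("stageNames"))
#' @rdname accessors
#' @export
setMethod("stageNames", "StageProjections",
          function(object) names(object@stacks))

#' @rdname accessors
#' @export
setGeneric("selectedEpoch", function(object) standardGeneric("selectedEpoch"))
#' @rdname accessors
#' @export
setMethod("selectedEpoch", "StageRun", function(object) object@selectedEpoch)

#' @rdname accessors
#' @export
setGeneric("artifactIndexMean",
           function(object) standardGeneric("artifactIndexMean"))
#' @rdname accessors
#' @export
setMethod("artifactIndexMean", "AIResult", function(object) object@mean)

setMethod("show", "AcquisitionGeometry", function(object) {
  cat("AcquisitionGeometry:", object@nViews, "views over",
      object@sweepAngle, "deg\n")
  cat("  source-isocenter", object@sourceIsocenter, "mm,",
      "source-detector", object@sourceDetector, "mm\n")
  cat("  detector", paste(object@detectorShape, collapse = " x "),
      "px @", object@detectorPitch, "mm, sweep axis", object@sweepAxis, "\n")
})

setMethod("show", "DoseLevel", function(object) {
  cat(sprintf("DoseLevel '%s': %.1f ms/view (relative fluence %.3f)\n",
              object@label, object@msPerView, object@relativeFluence))
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("ProjectionSet [%s domain]: %d views of %d x %d\n",
              object@domain, d[3], d[1], d[2]))
  cat(sprintf("  dose '%s' (%.1f ms/view), values in [%.4g, %.4g]\n",
              object@dose@label, object@dose@msPerView,
              min(object@images), max(object@images)))
})

setMethod("show", "MetalMask", function(object) {
  d <- dim(object@masks)
  cat(sprintf(
    "MetalMask: %d views of %d x %d, threshold %.4g, %.2f%% masked%s\n",
    d[3], d[1], d[2], object@threshold, 100 * mean(object@masks),
    if (object@empty) " [EMPTY]" else ""))
})

setMethod("show", "ReconVolume", function(object) {
  d <- dim(object@planes)
  cat(sprintf("ReconVolume [%s]: %d planes of %d x %d\n",
              object@algorithm, d[3], d[1], d[2]))
  cat("  heights (mm):", paste(signif(object@planeHeights, 4),
                               collapse = ", "), "\n")
})

setMethod("show", "StageProjections", function(object) {
  cat("StageProjections with stacks:",
      paste(names(object@stacks), collapse = ", "), "\n")
})

setMethod("show", "GumbelSample", function(object) {
  cat(sprintf("GumbelSample: q = %d, Pearson r = %.4f\n",
              object@q, object@pearsonR))
})

setMethod("show", "AIResult", function(object) {
  cat(sprintf("AIResult: mean AI %.4f +/- %.4f SE over %d ROIs (bg rSD %.4f)\n",
              object@mean, object@se, nrow(object@perROI),
              object@backgroundRSD))
})

setMethod("show", "StageRun", function(object) {
  cat(sprintf(
    "StageRun [%s]: %d epochs, selected epoch %d (MSE %.4g, MSSIM %.4f)\n",
    object@stage, object@epochs, object@selectedEpoch,
    object@mseCurve[object@selectedEpoch],
    object@mssimCurve[object@selectedEpoch]))
})
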
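#' Acquisition-geometry presets
#'
#' `clinicalGeometry()` is the clinical linear-sweep setting: 74 views over a
#' 40 degree sweep, source-isocenter 924 mm, source-detector 1100 mm,
#' 0.15 mm detector pitch, 1024 x 1024 detector matrix. `deskGeometry()` is
#' the down-scaled setting used throughout the test suite and examples:
#' 25 views, 64 x 64 detector at 3 mm pitch, same sweep and distances.
#'
#' @param nViews,detector,pitch overrides for the desk preset.
#' @return An [AcquisitionGeometry-class].
#' @export
deskGeometry <- function(nViews = 25L, detector = c(64L, 64L), pitch = 3) {
  AcquisitionGeometry(nViews = nViews, sweepAngle = 40,
                      sourceIsocenter = 924, sourceDetector = 1100,
                      detectorPitch = pitch, detectorShape = detector)
}

#' @rdname deskGeometry
#' @export
clinicalGeometry <- function() {
  AcquisitionGeometry(nViews = 74L, sweepAngle = 40,
                      sourceIsocenter = 924, sourceDetector = 1100,
                      detectorPitch = 0.15, detectorShape = c(1024L, 1024L))
}

#' Dose levels of the acquisition protocol
#'
#' The four dose levels of the protocol, defined by exposure time per view
#' at 80 kVp / 250 mA, with the effective doses reported for them:
#' reference 20 ms/view (0.69 mSv), then 12.8 ms/view (0.43 mSv),
#' 9.6 ms/view (0.31 mSv) and 6.4 ms/view (0.20 mSv). Relative fluence is
#' exposure time over the reference exposure time.
#'
#' @return A data.frame with columns `label`, `msPerView`,
#'   `relativeFluence`, `effectiveDose_mSv`.
#' @examples
#' doseTable()
#' @export
doseTable <- function() {
  data.frame(
    label = c("reference", "reduced_37pct", "reduced_55pct", "reduced_71pct"),
    msPerView = c(20, 12.8, 9.6, 6.4),
    relativeFluence = c(20, 12.8, 9.6, 6.4) / 20,
    effectiveDose_mSv = c(0.69, 0.43, 0.31, 0.20)
  )
}

#' Percent reduction between two effective doses
#'
#' @param referenceDose_mSv reference effective dose (mSv).
#' @param reducedDose_mSv reduced effective dose (mSv).
#' @param digits rounding digits (0 gives the integer percent labels used
#'   to name the dose levels, e.g. 0.69 to 0.31 mSv is a 55 percent
#'   reduction).
#' @return Percent dose reduction.
#' @examples
#' doseReductionPercent(0.69, 0.31)  # 55
#' doseReductionPercent(0.69, 0.20)  # 71
#' @export
doseReductionPercent <- function(referenceDose_mSv, reducedDose_mSv,
                                 digits = 0) {
  stopifnot(referenceDose_mSv > 0, reducedDose_mSv >= 0)
  round(100 * (1 - reducedDose_mSv / referenceDose_mSv), digits)
}

#' Dose level for a given exposure time
#'
#' @param msPerView exposure time per view in ms (one of 20, 12.8, 9.6, 6.4
#'   for the protocol levels, but any value in (0, 20] is accepted).
#' @return A [DoseLevel-class] with relative fluence `msPerView / 20`.
#' @examples
#' doseLevelFor(9.6)  # relative fluence 0.48
#' @export
doseLevelFor <- function(msPerView) {
  dt <- doseTable()
  i <- match(msPerView, dt$msPerView)
  label <- if (is.na(i)) sprintf("%gms", msPerView) else dt$label[i]
  DoseLevel(label, msPerView)
}

# View angles (degrees) of a linear sweep, evenly spaced across the total
# sweep angle and centred on zero.
viewAngles <- function(geometry) {
  n <- geometry@nViews
  if (n == 1L) return(0)
  seq(-geometry@sweepAngle / 2, geometry@sweepAngle / 2, length.out = n)
}
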
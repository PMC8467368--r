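#' Simulate a linear-sweep projection acquisition
#'
#' For each of the evenly spaced view angles across the sweep, the
#' polychromatic transmitted intensity is computed by shear ray tracing:
#' the source motion is modeled as a per-view parallel-beam shear, so a
#' voxel at height z (depth from the isocenter plane) is displaced on the
#' detector by `tan(theta) * z / pitch` pixels along the sweep axis. Per
#' energy bin the line integral L_b is accumulated by shifting each depth
#' slice with subpixel linear interpolation (zero outside the volume) and
#' summing; the transmitted fraction is `T = sum_b w_b exp(-L_b)`, which
#' makes the post-log signal sub-linear in thickness (beam hardening).
#' The expected photon count `N0 * relativeFluence * T` is Poisson-sampled,
#' clamped to a floor before the log (photon starvation: near-zero counts
#' behind the implant turn into biased, noisy post-log values), and
#' returned as post-log projections `log(N0 * f) - log(max(N, floor))`.
#'
#' @param phantom a voxelized phantom from [buildPhantom()] (or a
#'   [PhantomSpec-class], voxelized on the fly).
#' @param geometry an [AcquisitionGeometry-class]; the detector must match
#'   the phantom cross-section (rows x cols).
#' @param dose a [DoseLevel-class].
#' @param seed RNG seed for the Poisson noise.
#' @param noiseless skip photon statistics and return
#'   `-log(sum_b w_b exp(-L_b))` exactly.
#' @param referencePhotons mean photon count per detector element through
#'   air at the reference dose.
#' @param photonFloor count floor applied before the log (must be > 0).
#' @return A [ProjectionSet-class] with domain `"reference"` when
#'   `relativeFluence == 1`, else `"low"`.
#' @export
simulateProjections <- function(phantom, geometry, dose, seed = 1L,
                                noiseless = FALSE, referencePhotons = 1e4,
                                photonFloor = 0.5) {
  if (is(phantom, "PhantomSpec")) phantom <- buildPhantom(phantom)
  if (photonFloor <= 0) stop("photonFloor must be > 0")
  validObject(geometry); validObject(dose)
  d <- dim(phantom$labels)
  if (!all(geometry@detectorShape == d[1:2]))
    stop("detector shape must match phantom cross-section at desk scale")
  vox <- phantom$spec@voxelSize
  w <- phantom$spec@spectrum
  angles <- viewAngles(geometry) * pi / 180
  z0 <- (d[3] + 1) / 2
  nb <- length(w)
  proj <- array(0, c(d[1], d[2], geometry@nViews))
  set.seed(seed)
  for (v in seq_len(geometry@nViews)) {
    tanv <- tan(angles[v])
    Tsum <- matrix(0, d[1], d[2])
    L <- vector("list", nb)
    for (b in seq_len(nb)) L[[b]] <- matrix(0, d[1], d[2])
    for (z in seq_len(d[3])) {
      s <- tanv * (z - z0) * vox / geometry@detectorPitch
      for (b in seq_len(nb)) {
        L[[b]] <- L[[b]] + shiftRows(phantom$mu[[b]][, , z], s, "zero")
      }
    }
    for (b in seq_len(nb)) Tsum <- Tsum + w[b] * exp(-L[[b]] * vox)
    if (noiseless) {
      proj[, , v] <- -log(Tsum)
    } else {
      n0 <- referencePhotons * dose@relativeFluence
      counts <- matrix(rpois(length(Tsum), n0 * Tsum), d[1], d[2])
      proj[, , v] <- log(n0) - log(pmax(counts, photonFloor))
    }
  }
  ProjectionSet(proj, geometry, dose,
                domain = if (dose@relativeFluence == 1) "reference"
                         else "low")
}

#' Simulate a paired reference-dose / low-dose acquisition
#'
#' Runs [simulateProjections()] twice on the same phantom and geometry:
#' once at the reference dose (domain B) and once at the reduced dose
#' (domain A), with independent noise seeds. The two stacks are
#' view-aligned and together form the training material of the unpaired
#' dose-translation stage.
#'
#' @param phantom voxelized phantom (or [PhantomSpec-class]).
#' @param geometry an [AcquisitionGeometry-class].
#' @param refDose,lowDose [DoseLevel-class] objects.
#' @param seeds integer vector of two noise seeds (reference, low).
#' @param ... passed to [simulateProjections()].
#' @return A list with elements `B` (reference) and `A` (low dose).
#' @export
makePairedAcquisition <- function(phantom, geometry,
                                  refDose = doseLevelFor(20),
                                  lowDose = doseLevelFor(9.6),
                                  seeds = c(1L, 2L), ...) {
  if (is(phantom, "PhantomSpec")) phantom <- buildPhantom(phantom)
  B <- simulateProjections(phantom, geometry, refDose, seed = seeds[1], ...)
  A <- simulateProjections(phantom, geometry, lowDose, seed = seeds[2], ...)
  if (nViews(A) != nViews(B))
    stop("geometry error: mismatched view counts")
  list(B = B, A = A)
}
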
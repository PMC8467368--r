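# On-disk formats: multi-page 32-bit float TIFF for image stacks with a
# JSON sidecar carrying geometry, dose, domain and normalization
# constants; 8-bit TIFF (0/255) for masks; YAML for ROI/window and run
# configuration. Float TIFF pages are stored range-normalized to [0, 1]
# with the affine constants in the sidecar, so the round trip is lossless
# at 32-bit float precision.

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                     ".json")

writeFloatStack <- function(imgs, path, meta) {
  lo <- min(imgs); hi <- max(imgs)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(imgs)[3]),
                  function(v) (imgs[, , v] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta$storage <- list(offset = lo, scale = scale, pages = dim(imgs)[3])
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

readFloatStack <- function(path, expectType) {
  sc <- sidecarPath(path)
  if (!file.exists(sc)) stop("missing JSON sidecar for ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$type, expectType))
    stop("type error: sidecar says '", meta$type, "', expected '",
         expectType, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$storage$pages)
    stop("page count (", length(pages), ") differs from sidecar (",
         meta$storage$pages, ")")
  imgs <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (v in seq_along(pages)) {
    pg <- pages[[v]]
    if (length(dim(pg)) > 2L) pg <- pg[, , 1]
    imgs[, , v] <- pg * meta$storage$scale + meta$storage$offset
  }
  list(images = imgs, meta = meta)
}

#' Write / read a projection stack
#'
#' Multi-page 32-bit float TIFF plus a JSON sidecar carrying the
#' acquisition geometry, dose level, domain tag and the affine storage
#' constants. The round trip is lossless at single precision; a missing
#' sidecar, a page-count mismatch with the sidecar, or a sidecar of a
#' different object type is an error.
#'
#' @param pset a [ProjectionSet-class].
#' @param path TIFF file path (`.json` sidecar written next to it).
#' @return `readProjectionStack` returns the [ProjectionSet-class].
#' @export
writeProjectionStack <- function(pset, path) {
  g <- pset@geometry
  meta <- list(
    type = "ProjectionSet", domain = pset@domain,
    geometry = list(nViews = g@nViews, sweepAngle = g@sweepAngle,
                    sourceIsocenter = g@sourceIsocenter,
                    sourceDetector = g@sourceDetector,
                    detectorPitch = g@detectorPitch,
                    detectorShape = g@detectorShape,
                    sweepAxis = g@sweepAxis),
    dose = list(label = pset@dose@label, msPerView = pset@dose@msPerView,
                relativeFluence = pset@dose@relativeFluence)
  )
  writeFloatStack(pset@images, path, meta)
}

#' @rdname writeProjectionStack
#' @export
readProjectionStack <- function(path) {
  r <- readFloatStack(path, "ProjectionSet")
  m <- r$meta
  g <- AcquisitionGeometry(m$geometry$nViews, m$geometry$sweepAngle,
                           m$geometry$sourceIsocenter,
                           m$geometry$sourceDetector,
                           m$geometry$detectorPitch,
                           m$geometry$detectorShape, m$geometry$sweepAxis)
  if (dim(r$images)[3] != g@nViews)
    stop("page count differs from sidecar nViews")
  dose <- new("DoseLevel", label = m$dose$label,
              msPerView = m$dose$msPerView,
              relativeFluence = m$dose$relativeFluence)
  ProjectionSet(r$images, g, dose, m$domain)
}

#' Write / read a metal mask stack
#'
#' Multi-page 8-bit TIFF (0/255) plus a JSON sidecar with the threshold
#' and dilation used.
#'
#' @param mask a [MetalMask-class].
#' @param path TIFF file path.
#' @return `readMetalMask` returns the [MetalMask-class].
#' @export
writeMetalMask <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask@masks)[3]),
                  function(v) mask@masks[, , v])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(type = "MetalMask", threshold = mask@threshold,
         dilation = mask@dilation, empty = mask@empty,
         pages = dim(mask@masks)[3]),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProjectionStack
#' @export
readMetalMask <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc)) stop("missing JSON sidecar for ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$type, "MetalMask"))
    stop("type error: sidecar says '", meta$type, "', expected 'MetalMask'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$pages) stop("page count differs from sidecar")
  masks <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (v in seq_along(pages)) masks[, , v] <- round(pages[[v]])
  new("MetalMask", masks = masks, threshold = meta$threshold,
      dilation = as.integer(meta$dilation), empty = meta$empty)
}

#' Write / read a reconstructed volume
#'
#' Multi-page 32-bit float TIFF of the in-focus planes plus a JSON
#' sidecar with plane heights, pixel size, algorithm tag and provenance.
#'
#' @param recon a [ReconVolume-class].
#' @param path TIFF file path.
#' @return `readReconVolume` returns the [ReconVolume-class].
#' @export
writeReconVolume <- function(recon, path) {
  meta <- list(type = "ReconVolume",
               planeHeights = recon@planeHeights,
               pixelSize = recon@pixelSize,
               algorithm = recon@algorithm,
               sourceDomain = recon@sourceDomain)
  writeFloatStack(recon@planes, path, meta)
}

#' @rdname writeReconVolume
#' @export
readReconVolume <- function(path) {
  r <- readFloatStack(path, "ReconVolume")
  new("ReconVolume", planes = r$images,
      planeHeights = as.numeric(r$meta$planeHeights),
      pixelSize = r$meta$pixelSize, algorithm = r$meta$algorithm,
      sourceDomain = r$meta$sourceDomain)
}

#' Default ROI layout and Gumbel window for the desk-scale phantom
#'
#' The artifact index protocol uses two ROI groups: six 3 x 9 ROIs in the
#' streak-artifact area and eight 3 x 7 ROIs in the dark-artifact area,
#' plus one background ROI in the plain water region. With the per-view
#' shear acquisition model, dose-dependent metal artifacts concentrate in
#' the metal-trace columns and smear along the sweep axis beyond the nail
#' tips, so both groups sit on that band, lateral to (and clear of) the
#' implant footprint: the streak ROIs slightly wider and further out, the
#' dark ROIs centred on the trace columns immediately beyond the tips.
#' The Gumbel window (default width 8, length 24 along the sweep axis)
#' sits over the region lateral to the implant. Coordinates are 0-based
#' and refer to the 64 x 64 desk reconstruction.
#'
#' @return A list with `rois` (list of [ROISpec-class]) and `window`
#'   (list with `row`, `col`, `length`, `width`, `nProfiles`).
#' @export
defaultROIs <- function() {
  streak <- list(c(0, 26), c(3, 26), c(56, 26),
                 c(59, 26), c(3, 30), c(56, 30))
  dark <- list(c(0, 28), c(3, 28), c(56, 28), c(59, 28),
               c(0, 31), c(3, 31), c(56, 31), c(59, 31))
  rois <- c(
    lapply(seq_along(streak), function(i) {
      ROISpec(paste0("streak_", i), streak[[i]][1], streak[[i]][2],
              3L, 9L, "location_1")
    }),
    lapply(seq_along(dark), function(i) {
      ROISpec(paste0("dark_", i), dark[[i]][1], dark[[i]][2],
              3L, 7L, "location_2")
    }),
    list(ROISpec("background", 28L, 8L, 3L, 7L, "background"))
  )
  list(rois = rois,
       window = list(row = 20L, col = 37L, length = 24L, width = 8L,
                     nProfiles = 23L))
}

#' Write / read the ROI and Gumbel-window layout as YAML
#'
#' @param layout a list as returned by [defaultROIs()].
#' @param path YAML file path.
#' @return `readROILayout` returns the layout list.
#' @export
writeROILayout <- function(layout, path) {
  y <- list(
    rois = lapply(layout$rois, function(r) {
      list(label = r@label, row = r@row, col = r@col, height = r@height,
           width = r@width, group = r@group)
    }),
    window = layout$window
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname writeROILayout
#' @export
readROILayout <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    rois = lapply(y$rois, function(r) {
      ROISpec(r$label, r$row, r$col, r$height, r$width, r$group)
    }),
    window = y$window
  )
}

#' Run configuration
#'
#' `deskConfig()` returns the fully resolved desk-scale configuration;
#' `readRunConfig(path)` reads a YAML config, rejects unknown keys and
#' merges defaults; `writeRunConfig` serializes a resolved config (every
#' run should write its resolved config next to its outputs).
#'
#' @return A named list with blocks `geometry`, `phantom`, `dose`,
#'   `network`, `training`, `mar`, `evaluation`, `paths`.
#' @export
deskConfig <- function() {
  list(
    geometry = list(nViews = 25L, sweepAngle = 40, sourceIsocenter = 924,
                    sourceDetector = 1100, detectorPitch = 3,
                    detectorShape = c(64L, 64L), sweepAxis = 1L),
    phantom = list(n = 64L, voxelSize = 3),
    dose = list(referenceMsPerView = 20, lowMsPerView = 9.6,
                referencePhotons = 1e4, photonFloor = 0.5),
    network = list(base = 8L, depth = 3L),
    training = list(epochs = as.list(deskEpochs()), lambda = 10,
                    gamma = 100, eta = 100, lr = 2e-4, beta1 = 0.5,
                    beta2 = 0.999, batchSize = 1L, seed = 1L),
    mar = list(threshold = NULL, dilation = 1L),
    evaluation = list(planes = 9L, roiLayout = "default"),
    paths = list(outDir = "runs/desk")
  )
}

#' @rdname deskConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- deskConfig()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (blk in names(cfg)) {
    unknownKeys <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
    if (length(unknownKeys))
      stop("unknown key(s) in block '", blk, "': ",
           paste(unknownKeys, collapse = ", "))
    defaults[[blk]] <- modifyList(defaults[[blk]], cfg[[blk]])
  }
  defaults
}

#' @rdname deskConfig
#' @param cfg resolved configuration list.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Generate the canned desk-scale fixture dataset
#'
#' Writes a deterministic tiny dataset into a directory: reference and
#' low-dose projection stacks (25 views, 64 x 64) of the default
#' prosthesis phantom, the metal mask segmented from the reference stack,
#' and the ROI/Gumbel-window layout YAML. Regenerating with the same seed
#' reproduces the files byte-identically.
#'
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
makeFixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- deskGeometry()
  ph <- buildPhantom(defaultPhantom())
  pair <- makePairedAcquisition(ph, geom,
                                seeds = c(deriveSeed(seed, "ref"),
                                          deriveSeed(seed, "low")))
  mask <- extractMetalMask(pair$B)
  paths <- list(
    reference = file.path(dir, "projections_ref.tif"),
    low = file.path(dir, "projections_low.tif"),
    mask = file.path(dir, "metal_mask.tif"),
    roi = file.path(dir, "roi_layout.yaml")
  )
  writeProjectionStack(pair$B, paths$reference)
  writeProjectionStack(pair$A, paths$low)
  writeMetalMask(mask, paths$mask)
  writeROILayout(defaultROIs(), paths$roi)
  invisible(paths)
}
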
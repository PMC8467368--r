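# Small fixtures built in code: toy geometries, phantoms and reference
# oracles used across the test files.

toyGeometry <- function(nViews = 5L, n = 16L, pitch = 3) {
  deskGeometry(nViews = nViews, detector = c(n, n), pitch = pitch)
}

# A uniform water cylinder, optionally monoenergetic.
waterPhantomSpec <- function(n = 16L, radius = 0.4 * n, voxelSize = 3,
                             mono = FALSE) {
  mat <- defaultMaterials()
  spectrum <- if (mono) c(only = 1) else mat$spectrum
  att <- if (mono) {
    cbind(only = c(air = 0, water = 0.02, bone = 0.04, metal = 0.3))
  } else mat$attenuation
  PhantomSpec(dim = c(n, n, n), voxelSize = voxelSize,
              spectrum = spectrum, attenuation = att,
              shapes = list(list(material = "water",
                                 centerCol = (n + 1) / 2,
                                 centerDepth = (n + 1) / 2,
                                 radius = radius, rowRange = c(1L, n))))
}

# Water cylinder plus a centred metal rod along the sweep axis.
rodPhantomSpec <- function(n = 16L, rodRadius = 2.2, voxelSize = 3) {
  sp <- waterPhantomSpec(n, voxelSize = voxelSize)
  sp@shapes <- c(sp@shapes,
                 list(list(material = "metal", centerCol = (n + 1) / 2,
                           centerDepth = (n + 1) / 2, radius = rodRadius,
                           rowRange = c(1L, n))))
  sp
}

# Independent per-ray line-integral oracle: step-sample each sheared ray
# through the attenuation volume (trilinear along the row axis only, like
# the geometry: rays run along depth with a row offset per depth).
rayOracle <- function(mu, geometry, voxelSize) {
  d <- dim(mu)
  angles <- dtmar:::viewAngles(geometry) * pi / 180
  z0 <- (d[3] + 1) / 2
  out <- array(0, c(d[1], d[2], geometry@nViews))
  for (v in seq_along(angles)) {
    tanv <- tan(angles[v])
    for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
      acc <- 0
      for (z in seq_len(d[3])) {
        src <- r - tanv * (z - z0) * voxelSize / geometry@detectorPitch
        i0 <- floor(src); f <- src - i0
        v0 <- if (i0 >= 1 && i0 <= d[1]) mu[i0, cc, z] else 0
        v1 <- if (i0 + 1 >= 1 && i0 + 1 <= d[1]) mu[i0 + 1, cc, z] else 0
        acc <- acc + (1 - f) * v0 + f * v1
      }
      out[r, cc, v] <- acc * voxelSize
    }
  }
  out
}

# Independent shift-and-add oracle: per-pixel ray sum over views with the
# same replicate-edge subpixel interpolation contract as the recon.
bpOracle <- function(imgs, geometry, height) {
  d <- dim(imgs)
  angles <- dtmar:::viewAngles(geometry) * pi / 180
  out <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    acc <- 0
    for (v in seq_len(d[3])) {
      s <- -tan(angles[v]) * height / geometry@detectorPitch
      src <- r - s
      i0 <- floor(src); f <- src - i0
      i0c <- min(max(i0, 1), d[1]); i1c <- min(max(i0 + 1, 1), d[1])
      acc <- acc + (1 - f) * imgs[i0c, cc, v] + f * imgs[i1c, cc, v]
    }
    out[r, cc] <- acc / d[3]
  }
  out
}

# Gumbel(loc, scale) draws by inversion.
rGumbel <- function(n, loc = 0, scale = 1) {
  loc - scale * log(-log(runif(n)))
}

# A tiny paired acquisition used by the training smoke tests.
toyPair <- function(seed = 1L, nViews = 8L, n = 32L) {
  geom <- deskGeometry(nViews = nViews, detector = c(n, n))
  ph <- buildPhantom(defaultPhantom(n = n, voxelSize = 3))
  makePairedAcquisition(ph, geom,
                        seeds = c(dtmar:::deriveSeed(seed, "ref"),
                                  dtmar:::deriveSeed(seed, "low")))
}

# Unpaired domains with a gross gray-level mismatch: the translation task
# is far from the identity map, so short training shows a clear trend.
toyOffsetPair <- function(seed = 1L, nViews = 8L, n = 32L, offset = 1.5) {
  geom <- deskGeometry(nViews = nViews, detector = c(n, n))
  ph <- buildPhantom(defaultPhantom(n = n, voxelSize = 3))
  A <- simulateProjections(ph, geom, doseLevelFor(9.6),
                           seed = dtmar:::deriveSeed(seed, "low"))
  Braw <- simulateProjections(ph, geom, doseLevelFor(20),
                              seed = dtmar:::deriveSeed(seed, "ref"))
  B <- ProjectionSet(projImages(Braw) + offset, geom, doseLevelFor(20),
                     "reference")
  list(A = A, B = B)
}
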
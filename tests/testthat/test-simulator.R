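test_that("phantom voxelization handles empty, single- and multi-material specs", {
  mat <- defaultMaterials()
  airOnly <- PhantomSpec(dim = c(8, 8, 8), voxelSize = 1,
                         spectrum = mat$spectrum,
                         attenuation = mat$attenuation, shapes = list())
  ph <- buildPhantom(airOnly)
  expect_true(all(ph$labels == 0L))
  expect_true(all(vapply(ph$mu, function(m) all(m == 0), logical(1))))

  mono <- waterPhantomSpec(16L, mono = TRUE)
  ph <- buildPhantom(mono)
  expect_equal(ph$mu[[1]][8, 8, 8], 0.02)  # central voxel = water mu

  # metal rod voxel count vs analytic volume, within a one-voxel shell
  n <- 16L; rodR <- 2.2
  ph <- buildPhantom(rodPhantomSpec(n, rodRadius = rodR))
  nMetal <- sum(ph$labels == 3L)
  perSlice <- nMetal / n
  expect_lt(abs(perSlice - pi * rodR^2), 2 * pi * rodR + 1)
  # brute-force oracle: count voxels whose centre is inside the disc
  cc <- (n + 1) / 2
  brute <- sum(outer(seq_len(n), seq_len(n),
                     function(i, j) (i - cc)^2 + (j - cc)^2 <= rodR^2))
  expect_equal(perSlice, brute)
})

test_that("metal must attenuate strictly most in every energy bin", {
  mat <- defaultMaterials()
  bad <- mat$attenuation
  bad["metal", 1] <- bad["bone", 1]
  expect_error(PhantomSpec(dim = c(8, 8, 8), voxelSize = 1,
                           spectrum = mat$spectrum, attenuation = bad,
                           shapes = list()),
               "strictly greatest")
})

test_that("noiseless central ray through a water cylinder equals the analytic chord", {
  n <- 32L; r <- 10; vox <- 2
  spec <- waterPhantomSpec(n, radius = r, voxelSize = vox, mono = TRUE)
  geom <- toyGeometry(nViews = 1L, n = n, pitch = vox)
  ps <- simulateProjections(spec, geom, doseLevelFor(20), noiseless = TRUE)
  central <- projImages(ps)[n / 2, (n + 1) %/% 2, 1]
  # mu * chord length; voxelized disc -> within ~1 voxel of 2r
  expect_lt(abs(central - 0.02 * 2 * r * vox), 0.02 * 1.5 * vox)
})

test_that("relative fluence follows the exposure-time ratio", {
  expect_equal(doseLevelFor(9.6)@relativeFluence, 0.48)
  expect_equal(doseLevelFor(20)@relativeFluence, 1)
  expect_error(DoseLevel("too-high", 25), "relativeFluence")
})

test_that("zero-attenuation phantom projects to zero (exactly when noiseless)", {
  mat <- defaultMaterials()
  spec <- PhantomSpec(dim = c(16, 16, 16), voxelSize = 1,
                      spectrum = mat$spectrum,
                      attenuation = mat$attenuation, shapes = list())
  geom <- toyGeometry(nViews = 3L)
  ps0 <- simulateProjections(spec, geom, doseLevelFor(20), noiseless = TRUE)
  expect_true(all(projImages(ps0) == 0))
  psn <- simulateProjections(spec, geom, doseLevelFor(20), seed = 4L)
  expect_lt(mean(abs(projImages(psn))), 0.05)
})

test_that("noiseless projections match the independent per-ray oracle", {
  spec <- rodPhantomSpec(16L)
  ph <- buildPhantom(spec)
  geom <- toyGeometry(nViews = 5L, n = 16L)
  ps <- simulateProjections(ph, geom, doseLevelFor(20), noiseless = TRUE)
  w <- spec@spectrum
  Tsum <- 0
  for (b in seq_along(w))
    Tsum <- Tsum + w[b] * exp(-rayOracle(ph$mu[[b]], geom, spec@voxelSize))
  expected <- -log(Tsum)
  expect_lt(max(abs(projImages(ps) - expected)) /
              max(abs(expected)), 1e-4)
})

test_that("Poisson noise variance scales inversely with relative fluence", {
  spec <- waterPhantomSpec(16L)
  ph <- buildPhantom(spec)
  geom <- toyGeometry(nViews = 1L, n = 16L)
  varAt <- function(ms, seeds) {
    stack <- vapply(seeds, function(s) {
      projImages(simulateProjections(ph, geom, doseLevelFor(ms),
                                     seed = s))[, , 1]
    }, matrix(0, 16, 16))
    mean(apply(stack, c(1, 2), var))
  }
  v1 <- varAt(20, 1:25)
  v4 <- varAt(5, 101:125)  # quarter fluence
  expect_gt(v4 / v1, 4 * 0.8)
  expect_lt(v4 / v1, 4 * 1.2)
})

test_that("paired acquisition yields aligned domains with noisier low dose", {
  pair <- toyPair(seed = 3L, nViews = 6L, n = 16L)
  expect_equal(nViews(pair$A), 6L)
  expect_equal(nViews(pair$B), 6L)
  expect_equal(projDomain(pair$B), "reference")
  expect_equal(projDomain(pair$A), "low")
  expect_equal(trainingImageCount("cycle_gan", nViews(pair$A)), 12L)

  # identical seeds and identical fluence give identical stacks
  geom <- toyGeometry(nViews = 3L)
  ph <- buildPhantom(waterPhantomSpec(16L))
  same <- makePairedAcquisition(ph, geom, refDose = doseLevelFor(20),
                                lowDose = doseLevelFor(20),
                                seeds = c(9L, 9L))
  expect_identical(projImages(same$A), projImages(same$B))

  # Monte-Carlo variance: low dose strictly noisier (20 repeats)
  ph16 <- buildPhantom(waterPhantomSpec(16L))
  g1 <- toyGeometry(nViews = 1L)
  varOf <- function(dose, seeds) {
    stack <- vapply(seeds, function(s) {
      projImages(simulateProjections(ph16, g1, dose, seed = s))[, , 1]
    }, matrix(0, 16, 16))
    mean(apply(stack, c(1, 2), var))
  }
  expect_gt(varOf(doseLevelFor(9.6), 201:220),
            varOf(doseLevelFor(20), 301:320))
})

test_that("polychromatic beam hardens: post-log value is sub-linear in thickness", {
  mat <- defaultMaterials()
  postLog <- function(thick_mm, att, spectrum) {
    -log(sum(spectrum * exp(-att["water", ] * thick_mm)))
  }
  p1 <- postLog(60, mat$attenuation, mat$spectrum)
  p2 <- postLog(120, mat$attenuation, mat$spectrum)
  expect_lt(p2, 2 * p1)
  # monoenergetic case is exactly linear
  monoAtt <- rbind(water = 0.02)
  expect_equal(postLog(120, monoAtt, 1), 2 * postLog(60, monoAtt, 1))
  expect_error(simulateProjections(buildPhantom(waterPhantomSpec(16L)),
                                   toyGeometry(1L), doseLevelFor(20),
                                   photonFloor = 0),
               "photonFloor")
})
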
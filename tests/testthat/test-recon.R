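test_that("single-view back projection at height zero is the identity", {
  geom <- toyGeometry(nViews = 1L, n = 16L)
  set.seed(1)
  img <- array(rnorm(16 * 16), c(16, 16, 1))
  rv <- backproject(img, planeHeights = 0, geometry = geom)
  expect_equal(planes(rv)[, , 1], img[, , 1])
})

test_that("constant projections backproject to the constant everywhere", {
  geom <- toyGeometry(nViews = 5L, n = 16L)
  imgs <- array(2.5, c(16, 16, 5))
  rv <- backproject(imgs, planeHeights = c(-3, 0, 3), geometry = geom)
  expect_equal(planes(rv), array(2.5, c(16, 16, 3)))  # replicate edges
})

test_that("a point object focuses at its true plane and blurs off it", {
  n <- 32L
  mat <- defaultMaterials()
  spec <- PhantomSpec(dim = c(n, n, n), voxelSize = 3,
                      spectrum = c(only = 1),
                      attenuation = cbind(only = c(air = 0, water = 0.02,
                                                   bone = 0.04,
                                                   metal = 0.3)),
                      shapes = list(list(material = "water",
                                         centerCol = 16, centerDepth = 22,
                                         radius = 0.6,
                                         rowRange = c(16L, 16L))))
  geom <- toyGeometry(nViews = 9L, n = n)
  ps <- simulateProjections(spec, geom, doseLevelFor(20), noiseless = TRUE)
  trueH <- (22 - (n + 1) / 2) * 3
  heights <- seq(trueH - 12, trueH + 12, by = 3)
  rv <- backproject(ps, heights)
  peaks <- apply(planes(rv), 3, max)
  expect_equal(which.max(peaks), which(heights == trueH))
  rvF <- fbpReconstruct(ps, heights)
  peaksF <- apply(planes(rvF), 3, max)
  expect_equal(which.max(peaksF), which(heights == trueH))
  expect_true(all(peaksF[-which(heights == trueH)] <
                    peaksF[which(heights == trueH)]))
})

test_that("ramp filtering nulls DC and an impulse returns the kernel", {
  m <- matrix(3, 32, 4)
  f <- fbpFilter(m)
  # interior ~ 0: residual from the finite window stays below 2% of the
  # constant
  expect_lt(max(abs(f[12:21, ])), 0.02 * 3)
  # impulse response equals the analytic kernel of the ramp-Hann filter
  imp <- matrix(0, 32, 1); imp[16, 1] <- 1
  resp <- fbpFilter(imp)
  nfft <- 64
  fr <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) / nfft
  H <- (abs(fr) / 0.5) * 0.5 * (1 + cos(pi * abs(fr) / 0.5))
  kern <- Re(stats::fft(H, inverse = TRUE)) / nfft
  expected <- kern[((seq_len(32) - 16) %% nfft) + 1]
  expect_equal(resp[, 1], expected, tolerance = 1e-10)
})

test_that("DT-MAR combination follows the standard weighting", {
  expect_equal(dtmarCombine(matrix(1), matrix(0.5), w = 0.6),
               matrix(0.7))
  m1 <- matrix(rnorm(16), 4); m2 <- matrix(rnorm(16), 4)
  expect_equal(dtmarCombine(m1, m2, w = 0), m1)
  expect_equal(dtmarCombine(m1, m2, w = 1), m2)
  expect_error(dtmarCombine(m1, matrix(0, 2, 2)), "mismatch")
  expect_error(dtmarCombine(m1, m2, w = 1.2), "w must be")
})

test_that("reconstruction is linear in the projections", {
  geom <- toyGeometry(nViews = 5L, n = 16L)
  set.seed(2)
  p1 <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  p2 <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  h <- c(-3, 0, 3)
  lhs <- planes(backproject(2 * p1 + 3 * p2, h, geom))
  rhs <- 2 * planes(backproject(p1, h, geom)) +
    3 * planes(backproject(p2, h, geom))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  lhsF <- planes(fbpReconstruct(2 * p1 + 3 * p2, h, geom))
  rhsF <- 2 * planes(fbpReconstruct(p1, h, geom)) +
    3 * planes(fbpReconstruct(p2, h, geom))
  expect_equal(lhsF, rhsF, tolerance = 1e-12)
})

test_that("shift-and-add agrees with the per-pixel ray-sum oracle", {
  geom <- toyGeometry(nViews = 5L, n = 16L)
  set.seed(3)
  imgs <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  for (h in c(-4, 0, 5)) {
    rv <- backproject(imgs, planeHeights = h, geometry = geom)
    expect_lt(max(abs(planes(rv)[, , 1] - bpOracle(imgs, geom, h))), 1e-5)
  }
})

test_that("out-of-range plane shifts use replicate-edge handling, never error", {
  geom <- toyGeometry(nViews = 5L, n = 16L)
  imgs <- array(1, c(16, 16, 5))
  expect_silent(rv <- backproject(imgs, planeHeights = 500,
                                  geometry = geom))
  expect_true(all(is.finite(planes(rv))))
})
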
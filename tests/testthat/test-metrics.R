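test_that("MSE follows its closed forms", {
  m <- matrix(rnorm(64), 8)
  expect_equal(mse(m, m), 0)
  expect_equal(mse(matrix(c(1, 2), 1), matrix(c(3, 4), 1)), 4)
  expect_equal(mse(m, m + 0.7), 0.49)
  expect_error(mse(m, matrix(0, 2, 2)), "mismatch")
})

test_that("MSSIM is 1 at identity, below 0 against the negation, symmetric", {
  set.seed(11)
  m <- matrix(rnorm(144), 12)
  expect_equal(mssim(m, m), 1)
  # a zero-local-mean pattern: luminance stays 1 and the negation flips
  # the sign of the structure term, driving SSIM below 0
  chk <- outer((-1)^(1:12), (-1)^(1:12)) * (1 + 0.1 * m)
  expect_lt(mssim(chk, -chk, dataRange = diff(range(chk))), 0)
  n <- matrix(rnorm(144), 12)
  expect_equal(mssim(m, n), mssim(n, m))
  # continuity at identity for constants
  cst <- matrix(2, 12, 12)
  expect_gt(mssim(cst, cst + 1e-8, dataRange = 1), 0.999)
  expect_error(mssim(m, m, ssimParams(window = 16L)), "window")
})

test_that("MSE and MSSIM are invariant to a common spatial permutation", {
  set.seed(12)
  m <- matrix(rnorm(64), 8); n <- matrix(rnorm(64), 8)
  p <- sample(8)
  expect_equal(mse(m, n), mse(m[p, ], n[p, ]))
  # mean over local windows changes under permutation, but the identity
  # and symmetry invariants do not
  expect_equal(mssim(m[p, ], m[p, ]), 1)
})

test_that("the artifact index is |relative SD difference| with group statistics", {
  # construct ROIs with known SD/mean: artifact rSD 0.5, background 0.3
  plane <- matrix(1, 20, 20)
  art <- c(1 - 0.5, 1 + 0.5)  # mean 1, sd ~ 0.7071 -> scale to 0.5
  sdTarget <- function(vals, target) {
    (vals - mean(vals)) / stats::sd(vals) * target + 1
  }
  set.seed(13)
  plane[1:3, 1:9] <- sdTarget(rnorm(27), 0.5)
  plane[10:12, 1:7] <- sdTarget(rnorm(21), 0.3)
  rois <- list(ROISpec("artifact_1", 0, 0, 3, 9, "location_1"),
               ROISpec("background", 9, 0, 3, 7, "background"))
  ai <- artifactIndex(plane, rois)
  expect_equal(ai@perROI$AI[1], 0.2, tolerance = 1e-10)
  expect_equal(artifactIndexMean(ai), 0.2, tolerance = 1e-10)

  # statistically identical artifact and background: AI ~ 0
  plane2 <- matrix(rnorm(400, 10, 1), 20)
  rois2 <- list(ROISpec("artifact_1", 0, 0, 6, 9, "location_1"),
                ROISpec("background", 10, 0, 6, 9, "background"))
  expect_lt(artifactIndexMean(artifactIndex(plane2, rois2)), 0.1)

  # constant plane: all SDs are zero
  expect_equal(artifactIndexMean(artifactIndex(matrix(5, 20, 20), rois2)),
               0)
  # zero-mean ROI is an error naming the ROI
  plane3 <- matrix(0, 20, 20); plane3[11:16, 1:9] <- rnorm(54, 10)
  expect_error(artifactIndex(plane3, rois2), "artifact_1")
  # scale invariance of the coefficient-of-variation definition
  expect_equal(artifactIndexMean(artifactIndex(3 * plane2, rois2)),
               artifactIndexMean(artifactIndex(plane2, rois2)))
})

test_that("profile extraction yields adjacent-difference samples", {
  plane <- matrix(0, 40, 40)
  prof <- extractProfiles(plane, row = 0, col = 0, length = 24,
                          nProfiles = 23)
  expect_equal(dim(prof), c(23L, 23L))  # 24 positions -> 23 samples
  expect_true(all(prof == 0))
  ramp <- outer(seq_len(40) * 0.25, rep(1, 40))
  prof <- extractProfiles(ramp, 0, 0, 24, 8)
  expect_true(all(abs(prof - 0.25) < 1e-12))
  expect_error(extractProfiles(plane, 30, 30, 24, 23), "outside")
})

test_that("plotting positions depend only on the sample size", {
  expect_equal(gumbelPlottingPositions(4), c(0.125, 0.375, 0.625, 0.875))
  expect_equal(gumbelPlottingPositions(23)[1], 0.5 / 23)
  expect_equal(gumbelPlottingPositions(23)[1], 0.02174, tolerance = 1e-4)
  set.seed(14)
  g1 <- gumbelAnalysis(matrix(rnorm(23 * 23), 23))
  g2 <- gumbelAnalysis(matrix(rnorm(23 * 23, 5, 10), 23))
  expect_identical(g1@gamma, g2@gamma)  # rank-based, data-free
  expect_error(gumbelAnalysis(c(1, 2)), "at least 3")
})

test_that("Gumbel-distributed largest variations plot linearly", {
  set.seed(15)
  rs <- vapply(1:1000, function(i) {
    gumbelAnalysis(rGumbel(23, loc = 1, scale = 0.2))@pearsonR
  }, numeric(1))
  expect_gte(median(rs), 0.95)
})

test_that("Pearson correlation matches hand computations", {
  x <- 1:10
  expect_equal(pearsonR(x, 2 * x + 1), 1)
  expect_equal(pearsonR(x, -x), -1)
  expect_equal(pearsonR(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearsonR(c(1, 2, 3), c(2, 2, 2)), "variance")
  expect_error(pearsonR(1:2, 1:2), "length")
})
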
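# Training smoke tests run on a tiny 8-view 32x32 acquisition so the
# whole file stays fast; they check convergence trends, bookkeeping and
# the end-to-end pipeline contracts, not image quality. The stages are
# trained once at file scope and shared across the test blocks.

test_that("epoch selection follows the rank-sum rule", {
  expect_equal(selectEpoch(c(3, 1, 2), c(0.80, 0.90, 0.85)), 2L)
  expect_equal(selectEpoch(c(1, 2), c(0.5, 0.9)), 1L)  # tie -> earliest
  expect_equal(selectEpoch(5, 0.5), 1L)
  expect_error(selectEpoch(numeric(0), numeric(0)), "non-empty")
  expect_error(selectEpoch(c(1, 2), 0.5), "equal length")
})

test_that("stage training sets count the assembled images", {
  expect_equal(trainingImageCount("cycle_gan", 74), 148L)
  expect_equal(trainingImageCount("pix2pix", 74), 148L)
  expect_equal(trainingImageCount("mpn", 74), 222L)
  expect_equal(clinicalGeometry()@nViews, 74L)
})

pairToy <- toyPair(seed = 2L)
ckCycle <- trainCycleGan(pairToy$A, pairToy$B, epochs = 6L, seed = 5L,
                         base = 4L, depth = 2L)
transToy <- applyGenerator(ckCycle, pairToy$A, which = "AB")
maskToy <- extractMetalMask(transToy)
pTempToy <- removeMetal(transToy, maskToy)
pTempLIToy <- linearInterpolate(pTempToy, maskToy)
ckPix <- trainPix2pix(asStack(transToy), pTempLIToy, epochs = 5L,
                      seed = 6L, base = 4L, depth = 2L)
priorToy <- applyGenerator(ckPix, asStack(transToy))
ckMpn <- trainMpn(pTempToy, priorToy, maskToy, epochs = 6L, seed = 8L,
                  base = 4L, depth = 2L)

test_that("cycle-GAN training reduces translation error on a toy pair", {
  run <- ckCycle$run
  expect_s4_class(run, "StageRun")
  expect_equal(run@nTrainingImages, 16L)
  expect_true(run@selectedEpoch >= 1L && run@selectedEpoch <= 6L)
  expect_error(trainCycleGan(pairToy$A, pairToy$B, epochs = 0L),
               "epochs")

  # on grossly mismatched domains (gray-level offset) ten epochs show a
  # clear monotone trend and the checkpoint beats the raw input
  off <- toyOffsetPair(seed = 4L)
  ckOff <- trainCycleGan(off$A, off$B, epochs = 10L, seed = 5L,
                         base = 4L, depth = 2L)
  expect_lt(ckOff$run@mseCurve[10], ckOff$run@mseCurve[1])
  mseOf <- function(x) {
    mean(vapply(seq_len(nViews(off$B)), function(v) {
      mse(projImages(off$B)[, , v], asStack(x)[, , v])
    }, numeric(1)))
  }
  expect_lt(mseOf(applyGenerator(ckOff, off$A, which = "AB")),
            mseOf(off$A))
})

test_that("generator application is deterministic, bounded and identity-capable", {
  t1 <- applyGenerator(ckCycle, pairToy$A)
  t2 <- applyGenerator(ckCycle, pairToy$A)
  expect_identical(projImages(t1), projImages(t2))  # noise off
  zeroIn <- array(0, dim(projImages(pairToy$A)))
  out <- applyGenerator(ckCycle, zeroIn)
  expect_true(all(is.finite(out)))

  # an identity checkpoint (residual scale 0) returns its input
  set.seed(1)
  idGen <- buildGenerator(base = 4L, depth = 2L, residualScale = 0)
  idCk <- dtmar:::newCheckpoint("cycle_gan", list(AB = idGen, BA = idGen),
                                c(lo = -1, hi = 9),
                                list(detectorShape = c(32L, 32L)), 1L,
                                ckCycle$run)
  x <- asStack(pairToy$A)
  expect_equal(applyGenerator(idCk, x), x, tolerance = 1e-12)
})

test_that("conditional-completion training drives the L1 loss down", {
  expect_lt(ckPix$run@mseCurve[5], ckPix$run@mseCurve[1])
  expect_error(trainPix2pix(asStack(transToy),
                            pTempLIToy[, , 1, drop = FALSE]),
               "mismatch")

  # identical input/target pairs: L1 collapses quickly
  same <- asStack(transToy)
  ckSame <- trainPix2pix(same, same, epochs = 3L, seed = 7L,
                         base = 4L, depth = 2L)
  expect_lt(ckSame$run@mseCurve[3], 1e-2)  # near-zero on a ~[0,9] range
})

test_that("mask-pyramid training reduces the content error inside the trace", {
  expect_lt(ckMpn$run@mseCurve[6], ckMpn$run@mseCurve[1])
  expect_equal(ckMpn$run@nTrainingImages, 24L)
  expect_error(trainMpn(pTempToy, priorToy, array(0, dim(pTempToy)),
                        epochs = 2L),
               "empty metal mask")
})

test_that("an empty-mask view contributes zero adversarial loss", {
  set.seed(30)
  p <- array(runif(32 * 32), c(32, 32, 1))
  m <- array(0, dim(p))
  D <- buildDiscriminator(base = 4L, nBlocks = 2L, multiscale = TRUE)
  L1 <- mpnLosses(p, p, m, function(x) x * 0.5, D)
  expect_equal(L1$adv_D, 0)
  expect_equal(L1$adv_G, 0)
})

test_that("the full pipeline conserves off-trace pixels and returns all intermediates", {
  cks <- list(cycle_gan = ckCycle, pix2pix = ckPix, mpn = ckMpn)
  res <- runCgpmMar(pairToy$A, cks)
  expect_setequal(stageNames(res$stages),
                  c("translated", "metalRemoved", "liCorrected", "prior",
                    "composite", "completed"))
  m <- maskArray(res$mask)
  completed <- stageStack(res$stages, "completed")
  translated <- stageStack(res$stages, "translated")
  # guaranteed conservation: completed == metal-removed == translated
  # off the trace, bit-exact
  expect_identical(completed[m == 0], translated[m == 0])
  expect_false(anyNA(completed))
  expect_s4_class(res$recon, "ReconVolume")
  expect_equal(res$recon@algorithm, "CGpM-MAR")
})

test_that("identity checkpoints with an empty mask reduce the pipeline to FBP", {
  set.seed(2)
  idGen <- buildGenerator(base = 4L, depth = 2L, residualScale = 0)
  mkCk <- function(stage, models) {
    dtmar:::newCheckpoint(stage, models, c(lo = -1, hi = 9),
                          list(detectorShape = c(32L, 32L)), 1L,
                          ckCycle$run)
  }
  cks <- list(cycle_gan = mkCk("cycle_gan", list(AB = idGen, BA = idGen)),
              pix2pix = mkCk("pix2pix", list(G = idGen)),
              mpn = mkCk("mpn", list(G = idGen)))
  # threshold far above every value -> empty mask (warned twice: at
  # segmentation and at the pipeline level)
  w <- capture_warnings(res <- runCgpmMar(pairToy$A, cks,
                                          threshold = 1e6))
  expect_true(any(grepl("empty", w)))
  expect_equal(stageStack(res$stages, "completed"),
               projImages(pairToy$A), tolerance = 1e-10)
  ref <- fbpReconstruct(pairToy$A)
  expect_equal(planes(res$recon), planes(ref), tolerance = 1e-8)
})

test_that("checkpoints round-trip through their file format", {
  f <- tempfile(fileext = ".ckpt")
  writeCheckpoint(ckCycle, f)
  ck2 <- readCheckpoint(f)
  expect_identical(ck2$models, ckCycle$models)
  expect_identical(ck2$norm, ckCycle$norm)
  saveRDS(list(1), f)
  expect_error(readCheckpoint(f), "not a dtmar checkpoint")
})
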
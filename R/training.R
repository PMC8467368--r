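# Training loops for the three stages, epoch selection, and the
# end-to-end inference pipeline.
#
# All stages train with Adam at batch size 1 on view-shuffled orders
# (seeded); per epoch the stage records MSE and MSSIM of its output
# against the stage reference and snapshots the generator, so the
# checkpoint can be taken at the epoch the rank-sum rule selects.
# Projections are affinely normalized to [-1, 1] per stage (constants kept
# in the checkpoint and inverted on output).

normInfo <- function(...) {
  vals <- unlist(lapply(list(...), function(x) {
    x <- asStack(x); x[is.finite(x)]
  }))
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) hi <- lo + 1
  c(lo = lo, hi = hi)
}

normApply <- function(x, norm) 2 * (x - norm["lo"]) / (norm["hi"] - norm["lo"]) - 1
normInvert <- function(x, norm) (x + 1) / 2 * (norm["hi"] - norm["lo"]) + norm["lo"]

newCheckpoint <- function(stage, models, norm, config, seed, run) {
  structure(list(stage = stage, models = models, norm = norm,
                 config = config, seed = seed, run = run),
            class = "dtmarCheckpoint")
}

#' @export
print.dtmarCheckpoint <- function(x, ...) {
  cat(sprintf("dtmarCheckpoint [%s]: selected epoch %d of %d, seed %d\n",
              x$stage, x$run@selectedEpoch, x$run@epochs, x$seed))
  invisible(x)
}

#' Write / read a stage checkpoint
#'
#' One file per stage holding the model parameters, configuration,
#' normalization constants, seed and the stage run bookkeeping
#' (serialized with R's native format, version 3).
#'
#' @param checkpoint a checkpoint from one of the training functions.
#' @param path file path.
#' @return `readCheckpoint` returns the checkpoint.
#' @export
writeCheckpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path, version = 3)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "dtmarCheckpoint")) stop("not a dtmar checkpoint file")
  ck
}

#' Number of images in a stage's training set
#'
#' The dose-translation stage trains on the union of the low-dose and
#' reference-dose stacks (2 n images); the conditional-completion stage
#' on (translated, LI-corrected) pairs (2 n images); the mask-pyramid
#' stage on (metal-removed, prior, mask) triples (3 n images). At the
#' clinical preset of 74 views this gives 148, 148 and 222 images.
#'
#' @param stage `"cycle_gan"`, `"pix2pix"` or `"mpn"`.
#' @param nViews views per stack (74 at the clinical preset).
#' @return Integer image count.
#' @examples
#' trainingImageCount("cycle_gan", 74)  # 148
#' trainingImageCount("mpn", 74)        # 222
#' @export
trainingImageCount <- function(stage = c("cycle_gan", "pix2pix", "mpn"),
                               nViews) {
  stage <- match.arg(stage)
  nViews <- as.integer(nViews)
  switch(stage, cycle_gan = 2L * nViews, pix2pix = 2L * nViews,
         mpn = 3L * nViews)
}

#' Epoch budgets
#'
#' `deskEpochs()` are the desk-scale defaults used by the examples and
#' the test suite; `clinicalEpochs()` is the clinical-scale preset (the
#' order-of-magnitude budgets used on GPU hardware).
#'
#' @return Named integer vector with `cycle_gan`, `pix2pix`, `mpn`.
#' @export
deskEpochs <- function() c(cycle_gan = 8L, pix2pix = 6L, mpn = 8L)

#' @rdname deskEpochs
#' @export
clinicalEpochs <- function() c(cycle_gan = 1600L, pix2pix = 300L, mpn = 330L)

#' Select the optimal epoch from MSE and MSSIM curves
#'
#' Returns the epoch that minimizes MSE and maximizes MSSIM. When the two
#' criteria disagree, each epoch is ranked per criterion (rank 1 = lowest
#' MSE, rank 1 = highest MSSIM) and the epoch with the smallest rank sum
#' wins; ties resolve to the earliest epoch.
#'
#' @param mseCurve,mssimCurve equal-length numeric curves (one value per
#'   epoch).
#' @return Selected epoch index (1-based).
#' @examples
#' selectEpoch(c(3, 1, 2), c(0.80, 0.90, 0.85))  # 2
#' @export
selectEpoch <- function(mseCurve, mssimCurve) {
  if (length(mseCurve) == 0L || length(mseCurve) != length(mssimCurve))
    stop("curves must be non-empty and of equal length")
  rMse <- rank(mseCurve, ties.method = "min")
  rSsim <- rank(-mssimCurve, ties.method = "min")
  which.min(rMse + rSsim)   # earliest epoch on ties
}

# Per-epoch agreement metrics in raw (denormalized) units.
epochMetrics <- function(outN, refN, norm) {
  out <- normInvert(outN, norm); ref <- normInvert(refN, norm)
  nv <- dim(out)[3]
  ms <- mean(vapply(seq_len(nv),
                    function(v) mse(ref[, , v], out[, , v]), numeric(1)))
  ss <- mean(vapply(seq_len(nv),
                    function(v) mssim(ref[, , v], out[, , v]), numeric(1)))
  c(mse = ms, mssim = ss)
}

l1Grad <- function(out, target) sign(out - target) / length(out)

#' Train the unpaired dose-translation stage (cycle-consistent GAN)
#'
#' Alternating generator/discriminator Adam updates at batch size 1 over
#' seeded, independently shuffled view orders of the two domains. The
#' generator objective is the log-loss minimax form: the adversarial terms
#' plus `lambda` times the cycle-consistency L1 plus the identity L1 at
#' unit weight. Per epoch, MSE and MSSIM of the translated low-dose stack
#' against the reference stack are recorded and the generators are
#' snapshotted; the checkpoint holds the generators at the epoch selected
#' by [selectEpoch()].
#'
#' @param A low-dose [ProjectionSet-class] (or array).
#' @param B reference-dose [ProjectionSet-class] (or array), view-aligned
#'   with `A` for the epoch metrics.
#' @param epochs number of epochs (>= 1).
#' @param weights a [LossWeights-class].
#' @param seed RNG seed of the stage.
#' @param base,depth generator/discriminator size (see
#'   [buildGenerator()]).
#' @return A checkpoint (class `dtmarCheckpoint`) whose `models` hold the
#'   generators `AB` and `BA`; its `run` slot is the [StageRun-class].
#' @export
trainCycleGan <- function(A, B, epochs = deskEpochs()[["cycle_gan"]],
                          weights = LossWeights(), seed = 1L,
                          base = 8L, depth = 3L) {
  a <- asStack(A); b <- asStack(B)
  if (!identical(dim(a), dim(b))) stop("A and B must share one shape")
  if (epochs < 1L) stop("epochs must be >= 1")
  norm <- normInfo(a, b)
  an <- normApply(a, norm); bn <- normApply(b, norm)
  n <- dim(a)[3]
  set.seed(deriveSeed(seed, "cycle_gan"))
  AB <- buildGenerator("AB", base = base, depth = depth)
  BA <- buildGenerator("BA", base = base, depth = depth)
  DA <- buildDiscriminator("D_A", base = base)
  DB <- buildDiscriminator("D_B", base = base)
  optAB <- adamInit(AB); optBA <- adamInit(BA)
  optDA <- adamInit(DA); optDB <- adamInit(DB)
  tG <- 0L; tD <- 0L
  lam <- weights@lambda
  snaps <- vector("list", epochs)
  mseC <- numeric(epochs); ssimC <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ordA <- sample.int(n); ordB <- sample.int(n)
    for (i in seq_len(n)) {
      x <- asImage(an[, , ordA[i]]); y <- asImage(bn[, , ordB[i]])
      fAB <- unetForward(AB, x); fakeB <- fAB$y
      fBA <- unetForward(BA, y); fakeA <- fBA$y
      if (!all(is.finite(fakeB)) || !all(is.finite(fakeA)))
        stop("divergence (non-finite generator output) at epoch ", ep)
      fRecA <- unetForward(BA, fakeB); recA <- fRecA$y
      fRecB <- unetForward(AB, fakeA); recB <- fRecB$y
      fIdtA <- unetForward(BA, x); fIdtB <- unetForward(AB, y)

      # --- generator update -------------------------------------------
      dFB <- discForward(DB, fakeB)
      sFB <- dFB$scores[[1]]
      dFA <- discForward(DA, fakeA)
      sFA <- dFA$scores[[1]]
      # non-saturating generator direction: minimize -log D(fake)
      # (the plain minimax form log(1 - D) has a vanishing gradient
      # once the discriminator wins; the objective value is unchanged)
      dsFB <- list(); dsFB[[names(dFB$scores)[1]]] <-
        -1 / pmax(sFB, 1e-6) / length(sFB)
      dsFA <- list(); dsFA[[names(dFA$scores)[1]]] <-
        -1 / pmax(sFA, 1e-6) / length(sFA)
      advFakeB <- discBackward(DB, dFB$cache, dsFB)$dx
      advFakeA <- discBackward(DA, dFA$cache, dsFA)$dx
      bwRecA <- unetBackward(BA, fRecA$cache, lam * l1Grad(recA, x))
      bwRecB <- unetBackward(AB, fRecB$cache, lam * l1Grad(recB, y))
      bwAB_a <- unetBackward(AB, fAB$cache, advFakeB + bwRecA$dx)
      bwBA_b <- unetBackward(BA, fBA$cache, advFakeA + bwRecB$dx)
      bwIdtA <- unetBackward(BA, fIdtA$cache, l1Grad(fIdtA$y, x))
      bwIdtB <- unetBackward(AB, fIdtB$cache, l1Grad(fIdtB$y, y))
      gAB <- gradAdd(bwAB_a$grads, gradAdd(bwRecB$grads, bwIdtB$grads))
      gBA <- gradAdd(bwBA_b$grads, gradAdd(bwRecA$grads, bwIdtA$grads))
      tG <- tG + 1L
      up <- adamStep(AB, gAB, optAB, weights, tG); AB <- up$model
      optAB <- up$opt
      up <- adamStep(BA, gBA, optBA, weights, tG); BA <- up$model
      optBA <- up$opt

      # --- discriminator update ---------------------------------------
      tD <- tD + 1L
      for (side in 1:2) {
        D <- if (side == 1) DB else DA
        optD <- if (side == 1) optDB else optDA
        real <- if (side == 1) y else x
        fake <- if (side == 1) fakeB else fakeA
        fR <- discForward(D, real); sR <- fR$scores[[1]]
        fF <- discForward(D, fake); sF <- fF$scores[[1]]
        key <- names(fR$scores)[1]
        dsR <- list(); dsR[[key]] <- -1 / pmax(sR, 1e-6) / length(sR)
        dsF <- list(); dsF[[key]] <- 1 / pmax(1 - sF, 1e-6) / length(sF)
        gD <- gradAdd(discBackward(D, fR$cache, dsR)$grads,
                      discBackward(D, fF$cache, dsF)$grads)
        up <- adamStep(D, gD, optD, weights, tD)
        if (side == 1) { DB <- up$model; optDB <- up$opt }
        else { DA <- up$model; optDA <- up$opt }
      }
    }
    transN <- an
    for (v in seq_len(n)) transN[, , v] <- unetApply(AB, an[, , v])
    met <- epochMetrics(transN, bn, norm)
    mseC[ep] <- met["mse"]; ssimC[ep] <- met["mssim"]
    snaps[[ep]] <- list(AB = AB, BA = BA)
  }
  sel <- selectEpoch(mseC, ssimC)
  run <- new("StageRun", stage = "cycle_gan", epochs = as.integer(epochs),
             mseCurve = mseC, mssimCurve = ssimC,
             selectedEpoch = as.integer(sel),
             checkpoint = list(), nTrainingImages = trainingImageCount(
               "cycle_gan", n), seed = as.integer(seed))
  newCheckpoint("cycle_gan", snaps[[sel]], norm,
                list(base = base, depth = depth,
                     detectorShape = dim(a)[1:2]), seed, run)
}

#' Apply a generator checkpoint to a projection stack
#'
#' Per-view application of the checkpointed generator: inputs are mapped
#' to `[-1, 1]` with the checkpoint's normalization constants, passed
#' through the network deterministically (noise off unless requested),
#' and denormalized. A geometry differing from the training detector
#' shape is an error; a different view count only warns.
#'
#' @param checkpoint a `dtmarCheckpoint`; for the dose-translation stage
#'   the `AB` generator is used (set `which = "BA"` for the reverse).
#' @param projections a [ProjectionSet-class] or array.
#' @param which model name inside the checkpoint.
#' @param noise apply the generator's training-time noise mode.
#' @return Same type as the input (a [ProjectionSet-class] tagged
#'   `"intermediate"`, or an array).
#' @export
applyGenerator <- function(checkpoint, projections, which = NULL,
                           noise = FALSE) {
  x <- asStack(projections)
  gen <- if (is.null(which)) checkpoint$models[[1]]
         else checkpoint$models[[which]]
  if (!is.null(checkpoint$config$detectorShape) &&
      !all(dim(x)[1:2] == checkpoint$config$detectorShape))
    warning("projection shape differs from the training detector shape")
  xn <- normApply(x, checkpoint$norm)
  out <- xn
  for (v in seq_len(dim(x)[3]))
    out[, , v] <- unetApply(gen, xn[, , v], train = noise)
  out <- normInvert(out, checkpoint$norm)
  if (is(projections, "ProjectionSet")) {
    ProjectionSet(out, projections@geometry, projections@dose,
                  domain = "intermediate")
  } else out
}

#' Train the conditional-completion (pix2pix) stage
#'
#' Conditional adversarial training on view-aligned (translated,
#' LI-corrected) pairs: the discriminator scores (condition, image)
#' 2-channel inputs, the generator minimizes the conditional adversarial term
#' plus `gamma` times the L1 reconstruction loss. The noise input z is
#' dropout on the decoder activations during training.
#'
#' @param input condition stack (stage-1 translated projections).
#' @param target paired target stack (LI-corrected projections).
#' @inheritParams trainCycleGan
#' @return A checkpoint with model `G`; `run` is the [StageRun-class].
#' @export
trainPix2pix <- function(input, target,
                         epochs = deskEpochs()[["pix2pix"]],
                         weights = LossWeights(), seed = 1L,
                         base = 8L, depth = 3L) {
  x <- asStack(input); y <- asStack(target)
  if (!identical(dim(x), dim(y))) stop("unpaired input: shape mismatch")
  if (epochs < 1L) stop("epochs must be >= 1")
  norm <- normInfo(x, y)
  xn <- normApply(x, norm); yn <- normApply(y, norm)
  n <- dim(x)[3]
  set.seed(deriveSeed(seed, "pix2pix"))
  G <- buildGenerator("G_pix2pix", base = base, depth = depth,
                      noise = "dropout", noiseP = 0.3)
  D <- buildDiscriminator("D_pix2pix", inC = 2L, base = base)
  optG <- adamInit(G); optD <- adamInit(D)
  gam <- weights@gamma
  snaps <- vector("list", epochs)
  mseC <- numeric(epochs); ssimC <- numeric(epochs)
  tG <- 0L; tD <- 0L
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      xi <- asImage(xn[, , i]); yi <- asImage(yn[, , i])
      fG <- unetForward(G, xi, train = TRUE); g <- fG$y
      if (!all(is.finite(g)))
        stop("divergence (non-finite generator output) at epoch ", ep)
      fF <- discForward(D, concatC(xi, g)); sF <- fF$scores[[1]]
      key <- names(fF$scores)[1]
      # non-saturating conditional generator direction (see above)
      dsF <- list(); dsF[[key]] <- -1 / pmax(sF, 1e-6) / length(sF)
      dPair <- discBackward(D, fF$cache, dsF)$dx
      dAdv <- dPair[, , 2, drop = FALSE]
      bwG <- unetBackward(G, fG$cache, dAdv + gam * l1Grad(g, yi))
      tG <- tG + 1L
      up <- adamStep(G, bwG$grads, optG, weights, tG)
      G <- up$model; optG <- up$opt

      fR <- discForward(D, concatC(xi, yi)); sR <- fR$scores[[1]]
      fF2 <- discForward(D, concatC(xi, g)); sF2 <- fF2$scores[[1]]
      dsR <- list(); dsR[[key]] <- -1 / pmax(sR, 1e-6) / length(sR)
      dsF2 <- list(); dsF2[[key]] <- 1 / pmax(1 - sF2, 1e-6) / length(sF2)
      gD <- gradAdd(discBackward(D, fR$cache, dsR)$grads,
                    discBackward(D, fF2$cache, dsF2)$grads)
      tD <- tD + 1L
      up <- adamStep(D, gD, optD, weights, tD)
      D <- up$model; optD <- up$opt
    }
    outN <- xn
    for (v in seq_len(n)) outN[, , v] <- unetApply(G, xn[, , v])
    met <- epochMetrics(outN, yn, norm)
    mseC[ep] <- met["mse"]; ssimC[ep] <- met["mssim"]
    snaps[[ep]] <- list(G = G)
  }
  sel <- selectEpoch(mseC, ssimC)
  run <- new("StageRun", stage = "pix2pix", epochs = as.integer(epochs),
             mseCurve = mseC, mssimCurve = ssimC,
             selectedEpoch = as.integer(sel), checkpoint = list(),
             nTrainingImages = trainingImageCount("pix2pix", n),
             seed = as.integer(seed))
  newCheckpoint("pix2pix", snaps[[sel]], norm,
                list(base = base, depth = depth,
                     detectorShape = dim(x)[1:2]), seed, run)
}

#' Train the mask pyramid completion stage
#'
#' The completion generator sees the metal-removed stack with the trace
#' zeroed (in normalized units) and is trained so that the composite
#' `Msk * G + (1 - Msk) * P_temp` matches the prior inside the trace
#' (content L1, weight `eta`) while the multiscale discriminator's
#' mask-modulated least-squares scores drive the adversarial part. Views
#' with an empty mask contribute zero adversarial and content gradient;
#' an empty mask in every view is an error.
#'
#' @param pTemp metal-removed stack (NA inside the trace allowed).
#' @param prior refined prior stack (stage-2 output), view-aligned.
#' @param mask the [MetalMask-class] (or 0/1 array).
#' @inheritParams trainCycleGan
#' @return A checkpoint with model `G`; `run` is the [StageRun-class].
#' @export
trainMpn <- function(pTemp, prior, mask,
                     epochs = deskEpochs()[["mpn"]],
                     weights = LossWeights(), seed = 1L,
                     base = 8L, depth = 3L) {
  p <- asStack(pTemp); y <- asStack(prior)
  m <- if (is(mask, "MetalMask")) mask@masks else mask
  if (!identical(dim(p), dim(y)) || !identical(dim(p), dim(m)))
    stop("pTemp, prior and mask must be aligned")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!any(m == 1)) stop("empty metal mask in every view: nothing to learn")
  norm <- normInfo(p, y)
  pn <- normApply(p, norm); pn[!is.finite(pn)] <- 0; pn[m == 1] <- 0
  yn <- normApply(y, norm)
  n <- dim(p)[3]
  set.seed(deriveSeed(seed, "mpn"))
  G <- buildGenerator("G_mpn", base = base, depth = depth,
                      residual = FALSE, noise = "dropout", noiseP = 0.3)
  nBlocks <- 3L
  D <- buildDiscriminator("D_mpn", base = base, nBlocks = nBlocks,
                          multiscale = TRUE)
  pyramids <- lapply(seq_len(n),
                     function(v) buildMaskPyramid(m[, , v], nBlocks))
  optG <- adamInit(G); optD <- adamInit(D)
  eta <- weights@eta
  snaps <- vector("list", epochs)
  mseC <- numeric(epochs); ssimC <- numeric(epochs)
  tG <- 0L; tD <- 0L
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      pi_ <- asImage(pn[, , i]); yi <- asImage(yn[, , i])
      mi <- m[, , i]
      fG <- unetForward(G, pi_, train = TRUE); g <- fG$y
      if (!all(is.finite(g)))
        stop("divergence (non-finite generator output) at epoch ", ep)
      cm <- pi_[, , 1]; gm <- g[, , 1]
      cm[mi == 1] <- gm[mi == 1]
      comp <- asImage(cm)

      fF <- discForward(D, comp)
      dsF <- list()
      for (key in names(fF$scores)) {
        S <- pyramidLevelFor(pyramids[[i]], drop(fF$scores[[key]]))
        sF <- drop(fF$scores[[key]])
        dsF[[key]] <- asImage(-2 * S^2 * (1 - sF) / length(sF))
      }
      dComp <- discBackward(D, fF$cache, dsF)$dx
      dContent <- eta * sign(comp - yi) *
        asImage(mi) / length(comp)
      dG <- (dComp + dContent) * asImage(mi)
      bwG <- unetBackward(G, fG$cache, dG)
      tG <- tG + 1L
      up <- adamStep(G, bwG$grads, optG, weights, tG)
      G <- up$model; optG <- up$opt

      fR <- discForward(D, yi)
      fF2 <- discForward(D, comp)
      dsR <- list(); dsF2 <- list()
      for (key in names(fR$scores)) {
        S <- pyramidLevelFor(pyramids[[i]], drop(fR$scores[[key]]))
        sR <- drop(fR$scores[[key]]); sF2 <- drop(fF2$scores[[key]])
        dsR[[key]] <- asImage(-2 * S^2 * (1 - sR) / length(sR))
        dsF2[[key]] <- asImage(2 * S^2 * sF2 / length(sF2))
      }
      gD <- gradAdd(discBackward(D, fR$cache, dsR)$grads,
                    discBackward(D, fF2$cache, dsF2)$grads)
      tD <- tD + 1L
      up <- adamStep(D, gD, optD, weights, tD)
      D <- up$model; optD <- up$opt
    }
    compN <- pn
    for (v in seq_len(n)) {
      gv <- unetApply(G, pn[, , v])[, , 1]
      cv <- pn[, , v]; cv[m[, , v] == 1] <- gv[m[, , v] == 1]
      compN[, , v] <- cv
    }
    met <- epochMetrics(compN, yn, norm)
    mseC[ep] <- met["mse"]; ssimC[ep] <- met["mssim"]
    snaps[[ep]] <- list(G = G)
  }
  sel <- selectEpoch(mseC, ssimC)
  run <- new("StageRun", stage = "mpn", epochs = as.integer(epochs),
             mseCurve = mseC, mssimCurve = ssimC,
             selectedEpoch = as.integer(sel), checkpoint = list(),
             nTrainingImages = trainingImageCount("mpn", n),
             seed = as.integer(seed))
  newCheckpoint("mpn", snaps[[sel]], norm,
                list(base = base, depth = depth, nBlocks = nBlocks,
                     detectorShape = dim(p)[1:2]), seed, run)
}

#' Train all three stages end to end
#'
#' Stage 1 trains the dose translation on (A, B); its translated output
#' provides the metal segmentation, removal and LI correction that feed
#' stage 2; stage 2's refined prior and the metal-removed stack feed
#' stage 3. Stage seeds are derived deterministically from `seed`.
#'
#' @param A,B low-dose / reference-dose [ProjectionSet-class]s.
#' @param epochs named epochs vector (see [deskEpochs()]).
#' @param weights a [LossWeights-class].
#' @param seed master seed.
#' @param threshold,dilation metal segmentation settings (see
#'   [extractMetalMask()]).
#' @param base,depth network size.
#' @return List with checkpoints `cycle_gan`, `pix2pix`, `mpn`, the
#'   [MetalMask-class] `mask`, and `runs` (list of [StageRun-class]).
#' @export
trainAllStages <- function(A, B, epochs = deskEpochs(),
                           weights = LossWeights(), seed = 1L,
                           threshold = NULL, dilation = 1L,
                           base = 8L, depth = 3L) {
  ck1 <- trainCycleGan(A, B, epochs[["cycle_gan"]], weights,
                       deriveSeed(seed, "stage1"), base, depth)
  translated <- applyGenerator(ck1, A, which = "AB")
  mask <- extractMetalMask(translated, threshold, dilation)
  pTemp <- removeMetal(translated, mask)
  pTempLI <- linearInterpolate(pTemp, mask)
  ck2 <- trainPix2pix(asStack(translated), pTempLI, epochs[["pix2pix"]],
                      weights, deriveSeed(seed, "stage2"), base, depth)
  prior <- applyGenerator(ck2, asStack(translated))
  ck3 <- trainMpn(pTemp, prior, mask, epochs[["mpn"]], weights,
                  deriveSeed(seed, "stage3"), base, depth)
  list(cycle_gan = ck1, pix2pix = ck2, mpn = ck3, mask = mask,
       runs = list(cycle_gan = ck1$run, pix2pix = ck2$run, mpn = ck3$run))
}

#' Run the full projection-completion MAR pipeline
#'
#' Executes the three stages on a low-dose acquisition: (1) dose
#' translation; (2) metal segmentation, removal, LI correction and the
#' conditional prior; (3) mask-pyramid completion composited per
#' `Msk * G + (1 - Msk) * P_temp` (off-trace pixels are carried over
#' bit-exactly); then reconstructs the completed projections with
#' filtered back projection. In the reconstructed display planes the
#' metal footprint (majority back projection of the mask) is replaced by
#' a constant (the top of the display window by default).
#'
#' @param low low-dose [ProjectionSet-class].
#' @param checkpoints list from [trainAllStages()] (or the three
#'   checkpoints by name).
#' @param threshold,dilation metal segmentation settings.
#' @param planeHeights reconstruction heights (mm);
#'   [defaultPlaneHeights()] when NULL.
#' @param metalValue constant for the metal footprint; `NULL` uses the
#'   plane maximum ("white").
#' @return List with `stages` (a [StageProjections-class] holding the six
#'   named stacks), `recon` (a [ReconVolume-class] tagged `"CGpM-MAR"`)
#'   and `mask`.
#' @export
runCgpmMar <- function(low, checkpoints, threshold = NULL, dilation = 1L,
                       planeHeights = NULL, metalValue = NULL) {
  translated <- applyGenerator(checkpoints$cycle_gan, low, which = "AB")
  mask <- extractMetalMask(translated, threshold, dilation)
  if (mask@empty) warning("empty metal mask: completion degenerates to ",
                          "the translated projections")
  pTemp <- removeMetal(translated, mask)
  pTempLI <- linearInterpolate(pTemp, mask)
  prior <- applyGenerator(checkpoints$pix2pix, asStack(translated))
  ckM <- checkpoints$mpn
  pn <- normApply(asStack(pTemp), ckM$norm)
  pn[!is.finite(pn)] <- 0; pn[maskArray(mask) == 1] <- 0
  g <- pn
  for (v in seq_len(dim(pn)[3]))
    g[, , v] <- unetApply(ckM$models$G, pn[, , v])
  gRaw <- normInvert(g, ckM$norm)
  composite <- mpnComposite(pTemp, gRaw, mask)
  completed <- composite
  stages <- new("StageProjections",
                stacks = list(translated = asStack(translated),
                              metalRemoved = pTemp,
                              liCorrected = pTempLI,
                              prior = prior,
                              composite = composite,
                              completed = completed),
                mask = mask)
  ps <- ProjectionSet(completed, low@geometry, low@dose, "intermediate")
  recon <- fbpReconstruct(ps, planeHeights)
  recon@algorithm <- "CGpM-MAR"
  recon@sourceDomain <- low@domain
  if (!mask@empty) {
    fp <- backproject(maskArray(mask), recon@planeHeights, low@geometry)
    foot <- planes(fp) > 0.5
    pl <- recon@planes
    for (p in seq_len(dim(pl)[3])) {
      mv <- if (is.null(metalValue)) max(pl[, , p]) else metalValue
      plp <- pl[, , p]; plp[foot[, , p]] <- mv; pl[, , p] <- plp
    }
    recon@planes <- pl
  }
  list(stages = stages, recon = recon, mask = mask)
}
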
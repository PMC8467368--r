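# Loss functions of the three adversarial stages, as pure computations
# over image batches. Generators/discriminators may be the package's own
# models (buildGenerator / buildDiscriminator) or plain R functions, which
# keeps every loss unit-testable against hand-computed values.

applyGen <- function(G, x) {
  if (is.function(G)) G(x) else drop(unetApply(G, x))
}

# Score maps of a discriminator: a named list keyed by encoding-block
# index. A plain function is treated as a single-map discriminator.
discScoreMaps <- function(D, ...) {
  if (is.function(D)) {
    s <- D(...)
    list("1" = if (is.null(dim(s))) matrix(s, 1, 1) else s)
  } else {
    args <- list(...)
    x <- if (length(args) == 1L) asImage(args[[1]])
         else concatC(asImage(args[[1]]), asImage(args[[2]]))
    lapply(discForward(D, x)$scores, function(s) drop(s))
  }
}

viewList <- function(x) {
  x <- asStack(x)
  lapply(seq_len(dim(x)[3]), function(v) x[, , v])
}

#' Coerce to a projection stack array
#'
#' Returns the underlying `rows x cols x n` array of a
#' [ProjectionSet-class], promotes a matrix to a single-view stack, and
#' passes arrays through.
#'
#' @param x a [ProjectionSet-class], matrix or 3-d array.
#' @return A 3-d numeric array.
#' @export
asStack <- function(x) {
  if (is(x, "ProjectionSet")) return(x@images)
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

clampLog <- function(p) log(pmin(pmax(p, 1e-12), 1 - 1e-12))

meanAbs <- function(a, b) mean(abs(a - b))

checkFinite <- function(x, term) {
  if (!all(is.finite(x))) stop("non-finite network output in term '",
                               term, "'")
  x
}

#' Cycle-consistency stage losses
#'
#' Computes the adversarial, cycle-consistency and identity losses of the
#' unpaired dose-translation stage, and the total
#' `adv_AB + adv_BA + lambda * cyc + idt`. Each adversarial term is the
#' log-likelihood form `E_b[log D(b)] + E_a[log(1 - D(AB(a)))]`; the cycle
#' term is the L1 error of both round trips
#' `E_b|AB(BA(b)) - b| + E_a|BA(AB(a)) - a|`; the identity term is
#' `E_a|BA(a) - a| + E_b|AB(b) - b|` (unit weight).
#'
#' @param a,b image batches (matrix, `rows x cols x n` array, or
#'   [ProjectionSet-class]) from the low-dose domain A and reference-dose
#'   domain B.
#' @param AB,BA generators (A to B and B to A): `GeneratorModel`s or plain
#'   functions image -> image.
#' @param DA,DB discriminators for domains A and B: `DiscriminatorModel`s
#'   or functions image -> score map.
#' @param weights a [LossWeights-class]; `lambda` weights the cycle term.
#' @return Named list with `adv_AB`, `adv_BA`, `cyc`, `idt`, `total`.
#' @export
cycleGanLosses <- function(a, b, AB, BA, DA, DB, weights = LossWeights()) {
  av <- viewList(a); bv <- viewList(b)
  fakeB <- lapply(av, function(x) checkFinite(applyGen(AB, x), "AB(a)"))
  fakeA <- lapply(bv, function(x) checkFinite(applyGen(BA, x), "BA(b)"))
  recA <- lapply(fakeB, function(x) checkFinite(applyGen(BA, x), "BA(AB(a))"))
  recB <- lapply(fakeA, function(x) checkFinite(applyGen(AB, x), "AB(BA(b))"))
  idtA <- lapply(av, function(x) checkFinite(applyGen(BA, x), "BA(a)"))
  idtB <- lapply(bv, function(x) checkFinite(applyGen(AB, x), "AB(b)"))

  scoreMean <- function(D, xs, f) {
    mean(vapply(xs, function(x) {
      mean(f(discScoreMaps(D, x)[[1]]))
    }, numeric(1)))
  }
  advAB <- scoreMean(DB, bv, clampLog) +
    scoreMean(DB, fakeB, function(s) clampLog(1 - s))
  advBA <- scoreMean(DA, av, clampLog) +
    scoreMean(DA, fakeA, function(s) clampLog(1 - s))
  cyc <- mean(mapply(meanAbs, recB, bv)) + mean(mapply(meanAbs, recA, av))
  idt <- mean(mapply(meanAbs, idtA, av)) + mean(mapply(meanAbs, idtB, bv))
  total <- advAB + advBA + weights@lambda * cyc + idt
  list(adv_AB = advAB, adv_BA = advBA, cyc = cyc, idt = idt, total = total)
}

#' Conditional-completion (pix2pix) stage losses
#'
#' The conditional adversarial loss
#' `E[log D(x, y)] + E[log(1 - D(x, G(x)))]` over (condition, image) pairs,
#' the L1 reconstruction loss `E|y - G(x)|`, and the combined objective
#' `cgan + gamma * l1`.
#'
#' @param input condition batch (the metal-corrupted projections).
#' @param target paired target batch (the LI-corrected projections).
#' @param G generator (`GeneratorModel` or function).
#' @param D conditional discriminator: `DiscriminatorModel` over the
#'   2-channel (condition, image) input, or a function
#'   `(condition, image) -> score map`.
#' @param weights a [LossWeights-class]; `gamma` weights the L1 term.
#' @return Named list with `cgan`, `l1`, `total`.
#' @export
pix2pixLosses <- function(input, target, G, D, weights = LossWeights()) {
  xv <- viewList(input); yv <- viewList(target)
  if (length(xv) != length(yv) ||
      !identical(dim(xv[[1]]), dim(yv[[1]])))
    stop("input and target must be paired stacks of equal shape")
  gv <- lapply(xv, function(x) checkFinite(applyGen(G, x), "G(input)"))
  cgan <- mean(mapply(function(x, y) {
    mean(clampLog(discScoreMaps(D, x, y)[[1]]))
  }, xv, yv)) +
    mean(mapply(function(x, g) {
      mean(clampLog(1 - discScoreMaps(D, x, g)[[1]]))
    }, xv, gv))
  l1 <- mean(mapply(meanAbs, yv, gv))
  list(cgan = cgan, l1 = l1, total = cgan + weights@gamma * l1)
}

#' Mask composite of the completion stage
#'
#' Metal-trace pixels are taken from the completion-network output, all
#' other pixels from the metal-removed stack:
#' `Msk * g + (1 - Msk) * P_temp`, elementwise. Off-trace pixels are
#' copied bit-exactly (never recomputed), and missing (NA) trace pixels of
#' the metal-removed stack are overwritten by the network output.
#'
#' @param pTemp metal-removed stack (matrix or array; NA allowed inside
#'   the trace).
#' @param gOut completion-network output, same shape.
#' @param msk 0/1 metal mask ([MetalMask-class], matrix or array).
#' @return Array of the same shape.
#' @export
mpnComposite <- function(pTemp, gOut, msk) {
  m <- if (is(msk, "MetalMask")) msk@masks else msk
  if (is(pTemp, "ProjectionSet")) pTemp <- pTemp@images
  if (is(gOut, "ProjectionSet")) gOut <- gOut@images
  if (!identical(dim(pTemp), dim(gOut)) || !identical(dim(pTemp), dim(m)))
    stop("shape mismatch between pTemp, gOut and mask")
  out <- pTemp
  sel <- (m == 1)
  out[sel] <- gOut[sel]
  out
}

#' Mask pyramid of a metal mask
#'
#' Level 0 is the mask itself; level k is the `2^k`-downsampled mask via
#' 2x2 max pooling, so the nonzero support at every level contains the
#' downsampled support of the metal trace (faint traces are never diluted
#' away, which average pooling would do).
#'
#' @param msk 0/1 matrix (one view) or [MetalMask-class] (first view).
#' @param nLevels number of pooled levels (>= 1).
#' @return Object of class `MaskPyramid`: list with element `levels`
#'   (level 0 first, then `nLevels` pooled levels).
#' @export
buildMaskPyramid <- function(msk, nLevels = 3L) {
  m <- if (is(msk, "MetalMask")) msk@masks[, , 1] else msk
  if (nLevels < 1L) stop("nLevels must be >= 1")
  if (min(dim(m)) < 2^nLevels)
    stop("mask smaller than 2^nLevels; cannot build pyramid")
  levels <- vector("list", nLevels + 1L)
  levels[[1L]] <- m
  cur <- m
  for (k in seq_len(nLevels)) {
    cur <- maxPool2(cur)
    levels[[k + 1L]] <- cur
  }
  structure(list(levels = levels), class = "MaskPyramid")
}

maxPool2 <- function(m) {
  nr <- dim(m)[1]; nc <- dim(m)[2]
  if (nr %% 2L || nc %% 2L) {  # zero-pad odd sizes (support preserving)
    m2 <- matrix(0, nr + nr %% 2L, nc + nc %% 2L)
    m2[seq_len(nr), seq_len(nc)] <- m
    m <- m2; nr <- nrow(m); nc <- ncol(m)
  }
  io <- seq(1L, nr, by = 2L); jo <- seq(1L, nc, by = 2L)
  pmax(m[io, jo, drop = FALSE], m[io + 1L, jo, drop = FALSE],
       m[io, jo + 1L, drop = FALSE], m[io + 1L, jo + 1L, drop = FALSE])
}

# Pick the pyramid level whose size matches a score map; error when the
# pyramid and the discriminator's encoding depth disagree.
pyramidLevelFor <- function(S, score) {
  d <- dim(score)
  if (is.null(d)) d <- c(1L, 1L)
  for (lev in S$levels) {
    if (all(dim(lev) == d[1:2])) return(lev)
  }
  stop("pyramid/discriminator depth mismatch: no pyramid level of size ",
       d[1], " x ", d[2])
}

#' Mask-fusion losses of the completion stage
#'
#' The content loss is the L1 distance between the mask composite
#' `Msk * G(P_temp) + (1 - Msk) * P_temp` and the prior stack. The
#' adversarial terms are mask-modulated least-squares scores: per score
#' map, the pyramid level of matching size multiplies the map before the
#' squared norm, so unmasked regions contribute nothing. `adv_D` is
#' `sum_k mean((S_k (1 - D_k(prior)))^2) + mean((S_k D_k(composite))^2)`
#' and `adv_G` is `sum_k mean((S_k (1 - D_k(composite)))^2)`. The total is
#' the generator objective `adv_G + eta * content`.
#'
#' @param pTemp metal-removed stack with missing pixels encoded as the
#'   network input (zeros inside the trace); matrix or array.
#' @param prior the refined prior stack (completion target).
#' @param msk 0/1 metal mask, same shape.
#' @param G completion generator (`GeneratorModel` or function of pTemp).
#' @param D discriminator with per-block score maps (`DiscriminatorModel`
#'   built with `multiscale = TRUE`, or a function image -> score map).
#' @param S a `MaskPyramid` from [buildMaskPyramid()] (single-view use),
#'   or NULL to build one per view from `msk`.
#' @param weights a [LossWeights-class]; `eta` weights the content term.
#' @return Named list with `content`, `adv_D`, `adv_G`, `total`.
#' @export
mpnLosses <- function(pTemp, prior, msk, G, D, S = NULL,
                      weights = LossWeights()) {
  pv <- viewList(pTemp); rv <- viewList(prior)
  mv <- viewList(if (is(msk, "MetalMask")) msk@masks else msk)
  gv <- lapply(pv, function(x) checkFinite(applyGen(G, x), "G(P_temp)"))
  cv <- mapply(mpnComposite, pv, gv, mv, SIMPLIFY = FALSE)
  content <- mean(mapply(meanAbs, cv, rv))
  advD <- 0; advG <- 0
  for (v in seq_along(pv)) {
    Sv <- if (is.null(S)) {
      nb <- if (is.function(D)) 1L else D$config$nBlocks
      buildMaskPyramid(mv[[v]], nb)
    } else S
    realScores <- discScoreMaps(D, rv[[v]])
    fakeScores <- discScoreMaps(D, cv[[v]])
    for (key in names(realScores)) {
      lev <- pyramidLevelFor(Sv, realScores[[key]])
      advD <- advD + mean((lev * (1 - realScores[[key]]))^2) +
        mean((lev * fakeScores[[key]])^2)
      advG <- advG + mean((lev * (1 - fakeScores[[key]]))^2)
    }
  }
  advD <- advD / length(pv); advG <- advG / length(pv)
  list(content = content, adv_D = advD, adv_G = advG,
       total = advG + weights@eta * content)
}
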
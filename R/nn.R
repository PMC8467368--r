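# In-package neural-network core.
#
# The three trainable stages need only a small, fixed family of
# architectures: U-Net-style encoder-decoder generators and patch-based
# convolutional discriminators, trained with Adam at batch size 1. The
# forward/backward passes are written explicitly against the C++ conv
# primitives (conv2d_forward / conv2d_backward, nearest-neighbour 2x
# up/down sampling); there is no general autodiff graph.
#
# Conventions: a single image is an H x W x C array; a conv layer holds its
# weight as a (Cout x k*k*Cin) matrix (see src/nn_ops.cpp for the row
# ordering) plus a bias vector. Hidden activations are leaky ReLU (0.2);
# generator outputs are tanh-bounded, optionally added to the input as a
# scaled residual.

# He-style fan-in scaled init by default: without normalization layers
# the activation/gradient scale through the stack depends directly on the
# weight scale, so the DCGAN-style fixed 0.02 would starve deep gradients.
convNew <- function(inC, outC, k = 3L, stride = 1L, pad = 1L,
                    sd = NULL, zero = FALSE) {
  if (is.null(sd)) sd <- sqrt(2 / (k * k * inC))
  w <- if (zero) matrix(0, outC, k * k * inC)
       else matrix(rnorm(outC * k * k * inC, 0, sd), outC, k * k * inC)
  list(W = w, b = numeric(outC), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       inC = as.integer(inC), outC = as.integer(outC))
}

convFwd <- function(layer, x) {
  conv2d_forward(x, layer$W, layer$b, layer$k, layer$stride, layer$pad)
}

convBwd <- function(layer, x, dout) {
  conv2d_backward(x, layer$W, dout, layer$k, layer$stride, layer$pad)
}

lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lreluGrad <- function(pre, slope = 0.2) ifelse(pre > 0, 1, slope)

asImage <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

#' Build a U-Net-style generator
#'
#' An encoder-decoder with skip connections: `depth` encoding levels
#' (stride-2 convolutions after the first), a bottleneck convolution, and a
#' mirrored decoder using nearest-neighbour upsampling plus convolution on
#' the concatenation with the matching encoder activation. All hidden
#' activations are leaky ReLU (slope 0.2); the output convolution is
#' tanh-bounded. In residual mode the network output is
#' `input + residualScale * tanh(core(input))`, so a zero `residualScale`
#' (or zero-initialized output layer) gives the identity map - the natural
#' starting point for dose-translation tasks. The noise input z of the
#' conditional stages is realized as dropout on the decoder activations
#' (`noise = "dropout"`) or additive Gaussian noise on the bottleneck
#' (`noise = "gauss"`).
#'
#' @param role one of `"AB"`, `"BA"`, `"G_pix2pix"`, `"G_mpn"`.
#' @param inC,outC input/output channel counts.
#' @param base channels at the first level; level d has `base * 2^(d-1)`.
#' @param depth number of encoding levels (input must be divisible by
#'   `2^(depth-1)`).
#' @param residual use residual (identity-anchored) output.
#' @param residualScale scale of the tanh residual.
#' @param noise noise mode: `"none"`, `"dropout"` or `"gauss"`.
#' @param noiseP dropout probability / Gaussian sd.
#' @param zeroInitOut zero-initialize the output convolution (exact
#'   identity at initialization in residual mode).
#' @return A `GeneratorModel` (list with class attribute) holding the
#'   layer parameters and configuration.
#' @export
buildGenerator <- function(role = "AB", inC = 1L, outC = 1L, base = 8L,
                           depth = 3L, residual = TRUE, residualScale = 1,
                           noise = c("none", "dropout", "gauss"),
                           noiseP = 0.5, zeroInitOut = FALSE) {
  noise <- match.arg(noise)
  ch <- base * 2^(seq_len(depth) - 1L)
  layers <- list()
  prev <- inC
  for (d in seq_len(depth)) {
    layers[[paste0("enc", d)]] <-
      convNew(prev, ch[d], stride = if (d == 1L) 1L else 2L)
    prev <- ch[d]
  }
  layers$bott <- convNew(ch[depth], ch[depth])
  if (depth > 1L) {
    for (d in seq(depth - 1L, 1L)) {
      layers[[paste0("dec", d)]] <- convNew(ch[d + 1L] + ch[d], ch[d])
    }
  }
  # small output init: residual generators start near the identity map
  layers$out <- convNew(ch[1L], outC, sd = 0.02, zero = zeroInitOut)
  structure(list(role = role, layers = layers,
                 config = list(inC = inC, outC = outC, base = base,
                               depth = depth, residual = residual,
                               residualScale = residualScale,
                               noise = noise, noiseP = noiseP)),
            class = "GeneratorModel")
}

#' @export
print.GeneratorModel <- function(x, ...) {
  cat(sprintf("GeneratorModel [%s]: depth %d, base %d, %s%s\n", x$role,
              x$config$depth, x$config$base,
              if (x$config$residual)
                sprintf("residual (scale %g)", x$config$residualScale)
              else "direct tanh output",
              if (x$config$noise != "none")
                paste0(", noise=", x$config$noise) else ""))
  invisible(x)
}

# Forward pass. Returns list(y, cache). `train` activates the noise mode;
# noise draws use the current RNG state (seed management is the caller's).
unetForward <- function(gen, x, train = FALSE) {
  cfg <- gen$config
  L <- gen$layers
  x <- asImage(x)
  depth <- cfg$depth
  encPre <- vector("list", depth)
  encAct <- vector("list", depth)
  encInp <- vector("list", depth)
  a <- x
  for (d in seq_len(depth)) {
    encInp[[d]] <- a
    encPre[[d]] <- convFwd(L[[paste0("enc", d)]], a)
    a <- lrelu_forward(encPre[[d]], 0.2)
    encAct[[d]] <- a
  }
  bottPre <- convFwd(L$bott, a)
  cur <- lrelu_forward(bottPre, 0.2)
  gaussNoise <- NULL
  if (train && cfg$noise == "gauss") {
    gaussNoise <- array(rnorm(length(cur), 0, cfg$noiseP), dim(cur))
    cur <- cur + gaussNoise
  }
  decPre <- list(); decInp <- list(); dropMask <- list()
  if (depth > 1L) {
    for (d in seq(depth - 1L, 1L)) {
      nm <- paste0("dec", d)
      up <- upsample2_forward(cur)
      cc <- concatC(up, encAct[[d]])
      decInp[[nm]] <- cc
      decPre[[nm]] <- convFwd(L[[nm]], cc)
      cur <- lrelu_forward(decPre[[nm]], 0.2)
      if (train && cfg$noise == "dropout") {
        keep <- array(rbinom(length(cur), 1L, 1 - cfg$noiseP),
                      dim(cur)) / (1 - cfg$noiseP)
        dropMask[[nm]] <- keep
        cur <- cur * keep
      }
    }
  }
  outInp <- cur
  outPre <- convFwd(L$out, cur)
  tanhOut <- tanh(outPre)
  y <- if (cfg$residual) {
    x[, , seq_len(cfg$outC), drop = FALSE] + cfg$residualScale * tanhOut
  } else tanhOut
  list(y = y,
       cache = list(x = x, encPre = encPre, encAct = encAct,
                    encInp = encInp, bottPre = bottPre, decPre = decPre,
                    decInp = decInp, dropMask = dropMask, outInp = outInp,
                    tanhOut = tanhOut))
}

# Backward pass: returns list(dx, grads) where grads parallels gen$layers.
unetBackward <- function(gen, cache, dy) {
  cfg <- gen$config
  L <- gen$layers
  depth <- cfg$depth
  grads <- list()
  dTanh <- if (cfg$residual) dy * cfg$residualScale else dy
  dOutPre <- dTanh * (1 - cache$tanhOut^2)
  bw <- convBwd(L$out, cache$outInp, dOutPre)
  grads$out <- list(dw = bw$dw, db = bw$db)
  dCur <- bw$dx
  dEnc <- vector("list", depth)
  if (depth > 1L) {
    for (d in seq_len(depth - 1L)) {   # reverse of forward order
      nm <- paste0("dec", d)
      if (!is.null(cache$dropMask[[nm]])) dCur <- dCur * cache$dropMask[[nm]]
      dPre <- lrelu_backward(cache$decPre[[nm]], dCur, 0.2)
      bw <- convBwd(L[[nm]], cache$decInp[[nm]], dPre)
      grads[[nm]] <- list(dw = bw$dw, db = bw$db)
      chUp <- dim(bw$dx)[3] - dim(cache$encAct[[d]])[3]
      dUp <- bw$dx[, , seq_len(chUp), drop = FALSE]
      dSkip <- bw$dx[, , chUp + seq_len(dim(bw$dx)[3] - chUp), drop = FALSE]
      dEnc[[d]] <- if (is.null(dEnc[[d]])) dSkip else dEnc[[d]] + dSkip
      dCur <- upsample2_backward(dUp)
    }
  }
  dPre <- lrelu_backward(cache$bottPre, dCur, 0.2)
  bw <- convBwd(L$bott, cache$encAct[[depth]], dPre)
  grads$bott <- list(dw = bw$dw, db = bw$db)
  dEnc[[depth]] <- if (is.null(dEnc[[depth]])) bw$dx else dEnc[[depth]] + bw$dx
  dx <- NULL
  for (d in seq(depth, 1L)) {
    nm <- paste0("enc", d)
    dPre <- lrelu_backward(cache$encPre[[d]], dEnc[[d]], 0.2)
    bw <- convBwd(L[[nm]], cache$encInp[[d]], dPre)
    grads[[nm]] <- list(dw = bw$dw, db = bw$db)
    if (d > 1L) {
      dEnc[[d - 1L]] <- if (is.null(dEnc[[d - 1L]])) bw$dx
                        else dEnc[[d - 1L]] + bw$dx
    } else dx <- bw$dx
  }
  if (cfg$residual) {
    dx[, , seq_len(cfg$outC)] <- dx[, , seq_len(cfg$outC), drop = FALSE] + dy
  }
  list(dx = dx, grads = grads)
}

# Convenience: forward only, returning the image (drops the cache).
unetApply <- function(gen, x, train = FALSE) unetForward(gen, x, train)$y

#' Build a patch-based discriminator
#'
#' A stack of stride-2 convolution blocks (leaky ReLU) with 1x1
#' convolution + sigmoid score heads. With `multiscale = FALSE` only the
#' last block carries a head (a classic PatchGAN score map); with
#' `multiscale = TRUE` every encoding block has one, which is the
#' configuration the mask pyramid couples to: score map k has spatial size
#' `H / 2^k` and pairs with pyramid level k.
#'
#' @param role one of `"D_A"`, `"D_B"`, `"D_pix2pix"`, `"D_mpn"`.
#' @param inC input channels (2 for the conditional discriminator, which
#'   scores (condition, image) pairs).
#' @param base channels of the first block.
#' @param nBlocks number of stride-2 encoding blocks.
#' @param multiscale attach a score head to every block.
#' @return A `DiscriminatorModel` (list with class attribute).
#' @export
buildDiscriminator <- function(role = "D_B", inC = 1L, base = 8L,
                               nBlocks = 3L, multiscale = FALSE) {
  ch <- base * 2^(seq_len(nBlocks) - 1L)
  layers <- list()
  prev <- inC
  for (k in seq_len(nBlocks)) {
    layers[[paste0("blk", k)]] <- convNew(prev, ch[k], stride = 2L)
    prev <- ch[k]
  }
  headAt <- if (multiscale) seq_len(nBlocks) else nBlocks
  for (k in headAt) {
    layers[[paste0("head", k)]] <- convNew(ch[k], 1L, k = 1L, pad = 0L)
  }
  structure(list(role = role, layers = layers,
                 config = list(inC = inC, base = base, nBlocks = nBlocks,
                               multiscale = multiscale, headAt = headAt)),
            class = "DiscriminatorModel")
}

#' @export
print.DiscriminatorModel <- function(x, ...) {
  cat(sprintf("DiscriminatorModel [%s]: %d blocks, base %d%s\n", x$role,
              x$config$nBlocks, x$config$base,
              if (x$config$multiscale) ", multiscale heads" else ""))
  invisible(x)
}

# Forward: returns list(scores = list of sigmoid score maps keyed by block
# index, cache).
discForward <- function(disc, x) {
  cfg <- disc$config
  L <- disc$layers
  x <- asImage(x)
  a <- x
  blkPre <- list(); blkInp <- list(); blkAct <- list()
  headPre <- list(); scores <- list()
  for (k in seq_len(cfg$nBlocks)) {
    nm <- paste0("blk", k)
    blkInp[[nm]] <- a
    blkPre[[nm]] <- convFwd(L[[nm]], a)
    a <- lrelu_forward(blkPre[[nm]], 0.2)
    blkAct[[nm]] <- a
    if (k %in% cfg$headAt) {
      hp <- convFwd(L[[paste0("head", k)]], a)
      headPre[[as.character(k)]] <- hp
      scores[[as.character(k)]] <- 1 / (1 + exp(-hp))
    }
  }
  list(scores = scores,
       cache = list(x = x, blkPre = blkPre, blkInp = blkInp,
                    blkAct = blkAct, headPre = headPre, scores = scores))
}

# Backward from gradients w.r.t. the sigmoid score maps (named list keyed
# like `scores`). Returns list(dx, grads).
discBackward <- function(disc, cache, dScores) {
  cfg <- disc$config
  L <- disc$layers
  grads <- list()
  dAct <- vector("list", cfg$nBlocks)
  for (k in cfg$headAt) {
    key <- as.character(k)
    if (is.null(dScores[[key]])) next
    s <- cache$scores[[key]]
    dPre <- dScores[[key]] * s * (1 - s)
    bw <- convBwd(L[[paste0("head", k)]], cache$blkAct[[paste0("blk", k)]],
                  dPre)
    grads[[paste0("head", k)]] <- list(dw = bw$dw, db = bw$db)
    dAct[[k]] <- bw$dx
  }
  dNext <- NULL
  for (k in seq(cfg$nBlocks, 1L)) {
    nm <- paste0("blk", k)
    d <- dNext
    if (!is.null(dAct[[k]])) d <- if (is.null(d)) dAct[[k]] else d + dAct[[k]]
    if (is.null(d)) d <- array(0, dim(cache$blkPre[[nm]]))
    dPre <- lrelu_backward(cache$blkPre[[nm]], d, 0.2)
    bw <- convBwd(L[[nm]], cache$blkInp[[nm]], dPre)
    grads[[nm]] <- list(dw = bw$dw, db = bw$db)
    dNext <- bw$dx
  }
  list(dx = dNext, grads = grads)
}

# --- Adam ------------------------------------------------------------------

adamInit <- function(model) {
  lapply(model$layers, function(l) {
    list(mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W),
         ncol(l$W)), mb = numeric(length(l$b)), vb = numeric(length(l$b)))
  })
}

# One Adam step over every layer that has a gradient entry. `t` is the
# 1-based step counter (bias correction). Returns list(model, opt).
adamStep <- function(model, grads, opt, weights, t) {
  b1 <- weights@beta1; b2 <- weights@beta2; lr <- weights@lr
  eps <- 1e-8
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- opt[[nm]]
    st$mW <- b1 * st$mW + (1 - b1) * g$dw
    st$vW <- b2 * st$vW + (1 - b2) * g$dw^2
    st$mb <- b1 * st$mb + (1 - b1) * g$db
    st$vb <- b2 * st$vb + (1 - b2) * g$db^2
    mhatW <- st$mW / (1 - b1^t); vhatW <- st$vW / (1 - b2^t)
    mhatb <- st$mb / (1 - b1^t); vhatb <- st$vb / (1 - b2^t)
    model$layers[[nm]]$W <- model$layers[[nm]]$W -
      lr * mhatW / (sqrt(vhatW) + eps)
    model$layers[[nm]]$b <- model$layers[[nm]]$b -
      lr * mhatb / (sqrt(vhatb) + eps)
    opt[[nm]] <- st
  }
  list(model = model, opt = opt)
}

# Sum two gradient lists with the same structure (accumulation across
# loss terms).
gradAdd <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (nm in names(g2)) {
    if (is.null(g1[[nm]])) g1[[nm]] <- g2[[nm]]
    else {
      g1[[nm]]$dw <- g1[[nm]]$dw + g2[[nm]]$dw
      g1[[nm]]$db <- g1[[nm]]$db + g2[[nm]]$db
    }
  }
  g1
}

gradScale <- function(g, s) {
  for (nm in names(g)) {
    g[[nm]]$dw <- g[[nm]]$dw * s
    g[[nm]]$db <- g[[nm]]$db * s
  }
  g
}
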
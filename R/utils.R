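# Shared numeric helpers: subpixel row shifts, box filtering, Otsu
# thresholding, binary dilation and seed derivation.

# Shift a matrix along its rows by a (possibly fractional) number of pixels,
# using linear interpolation. `edge` = "zero" fills from outside with 0,
# "replicate" clamps to the nearest row. A positive shift moves content
# towards larger row indices.
shiftRows <- function(m, shift, edge = c("zero", "replicate")) {
  edge <- match.arg(edge)
  n <- nrow(m)
  src <- seq_len(n) - shift        # source position for each output row
  i0 <- floor(src)
  f <- src - i0
  clampi <- function(i) pmin(pmax(i, 1L), n)
  if (edge == "replicate") {
    lo <- clampi(i0); hi <- clampi(i0 + 1)
    m[lo, , drop = FALSE] * (1 - f) + m[hi, , drop = FALSE] * f
  } else {
    lo <- clampi(i0); hi <- clampi(i0 + 1)
    wlo <- ifelse(i0 >= 1 & i0 <= n, 1 - f, 0)
    whi <- ifelse(i0 + 1 >= 1 & i0 + 1 <= n, f, 0)
    m[lo, , drop = FALSE] * wlo + m[hi, , drop = FALSE] * whi
  }
}

# Mean over a h x w sliding window, "valid" region only
# (output is (nrow-h+1) x (ncol-w+1)). Uses a 2-d integral image.
boxMean <- function(m, h, w = h) {
  nr <- nrow(m); nc <- ncol(m)
  if (h > nr || w > nc) stop("window larger than image")
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  i <- seq_len(nr - h + 1L); j <- seq_len(nc - w + 1L)
  (S[i + h, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + h, j, drop = FALSE] + S[i, j, drop = FALSE]) / (h * w)
}

# Otsu threshold restricted to values above a lower quantile of the data
# (the metal trace lives in the upper tail of the projection-value
# histogram, so global Otsu would split water from air instead).
otsuThreshold <- function(x, lowerQuantile = 0.9, nbins = 256L) {
  x <- x[is.finite(x)]
  lo <- stats::quantile(x, lowerQuantile, names = FALSE)
  xs <- x[x >= lo]
  if (length(unique(xs)) < 2L) return(max(x) + 1)  # nothing to split
  breaks <- seq(min(xs), max(xs), length.out = nbins + 1L)
  h <- tabulate(findInterval(xs, breaks, all.inside = TRUE), nbins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# Binary dilation of a 0/1 matrix with a (2r+1)^2 square structuring element.
dilateMask <- function(m, r = 1L) {
  if (r < 1L) return(m)
  out <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(0, nrow(m), ncol(m))
    rsrc <- seq_len(nrow(m)) - dr
    csrc <- seq_len(ncol(m)) - dc
    rok <- rsrc >= 1 & rsrc <= nrow(m)
    cok <- csrc >= 1 & csrc <= ncol(m)
    sh[rok, cok] <- m[rsrc[rok], csrc[cok]]
    out <- pmax(out, sh)
  }
  out
}

# Derive a child seed from a base seed and a purpose tag, staying inside
# 32-bit integer range. Deterministic and order-independent.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

standardError <- function(x) stats::sd(x) / sqrt(length(x))
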
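# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Dense 2-D convolution with symmetric (edge-repeating) reflection,
# written as an explicit double loop over the kernel support.
dense_gauss_conv <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k1 <- stats::dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  nr <- nrow(m)
  nc <- ncol(m)
  reflect <- function(i, n) {
    # map an out-of-range index to its mirrored in-range position
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in seq(-r, r)) {
        for (dj in seq(-r, r)) {
          acc <- acc + k2[di + r + 1, dj + r + 1] *
            m[reflect(i + di, nr), reflect(j + dj, nc)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# 1-D resistor-chain solve for a layered slab: returns node potentials for
# per-node conductivities sigma (length n), electrodes at node 1 (0 V) and
# node n (v), harmonic-mean link conductances. Dense direct solve.
chain_potential <- function(sigma, v) {
  n <- length(sigma)
  g <- 2 * sigma[-n] * sigma[-1] / (sigma[-n] + sigma[-1])
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  b[n] <- v
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- -g[i - 1]
    A[i, i + 1] <- -g[i]
    A[i, i] <- g[i - 1] + g[i]
  }
  as.numeric(solve(A, b))
}

# Conductivity grid wrapper for a plain matrix
as_cond_grid <- function(m, spacing = 1) {
  structure(list(sigma = m, spacing = spacing), class = "conductivity_grid")
}

# Poration mask wrapper for a plain logical matrix
as_poration <- function(mask) {
  structure(list(porated = mask, threshold_field = NA_real_),
            class = "poration_mask")
}

# Square ROI polygon (um coordinates) of a given area (mm^2), with its
# lower-left corner at (x0, y0)
square_roi <- function(area_mm2, x0 = 0, y0 = 0) {
  side <- sqrt(area_mm2 * 1e6)
  list(x = c(x0, x0 + side, x0 + side, x0),
       y = c(y0, y0, y0 + side, y0 + side))
}

# Binarize every generated channel at the generator's nominal foreground
# midpoint (the "negative-control-informed manual threshold" for synthetic
# micrographs, where foreground = 200 over Poisson background)
gen_masks <- function(bundle, threshold = 100) {
  lapply(bundle$channels, function(ch) binarize(ch, value = threshold))
}
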
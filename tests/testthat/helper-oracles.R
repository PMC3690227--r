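# Independent oracles and fixture builders used across the test files.
# Each oracle is a direct, unoptimized transcription of the defining
# formula, kept independent of the package's implementation paths.

# Brute-force Otsu: evaluate the interclass variance from its definition
# at every threshold and take the first maximizer.
bruteOtsu <- function(values) {
  values <- as.integer(round(values))
  n <- length(values)
  best <- -Inf
  kBest <- NA_integer_
  for (k in 0:255) {
    lo <- values[values <= k]
    hi <- values[values > k]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / n
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; kBest <- k }
  }
  list(kStar = kBest, sigmaBSq = best)
}

# Naive per-pixel modal label over a cropped window, ties by the fixed
# priority BACKGROUND(0) > NORMAL(1) > ABNORMAL(2).
naiveRankFilter <- function(m, window = 9L) {
  r <- (window - 1L) %/% 2L
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      w <- m[max(1, i - r):min(nrow(m), i + r),
             max(1, j - r):min(ncol(m), j + r)]
      cnt <- c(sum(w == 0L), sum(w == 1L), sum(w == 2L))
      out[i, j] <- which(cnt == max(cnt))[1] - 1L
    }
  }
  out
}

# Rasterize a disc / rotated ellipse into a logical matrix (pixel-center
# inclusion), used as geometry fixtures with analytic oracles.
rasterDisc <- function(radius, pad = 4L) {
  n <- 2L * (radius + pad) + 1L
  c0 <- radius + pad + 1L
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - c0)^2 + (j - c0)^2 <= radius^2) m[i, j] <- TRUE
  m
}

rasterEllipse <- function(a, b, pad = 4L) {
  W <- 2L * (ceiling(a) + pad) + 1L
  H <- 2L * (ceiling(b) + pad) + 1L
  cx <- ceiling(a) + pad + 1L
  cy <- ceiling(b) + pad + 1L
  m <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    if (((j - cx) / a)^2 + ((i - cy) / b)^2 <= 1) m[i, j] <- TRUE
  m
}

# Flat-color RGB image builder.
flatImage <- function(height, width, rgb) {
  array(rep(rgb, each = height * width), c(height, width, 3))
}

# Paint a rectangle of one color into an image.
paintRect <- function(img, rows, cols, rgb) {
  for (ch in 1:3) img[rows, cols, ch] <- rgb[ch]
  img
}

# Deterministic field of planted rods and discs on a uniform background:
# grid placement guarantees non-overlap. Returns the R-channel-style
# grayscale expanded to RGB plus the planted counts.
plantedField <- function(nRod = 50L, nRound = 30L, cell = 60L,
                         bg = 200, fg = 40) {
  ncol <- 10L
  nrowCells <- ceiling((nRod + nRound) / ncol)
  H <- nrowCells * cell; W <- ncol * cell
  m <- matrix(bg, H, W)
  classes <- c(rep("rod", nRod), rep("round", nRound))
  for (k in seq_along(classes)) {
    ci <- (k - 1L) %/% ncol; cj <- (k - 1L) %% ncol
    cy <- ci * cell + cell / 2; cx <- cj * cell + cell / 2
    if (classes[k] == "rod") {
      a <- 20; b <- 2.5; phi <- (k %% 7) * pi / 7
    } else {
      a <- b <- 9; phi <- 0
    }
    for (i in floor(cy - 22):ceiling(cy + 22)) {
      for (j in floor(cx - 22):ceiling(cx + 22)) {
        u <- (j - cx) * cos(phi) + (i - cy) * sin(phi)
        v <- -(j - cx) * sin(phi) + (i - cy) * cos(phi)
        if ((u / a)^2 + (v / b)^2 <= 1) m[i, j] <- fg
      }
    }
  }
  list(channel = m, nRod = nRod, nRound = nRound)
}
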
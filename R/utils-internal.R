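# Internal pixel-level utilities shared across the pipeline.

# Tissue label codes (integer matrix encoding of a TissueLabelMap).
.BACKGROUND <- 0L
.NORMAL <- 1L
.ABNORMAL <- 2L

.tissueLevels <- c("BACKGROUND", "NORMAL", "ABNORMAL")

# round half-up (base round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Validate an RGB image array: height x width x 3, values in [0, 255].
assertRGB <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("'%s' must be a height x width x 3 array", arg), call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(sprintf("'%s' is empty", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("'%s' must have finite channel values in [0, 255]", arg),
         call. = FALSE)
  invisible(img)
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 2-D padded cumulative sum: returns (H+1) x (W+1) with zero first row/col.
cumsum2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 1L, W + 1L)
  P[-1L, -1L] <- apply(m, 2L, cumsum)
  P[-1L, ] <- t(apply(P[-1L, , drop = FALSE], 1L, cumsum))
  P
}

# Per-pixel sum of m over a (2r+1)^2 window cropped at the borders.
boxSum <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  P <- cumsum2(m)
  i1 <- pmax(seq_len(H) - r, 1L); i2 <- pmin(seq_len(H) + r, H)
  j1 <- pmax(seq_len(W) - r, 1L); j2 <- pmin(seq_len(W) + r, W)
  P[i2 + 1L, j2 + 1L, drop = FALSE] - P[i1, j2 + 1L, drop = FALSE] -
    P[i2 + 1L, j1, drop = FALSE] + P[i1, j1, drop = FALSE]
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected; diagonal
# adjacencies between 4-connected labels are merged with a union-find pass.
labelComponents8 <- function(mask) {
  mask <- mask & !is.na(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  H <- nrow(lab); W <- ncol(lab)
  pairs <- NULL
  if (H > 1L && W > 1L) {
    a <- lab[-H, -W]; b <- lab[-1L, -1L]            # down-right diagonal
    keep <- a > 0L & b > 0L & a != b
    p1 <- cbind(a[keep], b[keep])
    a <- lab[-H, -1L]; b <- lab[-1L, -W]            # down-left diagonal
    keep <- a > 0L & b > 0L & a != b
    pairs <- unique(rbind(p1, cbind(a[keep], b[keep])))
  }
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Inner boundary of a pixel set: pixels with at least one 4-neighbour
# outside the set (pixels on the image frame count as boundary).
innerBoundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  up <- pad[1:H, 2:(W + 1L)]; down <- pad[3:(H + 2L), 2:(W + 1L)]
  left <- pad[2:(H + 1L), 1:W]; right <- pad[2:(H + 1L), 3:(W + 2L)]
  core & !(up & down & left & right)
}

# Moore-neighbour contour trace of one connected pixel set, with diagonal
# steps weighted sqrt(2). Returns the traced perimeter length. `rows`/`cols`
# index the pixel set inside an (implicit) image; the trace works on a
# padded crop so frame pixels are handled uniformly.
tracePerimeter <- function(rows, cols) {
  r0 <- min(rows); c0 <- min(cols)
  H <- max(rows) - r0 + 3L; W <- max(cols) - c0 + 3L
  m <- matrix(FALSE, H, W)
  m[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- TRUE
  if (sum(m) == 1L) return(4)          # lone pixel: unit square
  # clockwise Moore neighbourhood offsets starting at "west"
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  # start: uppermost-leftmost pixel, entered from the west
  cand <- which(m, arr.ind = TRUE)
  sr <- min(cand[, 1L])
  sc <- min(cand[cand[, 1L] == sr, 2L])
  cr <- sr; cc <- sc
  bdir <- 1L                            # backtrack points west
  perim <- 0
  firstR <- NA_integer_; firstC <- NA_integer_
  maxIter <- 8L * length(rows) + 16L
  for (it in seq_len(maxIter)) {
    d <- NA_integer_
    for (s in 0:7) {
      dd <- ((bdir - 1L + s) %% 8L) + 1L
      if (m[cr + dr[dd], cc + dc[dd]]) { d <- dd; break }
    }
    if (is.na(d)) return(perim + 4)     # isolated after all (defensive)
    nr <- cr + dr[d]; nc <- cc + dc[d]
    if (is.na(firstR)) { firstR <- nr; firstC <- nc }
    else if (cr == sr && cc == sc && nr == firstR && nc == firstC)
      return(perim)                     # about to repeat the first move
    perim <- perim + if (dr[d] != 0L && dc[d] != 0L) sqrt(2) else 1
    # backtrack for the next pixel: neighbour scanned just before the hit
    prev <- ((d - 2L) %% 8L) + 1L
    pr <- cr + dr[prev]; pc <- cc + dc[prev]
    cr <- nr; cc <- nc
    bdir <- which(dr == (pr - cr) & dc == (pc - cc))[1]
  }
  perim
}
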
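# Internal numeric helpers shared across modules. All image grids are plain
# numeric matrices indexed [row, column], 0-based pixel coordinates in the
# documentation, (1,1) top-left in R indexing.

# round-half-away-from-zero; depth intensities are nonnegative so this is
# floor(x + 0.5). Base round() is round-half-even, which is not the binning
# rule used by the histogram contract.
roundHalfUp <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# symmetric (reflective, edge-inclusive) padding by r pixels on every side;
# requires r < dim. Used by all window filters so border statistics are
# dominated by interior values.
padReflect <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(r >= 0, r < h, r < w)
  if (r == 0L) return(m)
  ri <- c(r:1, 1:h, h:(h - r + 1))
  ci <- c(r:1, 1:w, w:(w - r + 1))
  m[ri, ci, drop = FALSE]
}

# box (moving-window) sum over a (2r+1)x(2r+1) window with reflective
# borders, via a summed-area table on the padded matrix.
boxSum <- function(m, r) {
  if (r == 0L) return(m)
  p <- padReflect(m, r)
  # integral image with a leading zero row/column
  s <- apply(p, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- rbind(0, s); s <- cbind(0, s)
  n <- 2L * r + 1L
  i <- seq_len(nrow(m)); j <- seq_len(ncol(m))
  s[i + n, j + n, drop = FALSE] - s[i, j + n, drop = FALSE] -
    s[i + n, j, drop = FALSE] + s[i, j, drop = FALSE]
}

boxMean <- function(m, r) boxSum(m, r) / (2 * r + 1)^2

# shift a padded matrix view: returns m offset by (di, dj) with reflective
# borders, same dims as m.
shiftReflect <- function(m, di, dj) {
  r <- max(abs(di), abs(dj))
  if (r == 0L) return(m)
  p <- padReflect(m, r)
  i <- seq_len(nrow(m)) + r + di
  j <- seq_len(ncol(m)) + r + dj
  p[i, j, drop = FALSE]
}

# separable 2-D convolution (correlation with symmetric kernels used here)
# with reflective borders; vr applies along rows (vertical), vc along columns.
convSep <- function(m, vr, vc) {
  rr <- (length(vr) - 1L) %/% 2L
  rc <- (length(vc) - 1L) %/% 2L
  p <- padReflect(m, max(rr, rc))
  off <- max(rr, rc)
  h <- nrow(m); w <- ncol(m)
  tmp <- matrix(0, h, ncol(p))
  for (k in seq_along(vr)) {
    tmp <- tmp + vr[k] * p[(off - rr) + k - 1L + seq_len(h), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (k in seq_along(vc)) {
    out <- out + vc[k] * tmp[, (off - rc) + k - 1L + seq_len(w), drop = FALSE]
  }
  out
}

# evaluate expr with a temporary RNG seed, restoring any pre-existing global
# state afterwards; keeps the package free of global random-state effects.
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

stopDim <- function(ok, what) {
  if (!ok) stop("dimension mismatch: ", what, call. = FALSE)
}
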
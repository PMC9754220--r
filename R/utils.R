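# Internal numerical helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' package functions are deterministic without clobbering the session stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and an index.
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

#' Bilinear interpolation on a regular grid
#'
#' Piecewise-linear (separable) interpolation of `Z` defined on the tensor
#' grid `x` (rows) by `y` (columns). Queries outside `[min(x), max(x)] x
#' [min(y), max(y)]` return `NA` (no extrapolation). Exact for affine fields
#' and at grid nodes.
#'
#' @param x,y strictly increasing node coordinates.
#' @param Z numeric matrix, `length(x)` rows by `length(y)` columns.
#' @param xp,yp query coordinates (equal length).
#' @return numeric vector of interpolated values.
#' @keywords internal
#' @noRd
interp_bilinear <- function(x, y, Z, xp, yp) {
  nx <- length(x); ny <- length(y)
  stopifnot(nrow(Z) == nx, ncol(Z) == ny, length(xp) == length(yp))
  inside <- xp >= x[1L] & xp <= x[nx] & yp >= y[1L] & yp <= y[ny]
  i <- findInterval(xp, x, rightmost.closed = TRUE)
  j <- findInterval(yp, y, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nx - 1L)
  j <- pmin(pmax(j, 1L), ny - 1L)
  tx <- (xp - x[i]) / (x[i + 1L] - x[i])
  ty <- (yp - y[j]) / (y[j + 1L] - y[j])
  v <- (1 - tx) * (1 - ty) * Z[cbind(i, j)] +
    tx * (1 - ty) * Z[cbind(i + 1L, j)] +
    (1 - tx) * ty * Z[cbind(i, j + 1L)] +
    tx * ty * Z[cbind(i + 1L, j + 1L)]
  v[!inside] <- NA_real_
  v
}

# Reshape raster samples (long data.frame with x_mm, y_mm and value columns)
# into the grid representation needed by interp_bilinear. The samples must
# form a complete regular raster (every x/y combination present exactly once);
# this holds for all supported acquisition protocols even after fixation
# offset and left-eye mirroring.
as_raster <- function(samples, value_cols) {
  x <- sort(unique(samples$x_mm))
  y <- sort(unique(samples$y_mm))
  n <- nrow(samples)
  if (length(x) * length(y) != n) {
    stop("samples do not form a complete regular raster grid")
  }
  ix <- match(samples$x_mm, x)
  iy <- match(samples$y_mm, y)
  idx <- cbind(ix, iy)
  out <- lapply(value_cols, function(cl) {
    Z <- matrix(NA_real_, length(x), length(y))
    Z[idx] <- samples[[cl]]
    if (anyNA(Z)) stop("samples do not form a complete regular raster grid")
    Z
  })
  names(out) <- value_cols
  list(x = x, y = y, values = out)
}

# Separable truncated-Gaussian smoothing of a matrix sampled at spacing `h`
# (same units as `sigma`). The kernel is cut at 3*sigma and renormalized at
# the edges (and over NA entries) so the smoother preserves constants.
gauss_smooth <- function(Z, h, sigma) {
  half <- max(1L, ceiling(3 * sigma / h))
  k <- exp(-0.5 * ((-half:half) * h / sigma)^2)
  smooth1 <- function(M) {
    n <- nrow(M)
    W <- matrix(0, n, n)
    for (d in -half:half) {
      idx <- seq_len(n) + d
      ok <- idx >= 1L & idx <= n
      W[cbind(which(ok), idx[ok])] <- k[d + half + 1L]
    }
    ok <- !is.na(M)
    M0 <- M; M0[!ok] <- 0
    num <- W %*% M0
    den <- W %*% ok
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  # rows then columns (kernel is isotropic and separable)
  t(smooth1(t(smooth1(Z))))
}
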
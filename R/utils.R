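# Internal helpers shared across modules.

#' @importFrom stats rnorm runif sd var
NULL

# Shift a matrix by (dr, dc), padding with `fill`. Used for vectorized
# neighborhood operations (thinning, curvature, neighbor counts).
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbour offsets in clockwise order starting north (used by thinning).
NBR8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
              dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# Count of 8-connected foreground neighbours for every pixel of a 0/1 matrix.
neighbor_count8 <- function(m) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(8)) acc <- acc + shift_mat(m, NBR8[k, 1], NBR8[k, 2])
  acc
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

# Odd-sized disc structuring element of the given radius (radius 0 -> 1x1).
disc_brush <- function(radius) {
  if (radius < 1) return(matrix(1, 1, 1))
  sz <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(sz, shape = "disc")
}

# Polygon area by the shoelace formula; vertices as (x, y) matrix.
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Length of a closed polygon through the given vertices.
polygon_perimeter <- function(xy) {
  j <- c(2:nrow(xy), 1)
  sum(sqrt(rowSums((xy[j, , drop = FALSE] - xy)^2)))
}

# Circular moving average of a closed sequence of points (n x 2), window odd.
smooth_closed_contour <- function(xy, window = 5L) {
  n <- nrow(xy)
  if (n <= window) return(xy)
  h <- (window - 1L) %/% 2L
  idx <- function(i) ((i - 1L) %% n) + 1L
  out <- xy
  for (d in setdiff(seq(-h, h), 0L)) out <- out + xy[idx(seq_len(n) + d), , drop = FALSE]
  out / window
}

`%||%` <- function(a, b) if (is.null(a)) b else a
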
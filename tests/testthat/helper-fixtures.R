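# Shared geometric fixtures, built in code. The drawing helpers here are
# deliberately independent of the package's internals so they can serve as
# oracles for the skeleton/graph code.

fix_size <- 304L
fix_px_mm <- 3 / 304

coord_grids <- function(size = fix_size) {
  rows <- matrix(seq_len(size), size, size)
  list(rows = rows, cols = t(rows))
}

disk_mask <- function(r, center = c(152.5, 152.5), size = fix_size) {
  g <- coord_grids(size)
  (g$rows - center[1])^2 + (g$cols - center[2])^2 <= r^2
}

square_mask <- function(side = 100L, from = 100L, size = fix_size) {
  m <- matrix(FALSE, size, size)
  m[from:(from + side - 1L), from:(from + side - 1L)] <- TRUE
  m
}

ellipse_mask <- function(a = 60, b = 30, center = c(152.5, 152.5),
                         size = fix_size) {
  g <- coord_grids(size)
  (g$rows - center[1])^2 / b^2 + (g$cols - center[2])^2 / a^2 <= 1
}

# plus-sign polyomino of five axis-aligned squares of side `a`
plus_mask <- function(a = 40L, size = fix_size) {
  m <- matrix(FALSE, size, size)
  c0 <- (size - 3L * a) %/% 2L
  m[(c0 + a):(c0 + 2L * a - 1L), c0:(c0 + 3L * a - 1L)] <- TRUE
  m[c0:(c0 + 3L * a - 1L), (c0 + a):(c0 + 2L * a - 1L)] <- TRUE
  m
}

sierpinski_carpet <- function(depth = 5L) {
  m <- matrix(TRUE, 1L, 1L)
  for (i in seq_len(depth)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, m, m), cbind(m, z, m), cbind(m, m, m))
  }
  m
}

# independent Bresenham-style segment rasterizer (oracle-side)
fix_segment <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0))
  if (n == 0) return(cbind(r0, c0))
  t <- 0:n / n
  unique(cbind(round(r0 + t * (r1 - r0)), round(c0 + t * (c1 - c0))))
}

draw_polyline <- function(pts, size = fix_size) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(nrow(pts) - 1L)) {
    m[fix_segment(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2])] <- TRUE
  }
  m
}

# semicircular arc of radius r (flat side up), as an 8-connected curve
semicircle_mask <- function(r = 60, center = c(200, 150), size = fix_size) {
  th <- seq(0, pi, length.out = ceiling(6 * r))
  draw_polyline(cbind(center[1] - r * sin(th), center[2] + r * cos(th)), size)
}

# "Y": one horizontal stem and two 45-degree arms of ~20 px
y_mask <- function(size = 101L) {
  m <- matrix(FALSE, size, size)
  m[51, 31:51] <- TRUE
  for (k in 0:20) {
    m[51 - k, 51 + k] <- TRUE
    m[51 + k, 51 + k] <- TRUE
  }
  m
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# boundary length proxy: count of 4-adjacent foreground/background pairs
boundary_length4 <- function(mask) {
  m <- mask * 1
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}
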
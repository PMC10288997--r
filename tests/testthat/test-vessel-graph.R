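test_that("thinning collapses simple shapes to their medial structure", {
  # 5 px x 100 px bar: ~1-px line, modest end erosion only
  bar <- matrix(FALSE, 120, 120)
  bar[58:62, 11:110] <- TRUE
  sk <- skeletonize(bar)
  expect_true(sum(sk$skeleton) >= 96 && sum(sk$skeleton) <= 100)
  g <- extract_branches(sk)
  expect_identical(g$B_num, 0L)
  expect_length(g$branches, 1)
  # no 2x2 foreground block anywhere (unit width)
  s <- sk$skeleton * 1
  blocks <- s[-nrow(s), -ncol(s)] + s[-1, -ncol(s)] +
    s[-nrow(s), -1] + s[-1, -1]
  expect_lt(max(blocks), 4)

  # filled disk collapses to a handful of pixels
  expect_lte(sum(skeletonize(disk_mask(10, c(50, 50), 100))$skeleton), 5)

  # empty mask: empty skeleton, no error
  expect_false(any(skeletonize(matrix(FALSE, 20, 20))$skeleton))

  # component correspondence: two separate bars -> two skeleton components
  two <- matrix(FALSE, 100, 100)
  two[20:24, 10:90] <- TRUE
  two[70:74, 10:90] <- TRUE
  expect_equal(max(EBImage::bwlabel(skeletonize(two)$skeleton * 1)), 2)
})

test_that("bifurcation detection counts junction clusters once", {
  line <- matrix(FALSE, 50, 50)
  line[25, 5:45] <- TRUE
  expect_identical(detect_bifurcations(skeletonize(line))$B_num, 0L)

  gy <- vessel_graph(y_mask())
  expect_identical(gy$B_num, 1L)
  expect_length(gy$branches, 3)
})

test_that("spur pruning removes short spurs and recomputes nodes once", {
  m <- matrix(FALSE, 101, 101)
  m[51, 31:51] <- TRUE
  for (k in 0:20) m[51 - k, 51 + k] <- TRUE
  m[52:54, 52] <- TRUE                  # 3-px spur at the bend
  g <- vessel_graph(m, min_branch_px = 5)
  expect_identical(g$B_num, 0L)
  expect_length(g$branches, 1)

  # pruning monotonicity: larger threshold never increases branch count
  gen <- generate_vessel_tree(tree_params(seed = 41))
  counts <- vapply(c(3, 5, 9), function(mb)
    length(vessel_graph(gen$mask, min_branch_px = mb)$branches), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("arc-chord tortuosity matches analytic and quadrature oracles", {
  # straight branch: exactly 1
  line <- matrix(FALSE, 100, 100)
  line[50, 10:90] <- TRUE
  expect_equal(as.numeric(tortuosity(vessel_graph(line))), 1, tolerance = 1e-9)

  # semicircular arc: arc/chord = pi/2 within 2%
  gs <- vessel_graph(semicircle_mask())
  expect_lt(abs(as.numeric(tortuosity(gs)) - pi / 2) / (pi / 2), 0.02)

  # rasterized sine y = 10 sin(2 pi x / 50), x in [0, 100]: numeric integral
  x <- 0:100
  m <- draw_polyline(cbind(round(151 + 10 * sin(2 * pi * x / 50)), 101 + x))
  tau <- as.numeric(tortuosity(vessel_graph(m)))
  arc <- stats::integrate(function(t)
    sqrt(1 + (10 * 2 * pi / 50 * cos(2 * pi * t / 50))^2), 0, 100)$value
  expect_lt(abs(tau - arc / 100) / (arc / 100), 0.03)

  # closed loops are excluded and counted
  ring <- disk_mask(40, c(150, 150)) & !disk_mask(36, c(150, 150))
  gl <- vessel_graph(ring)
  expect_error(tortuosity(gl), "loops")
  both <- ring | draw_polyline(cbind(c(20, 20), c(20, 120)))
  tb <- tortuosity(vessel_graph(both))
  expect_gte(attr(tb, "n_excluded"), 1)

  expect_error(tortuosity(list(branches = list())[["branches"]]))
})

test_that("B_num is invariant to rotations and mirroring", {
  gen <- generate_vessel_tree(tree_params(seed = 44))
  b0 <- vessel_graph(gen$mask)$B_num
  rot90 <- function(m) t(m)[ncol(m):1, ]
  m <- gen$mask
  for (k in 1:3) {
    m <- rot90(m)
    expect_identical(vessel_graph(m)$B_num, b0)
  }
  expect_identical(vessel_graph(gen$mask[, ncol(gen$mask):1])$B_num, b0)
})

test_that("branch arc lengths are bounded by skeleton pixel accounting", {
  gen <- generate_vessel_tree(tree_params(seed = 45))
  g <- vessel_graph(gen$mask)
  n_px <- sum(g$skeleton)
  total_arc <- skeleton_length(g)
  # each pixel contributes at most sqrt(2); node pixels are shared between
  # branches, so allow one extra step per node
  expect_lte(total_arc, sqrt(2) * (n_px + nrow(g$nodes)))
  for (b in g$branches) {
    expect_gte(b$arc_px, b$chord_px - 1e-9)
  }
})
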
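test_that("FAZ shape descriptors match closed-form oracles", {
  # perfect circle
  mc <- faz_shape_metrics(faz_region(disk_mask(50)), fix_px_mm)
  expect_gte(mc$FC, 0.98); expect_lte(mc$FC, 1.0)
  expect_gte(mc$FAR, 1.0); expect_lte(mc$FAR, 1.02)
  expect_gte(mc$FS, 0.99)
  expect_gt(mc$FR, 0.97); expect_lte(mc$FR, 1.05)

  # axis-aligned square: FC -> pi/4
  ms <- faz_shape_metrics(faz_region(square_mask()), fix_px_mm)
  expect_lt(abs(ms$FC - pi / 4) / (pi / 4), 0.03)
  expect_gte(ms$FS, 0.99)

  # 2:1 ellipse: FC via Ramanujan perimeter; FAR = 2
  a <- 60; b <- 30
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  fc_oracle <- 4 * pi * (pi * a * b) / per^2
  me <- faz_shape_metrics(faz_region(ellipse_mask(a, b)), fix_px_mm)
  expect_lt(abs(me$FC - fc_oracle) / fc_oracle, 0.03)
  expect_lt(abs(me$FAR - 2) / 2, 0.02)

  # plus-sign polyomino: solidity 5/7 against the analytic hull area
  mp <- faz_shape_metrics(faz_region(plus_mask()), fix_px_mm)
  expect_lt(abs(mp$FS - 5 / 7) / (5 / 7), 0.03)

  # FA unit triple is consistent
  expect_equal(mc$FA_mm2, mc$FA_px * fix_px_mm^2)
  expect_equal(mc$FA_pct, 100 * mc$FA_px / 304^2)

  # clipped regions are flagged, not rejected
  edge <- matrix(FALSE, 100, 100); edge[1:30, 40:60] <- TRUE
  expect_true("clipped" %in% faz_shape_metrics(faz_region(edge), fix_px_mm)$flags)
})

test_that("shape metrics are invariant to translation and right-angle rotation", {
  m1 <- faz_shape_metrics(faz_region(ellipse_mask(50, 28, c(120, 140))),
                          fix_px_mm)
  m2 <- faz_shape_metrics(faz_region(ellipse_mask(50, 28, c(180, 160))),
                          fix_px_mm)
  rot <- t(ellipse_mask(50, 28))[, 304:1]
  m3 <- faz_shape_metrics(faz_region(rot), fix_px_mm)
  for (k in c("FC", "FAR", "FR", "FS")) {
    expect_lt(abs(m1[[k]] - m2[[k]]) / m1[[k]], 0.02)
    expect_lt(abs(m1[[k]] - m3[[k]]) / m1[[k]], 0.02)
  }
})

test_that("structure-tensor orientations recover known directions", {
  bar <- matrix(FALSE, 100, 100); bar[50:52, 20:80] <- TRUE
  o <- orientation_field(bar)
  th <- o$theta[51, 45]
  expect_lt(min(th, pi - th) * 180 / pi, 5)

  d45 <- draw_polyline(cbind(c(20, 80), c(20, 80)), 100)
  d45 <- EBImage::dilate(d45 * 1, EBImage::makeBrush(3, "disc")) > 0
  o2 <- orientation_field(d45)
  expect_lt(abs(o2$theta[50, 50] - pi / 4) * 180 / pi, 5)

  # per-branch mean orientation matches the generator heading
  gen <- generate_vessel_tree(tree_params(seed = 51))
  of <- orientation_field(gen$mask)
  br <- gen$truth$branches
  errs <- c()
  for (i in seq_along(gen$truth$branch_polylines)) {
    if (is.na(br$orientation[i]) || br$arc_px[i] < 20) next
    pts <- round(gen$truth$branch_polylines[[i]])
    keep <- pts[, 1] >= 1 & pts[, 1] <= 304 & pts[, 2] >= 1 & pts[, 2] <= 304
    th <- of$theta[pts[keep, , drop = FALSE]]
    th <- th[!is.na(th)]
    if (length(th) < 3) next
    mt <- (atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2) %% pi
    d <- abs(mt - br$orientation[i])
    errs <- c(errs, min(d, pi - d) * 180 / pi)
  }
  expect_gt(length(errs), 5)
  expect_lt(stats::quantile(errs, 0.9), 10)

  # empty mask: empty field
  oe <- orientation_field(matrix(FALSE, 20, 20))
  expect_true(all(is.na(oe$theta)))
})

test_that("direction ellipse behaves like a second-moment rose fit", {
  set.seed(1)
  iso <- list(theta = matrix(runif(2e4, 0, pi), 200, 100))
  de <- direction_ellipse(iso)
  expect_gte(de$direction_ratio, 0.95)

  # halving the pixel count at fixed distribution quarters the area
  half <- list(theta = matrix(c(iso$theta[1:1e4], rep(NA, 1e4)), 200, 100))
  de2 <- direction_ellipse(half)
  expect_lt(abs(de2$direction_area / de$direction_area - 0.25), 0.05)

  # two equal orthogonal populations: near-isotropic four-fold rose
  orth <- list(theta = matrix(rep(c(0.02, pi / 2 + 0.02), each = 5000),
                              100, 100))
  expect_gte(direction_ellipse(orth)$direction_ratio, 0.9)

  # single-orientation degenerate rose is flagged
  one <- list(theta = matrix(rep(0.3, 100), 10, 10))
  d1 <- direction_ellipse(one)
  expect_true(d1$degenerate)
  expect_identical(d1$direction_ratio, 0)
  expect_identical(d1$direction_area, 0)
})

test_that("vessel densities are exact ratios", {
  full <- matrix(TRUE, 100, 100)
  skel <- matrix(FALSE, 100, 100)
  expect_equal(vessel_densities(full, skel)$VAD, 100)
  half <- matrix(FALSE, 100, 100); half[, 1:50] <- TRUE
  expect_equal(vessel_densities(half, skel)$VAD, 50)
  skel[30, ] <- TRUE
  expect_equal(vessel_densities(half, skel)$VLD, 1)
  expect_error(vessel_densities(half, skel, matrix(FALSE, 100, 100)), "empty")
})

test_that("box-counting dimension matches known dimensions", {
  line <- matrix(FALSE, 256, 256); line[100, ] <- TRUE
  expect_lt(abs(fractal_dimension(line) - 1), 0.05)
  expect_lt(abs(fractal_dimension(matrix(TRUE, 256, 256)) - 2), 0.05)
  expect_lt(abs(fractal_dimension(sierpinski_carpet(5)) - log(8) / log(3)),
            0.05)
  # monotone under supersets
  gen <- generate_vessel_tree(tree_params(seed = 55))
  sup <- EBImage::dilate(gen$mask * 1, EBImage::makeBrush(5, "disc")) > 0
  expect_gte(fractal_dimension(sup), fractal_dimension(gen$mask))
  # degenerate inputs
  expect_error(fractal_dimension(matrix(FALSE, 10, 10)), "empty")
  expect_error(fractal_dimension(matrix(TRUE, 10, 10),
                                 box_sizes = c(2, 32, 64)), "3 usable")
})

test_that("metric vector assembly composes the individual metrics", {
  gen <- generate_vessel_tree(tree_params(seed = 56))
  fz <- segment_faz(gen$mask)
  mv <- compute_metric_vector(gen$image, gen$mask, fz)
  expect_named(mv, METRIC_NAMES)
  # composition identity against individually computed pieces
  fm <- faz_shape_metrics(fz, fix_px_mm)
  expect_equal(mv$FC, fm$FC)
  expect_equal(mv$FA, fm$FA_pct)
  g <- vessel_graph(gen$mask)
  expect_identical(mv$B_num, g$B_num)
  expect_equal(mv$VAD, vessel_densities(gen$mask, g$skeleton)$VAD)
  expect_equal(mv$FD, fractal_dimension(gen$mask))
  # domain invariants
  expect_lte(mv$FC, 1.05); expect_lte(mv$FS, 1); expect_gte(mv$FAR, 1)
  expect_gte(mv$VAD, mv$VLD)
  expect_gte(mv$FD, 0); expect_lte(mv$FD, 2)
  expect_gte(mv$tortuosity, 1)
  expect_gt(mv$direction_ratio, 0); expect_lte(mv$direction_ratio, 1)

  # empty vessel mask: densities and counts zero, curve metrics missing
  mv0 <- compute_metric_vector(gen$image, matrix(FALSE, 304, 304), fz)
  expect_equal(mv0$VAD, 0); expect_equal(mv0$VLD, 0)
  expect_identical(mv0$B_num, 0L)
  expect_true(is.na(mv0$FD) && is.na(mv0$tortuosity))
})
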
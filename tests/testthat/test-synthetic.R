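test_that("vessel tree generator is deterministic and honours branch_prob = 0", {
  tp <- tree_params(seed = 5)
  g1 <- generate_vessel_tree(tp)
  g2 <- generate_vessel_tree(tp)
  expect_identical(g1$mask, g2$mask)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$truth$bifurcation_count, g2$truth$bifurcation_count)

  g0 <- generate_vessel_tree(tree_params(branch_prob = 0, seed = 2))
  expect_identical(g0$truth$bifurcation_count, 0L)
})

test_that("ground truth bookkeeping is conserved", {
  gen <- generate_vessel_tree(tree_params(seed = 9))
  tr <- gen$truth
  # total centreline length is the sum of per-branch arcs
  expect_equal(tr$total_centerline_length_px, sum(tr$branches$arc_px))
  # arc >= chord for every branch
  expect_true(all(tr$branches$arc_px >= tr$branches$chord_px - 1e-9))
  # every split ends one branch and starts two: branches = roots + 2*splits
  # (+1 for the perifoveal arcade loop)
  expect_equal(nrow(tr$branches),
               tr$n_roots + 2 * tr$bifurcation_count + tr$has_faz_ring)
  # recorded vessel pixel count is the mask's own count, so the full-image
  # VAD identity holds exactly
  expect_equal(vessel_densities(gen$mask, gen$mask)$VAD,
               100 * tr$vessel_pixel_count / prod(dim(gen$mask)))
  # junction separation floor respected
  if (nrow(tr$junctions_px) > 1) {
    d <- as.matrix(stats::dist(tr$junctions_px))
    diag(d) <- Inf
    expect_gte(min(d), 8)
  }
})

test_that("synthetic FAZ shapes match their analytic descriptors", {
  # noise-free circle: rasterized circularity within rasterization slack
  p0 <- faz_shape_params(area_mm2 = 0.3, axial_ratio = 1, boundary_noise = 0)
  fz <- generate_faz_shape(p0, fix_px_mm, seed = 1)
  m <- faz_shape_metrics(fz$faz, fix_px_mm)
  expect_gte(m$FC, 0.98)
  expect_lte(m$FC, 1.0)
  # rasterized pixel area within 2% of shoelace area
  expect_lt(abs(sum(fz$faz$pixels) * fix_px_mm^2 - fz$area_mm2) / fz$area_mm2,
            0.02)

  # 2:1 ellipse: measured axial ratio within 2%
  p2 <- faz_shape_params(area_mm2 = 0.35, axial_ratio = 2, boundary_noise = 0)
  fz2 <- generate_faz_shape(p2, fix_px_mm, seed = 1)
  m2 <- faz_shape_metrics(fz2$faz, fix_px_mm)
  expect_lt(abs(m2$FAR - 2) / 2, 0.02)

  # noisy boundary keeps the area identity (vertices rescaled to target)
  pn <- faz_shape_params(area_mm2 = 0.4, axial_ratio = 1.3,
                         boundary_noise = 0.2)
  fzn <- generate_faz_shape(pn, fix_px_mm, seed = 7)
  expect_equal(fzn$area_mm2, 0.4, tolerance = 1e-8)
  expect_lt(abs(sum(fzn$faz$pixels) * fix_px_mm^2 - 0.4) / 0.4, 0.02)

  # a polygon larger than the image is rejected
  expect_error(generate_faz_shape(faz_shape_params(area_mm2 = 9), fix_px_mm,
                                  seed = 1),
               "fit")
})

test_that("bifurcation recovery is exact on self-avoiding fixtures", {
  for (s in 1:25) {
    tp <- tree_params(seed = 200 + s)
    gen <- generate_vessel_tree(tp)
    vg <- vessel_graph(gen$mask)
    expect_identical(vg$B_num, gen$truth$bifurcation_count)
    sl <- skeleton_length(vg, endpoint_correction_px = tp$vessel_width_px)
    rel <- abs(sl - gen$truth$total_centerline_length_px) /
      gen$truth$total_centerline_length_px
    expect_lt(rel, 0.05)
  }
})

test_that("cohort simulation reproduces the specified moments", {
  spec <- cohort_preset("table2")
  tab <- simulate_cohort(spec, seed = 1)
  expect_equal(nrow(tab), (50 + 44) * 3)
  expect_setequal(unique(tab$group), c("HC", "NMOSD"))
  expect_true(all(METRIC_NAMES %in% names(tab)))
  expect_identical(tab, simulate_cohort(spec, seed = 1))

  # zero-SD spec: every eye identical to the mean
  s0 <- cohort_spec(list(list(
    name = "HC", n_eyes = 4,
    covariates = list(age = c(mean = 50, sd = 0)),
    metrics = data.frame(plexus = "SVC", metric = "VAD", mean = 15, sd = 0))))
  t0 <- simulate_cohort(s0, seed = 3)
  expect_true(all(t0$VAD == 15))
  expect_true(all(t0$age == 50))

  # law of large numbers on the demographic preset: the mean of sample
  # means over replicate cohorts stays within 3 SE of the published means
  t1 <- cohort_preset("table1")
  mhc <- mon <- numeric(400)
  for (r in seq_len(400)) {
    d <- simulate_cohort(t1, seed = 5000 + r)
    mhc[r] <- mean(d$age[d$group == "HC"])
    mon[r] <- mean(d$age[d$group == "NMOSD"])
  }
  se_hc <- 13.21 / sqrt(50) / sqrt(400)
  se_on <- 12.48 / sqrt(44) / sqrt(400)
  expect_lt(abs(mean(mhc) - 47.36), 3 * se_hc)
  expect_lt(abs(mean(mon) - 47.68), 3 * se_on)
})

test_that("cohort spec validation rejects bad inputs", {
  expect_error(cohort_spec(list(list(name = "HC", n_eyes = 1,
                                     covariates = list(), metrics = NULL))))
  expect_error(cohort_spec(list(list(
    name = "HC", n_eyes = 5, covariates = list(),
    metrics = data.frame(plexus = "SVC", metric = "VAD",
                         mean = 1, sd = -1)))))
})
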
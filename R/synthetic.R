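#' @title Synthetic angiogram and cohort simulation
#' @name synthetic
#' @description Stochastic vascular-tree images with exactly book-kept ground
#'   truth (bifurcation count, centerline length, per-branch arc/chord,
#'   analytic FAZ polygon) and Gaussian cohort simulation from published
#'   group summaries. Every generator is a pure function of (params, seed).
NULL

#' Parameters for the synthetic vascular tree generator
#'
#' Trees are grown as discrete random walks from image-border roots toward
#' the centre, bifurcating with a fixed per-step probability, forbidden from
#' entering the FAZ polygon and from approaching non-adjacent vessels
#' (self-avoidance), so that the recorded topology is exactly the topology
#' of the rasterized mask.
#'
#' @param n_roots number of trunks entering from the image border.
#' @param branch_prob per-growth-step probability of a bifurcation attempt.
#' @param step_px growth-segment length in pixels.
#' @param angle_sigma_deg per-step heading jitter (degrees, SD).
#' @param bifurcation_angle_deg mean half-angle of a split (degrees).
#' @param vessel_width_px rasterization radius of the dilated centerline.
#' @param min_junction_sep_px minimum distance between junction points, so
#'   skeleton-based bifurcation detection is unambiguous.
#' @param speckle_sigma multiplicative Gaussian speckle SD on the intensity
#'   image.
#' @param background_ramp amplitude of the linear background gradient.
#' @param faz a [faz_shape_params()] object.
#' @param faz_ring draw a perifoveal capillary arcade: a closed loop just
#'   outside the FAZ boundary, as in real maculae, which also guarantees the
#'   FAZ is sealed for downstream extraction.
#' @param seed integer RNG seed.
#' @return A `tree_params` list.
#' @export
tree_params <- function(n_roots = 8L, branch_prob = 0.08, step_px = 3,
                        angle_sigma_deg = 10, bifurcation_angle_deg = 35,
                        vessel_width_px = 2L, min_junction_sep_px = 8,
                        speckle_sigma = 0.15, background_ramp = 0.1,
                        faz = faz_shape_params(), faz_ring = TRUE,
                        seed = 1L) {
  stopifnot(n_roots >= 1, branch_prob >= 0, branch_prob <= 1, step_px > 0,
            angle_sigma_deg >= 0, bifurcation_angle_deg > 0,
            vessel_width_px >= 0, min_junction_sep_px > 0,
            speckle_sigma >= 0, background_ramp >= 0)
  structure(list(n_roots = as.integer(n_roots), branch_prob = branch_prob,
                 step_px = step_px, angle_sigma_deg = angle_sigma_deg,
                 bifurcation_angle_deg = bifurcation_angle_deg,
                 vessel_width_px = as.integer(vessel_width_px),
                 min_junction_sep_px = min_junction_sep_px,
                 speckle_sigma = speckle_sigma,
                 background_ramp = background_ramp,
                 faz = faz, faz_ring = isTRUE(faz_ring),
                 seed = as.integer(seed)),
            class = "tree_params")
}

#' Parameters for the synthetic FAZ polygon
#'
#' A noise-perturbed ellipse whose area, perimeter, circularity and axial
#' ratio are analytically known before rasterization.
#'
#' @param area_mm2 target polygon area (mm^2); the vertex set is rescaled so
#'   its shoelace area matches exactly.
#' @param axial_ratio major/minor axis ratio of the generating ellipse
#'   (>= 1).
#' @param boundary_noise radial perturbation amplitude as a fraction of the
#'   local radius, in `[0, 0.5)`.
#' @param n_vertices polygon resolution.
#' @export
faz_shape_params <- function(area_mm2 = 0.35, axial_ratio = 1.2,
                             boundary_noise = 0.08, n_vertices = 256L) {
  stopifnot(area_mm2 > 0, axial_ratio >= 1,
            boundary_noise >= 0, boundary_noise < 0.5, n_vertices >= 8)
  structure(list(area_mm2 = area_mm2, axial_ratio = axial_ratio,
                 boundary_noise = boundary_noise,
                 n_vertices = as.integer(n_vertices)),
            class = "faz_shape_params")
}

#' A FAZ region object
#'
#' @param mask logical matrix, exactly one connected component.
#' @param flags character vector of quality flags (e.g. `"degenerate"`,
#'   `"clipped"`).
#' @return list with `pixels`, `centroid_px` (row, col), `boundary`
#'   (closed contour, n x 2 matrix of (row, col)), `flags`.
#' @export
faz_region <- function(mask, flags = character()) {
  mask <- mask != 0
  idx <- which(mask, arr.ind = TRUE)
  centroid <- if (nrow(idx)) colMeans(idx) else c(NA_real_, NA_real_)
  boundary <- mask_contour(mask)
  structure(list(pixels = mask, centroid_px = unname(centroid),
                 boundary = boundary, flags = flags),
            class = "faz_region")
}

# Longest closed outer contour of a mask, as (row, col) 1-based coordinates.
mask_contour <- function(mask) {
  if (!any(mask)) return(matrix(numeric(0), 0, 2))
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))
  cont <- oc[[which.max(vapply(oc, nrow, 1L))]]
  # EBImage indexes its first dimension along our matrix rows, 0-based.
  cbind(row = cont[, 1] + 1, col = cont[, 2] + 1)
}

#' Generate a synthetic FAZ polygon and its rasterization
#'
#' @param params a [faz_shape_params()] object.
#' @param pixel_size_mm physical pixel size.
#' @param size image width in pixels.
#' @param center_px polygon centre (row, col); defaults to the image centre.
#' @param seed RNG seed; `NULL` draws from the current stream.
#' @return list: `faz` ([faz_region()]), `vertices_px` (n x 2 (row, col)),
#'   `area_mm2` and `perimeter_mm` (shoelace/polyline, analytic),
#'   `axial_ratio` of the generating ellipse.
#' @export
generate_faz_shape <- function(params, pixel_size_mm, size = OCTA_IMAGE_SIZE,
                               center_px = NULL, seed = NULL) {
  run <- function() {
    n <- params$n_vertices
    phi <- 2 * pi * (seq_len(n) - 1) / n
    ar <- params$axial_ratio
    a <- sqrt(ar); b <- 1 / sqrt(ar)            # unit-area-ish ellipse axes
    r0 <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    if (params$boundary_noise > 0) {
      pert <- rep(0, n)
      for (h in 2:5) {
        pert <- pert + rnorm(1) * cos(h * phi) + rnorm(1) * sin(h * phi)
      }
      pert <- pert / max(abs(pert), 1e-12) * params$boundary_noise
      r <- r0 * (1 + pert)
    } else r <- r0
    target_px2 <- params$area_mm2 / pixel_size_mm^2
    xy <- cbind(r * cos(phi), r * sin(phi))
    s <- sqrt(target_px2 / shoelace_area(xy))
    xy <- xy * s
    if (max(sqrt(rowSums(xy^2))) >= size / 2) {
      stop("FAZ polygon does not fit inside the image")
    }
    ctr <- center_px %||% c((size + 1) / 2, (size + 1) / 2)
    verts <- cbind(row = ctr[1] + xy[, 2], col = ctr[2] + xy[, 1])
    mask <- rasterize_star_polygon(r * s, phi, ctr, size)
    area_mm2 <- shoelace_area(xy) * pixel_size_mm^2
    per_mm <- polygon_perimeter(xy) * pixel_size_mm
    list(faz = faz_region(mask), vertices_px = verts,
         area_mm2 = area_mm2, perimeter_mm = per_mm,
         axial_ratio = params$axial_ratio)
  }
  if (is.null(seed)) run() else with_rng_seed(seed, run())
}

# Fill a star-shaped polygon given its radius function r(phi) sampled at
# `phi` (ascending on [0, 2pi)), centred at ctr, into a size x size mask.
rasterize_star_polygon <- function(r, phi, ctr, size) {
  rows <- matrix(seq_len(size), size, size) - ctr[1]
  cols <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr[2]
  ang <- atan2(rows, cols) %% (2 * pi)
  rad <- sqrt(rows^2 + cols^2)
  rb <- stats::approx(c(phi, 2 * pi + phi[1]), c(r, r[1]), xout = ang,
                      rule = 2)$y
  matrix(rad <= rb, size, size)
}

# Pixels of the segment (r0,c0) -> (r1,c1), excluding the start (Bresenham).
segment_pixels <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  n <- max(dr, dc)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  t <- seq_len(n) / n
  cbind(round(r0 + t * (r1 - r0)), round(c0 + t * (c1 - c0)))
}

#' Grow a synthetic vascular tree with exact ground truth
#'
#' See [tree_params()] for the growth model. The centerline polylines are
#' recorded exactly during growth: each successful split increments the
#' ground-truth bifurcation count, every branch's arc and chord length is
#' accumulated from its segments, and the vessel mask is the dilation of the
#' drawn centerlines by `vessel_width_px`. The intensity image is the mask
#' plus multiplicative speckle and a linear background ramp. Identical
#' parameters and seed give identical output.
#'
#' @param params a [tree_params()] object.
#' @param size image width (pixels).
#' @param fov_mm physical field width (mm).
#' @return list: `image` ([en_face_image()]), `mask` (logical matrix),
#'   `truth` (list: `bifurcation_count`, `total_centerline_length_px`,
#'   `vessel_pixel_count`, `centerline` mask, `junctions_px`, `branches`
#'   data frame with arc/chord/orientation, `faz` polygon info, `n_roots`).
#' @export
generate_vessel_tree <- function(params, size = OCTA_IMAGE_SIZE,
                                 fov_mm = OCTA_FOV_MM) {
  with_rng_seed(params$seed, {
    px_mm <- fov_mm / size
    fazgen <- generate_faz_shape(params$faz, px_mm, size = size)
    w <- params$vessel_width_px
    # centreline separation floor: two discs of radius ~w+0.5 dilated onto
    # 8-connected chains can touch up to d = 2(w+0.5)+sqrt(2) ~ 2w+2.42, so
    # anything at or below 2w+3 is rejected
    sep <- 2 * w + 3
    exempt_r <- sep + 2                   # junction-neighbourhood exemption
    lookahead <- 10                       # guaranteed initial branch length
    border_margin <- 4
    jct_margin <- 12
    # forbidden zone: FAZ dilated so the dilated mask cannot enter the FAZ
    faz_forbid <- EBImage::dilate(fazgen$faz$pixels * 1, disc_brush(w + 1)) > 0

    occ_id <- matrix(0L, size, size)      # branch id per centreline pixel
    occ_step <- matrix(0L, size, size)    # growth-step stamp per pixel
    junctions <- matrix(numeric(0), 0, 2)
    branches <- list()                    # each: origin, pts, arc, headings
    bif_count <- 0L
    sigma <- params$angle_sigma_deg * pi / 180
    half <- params$bifurcation_angle_deg * pi / 180
    step <- params$step_px
    n_steps_look <- ceiling(lookahead / step)

    inside <- function(p) p[1] >= 1 && p[1] <= size && p[2] >= 1 && p[2] <= size
    blocked <- function(pix, id, origin, young, step_now, ex_r = exempt_r,
                        kin = integer(0)) {
      # returns TRUE if any pixel of `pix` collides
      for (i in seq_len(nrow(pix))) {
        r <- pix[i, 1]; c <- pix[i, 2]
        if (r < border_margin || r > size - border_margin + 1 ||
            c < border_margin || c > size - border_margin + 1) {
          if (r < 1 || r > size || c < 1 || c > size) return(TRUE)
        }
        if (faz_forbid[r, c]) return(TRUE)
        rs <- max(1, r - sep):min(size, r + sep)
        cs <- max(1, c - sep):min(size, c + sep)
        win_id <- occ_id[rs, cs]
        hit <- which(win_id > 0L)
        if (!length(hit)) next
        wr <- ((hit - 1) %% length(rs)) + 1; wc <- ((hit - 1) %/% length(rs)) + 1
        hr <- rs[wr]; hc <- cs[wc]
        d2 <- (hr - r)^2 + (hc - c)^2
        near <- d2 <= sep^2
        if (!any(near)) next
        ids <- win_id[hit[near]]
        steps <- occ_step[rs, cs][hit[near]]
        hrr <- hr[near]; hcc <- hc[near]
        for (k in seq_along(ids)) {
          if (ids[k] == 1L) return(TRUE)      # perifoveal arcade: hard wall
          if (ids[k] == id && (step_now - steps[k]) <= 6L) next   # own tail
          # near-origin exemption applies only to the parent/sibling
          # branches, so unrelated vessels passing a junction still block
          if (young && ex_r > 0 && ids[k] %in% kin &&
              (hrr[k] - origin[1])^2 + (hcc[k] - origin[2])^2 <= ex_r^2) next
          return(TRUE)
        }
      }
      FALSE
    }

    # tip stack entries: r, c, heading, id, origin, arc, step index at birth
    tips <- list()
    ctr <- c((size + 1) / 2, (size + 1) / 2)
    ring_len <- 0
    if (params$faz_ring) {
      # perifoveal arcade: closed loop offset w+1 px outside the FAZ polygon
      vr <- sweep(fazgen$vertices_px, 2, ctr)
      rad <- sqrt(rowSums(vr^2))
      ringv <- round(sweep(vr * ((rad + w + 1) / rad), 2, ctr, `+`))
      prev <- ringv[nrow(ringv), ]
      for (i in seq_len(nrow(ringv))) {
        pix <- segment_pixels(prev[1], prev[2], ringv[i, 1], ringv[i, 2])
        if (nrow(pix)) { occ_id[pix] <- 1L; occ_step[pix] <- 0L }
        ring_len <- ring_len + sqrt(sum((ringv[i, ] - prev)^2))
        prev <- ringv[i, ]
      }
      branches[[1L]] <- list(id = 1L, pts = rbind(ringv, ringv[1, ]),
                             arc = ring_len, chord = 0,
                             orientation = NA_real_)
    }
    next_id <- 2L
    # roots spread around the border
    for (i in seq_len(params$n_roots)) {
      side <- sample.int(4L, 1L)
      pos <- runif(1, border_margin + 2, size - border_margin - 1)
      p <- switch(side,
                  c(border_margin, pos), c(size - border_margin + 1, pos),
                  c(pos, border_margin), c(pos, size - border_margin + 1))
      p <- round(p)
      heading <- atan2(ctr[1] - p[1], ctr[2] - p[2]) + rnorm(1, 0, sigma)
      look <- segment_pixels(p[1], p[2], p[1] + sin(heading) * lookahead,
                             p[2] + cos(heading) * lookahead)
      if (!inside(p) || occ_id[p[1], p[2]] > 0L ||
          blocked(look, next_id, p, TRUE, 0L, ex_r = 0)) next
      # commit the validated entry segment so the trunk is guaranteed
      occ_id[p[1], p[2]] <- next_id
      occ_step[p[1], p[2]] <- 0L
      occ_id[look] <- next_id
      occ_step[look] <- 0L
      endp <- look[nrow(look), ]
      tips[[length(tips) + 1L]] <- list(p = endp, heading = heading,
                                        id = next_id, origin = p,
                                        arc = sqrt(sum((endp - p)^2)),
                                        pts = rbind(p, endp),
                                        headings = heading,
                                        nsteps = n_steps_look, ex_r = 0,
                                        kin = integer(0))
      next_id <- next_id + 1L
    }
    n_roots_placed <- length(tips)

    finish_branch <- function(tip) {
      branches[[length(branches) + 1L]] <<- list(
        id = tip$id, pts = tip$pts, arc = tip$arc,
        chord = sqrt(sum((tip$pts[nrow(tip$pts), ] - tip$pts[1, ])^2)),
        orientation = if (length(tip$headings))
          (atan2(mean(sin(2 * tip$headings)), mean(cos(2 * tip$headings))) / 2) %% pi
        else NA_real_)
    }

    max_branches <- 400L
    while (length(tips) > 0L) {
      tip <- tips[[length(tips)]]
      tips[[length(tips)]] <- NULL
      alive <- TRUE
      while (alive) {
        tip$nsteps <- tip$nsteps + 1L
        heading <- tip$heading + rnorm(1, 0, sigma)
        p0 <- tip$p
        p1 <- c(p0[1] + sin(heading) * step, p0[2] + cos(heading) * step)
        pix <- segment_pixels(p0[1], p0[2], round(p1[1]), round(p1[2]))
        young <- tip$arc < (lookahead + sep)
        if (nrow(pix) == 0 ||
            blocked(pix, tip$id, tip$origin, young, tip$nsteps, tip$ex_r,
                    tip$kin)) {
          finish_branch(tip); alive <- FALSE; break
        }
        occ_id[pix] <- tip$id
        occ_step[pix] <- tip$nsteps
        seglen <- sqrt(sum((pix[nrow(pix), ] - p0)^2))
        tip$p <- pix[nrow(pix), ]
        tip$heading <- heading
        tip$arc <- tip$arc + seglen
        tip$pts <- rbind(tip$pts, tip$p)
        tip$headings <- c(tip$headings, heading)
        # attempt a bifurcation
        can_split <- tip$arc >= lookahead &&
          length(branches) + length(tips) < max_branches &&
          tip$p[1] > jct_margin && tip$p[1] <= size - jct_margin &&
          tip$p[2] > jct_margin && tip$p[2] <= size - jct_margin &&
          (nrow(junctions) == 0 ||
           min((junctions[, 1] - tip$p[1])^2 + (junctions[, 2] - tip$p[2])^2) >
             params$min_junction_sep_px^2)
        if (can_split && runif(1) < params$branch_prob) {
          h1 <- heading + max(25, min(45, params$bifurcation_angle_deg +
                                        rnorm(1, 0, 5))) * pi / 180
          h2 <- heading - max(25, min(45, params$bifurcation_angle_deg +
                                        rnorm(1, 0, 5))) * pi / 180
          ok <- TRUE
          for (h in c(h1, h2)) {
            look <- segment_pixels(tip$p[1], tip$p[2],
                                   tip$p[1] + sin(h) * lookahead,
                                   tip$p[2] + cos(h) * lookahead)
            if (blocked(look, -1L, tip$p, TRUE, 0L, kin = tip$id)) {
              ok <- FALSE; break
            }
          }
          if (ok) {
            junctions <- rbind(junctions, tip$p)
            bif_count <- bif_count + 1L
            finish_branch(tip)
            # commit both validated initial child segments: every counted
            # split is guaranteed two branches of >= lookahead px
            child_ids <- c(next_id, next_id + 1L)
            next_id <- next_id + 2L
            for (ci in 1:2) {
              h <- c(h1, h2)[ci]
              look <- segment_pixels(tip$p[1], tip$p[2],
                                     tip$p[1] + sin(h) * lookahead,
                                     tip$p[2] + cos(h) * lookahead)
              occ_id[look] <- child_ids[ci]
              occ_step[look] <- 0L
              endp <- look[nrow(look), ]
              tips[[length(tips) + 1L]] <- list(
                p = endp, heading = h, id = child_ids[ci], origin = tip$p,
                arc = sqrt(sum((endp - tip$p)^2)), pts = rbind(tip$p, endp),
                headings = h, nsteps = n_steps_look, ex_r = exempt_r,
                kin = c(tip$id, child_ids[3 - ci]))
            }
            alive <- FALSE
          }
        }
        if (alive && tip$arc > 2 * size) { finish_branch(tip); alive <- FALSE }
      }
    }

    centerline <- occ_id > 0L
    mask <- if (w > 0) EBImage::dilate(centerline * 1, disc_brush(w)) > 0
            else centerline
    branch_df <- if (length(branches)) data.frame(
      id = vapply(branches, `[[`, 1L, "id"),
      arc_px = vapply(branches, `[[`, 1, "arc"),
      chord_px = vapply(branches, `[[`, 1, "chord"),
      orientation = vapply(branches, `[[`, 1, "orientation")
    ) else data.frame(id = integer(), arc_px = numeric(),
                      chord_px = numeric(), orientation = numeric())

    base <- 0.25 + 0.65 * mask
    ramp <- params$background_ramp *
      (matrix(seq_len(size), size, size, byrow = TRUE) / size - 0.5)
    speck <- matrix(rnorm(size * size, 0, params$speckle_sigma), size, size)
    img <- clamp01(base * (1 + speck) + ramp)

    list(image = en_face_image(img, fov_mm = fov_mm),
         mask = mask,
         truth = list(bifurcation_count = bif_count,
                      total_centerline_length_px = sum(branch_df$arc_px),
                      vessel_pixel_count = sum(mask),
                      centerline = centerline,
                      junctions_px = junctions,
                      branches = branch_df,
                      branch_polylines = lapply(branches, `[[`, "pts"),
                      faz = fazgen,
                      has_faz_ring = params$faz_ring,
                      n_roots = n_roots_placed))
  })
}

#' Cohort specification
#'
#' @param groups list of groups, each a list with `name`, `n_eyes` (>= 2),
#'   `covariates` (named list of `c(mean, sd)`), and `metrics` (data frame
#'   with columns plexus, metric, mean, sd, or `NULL`).
#' @export
cohort_spec <- function(groups) {
  for (g in groups) {
    stopifnot(g$n_eyes >= 2)
    if (!is.null(g$metrics)) stopifnot(all(g$metrics$sd >= 0))
    for (cv in g$covariates) stopifnot(cv[["sd"]] >= 0)
  }
  structure(list(groups = groups), class = "cohort_spec")
}

#' Simulate a per-eye metric cohort
#'
#' Independent Gaussian draws per eye and metric with the specification's
#' group means/SDs (the published tables disclose only marginal summaries,
#' so no inter-metric correlation is imposed). Seed-reproducible.
#'
#' @param spec a [cohort_spec()], e.g. from [cohort_preset()].
#' @param seed integer seed.
#' @return data frame, one row per eye x plexus (or per eye if the spec has
#'   no metrics): subject, eye, group, covariates, plexus, metric columns.
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_rng_seed(seed, {
    out <- list()
    eye_i <- 0L
    for (g in spec$groups) {
      n <- g$n_eyes
      base <- data.frame(
        subject = sprintf("S%03d", eye_i + seq_len(n)),
        eye = ifelse(seq_len(n) %% 2L == 1L, "OD", "OS"),
        group = g$name, stringsAsFactors = FALSE)
      eye_i <- eye_i + n
      for (nm in names(g$covariates)) {
        cv <- g$covariates[[nm]]
        base[[nm]] <- rnorm(n, cv[["mean"]], cv[["sd"]])
      }
      if (is.null(g$metrics)) { out[[length(out) + 1L]] <- base; next }
      for (px in unique(g$metrics$plexus)) {
        m <- g$metrics[g$metrics$plexus == px, ]
        blk <- base
        blk$plexus <- px
        draws <- matrix(rnorm(n * nrow(m)), n, nrow(m), byrow = FALSE)
        draws <- sweep(sweep(draws, 2, m$sd, `*`), 2, m$mean, `+`)
        for (i in seq_len(nrow(m))) blk[[m$metric[i]]] <- draws[, i]
        out[[length(out) + 1L]] <- blk
      }
    }
    do.call(rbind, out)
  })
}
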
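#' @title Morphometric biomarkers
#' @name morphometrics
#' @description The twelve en-face biomarkers: five FAZ shape descriptors
#'   (area, circularity, axial ratio, roundness, solidity), the
#'   orientation-rose ellipse (direction area and ratio), arc-chord
#'   tortuosity, vessel area and length density, box-counting fractal
#'   dimension, and the bifurcation count.
NULL

#' FAZ shape metrics
#'
#' With `A` the pixel area and `P` the boundary perimeter (closed contour
#' smoothed by a circular moving average, which corrects the staircase bias
#' of raw chain length):
#' circularity `FC = 4*pi*A / P^2` (1 for a perfect circle), axial ratio
#' `FAR = major/minor` of the second-central-moment ellipse, roundness
#' `FR = 4*A / (pi * major^2)` (perimeter-free, hence robust to boundary
#' irregularity), solidity `FS = A / convex hull area`. The area is
#' reported in pixels, mm^2 and percent of the image.
#'
#' @param faz a [faz_region()].
#' @param pixel_size_mm physical pixel size.
#' @param contour_smooth_window odd window of the contour moving average.
#' @return list: `FA_px`, `FA_mm2`, `FA_pct`, `FC`, `FAR`, `FR`, `FS`,
#'   `perimeter_px`, `flags` (includes `"clipped"` when the region touches
#'   the image border).
#' @export
faz_shape_metrics <- function(faz, pixel_size_mm, contour_smooth_window = 5L) {
  mask <- faz$pixels
  A <- sum(mask)
  if (A == 0) stop("empty FAZ region")
  n_r <- nrow(mask); n_c <- ncol(mask)
  flags <- faz$flags
  if ((any(mask[1, ]) || any(mask[n_r, ]) || any(mask[, 1]) ||
       any(mask[, n_c])) && !"clipped" %in% flags) flags <- c(flags, "clipped")
  contour <- faz$boundary
  # moving-average smoothing removes the staircase bias of the chain; the
  # +pi term is the Minkowski correction for the half-pixel inset of a
  # centre-traced contour (outward offset by 0.5 px adds 2*pi*0.5).
  P <- if (nrow(contour) >= 8) {
    polygon_perimeter(smooth_closed_contour(contour, contour_smooth_window)) + pi
  } else max(nrow(contour), 1)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  dd <- sweep(idx, 2, ctr)
  cov <- crossprod(dd) / A + diag(2) / 12   # pixel-as-square correction
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  # hull over pixel centres; FS clamped at 1 (a digital convex region's
  # pixel count slightly exceeds its centre-hull area)
  hull <- idx[grDevices::chull(idx[, 2], idx[, 1]), , drop = FALSE]
  hull_area <- if (nrow(hull) >= 3) shoelace_area(hull[, c(2, 1)]) else A
  list(FA_px = A,
       FA_mm2 = A * pixel_size_mm^2,
       FA_pct = 100 * A / (n_r * n_c),
       FC = 4 * pi * A / P^2,
       FAR = major / minor,
       FR = 4 * A / (pi * major^2),
       FS = min(1, A / hull_area),
       perimeter_px = P,
       flags = flags)
}

#' Per-pixel vessel orientation field (structure tensor)
#'
#' Gradients of the (lightly smoothed) mask are combined into the structure
#' tensor, Gaussian-smoothed at `sigma_px`; the vessel direction is the
#' minor-eigenvector orientation (perpendicular to the dominant gradient),
#' mapped to `[0, pi)` measured from the column axis (0 = horizontal).
#' Coherence is the tensor anisotropy `(l1 - l2) / (l1 + l2)`.
#'
#' @param mask logical vessel mask.
#' @param image optional intensity matrix to differentiate instead of the
#'   mask.
#' @param sigma_px tensor smoothing scale (pixels).
#' @return list: `theta` (matrix, `NA` off the mask), `coherence`, `mask`.
#' @export
orientation_field <- function(mask, image = NULL, sigma_px = 2) {
  if (!any(mask)) {
    return(list(theta = matrix(NA_real_, nrow(mask), ncol(mask)),
                coherence = matrix(NA_real_, nrow(mask), ncol(mask)),
                mask = mask))
  }
  src <- if (is.null(image)) EBImage::gblur(mask * 1, sigma = 1)
         else EBImage::gblur(image, sigma = 1)
  gr <- (shift_mat(src, -1, 0, NA) - shift_mat(src, 1, 0, NA)) / 2   # d/drow
  gc <- (shift_mat(src, 0, -1, NA) - shift_mat(src, 0, 1, NA)) / 2   # d/dcol
  gr[is.na(gr)] <- 0; gc[is.na(gc)] <- 0
  Jrr <- EBImage::gblur(gr * gr, sigma = sigma_px)
  Jcc <- EBImage::gblur(gc * gc, sigma = sigma_px)
  Jrc <- EBImage::gblur(gr * gc, sigma = sigma_px)
  # gradient (major eigenvector) orientation, then rotate a quarter turn
  grad_theta <- 0.5 * atan2(2 * Jrc, Jcc - Jrr)   # vs column axis
  theta <- (grad_theta + pi / 2) %% pi
  tr <- Jrr + Jcc
  coh <- sqrt((Jcc - Jrr)^2 + 4 * Jrc^2) / (tr + 1e-12)
  theta[!mask] <- NA_real_
  coh[!mask] <- NA_real_
  list(theta = theta, coherence = coh, mask = mask)
}

#' Orientation-rose ellipse: direction area and direction ratio
#'
#' Vessel-pixel orientations are histogrammed over `[0, pi)` in `n_bins`
#' bins, mirrored to `[0, 2*pi)` to form a polar rose (radius = bin count),
#' and an ellipse is fitted to the second moments of the rose points.
#' `direction_area = pi*a*b` (rose units squared) and
#' `direction_ratio = b/a` in `(0, 1]`; an isotropic network gives a ratio
#' near 1, a dominant orientation an elongated rose and a small ratio.
#'
#' @param field an [orientation_field()] result.
#' @param n_bins orientation histogram bins over `[0, pi)`.
#' @return list: `direction_area`, `direction_ratio`, `degenerate` flag.
#' @export
direction_ellipse <- function(field, n_bins = 36L) {
  th <- field$theta[!is.na(field$theta)]
  if (!length(th)) stop("direction_ellipse requires at least one oriented pixel")
  bin <- pmin(n_bins, floor(th / pi * n_bins) + 1L)
  counts <- tabulate(bin, nbins = n_bins)
  if (sum(counts > 0) == 1L) {
    return(list(direction_area = 0, direction_ratio = 0, degenerate = TRUE))
  }
  centers <- (seq_len(n_bins) - 0.5) * pi / n_bins
  ang <- c(centers, centers + pi)
  r <- c(counts, counts)
  pts <- cbind(r * cos(ang), r * sin(ang))
  M <- crossprod(pts) / nrow(pts)
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  a <- sqrt(2 * max(ev[1], 0)); b <- sqrt(2 * max(ev[2], 0))
  if (a <= 0) {
    return(list(direction_area = 0, direction_ratio = 0, degenerate = TRUE))
  }
  list(direction_area = pi * a * b, direction_ratio = b / a,
       degenerate = FALSE)
}

#' Vessel area and length density (percent)
#'
#' `VAD = 100 * |mask and region| / |region|`;
#' `VLD = 100 * |skeleton and region| / |region|`.
#'
#' @param mask logical vessel mask.
#' @param skeleton logical centerline matrix (e.g. from [vessel_graph()]).
#' @param region_mask analysis region; `NULL` = whole image.
#' @return list with `VAD` and `VLD`.
#' @export
vessel_densities <- function(mask, skeleton, region_mask = NULL) {
  region <- region_mask %||% matrix(TRUE, nrow(mask), ncol(mask))
  n <- sum(region)
  if (n == 0) stop("empty analysis region")
  list(VAD = 100 * sum(mask & region) / n,
       VLD = 100 * sum(skeleton & region) / n)
}

#' Box-counting fractal dimension
#'
#' `N(s)` = number of cells of an `s x s` grid anchored at the image origin
#' containing at least one foreground pixel; FD is minus the slope of the
#' ordinary-least-squares fit of `log N(s)` on `log s`. Box sizes larger
#' than the image are dropped; fewer than three usable sizes is an error.
#'
#' @param x logical matrix (vessel mask or skeleton).
#' @param box_sizes grid cell sizes in pixels.
#' @param offset_average average counts over 4 half-cell grid offsets.
#' @return fractal dimension in `[0, 2]`.
#' @export
fractal_dimension <- function(x, box_sizes = c(2, 4, 8, 16, 32, 64, 128),
                              offset_average = FALSE) {
  fg <- which(x != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("fractal_dimension: empty input")
  usable <- box_sizes[box_sizes <= min(dim(x))]
  if (length(usable) < 3) stop("fewer than 3 usable box sizes")
  count_boxes <- function(s, off_r = 0, off_c = 0) {
    key <- ((fg[, 1] - 1 + off_r) %/% s) * 1e6 + ((fg[, 2] - 1 + off_c) %/% s)
    length(unique(key))
  }
  N <- vapply(usable, function(s) {
    if (offset_average) {
      h <- s %/% 2
      mean(c(count_boxes(s), count_boxes(s, h, 0),
             count_boxes(s, 0, h), count_boxes(s, h, h)))
    } else count_boxes(s)
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(usable)), log(N))
  unname(-fit$coefficients[2])
}

#' Assemble the 12-biomarker metric vector
#'
#' FAZ shape metrics are computed on the whole image (the FAZ is central by
#' definition); vessel metrics on `region_mask` (default: whole image). An
#' empty vessel mask yields zero densities and bifurcations with the
#' remaining vessel metrics `NA`.
#'
#' @param image an [en_face_image()] or intensity matrix (currently only
#'   carried for provenance; metrics derive from the masks).
#' @param mask logical vessel mask.
#' @param faz a [faz_region()].
#' @param region_mask optional analysis region for the vessel metrics.
#' @param pixel_size_mm physical pixel size (taken from `image` when it is
#'   an `enface_image`).
#' @param config metrics parameter block (see [octa_config()]).
#' @return one-row data frame with columns [METRIC_NAMES]; attribute
#'   `details` holds the FA unit variants, perimeter and flags.
#' @export
compute_metric_vector <- function(image, mask, faz, region_mask = NULL,
                                  pixel_size_mm = NULL,
                                  config = octa_config()$metrics) {
  if (inherits(image, "enface_image") && is.null(pixel_size_mm)) {
    pixel_size_mm <- image$pixel_size_mm
  }
  stopifnot(!is.null(pixel_size_mm))
  fz <- faz_shape_metrics(faz, pixel_size_mm, config$contour_smooth_window)
  FA <- switch(config$fa_unit, percent = fz$FA_pct, mm2 = fz$FA_mm2,
               px = fz$FA_px, fz$FA_pct)
  if (!any(mask)) {
    out <- data.frame(FA = FA, FC = fz$FC, FAR = fz$FAR, FR = fz$FR,
                      FS = fz$FS, direction_area = NA_real_,
                      direction_ratio = NA_real_, tortuosity = NA_real_,
                      VAD = 0, VLD = 0, FD = NA_real_, B_num = 0L)
    attr(out, "details") <- c(fz, list(missing = c("direction_area",
                                                   "direction_ratio",
                                                   "tortuosity", "FD")))
    return(out)
  }
  graph <- vessel_graph(mask, config$min_branch_px, config$merge_radius_px)
  dens <- vessel_densities(mask, graph$skeleton, region_mask)
  fd_input <- if (identical(config$fd_target, "skeleton")) graph$skeleton else mask
  if (!is.null(region_mask)) fd_input <- fd_input & region_mask
  FD <- tryCatch(fractal_dimension(fd_input, config$fd_box_sizes,
                                   config$fd_offset_average),
                 error = function(e) NA_real_)
  tort <- tryCatch(as.numeric(tortuosity(graph, config$tortuosity_weighting)),
                   error = function(e) NA_real_)
  of <- orientation_field(mask, sigma_px = config$orientation_sigma_px)
  de <- direction_ellipse(of, config$direction_bins)
  out <- data.frame(FA = FA, FC = fz$FC, FAR = fz$FAR, FR = fz$FR, FS = fz$FS,
                    direction_area = de$direction_area,
                    direction_ratio = de$direction_ratio,
                    tortuosity = tort, VAD = dens$VAD, VLD = dens$VLD,
                    FD = FD, B_num = graph$B_num)
  attr(out, "details") <- c(fz, list(direction_degenerate = de$degenerate))
  out
}
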
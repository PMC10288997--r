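#' @title Vessel and FAZ segmentation
#' @name segmentation
#' @description Local-phase vessel enhancement through log-Gabor quadrature
#'   filters, a two-region active-contour segmentation driven jointly by the
#'   intensity and enhancement channels, and morphological FAZ extraction
#'   from the vessel mask.
NULL

#' Segmentation parameters
#'
#' @param scales_px log-Gabor filter wavelengths in pixels.
#' @param n_orientations number of filter orientations over `[0, pi)`.
#' @param sigma_on_f bandwidth ratio of the radial log-Gabor lobe.
#' @param lambda_intensity,lambda_phase region-term weights of the intensity
#'   and enhancement channels.
#' @param mu_regularizer boundary-length regularization weight.
#' @param n_iterations maximum contour-evolution iterations.
#' @param convergence_tol stop when the changed-pixel fraction per iteration
#'   falls below this.
#' @param faz_close_radius_px radius of the morphological closing that seals
#'   capillary gaps before FAZ extraction.
#' @export
segmentation_params <- function(scales_px = c(2, 3, 4, 6), n_orientations = 6L,
                                sigma_on_f = 0.55, lambda_intensity = 1.0,
                                lambda_phase = 1.0, mu_regularizer = 0.1,
                                n_iterations = 300L, convergence_tol = 1e-4,
                                faz_close_radius_px = 6L) {
  stopifnot(all(scales_px > 0), lambda_intensity >= 0, lambda_phase >= 0,
            mu_regularizer >= 0, n_iterations >= 1, convergence_tol >= 0)
  structure(list(scales_px = scales_px,
                 n_orientations = as.integer(n_orientations),
                 sigma_on_f = sigma_on_f,
                 lambda_intensity = lambda_intensity,
                 lambda_phase = lambda_phase,
                 mu_regularizer = mu_regularizer,
                 n_iterations = as.integer(n_iterations),
                 convergence_tol = convergence_tol,
                 faz_close_radius_px = as.integer(faz_close_radius_px)),
            class = "segmentation_params")
}

# Single-sided log-Gabor frequency-domain filter bank. Returns a list of
# complex frequency masks; multiplying the image spectrum by one and inverse
# transforming yields the analytic (even + i*odd) response.
log_gabor_bank <- function(size, scales_px, n_orient, sigma_on_f) {
  fx <- (seq_len(size) - 1) / size
  fx[fx > 0.5] <- fx[fx > 0.5] - 1
  u <- matrix(fx, size, size, byrow = TRUE)   # along columns (x)
  v <- matrix(fx, size, size)                 # along rows (y)
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rho[1, 1] <- 1            # avoid log(0); DC forced to zero below
  bank <- list()
  sig_theta <- pi / n_orient * 0.65
  for (s in scales_px) {
    f0 <- 1 / s
    radial <- exp(-(log(rho / f0))^2 / (2 * log(sigma_on_f)^2))
    radial[1, 1] <- 0
    for (o in seq_len(n_orient)) {
      phi <- (o - 1) * pi / n_orient
      # single-sided: keep only frequencies within pi/2 of the orientation
      d <- atan2(sin(theta - phi), cos(theta - phi))
      ang <- exp(-d^2 / (2 * sig_theta^2))
      ang[abs(d) > pi / 2] <- 0
      bank[[length(bank) + 1L]] <- list(scale = s, filt = radial * ang * 2)
    }
  }
  bank
}

#' Local-phase vessel enhancement map
#'
#' Quadrature (even/odd) log-Gabor filtering over orientations and scales;
#' the per-pixel response is the even-symmetric phase dominance
#' `max(0, even - |odd|) / (amplitude + eps)`, maximum-combined over the
#' bank. Because the measure is an amplitude-normalised phase quantity, the
#' map is invariant to global intensity scaling (to well under 1% RMS).
#'
#' @param image an [en_face_image()] or numeric matrix.
#' @param scales_px filter wavelengths (pixels); each must be at most a
#'   quarter of the image width.
#' @param n_orientations,sigma_on_f see [segmentation_params()].
#' @param noise_k noise-compensation factor: per filter, `noise_k` times the
#'   median response amplitude is subtracted from the even-dominance
#'   numerator, suppressing speckle-driven responses. Scales with the
#'   amplitude, so contrast invariance is preserved.
#' @return An `enhancement_map`: list with `pixels` in `[0,1]` and
#'   `scales_px`.
#' @export
local_phase_enhancement <- function(image, scales_px = c(2, 3, 4, 6),
                                    n_orientations = 6L, sigma_on_f = 0.55,
                                    noise_k = 2) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  size <- nrow(px)
  if (any(scales_px > size / 4)) {
    stop("filter scale exceeds image width / 4 (", size / 4, " px)")
  }
  if (diff(range(px)) == 0) {           # structureless image
    return(structure(list(pixels = matrix(0, size, ncol(px)),
                          scales_px = scales_px),
                     class = "enhancement_map"))
  }
  bank <- log_gabor_bank(size, scales_px, n_orientations, sigma_on_f)
  spec <- stats::fft(px)
  out <- matrix(0, size, size)
  for (b in bank) {
    resp <- stats::fft(spec * b$filt, inverse = TRUE) / length(px)
    even <- Re(resp); odd <- Im(resp)
    amp <- sqrt(even^2 + odd^2)
    eps <- 0.01 * mean(amp) + 1e-12
    fs <- pmax(0, even - abs(odd) - noise_k * stats::median(amp)) / (amp + eps)
    out <- pmax(out, fs)
  }
  structure(list(pixels = clamp01(out), scales_px = scales_px),
            class = "enhancement_map")
}

# One 3x3 binomial smoothing pass (approximate heat flow on the level-set).
smooth3 <- function(m) {
  k <- c(0.25, 0.5, 0.25)
  h <- k[1] * shift_mat(m, 0, -1, fill = NA) + k[2] * m +
       k[3] * shift_mat(m, 0, 1, fill = NA)
  h[is.na(h)] <- m[is.na(h)]
  v <- k[1] * shift_mat(h, -1, 0, fill = NA) + k[2] * h +
       k[3] * shift_mat(h, 1, 0, fill = NA)
  v[is.na(v)] <- h[is.na(v)]
  v
}

#' Segment the retinal microvasculature
#'
#' Two-region active-contour (level-set) evolution minimising a weighted sum
#' of inside/outside mean-deviation region terms on both the intensity and
#' the local-phase enhancement channel, with a boundary-length penalty of
#' weight `mu_regularizer` realised as level-set diffusion. Initialised from
#' the Otsu threshold of the enhancement map (deterministic, seed-free).
#'
#' @param image an [en_face_image()].
#' @param enh an enhancement map from [local_phase_enhancement()]; computed
#'   on the fly if `NULL`.
#' @param params a [segmentation_params()] object.
#' @return logical vessel mask with attributes `converged` (logical) and
#'   `iterations`. Non-convergence returns the current mask with
#'   `converged = FALSE`, never an error.
#' @export
segment_vessels <- function(image, enh = NULL, params = segmentation_params()) {
  I <- if (inherits(image, "enface_image")) image$pixels else image
  if (is.null(enh)) {
    enh <- local_phase_enhancement(I, params$scales_px, params$n_orientations,
                                   params$sigma_on_f)
  }
  E <- enh$pixels
  stopifnot(all(dim(I) == dim(E)))
  if (max(E) <= 0) {      # structureless image: nothing to segment
    out <- matrix(FALSE, nrow(I), ncol(I))
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    return(out)
  }
  th <- EBImage::otsu(EBImage::Image(E), range = c(0, 1))
  mask <- E > th
  phi <- ifelse(mask, 1, -1)
  phi <- smooth3(phi)
  # length-penalty diffusion: total smoothing variance ~ 2*mu per iteration
  n_pass <- ceiling(2 * params$mu_regularizer / 0.5)
  alpha <- (2 * params$mu_regularizer / 0.5) / max(n_pass, 1)
  npix <- length(I)
  converged <- FALSE
  iterations <- params$n_iterations
  prev <- phi > 0
  for (it in seq_len(params$n_iterations)) {
    inside <- phi > 0
    n_in <- sum(inside)
    if (n_in == 0 || n_in == npix) break
    cI <- c(mean(I[inside]), mean(I[!inside]))
    cE <- c(mean(E[inside]), mean(E[!inside]))
    F <- params$lambda_intensity * ((I - cI[2])^2 - (I - cI[1])^2) +
         params$lambda_phase * ((E - cE[2])^2 - (E - cE[1])^2)
    phi <- phi + F / (max(abs(F)) + 1e-12)
    for (k in seq_len(n_pass)) {
      sm <- smooth3(phi)
      phi <- (1 - alpha) * phi + alpha * sm
    }
    phi[phi > 3] <- 3
    phi[phi < -3] <- -3
    cur <- phi > 0
    if (mean(cur != prev) < params$convergence_tol) {
      converged <- TRUE; iterations <- it; break
    }
    prev <- cur
  }
  out <- phi > 0
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  out
}

#' Extract the foveal avascular zone from a vessel mask
#'
#' Morphological closing of the vessel mask (radius `faz_close_radius_px`)
#' seals inter-capillary gaps; the avascular connected component containing
#' the image centre (or the nearest one within a 15-pixel search radius) is
#' returned with holes filled and its boundary contour extracted.
#'
#' @param vessels logical vessel mask.
#' @param params a [segmentation_params()] object.
#' @param center_px centre to anchor the search; defaults to image centre.
#' @return A [faz_region()]; a vessel-free mask yields the whole image
#'   flagged `"degenerate"`.
#' @export
segment_faz <- function(vessels, params = segmentation_params(),
                        center_px = NULL) {
  size_r <- nrow(vessels); size_c <- ncol(vessels)
  ctr <- round(center_px %||% c((size_r + 1) / 2, (size_c + 1) / 2))
  if (!any(vessels)) {
    return(faz_region(matrix(TRUE, size_r, size_c), flags = "degenerate"))
  }
  closed <- EBImage::closing(vessels * 1,
                             disc_brush(params$faz_close_radius_px)) > 0
  avasc <- !closed
  labs <- EBImage::bwlabel(avasc * 1)
  lab_ctr <- labs[ctr[1], ctr[2]]
  if (lab_ctr == 0) {
    rr <- matrix(seq_len(size_r), size_r, size_c) - ctr[1]
    cc <- matrix(seq_len(size_c), size_r, size_c, byrow = TRUE) - ctr[2]
    d2 <- rr^2 + cc^2
    cand <- which(labs > 0 & d2 <= 15^2)
    if (!length(cand)) {
      stop("no avascular region found within 15 px of the image centre")
    }
    lab_ctr <- labs[cand[which.min(d2[cand])]]
  }
  comp <- labs == lab_ctr
  comp <- EBImage::fillHull(comp * 1) > 0
  flags <- character()
  if (any(comp[1, ]) || any(comp[size_r, ]) ||
      any(comp[, 1]) || any(comp[, size_c])) flags <- c(flags, "clipped")
  faz_region(comp, flags = flags)
}

#' Overlap fraction between a FAZ region and a vessel mask
#'
#' Quality check: the FAZ is by definition avascular, so its overlap with
#' the vessel foreground should stay below a small tolerance (default 5% of
#' the FAZ area).
#'
#' @param faz a [faz_region()].
#' @param vessels logical vessel mask.
#' @return overlap as a fraction of the FAZ area.
#' @export
faz_vessel_overlap <- function(faz, vessels) {
  a <- sum(faz$pixels)
  if (a == 0) return(0)
  sum(faz$pixels & vessels) / a
}
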
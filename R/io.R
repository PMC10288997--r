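#' @title Image, mask and table input/output
#' @name io
#' @description Readers and writers for en-face angiograms, binary masks and
#'   tidy metric tables, plus the shared acquisition-geometry constants and
#'   the run configuration document.
NULL

#' Geometry and naming constants
#'
#' The acquisition geometry of macular en-face OCTA used throughout: a
#' 3 x 3 mm field of view centred on the fovea sampled at 304 x 304 pixels,
#' exported per retinal plexus (superficial, deep and intermediate vascular
#' complexes).
#' @export
OCTA_IMAGE_SIZE <- 304L

#' @rdname OCTA_IMAGE_SIZE
#' @export
OCTA_FOV_MM <- 3.0

#' @rdname OCTA_IMAGE_SIZE
#' @export
PLEXUS_LEVELS <- c("SVC", "DVC", "IVC")

#' @rdname OCTA_IMAGE_SIZE
#' @export
LATERALITY_LEVELS <- c("OD", "OS")

#' @rdname OCTA_IMAGE_SIZE
#' @export
GROUP_LEVELS <- c("HC", "ON", "NON_ON")

#' @rdname OCTA_IMAGE_SIZE
#' @export
METRIC_NAMES <- c("FA", "FC", "FAR", "FR", "FS",
                  "direction_area", "direction_ratio", "tortuosity",
                  "VAD", "VLD", "FD", "B_num")

#' Construct an en-face angiogram object
#'
#' Wraps a square intensity matrix with its physical scale and laterality.
#' Intensities are min-max normalised to `[0, 1]`; a constant image
#' normalises to all zeros. Pixels are addressed `(row, col)`, 0-based in
#' physical conversions never occur: all geometry goes through
#' `pixel_size_mm = fov_mm / width`.
#'
#' @param pixels numeric matrix (rows = vertical, row 1 = superior edge).
#' @param plexus one of `"SVC"`, `"DVC"`, `"IVC"`.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param fov_mm physical width of the field of view in millimetres.
#' @param normalize min-max normalise intensities (default `TRUE`).
#' @return An object of class `enface_image` with fields `pixels`, `plexus`,
#'   `laterality`, `fov_mm`, `pixel_size_mm`.
#' @export
en_face_image <- function(pixels, plexus = "SVC", laterality = "OD",
                          fov_mm = OCTA_FOV_MM, normalize = TRUE) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) {
    stop(sprintf("en-face image must be square; got %d x %d",
                 nrow(pixels), ncol(pixels)))
  }
  plexus <- match.arg(plexus, PLEXUS_LEVELS)
  laterality <- match.arg(laterality, LATERALITY_LEVELS)
  stopifnot(fov_mm > 0)
  if (normalize) {
    rng <- range(pixels)
    pixels <- if (rng[2] > rng[1]) (pixels - rng[1]) / (rng[2] - rng[1])
              else matrix(0, nrow(pixels), ncol(pixels))
  }
  structure(list(pixels = pixels, plexus = plexus, laterality = laterality,
                 fov_mm = fov_mm, pixel_size_mm = fov_mm / ncol(pixels)),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, plexus %s, eye %s, %.3g mm FOV (%.5f mm/px)\n",
              nrow(x$pixels), ncol(x$pixels), x$plexus, x$laterality,
              x$fov_mm, x$pixel_size_mm))
  invisible(x)
}

#' Read an en-face angiogram from PNG or TIFF
#'
#' Accepts 8/16-bit grayscale images; colour or non-square images are
#' rejected. Non-304 widths are accepted and the pixel scale recomputed as
#' `fov_mm / width`.
#'
#' @inheritParams en_face_image
#' @param path a grayscale PNG or TIFF file.
#' @return An [en_face_image()] object.
#' @export
read_enface <- function(path, plexus = "SVC", laterality = "OD",
                        fov_mm = OCTA_FOV_MM) {
  px <- read_gray_image(path)
  en_face_image(px, plexus = plexus, laterality = laterality, fov_mm = fov_mm)
}

# Shared grayscale reader (matrix, rows = image rows).
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3 &&
        !(all(arr[, , 1] == arr[, , 2]) && all(arr[, , 2] == arr[, , 3]))) {
      stop("colour image rejected: expected single-channel grayscale")
    }
    arr <- arr[, , 1]
  }
  arr
}

#' Write / read a binary mask as PNG (0/255)
#'
#' @param mask logical or 0/1 matrix.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @return `read_mask` returns a logical matrix.
#' @export
read_mask <- function(path) {
  read_gray_image(path) > 0.5
}

#' Construct a per-eye record
#'
#' One study eye: identity, group label, demographic covariates and a nested
#' `metrics` map `plexus -> region -> named metric vector`.
#'
#' @param subject_id subject identifier.
#' @param eye `"OD"` or `"OS"`.
#' @param group `"HC"`, `"ON"` or `"NON_ON"` (the latter two are
#'   NMOSD eyes with/without an optic-neuritis history).
#' @param age,bmi,bcva demographic covariates (years, kg/m2, decimal acuity).
#' @param metrics nested list `plexus -> region -> named numeric vector`.
#' @export
eye_record <- function(subject_id, eye, group, age = NA_real_, bmi = NA_real_,
                       bcva = NA_real_, metrics = list()) {
  eye <- match.arg(eye, LATERALITY_LEVELS)
  group <- match.arg(group, GROUP_LEVELS)
  structure(list(subject_id = as.character(subject_id), eye = eye,
                 group = group, age = age, bmi = bmi, bcva = bcva,
                 metrics = metrics),
            class = "eye_record")
}

#' Write eye records to a tidy CSV, one row per (eye, plexus, region)
#'
#' Columns: subject, eye, group, age, bmi, bcva, plexus, region, then one
#' column per metric. All records must carry identical metric name sets;
#' round-tripping through [read_metrics_table()] preserves values to 1e-9.
#'
#' @param records list of [eye_record()] objects.
#' @param path output CSV path.
#' @export
write_metrics_table <- function(records, path) {
  rows <- list()
  metric_names <- NULL
  for (rec in records) {
    for (plexus in names(rec$metrics)) {
      for (region in names(rec$metrics[[plexus]])) {
        mv <- rec$metrics[[plexus]][[region]]
        if (is.null(metric_names)) metric_names <- names(mv)
        if (!identical(sort(names(mv)), sort(metric_names))) {
          stop("inconsistent metric set for subject ", rec$subject_id,
               " (", plexus, "/", region, "): expected {",
               paste(metric_names, collapse = ", "), "}")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = rec$subject_id, eye = rec$eye, group = rec$group,
          age = rec$age, bmi = rec$bmi, bcva = rec$bcva,
          plexus = plexus, region = region,
          as.list(mv[metric_names]), check.names = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(), eye = character(), group = character(),
               age = numeric(), bmi = numeric(), bcva = numeric(),
               plexus = character(), region = character())
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one named-blocks document
#' (segmentation, metrics, etdrs, stats, simulate), serialisable to JSON via
#' [write_config()].
#'
#' @return nested list of parameter blocks.
#' @export
octa_config <- function() {
  list(
    segmentation = list(
      scales_px = c(2, 3, 4, 6), n_orientations = 6L, sigma_on_f = 0.55,
      lambda_intensity = 1.0, lambda_phase = 1.0, mu_regularizer = 0.1,
      n_iterations = 300L, convergence_tol = 1e-4, faz_close_radius_px = 6L,
      faz_center_search_radius_px = 15L, faz_overlap_tolerance = 0.05),
    metrics = list(
      fa_unit = "percent", contour_smooth_window = 5L,
      orientation_sigma_px = 2, direction_bins = 36L,
      fd_box_sizes = c(2, 4, 8, 16, 32, 64, 128), fd_target = "mask",
      fd_offset_average = FALSE,
      tortuosity_weighting = "length",
      min_branch_px = 5L, merge_radius_px = 2L),
    etdrs = list(ring_diameters_mm = c(0.75, 1.5, 2.25),
                 center = "faz_centroid"),
    stats = list(t_variant = "welch", standardized = TRUE,
                 covariates = c("age"), p_thresholds = c(0.001, 0.05),
                 adjust = "none", demographic_n = "eye"),
    simulate = list(n_roots = 8L, branch_prob = 0.08, step_px = 3,
                    angle_sigma_deg = 10, bifurcation_angle_deg = 35,
                    vessel_width_px = 2L, min_junction_sep_px = 8,
                    speckle_sigma = 0.15, background_ramp = 0.1,
                    faz = list(area_mm2 = 0.35, axial_ratio = 1.2,
                               boundary_noise = 0.08, n_vertices = 256L))
  )
}

#' Write / read a configuration document as JSON
#' @param config nested parameter list, e.g. from [octa_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
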
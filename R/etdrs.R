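#' @title ETDRS macular grid
#' @name etdrs
#' @description The standard macular partition: a central disk of diameter
#'   0.75 mm, an internal annulus out to 1.5 mm and an external annulus out
#'   to 2.25 mm, each annulus split by the two 45-degree diagonals into
#'   superior / temporal / inferior / nasal sectors (temporal is to the left
#'   for a right eye, OD, and to the right for a left eye, OS).
NULL

ETDRS_SECTORS <- c("SI", "TI", "II", "NI", "SE", "TE", "IE", "NE")

#' Build an ETDRS grid of sector masks
#'
#' @param center_px grid centre (row, col); typically the FAZ centroid.
#' @param pixel_size_mm physical pixel size.
#' @param laterality `"OD"` or `"OS"` (decides the temporal/nasal side).
#' @param size image width in pixels.
#' @param ring_diameters_mm diameters of the central disk and the two rings.
#' @return An `etdrs_grid`: `center_px`, `laterality`, `ring_diameters_mm`,
#'   and `sector_masks` (named list `C`, `SI`, `TI`, `II`, `NI`, `SE`,
#'   `TE`, `IE`, `NE` of pairwise-disjoint logical masks; the union of the
#'   four internal sectors is the internal annulus and likewise for the
#'   external ring).
#' @export
build_grid <- function(center_px, pixel_size_mm, laterality = "OD",
                       size = OCTA_IMAGE_SIZE,
                       ring_diameters_mm = c(0.75, 1.5, 2.25)) {
  laterality <- match.arg(laterality, LATERALITY_LEVELS)
  radii_px <- ring_diameters_mm / 2 / pixel_size_mm
  over <- max(radii_px[3] - (center_px[1] - 1), radii_px[3] - (size - center_px[1]),
              radii_px[3] - (center_px[2] - 1), radii_px[3] - (size - center_px[2]))
  if (over > 0) {
    stop(sprintf("ETDRS grid exceeds image bounds by %.3f mm",
                 over * pixel_size_mm))
  }
  rows <- matrix(seq_len(size), size, size) - center_px[1]
  cols <- matrix(seq_len(size), size, size, byrow = TRUE) - center_px[2]
  rad <- sqrt(rows^2 + cols^2)
  ang <- (atan2(-rows, cols) * 180 / pi) %% 360    # 0 = right, 90 = up
  quad <- list(S = ang > 45 & ang <= 135,
               L = ang > 135 & ang <= 225,
               I = ang > 225 & ang <= 315,
               R = ang > 315 | ang <= 45)
  temporal <- if (laterality == "OD") quad$L else quad$R
  nasal <- if (laterality == "OD") quad$R else quad$L
  internal <- rad > radii_px[1] & rad <= radii_px[2]
  external <- rad > radii_px[2] & rad <= radii_px[3]
  masks <- list(C = rad <= radii_px[1],
                SI = internal & quad$S, TI = internal & temporal,
                II = internal & quad$I, NI = internal & nasal,
                SE = external & quad$S, TE = external & temporal,
                IE = external & quad$I, NE = external & nasal)
  structure(list(center_px = center_px, pixel_size_mm = pixel_size_mm,
                 laterality = laterality,
                 ring_diameters_mm = ring_diameters_mm,
                 sector_masks = masks),
            class = "etdrs_grid")
}

#' Sub-regional metrics per ETDRS sector
#'
#' For each of the eight annular sectors: VAD and VLD on the sector mask,
#' B-num as the count of bifurcation nodes whose coordinates fall in the
#' sector, tortuosity as the arc-weighted mean over branches whose midpoint
#' falls in the sector, and FD box-counted on the sector-cropped foreground
#' (out-of-sector pixels cleared). Sectors without skeleton pixels get
#' `VLD = 0` and missing tortuosity/FD.
#'
#' @param mask logical vessel mask aligned with the grid.
#' @param graph a `skeleton_graph` from [vessel_graph()]; computed from
#'   `mask` when `NULL`.
#' @param grid an [build_grid()] result.
#' @param config metrics parameter block (see [octa_config()]).
#' @return data frame, one row per sector, columns `sector`, `VAD`, `VLD`,
#'   `FD`, `tortuosity`, `B_num`.
#' @export
sector_metrics <- function(mask, graph = NULL, grid,
                           config = octa_config()$metrics) {
  if (is.null(graph)) {
    graph <- vessel_graph(mask, config$min_branch_px, config$merge_radius_px)
  }
  skel <- graph$skeleton
  bif <- graph$nodes[graph$nodes$kind == "bifurcation", , drop = FALSE]
  mids <- do.call(rbind, lapply(graph$branches, function(b)
    b$pts[ceiling(nrow(b$pts) / 2), ]))
  arcs <- vapply(graph$branches, `[[`, 1, "arc_px")
  chords <- vapply(graph$branches, `[[`, 1, "chord_px")
  rows <- lapply(ETDRS_SECTORS, function(sn) {
    sm <- grid$sector_masks[[sn]]
    dens <- vessel_densities(mask, skel, sm)
    b_in <- if (nrow(bif)) sum(sm[cbind(pmax(1, pmin(nrow(sm), round(bif$row))),
                                        pmax(1, pmin(ncol(sm), round(bif$col))))])
            else 0L
    tort <- NA_real_
    if (!is.null(mids) && nrow(mids)) {
      inb <- sm[mids] & chords > 0
      if (any(inb)) tort <- sum(arcs[inb] * (arcs[inb] / chords[inb])) /
                            sum(arcs[inb])
    }
    fd <- NA_real_
    if (dens$VLD > 0) {
      sub <- mask & sm
      bb <- which(sub, arr.ind = TRUE)
      crop <- sub[min(bb[, 1]):max(bb[, 1]), min(bb[, 2]):max(bb[, 2]),
                  drop = FALSE]
      fd <- tryCatch(fractal_dimension(crop, config$fd_box_sizes,
                                       config$fd_offset_average),
                     error = function(e) NA_real_)
    }
    data.frame(sector = sn, VAD = dens$VAD, VLD = dens$VLD, FD = fd,
               tortuosity = tort, B_num = b_in, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render the grid as a label matrix (0 background, 1..9 = C + sectors)
#'
#' Convenience for overlays and inspection.
#' @param grid an `etdrs_grid`.
#' @export
grid_label_matrix <- function(grid) {
  out <- matrix(0L, nrow(grid$sector_masks$C), ncol(grid$sector_masks$C))
  for (i in seq_along(grid$sector_masks)) out[grid$sector_masks[[i]]] <- i
  out
}
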
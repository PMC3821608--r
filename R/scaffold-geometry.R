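## Voxelized strut-scaffold geometry: alternating 90-degree-rotated layers.

#' Parametric description of a layered strut scaffold
#'
#' The model scaffold is a stack of `total_thickness / layer_height` layers;
#' each layer carries parallel rectangular struts (width `strut_width`,
#' height `layer_height`) at centre-to-centre spacing `pitch`, and
#' consecutive layers are rotated 90 degrees.  In the `"lattice"`
#' arrangement struts of the same orientation are vertically aligned; in the
#' `"staggered"` arrangement every second layer of the same orientation is
#' offset laterally by half a pitch (the zigzag pattern).  The modelled
#' domain is one lateral period (`pitch` x `pitch`), intended for
#' mirror-symmetric lateral boundaries: struts are placed centred in the
#' period so that reflection at the domain edges continues the infinite
#' pattern at the stated pitch.
#'
#' `alpha` is the strut volume fraction (strut volume / total volume); for
#' this geometry it equals `strut_width / pitch`, so `strut_width` is
#' derived as `alpha * pitch` when not given.
#'
#' @param total_thickness scaffold thickness, micrometers (default 1000).
#' @param layer_height strut/layer height, micrometers (default 50); must
#'   divide `total_thickness`.
#' @param pitch centre-to-centre strut spacing within a layer, micrometers.
#'   Not fixed by the physical line patterns; the default 600 makes the
#'   strut width at alpha = 0.5 (300 um) match the measured printed-line
#'   width.
#' @param alpha target strut volume fraction in `[0, 1]`.
#' @param strut_width strut width, micrometers; derived from `alpha` when
#'   missing.
#' @param arrangement `"lattice"` or `"staggered"`.
#' @param voxel_size voxel edge, micrometers; must divide `layer_height` and
#'   `pitch`.
#' @return object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(total_thickness = 1000, layer_height = 50,
                          pitch = 600, alpha = 0.5,
                          strut_width = alpha * pitch,
                          arrangement = c("lattice", "staggered"),
                          voxel_size = 10) {
  arrangement <- match.arg(arrangement)
  chk_div <- function(num, den, num_name, den_name) {
    if (abs(num / den - round(num / den)) > 1e-9)
      ps_stop("permstrut_resolution_mismatch",
              sprintf("%s (%g) must divide %s (%g)", den_name, den,
                      num_name, num))
  }
  if (alpha < 0 || alpha > 1)
    ps_stop("permstrut_domain_error", "alpha must lie in [0, 1]")
  if (total_thickness <= 0 || layer_height <= 0 || pitch <= 0 ||
      voxel_size <= 0 || strut_width < 0 || strut_width > pitch)
    ps_stop("permstrut_domain_error", "geometry dimensions out of range")
  chk_div(total_thickness, layer_height, "total_thickness", "layer_height")
  chk_div(layer_height, voxel_size, "layer_height", "voxel_size")
  chk_div(pitch, voxel_size, "pitch", "voxel_size")
  structure(list(total_thickness = total_thickness,
                 layer_height = layer_height, pitch = pitch,
                 strut_width = strut_width, alpha = strut_width / pitch,
                 arrangement = arrangement, voxel_size = voxel_size),
            class = "scaffold_spec")
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf("<scaffold_spec> %s, %g um thick (%g um layers), pitch %g um,\n",
              x$arrangement, x$total_thickness, x$layer_height, x$pitch))
  cat(sprintf("  strut width %g um (alpha = %.3f), voxel %g um\n",
              x$strut_width, x$alpha, x$voxel_size))
  invisible(x)
}

#' Voxelize a scaffold specification
#'
#' Labels each voxel of one lateral period as strut or culture.  Odd layers
#' (counted from the top, z = 0 at the media-exposed surface, z increasing
#' downward) carry struts parallel to x (so the strut band runs across y);
#' even layers carry struts parallel to y.  Voxel membership uses the voxel
#' centre against the half-open strut band, so the achieved volume fraction
#' is exact whenever `strut_width` is a whole number of voxels.
#'
#' @param spec a [scaffold_spec()].
#' @return object of class `voxel_grid`: list with `labels` (3D integer
#'   array over (x, y, z); 1 = strut, 0 = culture), `voxel_size`, and the
#'   originating `spec`.
#' @export
build_scaffold <- function(spec) {
  if (!inherits(spec, "scaffold_spec"))
    ps_stop("permstrut_domain_error", "spec must be a scaffold_spec")
  vs <- spec$voxel_size
  n_xy <- round(spec$pitch / vs)
  n_z <- round(spec$total_thickness / vs)
  vox_per_layer <- round(spec$layer_height / vs)
  centers <- (seq_len(n_xy) - 0.5) * vs
  # strut band centred in the period, optional half-pitch shift (wrapping)
  in_band <- function(offset) {
    if (spec$strut_width <= 0) return(rep(FALSE, n_xy))
    start <- (spec$pitch - spec$strut_width) / 2 + offset
    ((centers - start) %% spec$pitch) < spec$strut_width
  }
  labels <- array(0L, dim = c(n_xy, n_xy, n_z))
  for (l in seq_len(round(spec$total_thickness / spec$layer_height))) {
    zs <- ((l - 1L) * vox_per_layer + 1L):(l * vox_per_layer)
    along_x <- (l %% 2L) == 1L        # struts run along x, banded in y
    ordinal <- ceiling(l / 2)         # index among layers of this orientation
    offset <- if (spec$arrangement == "staggered" && ordinal %% 2L == 0L)
      spec$pitch / 2 else 0
    band <- in_band(offset)
    if (any(band)) {
      if (along_x) labels[, band, zs] <- 1L else labels[band, , zs] <- 1L
    }
  }
  structure(list(labels = labels, voxel_size = vs, spec = spec),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels of %g um (achieved alpha = %.4f)\n",
              d[1L], d[2L], d[3L], x$voxel_size, achieved_volume_fraction(x)))
  invisible(x)
}

#' Achieved strut volume fraction of a voxel grid
#'
#' Simply the strut-voxel count over the total voxel count.
#'
#' @param grid a [build_scaffold()] result.
#' @return dimensionless fraction in `[0, 1]`.
#' @export
achieved_volume_fraction <- function(grid) {
  mean(grid$labels == 1L)
}

#' Is the culture domain one connected component reaching the bottom?
#'
#' Flood fill (6-neighbour) from the culture voxels of the top slab; the
#' culture space must form a single connected component with a path from the
#' media-exposed surface to the scaffold bottom for nutrients (and cells) to
#' reach depth.
#'
#' @param grid a [build_scaffold()] result.
#' @return `TRUE` when every culture voxel is reachable from the top surface
#'   and the flood reaches the bottom slab.
#' @export
culture_connected <- function(grid) {
  lab <- grid$labels
  d <- dim(lab)
  open <- lab == 0L
  if (!any(open)) return(FALSE)
  visited <- array(FALSE, dim = d)
  frontier <- which(open & slice.index(lab, 3L) == 1L)
  if (length(frontier) == 0L) return(FALSE)
  visited[frontier] <- TRUE
  nxy <- d[1L] * d[2L]
  repeat {
    nb <- c(frontier - 1L, frontier + 1L,
            frontier - d[1L], frontier + d[1L],
            frontier - nxy, frontier + nxy)
    # reject x/y wrap-around between columns
    i0 <- ((frontier - 1L) %% d[1L])
    j0 <- ((frontier - 1L) %/% d[1L]) %% d[2L]
    ok <- c(i0 > 0L, i0 < d[1L] - 1L, j0 > 0L, j0 < d[2L] - 1L,
            rep(TRUE, 2L * length(frontier)))
    nb <- nb[ok & nb >= 1L & nb <= length(lab)]
    nb <- unique(nb[open[nb] & !visited[nb]])
    if (length(nb) == 0L) break
    visited[nb] <- TRUE
    frontier <- nb
  }
  all(visited[open]) && any(visited[, , d[3L]])
}

#' Export a voxel field as legacy-ASCII VTK structured points
#'
#' Writes the strut/culture labels (or any same-shaped numeric field) for
#' visualization in ParaView and friends.
#'
#' @param grid a [build_scaffold()] result.
#' @param path output file.
#' @param field optional numeric array with `dim(grid$labels)`; defaults to
#'   the labels themselves.
#' @param name scalar field name in the VTK header.
#' @return the path, invisibly.
#' @export
export_vtk <- function(grid, path, field = NULL, name = "labels") {
  d <- dim(grid$labels)
  if (is.null(field)) field <- grid$labels
  if (!identical(dim(field), d))
    ps_stop("permstrut_domain_error", "field shape must match the grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "permstrut voxel grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1L], d[2L], d[3L]),
               sprintf("ORIGIN 0 0 0"),
               sprintf("SPACING %g %g %g", grid$voxel_size,
                       grid$voxel_size, grid$voxel_size),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(field), trim = TRUE), con)
  invisible(path)
}
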
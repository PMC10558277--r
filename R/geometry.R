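#' Build a structured cell-centered box mesh
#'
#' Creates an axis-aligned uniform grid in 1, 2 or 3 dimensions for the
#' finite-volume discretization. All boundary faces are initially tagged
#' `"FAR"` (far boundary); use [tag_vessel()] to mark the tissue-vessel
#' interface. Faces carry an owner cell, a neighbor cell (or boundary tag),
#' an area, a center-to-center (or center-to-face, for boundary) distance,
#' and an outward orientation sign along their axis.
#'
#' @param extents physical extents per axis (m), length 1-3.
#' @param cells cell counts per axis, same length as `extents`.
#' @return a `thermo_mesh` list: `dim`, `cells`, `extents`, `h` (cell sizes),
#'   `ncell`, `centers` (ncell x dim matrix of cell centers), `volume`
#'   (per-cell volume, uniform), and `faces` (a data frame with columns
#'   `axis`, `owner`, `neighbor` (NA on the boundary), `area`, `dist`,
#'   `nsign` (+1 along +axis, -1 along -axis, outward from owner), `tag`
#'   (NA interior, `"FAR"`/`"VESSEL"` on the boundary), and face centroids
#'   `c1..c<dim>`).
#' @examples
#' m <- make_box_mesh(0.01, 10)          # 1D, 1 mm cells
#' m2 <- make_box_mesh(c(0.02, 0.02), c(4, 4))
#' @export
make_box_mesh <- function(extents, cells) {
  dim <- length(extents)
  if (dim < 1 || dim > 3 || length(cells) != dim) {
    abort("extents and cells must have matching length 1, 2 or 3",
          class = "thermo_input_error")
  }
  if (any(extents <= 0)) {
    abort("extents must be positive", class = "thermo_input_error")
  }
  if (any(cells <= 0) || any(cells != round(cells))) {
    abort("cell counts must be positive integers", class = "thermo_input_error")
  }
  cells <- as.integer(cells)
  h <- extents / cells
  ncell <- prod(cells)
  strides <- cumprod(c(1L, cells))[seq_len(dim)]
  idx <- arrayInd(seq_len(ncell), .dim = cells)
  centers <- sweep(idx - 0.5, 2, h, `*`)
  vol <- prod(h)

  face_block <- function(own, nb, d, shift, dist, nsign, tag) {
    fc <- centers[own, , drop = FALSE]
    fc[, d] <- fc[, d] + shift
    df <- data.frame(axis = d, owner = own, neighbor = nb,
                     area = vol / h[d], dist = dist, nsign = nsign,
                     tag = tag, stringsAsFactors = FALSE)
    colnames(fc) <- paste0("c", seq_len(dim))
    cbind(df, fc)
  }

  blocks <- list()
  for (d in seq_len(dim)) {
    along <- idx[, d]
    own <- which(along < cells[d])
    blocks[[length(blocks) + 1L]] <- face_block(
      own, own + strides[d], d, h[d] / 2, h[d], 1L, NA_character_)
    own <- which(along == 1L)
    blocks[[length(blocks) + 1L]] <- face_block(
      own, NA_integer_, d, -h[d] / 2, h[d] / 2, -1L, "FAR")
    own <- which(along == cells[d])
    blocks[[length(blocks) + 1L]] <- face_block(
      own, NA_integer_, d, h[d] / 2, h[d] / 2, 1L, "FAR")
  }
  faces <- do.call(rbind, blocks)
  rownames(faces) <- NULL

  structure(list(dim = dim, cells = cells, extents = extents, h = h,
                 ncell = ncell, centers = centers, volume = vol,
                 faces = faces),
            class = "thermo_mesh")
}

#' @export
print.thermo_mesh <- function(x, ...) {
  cat(sprintf("<thermo_mesh> %dD, %s cells (%s m), %d faces (%d boundary: %d VESSEL, %d FAR)\n",
              x$dim, paste(x$cells, collapse = "x"),
              paste(signif(x$extents, 3), collapse = " x "),
              nrow(x$faces), sum(!is.na(x$faces$tag)),
              sum(x$faces$tag %in% "VESSEL"), sum(x$faces$tag %in% "FAR")))
  invisible(x)
}

#' Describe a synthetic vessel for boundary tagging
#'
#' A vessel is a tube of given radius around a centerline polyline. The lumen
#' itself is not meshed; boundary faces of the porous domain whose centroids
#' fall inside the tube become the tissue-vessel inflow interface.
#'
#' @param centerline a matrix of waypoints (rows = points, cols = up to the
#'   mesh dimension; a single row describes a point "vessel mouth").
#' @param radius tube radius (m), > 0.
#' @return a `vessel_spec` list.
#' @examples
#' vessel_spec(matrix(0, 1, 1), radius = 5e-4)  # 1D vessel at x = 0
#' @export
vessel_spec <- function(centerline, radius) {
  centerline <- as.matrix(centerline)
  if (!is.numeric(radius) || radius <= 0) {
    abort("vessel radius must be positive", class = "thermo_input_error")
  }
  structure(list(centerline = centerline, radius = radius),
            class = "vessel_spec")
}

# Distance from each row of pts to a polyline given by waypoint rows.
dist_to_polyline <- function(pts, waypoints) {
  d <- rep(Inf, nrow(pts))
  nw <- nrow(waypoints)
  segs <- if (nw == 1L) list(c(1L, 1L)) else lapply(seq_len(nw - 1L), function(i) c(i, i + 1L))
  for (s in segs) {
    a <- waypoints[s[1], ]
    b <- waypoints[s[2], ]
    ab <- b - a
    ab2 <- sum(ab^2)
    rel <- sweep(pts, 2, a)
    tt <- if (ab2 == 0) rep(0, nrow(pts)) else pmin(1, pmax(0, rel %*% ab / ab2))
    proj <- rel - outer(as.numeric(tt), ab)
    d <- pmin(d, sqrt(rowSums(proj^2)))
  }
  d
}

#' Tag vessel-interface boundary faces
#'
#' Retags boundary faces whose centroid lies within the vessel tube
#' (distance to the centerline at most the radius) as `"VESSEL"`. Errors if
#' the vessel misses the boundary entirely.
#'
#' @param mesh a [make_box_mesh()] mesh.
#' @param spec a [vessel_spec()].
#' @return the mesh with updated face tags.
#' @export
tag_vessel <- function(mesh, spec) {
  stopifnot(inherits(mesh, "thermo_mesh"), inherits(spec, "vessel_spec"))
  bidx <- which(!is.na(mesh$faces$tag))
  cent <- as.matrix(mesh$faces[bidx, paste0("c", seq_len(mesh$dim)), drop = FALSE])
  wp <- spec$centerline
  if (ncol(wp) < mesh$dim) {
    wp <- cbind(wp, matrix(0, nrow(wp), mesh$dim - ncol(wp)))
  }
  d <- dist_to_polyline(cent, wp[, seq_len(mesh$dim), drop = FALSE])
  hit <- d <= spec$radius + 1e-12
  if (!any(hit)) {
    abort("vessel does not intersect the domain boundary; no face tagged",
          class = "thermo_geometry_error")
  }
  mesh$faces$tag[bidx[hit]] <- "VESSEL"
  mesh
}

#' Measure the boundary area carrying a tag
#'
#' @param mesh a `thermo_mesh`.
#' @param tag `"VESSEL"` or `"FAR"`.
#' @return total face area with that tag (m^2; in 2D this is a length since
#'   the out-of-plane thickness is unit, and in 1D a count of unit areas).
#' @export
measure_boundary <- function(mesh, tag) {
  if (!tag %in% c("VESSEL", "FAR")) {
    abort(paste0("unknown boundary tag '", tag, "'"),
          class = "thermo_input_error")
  }
  sum(mesh$faces$area[mesh$faces$tag %in% tag])
}

# Outward face-area vectors summed per cell; zero for a closed cell.
# Used by tests as a watertightness check and by the VTK writer.
cell_area_vector_sums <- function(mesh) {
  out <- matrix(0, mesh$ncell, mesh$dim)
  f <- mesh$faces
  for (k in seq_len(nrow(f))) {
    v <- numeric(mesh$dim)
    v[f$axis[k]] <- f$nsign[k] * f$area[k]
    out[f$owner[k], ] <- out[f$owner[k], ] + v
    if (!is.na(f$neighbor[k])) out[f$neighbor[k], ] <- out[f$neighbor[k], ] - v
  }
  out
}
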
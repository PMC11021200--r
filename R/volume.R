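#' Volumetric containers with physical geometry
#'
#' `volume_grid()` wraps a 3D numeric array of intensities together with its
#' per-axis physical voxel spacing; `label_volume()` does the same for
#' non-negative integer annotation/label arrays (0 = background). All
#' downstream morphometry and spatial statistics work in physical units (µm
#' for lengths, mm³ for volumes), so these containers are the only place
#' voxel indices meet the real world.
#'
#' Axis order is fixed as (z, y, x): `dim(data)[1]` is the number of
#' z-slices. Voxel indices are 0-based in physical formulas; the physical
#' position of a voxel's center is `origin_um + index * spacing_um`, with
#' the default origin `spacing_um / 2` placing voxel (0,0,0)'s center half a
#' voxel in from the volume corner.
#'
#' @param data 3D numeric array, axis order (z, y, x).
#' @param spacing_um numeric length-3, physical voxel size per axis in µm.
#' @param origin_um numeric length-3, physical position (µm) of the center of
#'   voxel (0,0,0). Defaults to `spacing_um / 2`.
#' @param label_names optional named character vector or list mapping label
#'   integers (as names) to region names, e.g. `c("1" = "lung")`.
#' @return An object of class `volume_grid` or `label_volume`: a list with
#'   elements `data`, `spacing_um`, `origin_um` (and `label_names`).
#' @examples
#' v <- volume_grid(array(runif(8), c(2, 2, 2)), spacing_um = c(10, 6.5, 6.5))
#' grid_extent_um(v)
#' @export
volume_grid <- function(data, spacing_um, origin_um = spacing_um / 2) {
  check_geometry(data, spacing_um, origin_um)
  if (!all(is.finite(data))) {
    stop("volume_grid: intensity data must be finite", call. = FALSE)
  }
  structure(
    list(data = data, spacing_um = as.numeric(spacing_um),
         origin_um = as.numeric(origin_um)),
    class = "volume_grid"
  )
}

#' @rdname volume_grid
#' @export
label_volume <- function(data, spacing_um, origin_um = spacing_um / 2,
                         label_names = NULL) {
  check_geometry(data, spacing_um, origin_um)
  if (any(!is.finite(data)) || any(data < 0) || any(data != round(data))) {
    stop("label_volume: labels must be finite non-negative integers (0 = background)",
         call. = FALSE)
  }
  storage.mode(data) <- "integer"
  structure(
    list(data = data, spacing_um = as.numeric(spacing_um),
         origin_um = as.numeric(origin_um), label_names = label_names),
    class = "label_volume"
  )
}

check_geometry <- function(data, spacing_um, origin_um) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3D array with axis order (z, y, x)", call. = FALSE)
  }
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0)) {
    stop("spacing_um must be 3 positive finite values (z, y, x)", call. = FALSE)
  }
  if (length(origin_um) != 3L || any(!is.finite(origin_um))) {
    stop("origin_um must be 3 finite values (z, y, x)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels (z,y,x), spacing %s um, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_um), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels (z,y,x), spacing %s um, %d foreground voxels, max label %d\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_um), collapse = ", "),
              sum(x$data > 0L), max(x$data)))
  invisible(x)
}

#' Geometry helpers
#'
#' `grid_extent_um()` is the physical size of the volume per axis,
#' `voxel_volume_mm3()` the physical volume of one voxel (1 mm³ = 1e9 µm³),
#' `voxel_centers_um()` the physical center coordinates of a matrix of
#' 1-based array indices, and `point_to_index()` the inverse map from
#' physical coordinates to 1-based indices (NA outside the grid).
#'
#' @param vol a `volume_grid` or `label_volume`.
#' @param idx integer matrix (n x 3) of 1-based (z,y,x) array indices.
#' @param points_um numeric matrix (n x 3) of physical (z,y,x) coordinates.
#' @return See descriptions above; coordinates in µm, volumes in mm³.
#' @export
grid_extent_um <- function(vol) dim(vol$data) * vol$spacing_um

#' @rdname grid_extent_um
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing_um) / 1e9

#' @rdname grid_extent_um
#' @export
voxel_centers_um <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, vol$spacing_um, "*"), 2L, vol$origin_um, "+")
}

#' @rdname grid_extent_um
#' @export
point_to_index <- function(vol, points_um) {
  points_um <- matrix(as.numeric(points_um), ncol = 3L)
  half <- vol$origin_um  # origin is the center of voxel 0 (0-based)
  idx0 <- sweep(points_um, 2L, half - vol$spacing_um / 2, "-")
  idx0 <- floor(sweep(idx0, 2L, vol$spacing_um, "/"))
  idx <- idx0 + 1
  d <- dim(vol$data)
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
    idx[, 3] < 1 | idx[, 3] > d[3]
  idx[bad, ] <- NA_real_
  storage.mode(idx) <- "integer"
  idx
}

#' Check two volumes share the same grid geometry
#'
#' Shape, spacing and origin must match exactly; used by every operation that
#' pairs an intensity volume with an annotation or region volume.
#'
#' @param a,b `volume_grid` / `label_volume` objects.
#' @param what label used in the error message.
#' @return Invisibly `TRUE`; stops with an informative error on mismatch.
#' @export
assert_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$spacing_um, b$spacing_um, tolerance = 0)) ||
      !isTRUE(all.equal(a$origin_um, b$origin_um, tolerance = 0))) {
    stop(sprintf("geometry mismatch between %s: shape/spacing/origin must be identical",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

axis_to_dim <- function(axis) {
  i <- match(axis, c("z", "y", "x"))
  if (is.na(i)) stop("axis must be one of 'z', 'y', 'x'", call. = FALSE)
  i
}

is_binary_mask <- function(vol) {
  inherits(vol, "label_volume") && all(vol$data %in% c(0L, 1L))
}
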
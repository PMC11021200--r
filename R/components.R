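#' Label connected components in a 3D binary mask
#'
#' Partitions the foreground of a binary mask into connected components under
#' 6-, 18- or 26-neighbor adjacency, using a single raster pass with
#' union-find (path compression). Component IDs are assigned 1..n in the
#' raster-scan order of each component's first voxel, so labeling is
#' deterministic and platform-independent.
#'
#' The default connectivity is 26, the common convention for blob-like
#' objects in 3D: two voxels belong together if they touch by face, edge or
#' corner.
#'
#' @param mask a binary `label_volume` (values 0/1).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' @return list with `labels` (a `label_volume` with components 1..n) and
#'   `n_components`.
#' @examples
#' m <- label_volume(array(c(1, 0, 0, 1, 0, 0, 0, 0), c(2, 2, 2)),
#'                   spacing_um = c(10, 10, 10))
#' label_components(m, connectivity = 6)$n_components
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!inherits(mask, "label_volume")) {
    stop("mask must be a label_volume", call. = FALSE)
  }
  if (!all(mask$data %in% c(0L, 1L))) {
    stop("label_components: mask must be binary (0/1); found other values",
         call. = FALSE)
  }
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  lab <- cc_label_3d(as.integer(mask$data), dim(mask$data), as.integer(connectivity))
  n <- attr(lab, "n_components")
  attr(lab, "n_components") <- NULL
  dim(lab) <- dim(mask$data)
  list(
    labels = label_volume(lab, mask$spacing_um, mask$origin_um),
    n_components = n
  )
}

#' Measure labeled objects in physical units
#'
#' Computes per-component morphometry from a labeled volume: voxel count,
#' physical volume in mm³ (`voxel_count * prod(spacing_um) / 1e9`), the
#' unweighted centroid of member voxel centers in µm, the physical bounding
#' box, whether the object touches the volume border, and (optionally) the
#' organ region containing its centroid.
#'
#' @param labels a `label_volume` of components (from [label_components()]).
#' @param class_name object class recorded in the table (e.g. "metastasis",
#'   "TLS"); default "generic".
#' @param regions optional `label_volume` of organ regions with `label_names`;
#'   must share the labels' geometry. Centroids falling in region 0 (or with
#'   no `regions` given) are assigned region "none".
#' @return An object table: `data.frame` with columns `object_id`, `class`,
#'   `voxel_count`, `volume_mm3`, `centroid_z_um`, `centroid_y_um`,
#'   `centroid_x_um`, `bbox_zmin_um` .. `bbox_xmax_um`, `on_border`, `region`.
#' @export
measure_objects <- function(labels, class_name = "generic", regions = NULL) {
  if (!inherits(labels, "label_volume")) {
    stop("labels must be a label_volume", call. = FALSE)
  }
  if (!is.null(regions)) {
    assert_same_geometry(labels, regions, "labels and regions")
  }
  d <- dim(labels$data)
  fg <- which(labels$data > 0L)
  if (length(fg) == 0L) {
    return(empty_object_table())
  }
  idx <- arrayInd(fg, d)
  ctr <- voxel_centers_um(labels, idx)
  sp <- labels$spacing_um
  half <- sp / 2
  dt <- data.table::data.table(
    lab = labels$data[fg],
    z = ctr[, 1], y = ctr[, 2], x = ctr[, 3],
    i1 = idx[, 1], i2 = idx[, 2], i3 = idx[, 3]
  )
  lab <- i1 <- i2 <- i3 <- z <- y <- x <- NULL  # data.table NSE
  tab <- dt[, list(
    voxel_count = .N,
    centroid_z_um = mean(z), centroid_y_um = mean(y), centroid_x_um = mean(x),
    bbox_zmin_um = min(z) - half[1], bbox_zmax_um = max(z) + half[1],
    bbox_ymin_um = min(y) - half[2], bbox_ymax_um = max(y) + half[2],
    bbox_xmin_um = min(x) - half[3], bbox_xmax_um = max(x) + half[3],
    on_border = any(i1 == 1L | i1 == d[1] | i2 == 1L | i2 == d[2] |
                      i3 == 1L | i3 == d[3])
  ), by = "lab"]
  data.table::setorder(tab, lab)
  out <- data.frame(
    object_id = tab$lab,
    class = class_name,
    voxel_count = tab$voxel_count,
    volume_mm3 = tab$voxel_count * voxel_volume_mm3(labels),
    centroid_z_um = tab$centroid_z_um,
    centroid_y_um = tab$centroid_y_um,
    centroid_x_um = tab$centroid_x_um,
    bbox_zmin_um = tab$bbox_zmin_um, bbox_zmax_um = tab$bbox_zmax_um,
    bbox_ymin_um = tab$bbox_ymin_um, bbox_ymax_um = tab$bbox_ymax_um,
    bbox_xmin_um = tab$bbox_xmin_um, bbox_xmax_um = tab$bbox_xmax_um,
    on_border = tab$on_border,
    region = "none",
    stringsAsFactors = FALSE
  )
  if (!is.null(regions)) {
    out$region <- region_of_points(
      regions, as.matrix(out[, c("centroid_z_um", "centroid_y_um", "centroid_x_um")])
    )
  }
  out
}

empty_object_table <- function() {
  data.frame(
    object_id = integer(0), class = character(0), voxel_count = integer(0),
    volume_mm3 = numeric(0), centroid_z_um = numeric(0),
    centroid_y_um = numeric(0), centroid_x_um = numeric(0),
    bbox_zmin_um = numeric(0), bbox_zmax_um = numeric(0),
    bbox_ymin_um = numeric(0), bbox_ymax_um = numeric(0),
    bbox_xmin_um = numeric(0), bbox_xmax_um = numeric(0),
    on_border = logical(0), region = character(0), stringsAsFactors = FALSE
  )
}

# region name containing each physical point; "none" outside all regions
region_of_points <- function(regions, points_um) {
  idx <- point_to_index(regions, points_um)
  lab <- rep(0L, nrow(idx))
  ok <- stats::complete.cases(idx)
  lab[ok] <- regions$data[idx[ok, , drop = FALSE]]
  region_label_to_name(regions, lab)
}

region_label_to_name <- function(regions, lab) {
  nm <- rep("none", length(lab))
  pos <- lab > 0L
  if (!is.null(regions$label_names)) {
    mapped <- unlist(regions$label_names)[as.character(lab[pos])]
    nm[pos] <- ifelse(is.na(mapped), paste0("region_", lab[pos]), mapped)
  } else {
    nm[pos] <- paste0("region_", lab[pos])
  }
  nm
}

#' Filter an object table by physical volume
#'
#' Keeps objects with `min_volume_mm3 <= volume_mm3 <= max_volume_mm3`. The
#' default bounds keep everything; the number of removed rows is attached as
#' attribute `n_removed` and reported via message.
#'
#' @param table an object table from [measure_objects()].
#' @param min_volume_mm3,max_volume_mm3 inclusive volume bounds (mm³).
#' @return The filtered object table (attribute `n_removed` records drops).
#' @export
filter_objects <- function(table, min_volume_mm3 = 0, max_volume_mm3 = Inf) {
  if (min_volume_mm3 < 0 || max_volume_mm3 < 0 || min_volume_mm3 > max_volume_mm3) {
    stop("volume bounds must be non-negative with min <= max", call. = FALSE)
  }
  keep <- table$volume_mm3 >= min_volume_mm3 & table$volume_mm3 <= max_volume_mm3
  out <- table[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_objects: removed %d of %d objects outside [%g, %g] mm3",
                    n_removed, nrow(table), min_volume_mm3, max_volume_mm3))
  }
  attr(out, "n_removed") <- n_removed
  out
}
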
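#' Sample random non-overlapping cubic subvolumes
#'
#' Draws `n` cubic subvolumes of physical edge `edge_um` uniformly at random
#' among positions fully inside the mask volume (and, if given, fully inside
#' an ROI), rejecting overlaps between samples — the sampling protocol used
#' for plexus density quantification (five 200 µm cubes per condition).
#' Deterministic given the seed.
#'
#' @param mask a binary `label_volume` (the filament/plexus mask).
#' @param edge_um cube edge length in µm (default 200).
#' @param n number of cubes (default 5).
#' @param seed integer RNG seed.
#' @param roi optional binary `label_volume`; cubes must lie entirely in its
#'   foreground.
#' @param max_restarts how many times a blocked partial layout may be
#'   discarded and resampled before giving up.
#' @return list of subvolume samples: each a list with `sample_id`,
#'   `corner_index` (1-based), `corner_um` (physical min corner),
#'   `edge_um`, `edge_voxels`, and `mask_crop` (binary `label_volume`).
#' @export
sample_subvolumes <- function(mask, edge_um = 200, n = 5L, seed = 1L,
                              roi = NULL, max_restarts = 50L) {
  stopifnot(inherits(mask, "label_volume"), n >= 1L)
  if (!is.null(roi)) assert_same_geometry(mask, roi, "mask and roi")
  d <- dim(mask$data)
  sp <- mask$spacing_um
  ev <- pmax(1L, as.integer(round(edge_um / sp)))  # edge in voxels per axis
  if (any(ev > d)) {
    stop(sprintf("cube edge %g um (%s voxels) does not fit in the volume (%s voxels)",
                 edge_um, paste(ev, collapse = "x"),
                 paste(d, collapse = "x")), call. = FALSE)
  }
  set.seed(sub_seed(seed, 21L))
  cd <- d - ev + 1L  # corner-position grid
  roi_bad <- array(FALSE, cd)  # corners whose cube leaves the ROI
  corners <- matrix(integer(0), ncol = 3)
  best <- 0L
  restarts <- 0L
  valid <- !roi_bad
  while (nrow(corners) < n) {
    open <- which(valid & !roi_bad)
    if (length(open) == 0L) {
      # a greedy partial layout can block the rest: restart from scratch
      best <- max(best, nrow(corners))
      restarts <- restarts + 1L
      if (restarts > max_restarts) {
        stop(sprintf("could not place %d non-overlapping cubes (achieved at most %d over %d restarts)",
                     n, best, restarts - 1L), call. = FALSE)
      }
      corners <- matrix(integer(0), ncol = 3)
      valid <- array(TRUE, cd)
      next
    }
    corner <- arrayInd(open[sample.int(length(open), 1L)], cd)[1, ]
    if (!is.null(roi)) {
      rng <- lapply(1:3, function(k) corner[k]:(corner[k] + ev[k] - 1L))
      if (any(roi$data[rng[[1]], rng[[2]], rng[[3]]] == 0L)) {
        roi_bad[corner[1], corner[2], corner[3]] <- TRUE
        next
      }
    }
    corners <- rbind(corners, corner)
    best <- max(best, nrow(corners))
    # forbid every corner whose cube would intersect the accepted one
    blk <- lapply(1:3, function(k) {
      max(1L, corner[k] - ev[k] + 1L):min(cd[k], corner[k] + ev[k] - 1L)
    })
    valid[blk[[1]], blk[[2]], blk[[3]]] <- FALSE
  }
  lapply(seq_len(n), function(i) {
    corner <- corners[i, ]
    rng <- lapply(1:3, function(k) corner[k]:(corner[k] + ev[k] - 1L))
    list(
      sample_id = i,
      corner_index = corner,
      corner_um = (corner - 1L) * sp,
      edge_um = edge_um,
      edge_voxels = ev,
      mask_crop = label_volume(mask$data[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
                               sp, mask$origin_um)
    )
  })
}

#' Skeletonize a binary volume to a one-voxel-thick centerline
#'
#' Topology-preserving sequential thinning: border voxels are removed one at
#' a time only when removal provably preserves the 26-connectivity of the
#' foreground and the 6-connectivity of the background in their 3×3×3
#' neighborhood (simple points) and they are not curve endpoints, cycling
#' through six directional sub-iterations until stable. The result is a
#' subset of the mask with the same number of 26-connected components; it
#' replaces interactive filament tracing with a deterministic algorithm.
#'
#' @param mask_crop a binary `label_volume`.
#' @return binary `label_volume` containing the skeleton.
#' @export
skeletonize_mask <- function(mask_crop) {
  stopifnot(inherits(mask_crop, "label_volume"))
  if (!all(mask_crop$data %in% c(0L, 1L))) {
    stop("skeletonize_mask: mask must be binary", call. = FALSE)
  }
  sk <- thin_3d(as.integer(mask_crop$data), dim(mask_crop$data))
  dim(sk) <- dim(mask_crop$data)
  label_volume(sk, mask_crop$spacing_um, mask_crop$origin_um)
}

# TRUE if the volume contains a 2x2x2 all-foreground block (i.e. not thin)
has_thick_block <- function(arr) {
  d <- dim(arr)
  if (any(d < 2L)) return(FALSE)
  a <- arr > 0
  s <- a[-d[1], -d[2], -d[3]] & a[-1, -d[2], -d[3]] &
    a[-d[1], -1, -d[3]] & a[-1, -1, -d[3]] &
    a[-d[1], -d[2], -1] & a[-1, -d[2], -1] &
    a[-d[1], -1, -1] & a[-1, -1, -1]
  any(s)
}

#' Physical centerline length of a skeleton
#'
#' Builds the 26-neighbor graph of the skeleton voxels with edges weighted
#' by the physical center-to-center distance and sums the edge weights of a
#' minimum spanning structure per connected component. Spanning-tree length
#' avoids double-counting the chord edges that 26-adjacency introduces along
#' digital curves; for a network with cycles it undercounts each independent
#' cycle by one edge — a small, deterministic bias that is identical across
#' compared conditions. Isolated voxels contribute 0.
#'
#' @param skeleton a one-voxel-thick binary `label_volume` (from
#'   [skeletonize_mask()]); passing a non-thin mask is an error.
#' @return total centerline length in µm.
#' @export
skeleton_length <- function(skeleton) {
  stopifnot(inherits(skeleton, "label_volume"))
  if (!all(skeleton$data %in% c(0L, 1L))) {
    stop("skeleton must be binary", call. = FALSE)
  }
  if (has_thick_block(skeleton$data)) {
    stop("input is not one-voxel-thick; run skeletonize_mask() first", call. = FALSE)
  }
  d <- dim(skeleton$data)
  sp <- skeleton$spacing_um
  fg <- which(skeleton$data > 0L)
  if (length(fg) < 2L) return(0)
  idx <- arrayInd(fg, d)
  lin_of <- function(m) (m[, 1] - 1) + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1))
  lin <- lin_of(idx)
  # 13 forward offsets of the 26-neighborhood
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nb <- sweep(idx, 2L, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    j <- match(lin_of(nb[ok, , drop = FALSE]), lin)
    hit <- !is.na(j)
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
    w <- c(w, rep(sqrt(sum((o * sp)^2)), sum(hit)))
  }
  if (length(from) == 0L) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_along(fg))
  )
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  sum(igraph::E(mst)$weight)
}

#' Centerline length and density of sampled subvolumes
#'
#' Skeletonizes each cube's mask crop, measures its centerline length and
#' derives the density (length per cube volume), returned both in µm/µm³
#' and the conventional mm/mm³ (1 mm/mm³ = 1e-6 µm/µm³).
#'
#' @param samples list of subvolume samples from [sample_subvolumes()].
#' @return data.frame with `sample_id`, `length_um`, `volume_um3`,
#'   `density_um_per_um3`, `density_mm_per_mm3`.
#' @export
quantify_subvolumes <- function(samples) {
  rows <- lapply(samples, function(s) {
    sk <- skeletonize_mask(s$mask_crop)
    len <- skeleton_length(sk)
    vol_um3 <- prod(dim(s$mask_crop$data) * s$mask_crop$spacing_um)
    data.frame(
      sample_id = s$sample_id,
      length_um = len,
      volume_um3 = vol_um3,
      density_um_per_um3 = len / vol_um3,
      density_mm_per_mm3 = len / vol_um3 * 1e6
    )
  })
  do.call(rbind, rows)
}

#' Compare plexus density between conditions
#'
#' Summarizes per-cube densities by condition (mean ± s.d.) and tests the
#' difference: unpaired t-test for two conditions ([group_compare()]),
#' one-way ANOVA for more, and an explicit notice (no test) for a single
#' condition.
#'
#' @param condition_samples named list; each element is either a numeric
#'   vector of densities or a list of subvolume samples (then quantified via
#'   [quantify_subvolumes()], using `density_mm_per_mm3`).
#' @param var_equal passed to [group_compare()] for two conditions.
#' @return list with `summary` (per-condition n/mean/sd data.frame), `test`
#'   (the comparison result or NULL), and `note`.
#' @export
plexus_density_report <- function(condition_samples, var_equal = TRUE) {
  stopifnot(is.list(condition_samples), length(condition_samples) >= 1L)
  if (is.null(names(condition_samples))) {
    names(condition_samples) <- paste0("condition_", seq_along(condition_samples))
  }
  dens <- lapply(condition_samples, function(x) {
    if (is.numeric(x)) x else quantify_subvolumes(x)$density_mm_per_mm3
  })
  if (any(lengths(dens) < 2L)) {
    stop("each condition needs >= 2 samples", call. = FALSE)
  }
  summ <- data.frame(
    condition = names(dens),
    n = lengths(dens),
    mean_density = vapply(dens, mean, 0),
    sd_density = vapply(dens, stats::sd, 0)
  )
  rownames(summ) <- NULL
  if (length(dens) == 1L) {
    return(list(summary = summ, test = NULL,
                note = "single condition: summaries only, no test performed"))
  }
  if (length(dens) == 2L) {
    test <- group_compare(dens[[1]], dens[[2]], var_equal = var_equal)
    note <- sprintf("two conditions compared by %s", test$method)
  } else {
    test <- group_compare_anova(dens)
    note <- "more than two conditions compared by one-way ANOVA"
  }
  list(summary = summ, test = test, note = note)
}
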
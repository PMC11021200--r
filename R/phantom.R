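#' Configuration for synthetic whole-body imaging phantoms
#'
#' Builds and validates the configuration for the phantom generator, which
#' emulates the statistical structure of annotated whole-body light-sheet
#' scans of tumor-bearing mice: two object classes (metastases and tertiary
#' lymphoid structures, TLS) with log-normal volume distributions, optional
#' spatial coupling of TLS to metastases, organ-region placement priors, and
#' an imaging model with depth attenuation and additive noise.
#'
#' Defaults mirror the acquisition geometry of whole-body scans (z step
#' 10 µm with finer lateral sampling) and the reported organ distribution of
#' micrometastases (62% lung, 19% gut). Volume medians are on the
#' micrometastasis scale (~0.002 mm³ for metastases, ~0.0015 mm³ for TLS,
#' i.e. TLS markedly smaller, as observed in vivo).
#'
#' @param grid_shape integer length-3, voxels per axis (z, y, x).
#' @param spacing_um numeric length-3, physical voxel size (µm).
#' @param n_metastases,n_tls object counts per class.
#' @param met_volume_lognormal,tls_volume_lognormal numeric length-2
#'   `(median_mm3, log_sd)` of the log-normal volume distribution.
#' @param coupling_scale_um characteristic TLS-to-metastasis placement
#'   distance in µm, or `"uncoupled"` / `Inf` for independent placement.
#' @param region_priors named list with elements `metastasis` and `TLS`, each
#'   a named probability vector over region names summing to 1.
#' @param noise_sd additive Gaussian noise sd (intensity units; foreground
#'   amplitude is 1).
#' @param attenuation_per_um exponential intensity decay per µm of depth
#'   (0 disables attenuation).
#' @param seed integer RNG seed; all generator output is a pure function of
#'   the configuration including this seed.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64L, 96L, 96L),
                           spacing_um = c(10, 6.5, 6.5),
                           n_metastases = 40L,
                           n_tls = 30L,
                           met_volume_lognormal = c(0.002, 0.6),
                           tls_volume_lognormal = c(0.0015, 0.5),
                           coupling_scale_um = 100,
                           region_priors = list(
                             metastasis = c(lung = 0.62, gut = 0.19, other = 0.19),
                             TLS = c(lung = 0.62, gut = 0.19, other = 0.19)
                           ),
                           noise_sd = 0.02,
                           attenuation_per_um = 0,
                           seed = 1L) {
  cfg <- list(
    grid_shape = as.integer(grid_shape), spacing_um = as.numeric(spacing_um),
    n_metastases = as.integer(n_metastases), n_tls = as.integer(n_tls),
    met_volume_lognormal = as.numeric(met_volume_lognormal),
    tls_volume_lognormal = as.numeric(tls_volume_lognormal),
    coupling_scale_um = if (identical(coupling_scale_um, "uncoupled")) Inf
                        else as.numeric(coupling_scale_um),
    region_priors = region_priors,
    noise_sd = as.numeric(noise_sd),
    attenuation_per_um = as.numeric(attenuation_per_um),
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 1L))
  if (any(cfg$spacing_um <= 0) || length(cfg$spacing_um) != 3L) {
    stop("spacing_um must be positive on every axis", call. = FALSE)
  }
  if (cfg$n_metastases < 0L || cfg$n_tls < 0L) {
    stop("object counts must be >= 0", call. = FALSE)
  }
  for (nm in c("met_volume_lognormal", "tls_volume_lognormal")) {
    v <- cfg[[nm]]
    if (length(v) != 2L || v[1] <= 0 || v[2] < 0) {
      stop(sprintf("%s must be (median_mm3 > 0, log_sd >= 0)", nm), call. = FALSE)
    }
  }
  if (!is.infinite(cfg$coupling_scale_um) && cfg$coupling_scale_um <= 0) {
    stop("coupling_scale_um must be positive, or 'uncoupled'/Inf", call. = FALSE)
  }
  for (cls in c("metastasis", "TLS")) {
    p <- cfg$region_priors[[cls]]
    if (is.null(p) || is.null(names(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("region_priors$%s must be a named probability vector summing to 1",
                   cls), call. = FALSE)
    }
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$attenuation_per_um < 0) stop("attenuation_per_um must be >= 0", call. = FALSE)
  invisible(TRUE)
}

# deterministic per-stage sub-seed, kept below 2^31
sub_seed <- function(seed, stage) {
  (as.numeric(seed) %% 65521) * 31907 + 7919 * stage
}

#' Generate a two-class object phantom with exact ground truth
#'
#' Places voxelized axis-aligned ellipsoids of two classes (metastases and
#' TLS) into a 3D grid: regions are axis-aligned slabs named after the
#' configured priors; each object's region is drawn from its class prior and
#' its center uniformly within that region with a margin, so the whole
#' ellipsoid lies inside the grid. Within a class, centers are rejected
#' until every pair of ellipsoids is separated by at least one voxel in
#' every direction, which guarantees connected-component labeling recovers
#' the object count exactly. When `coupling_scale_um` is finite, each TLS
#' center is drawn at an exponentially distributed distance (mean
#' `coupling_scale_um`) in a uniformly random direction from a randomly
#' chosen metastasis center, emulating the observed clustering of TLS near
#' metastases; its region is then the region containing the drawn center.
#'
#' A voxel belongs to an object iff its center lies inside the ellipsoid.
#' Intensity channels are the annotation at unit amplitude passed through
#' [apply_imaging_model()].
#'
#' @param config a [phantom_config()].
#' @return list with `intensity` (list of `volume_grid` per class),
#'   `annotation` (list of `label_volume` per class, objects numbered in
#'   placement order), `regions` (a `label_volume` with `label_names`), and
#'   `truth` (list with `objects` data.frame — `object_id`, `class`,
#'   `center_*_um`, `radius_*_um`, `true_volume_mm3`, `region` — and
#'   `config_echo`).
#' @export
generate_object_phantom <- function(config) {
  validate_phantom_config(config)
  regions <- make_region_volume(config)
  extent <- config$grid_shape * config$spacing_um

  set.seed(sub_seed(config$seed, 1L))
  met <- place_class(config, regions, class = "metastasis",
                     n = config$n_metastases,
                     lognorm = config$met_volume_lognormal)
  tls <- place_class(config, regions, class = "TLS",
                     n = config$n_tls,
                     lognorm = config$tls_volume_lognormal,
                     couple_to = if (is.finite(config$coupling_scale_um)) met else NULL,
                     coupling_scale_um = config$coupling_scale_um)

  ann_met <- voxelize_objects(config, met)
  ann_tls <- voxelize_objects(config, tls)

  objects <- rbind(met, tls)
  if (nrow(objects)) rownames(objects) <- NULL

  int_met <- apply_imaging_model(
    volume_grid((ann_met$data > 0L) * 1.0, config$spacing_um), config, stage = 1L)
  int_tls <- apply_imaging_model(
    volume_grid((ann_tls$data > 0L) * 1.0, config$spacing_um), config, stage = 2L)

  list(
    intensity = list(metastasis = int_met, TLS = int_tls),
    annotation = list(metastasis = ann_met, TLS = ann_tls),
    regions = regions,
    truth = list(objects = objects, config_echo = config)
  )
}

# regions are slabs of equal thickness along y, named after the metastasis
# prior; prior names of both classes must agree with the region volume
make_region_volume <- function(config) {
  nms <- names(config$region_priors$metastasis)
  extra <- setdiff(names(config$region_priors$TLS), nms)
  if (length(extra)) {
    stop(sprintf("region prior references region(s) absent from the region volume: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  d <- config$grid_shape
  k <- length(nms)
  ycut <- ceiling(seq_len(d[2]) / (d[2] / k))  # slab id per y index
  arr <- array(0L, d)
  for (j in seq_len(d[2])) arr[, j, ] <- ycut[j]
  label_volume(arr, config$spacing_um,
               label_names = stats::setNames(as.list(nms), seq_len(k)))
}

# bounds of region slab r (µm) along y
region_y_bounds <- function(config, region_index) {
  k <- length(names(config$region_priors$metastasis))
  d2 <- config$grid_shape[2]
  lo_idx <- which(ceiling(seq_len(d2) / (d2 / k)) == region_index)
  c((min(lo_idx) - 1), max(lo_idx)) * config$spacing_um[2]
}

place_class <- function(config, regions, class, n, lognorm,
                        couple_to = NULL, coupling_scale_um = Inf,
                        retry_cap = 2000L) {
  extent <- config$grid_shape * config$spacing_um
  sp <- config$spacing_um
  prior <- config$region_priors[[if (class == "metastasis") "metastasis" else "TLS"]]
  nms <- names(config$region_priors$metastasis)
  rows <- vector("list", n)
  centers <- matrix(numeric(0), ncol = 3)
  maxr <- numeric(0)
  if (n == 0L) return(empty_truth_objects())
  coupled <- !is.null(couple_to) && nrow(couple_to) > 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    # the region is drawn once per object so the prior stays an unbiased
    # multinomial; retries only redraw size and position within that region
    if (!coupled) {
      ridx <- match(names(prior)[sample.int(length(prior), 1L, prob = prior)], nms)
      yb <- region_y_bounds(config, ridx)
    }
    for (try in seq_len(retry_cap)) {
      vol_mm3 <- stats::rlnorm(1, meanlog = log(lognorm[1]), sdlog = lognorm[2])
      radii <- sample_ellipsoid_radii(vol_mm3)
      margin <- radii + sp  # ellipsoid + one-voxel gap inside the grid
      if (!coupled) {
        lo <- c(margin[1], max(yb[1], 0) + margin[2], margin[3])
        hi <- c(extent[1] - margin[1], min(yb[2], extent[2]) - margin[2],
                extent[3] - margin[3])
        if (any(lo >= hi)) next
        ctr <- lo + stats::runif(3) * (hi - lo)
      } else {
        anchor <- couple_to[sample.int(nrow(couple_to), 1L), ]
        dist <- stats::rexp(1, rate = 1 / coupling_scale_um)
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        ctr <- c(anchor$center_z_um, anchor$center_y_um, anchor$center_x_um) +
          dist * u
        if (any(ctr < radii + sp) || any(ctr > extent - radii - sp)) next
      }
      # same-class separation: conservative bounding-sphere test with a
      # two-voxel cushion so voxelized objects never touch at 26-connectivity
      if (length(maxr)) {
        dd <- sqrt(colSums((t(centers) - ctr)^2))
        if (any(dd < maxr + max(radii) + 2 * max(sp))) next
      }
      centers <- rbind(centers, ctr)
      maxr <- c(maxr, max(radii))
      region <- region_of_points(regions, matrix(ctr, ncol = 3))
      rows[[i]] <- data.frame(
        object_id = i, class = class,
        center_z_um = ctr[1], center_y_um = ctr[2], center_x_um = ctr[3],
        radius_z_um = radii[1], radius_y_um = radii[2], radius_x_um = radii[3],
        true_volume_mm3 = vol_mm3, region = region,
        stringsAsFactors = FALSE
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf("phantom overcrowded: could not place %s %d of %d after %d retries",
                   class, i, n, retry_cap), call. = FALSE)
    }
  }
  do.call(rbind, rows)
}

empty_truth_objects <- function() {
  data.frame(
    object_id = integer(0), class = character(0),
    center_z_um = numeric(0), center_y_um = numeric(0), center_x_um = numeric(0),
    radius_z_um = numeric(0), radius_y_um = numeric(0), radius_x_um = numeric(0),
    true_volume_mm3 = numeric(0), region = character(0), stringsAsFactors = FALSE
  )
}

# radii (µm) of a random-aspect ellipsoid with exact volume vol_mm3
sample_ellipsoid_radii <- function(vol_mm3, aspect_log_sd = 0.15) {
  r0 <- (3 * vol_mm3 * 1e9 / (4 * pi))^(1 / 3)
  a <- exp(stats::rnorm(3, 0, aspect_log_sd))
  r0 * a / prod(a)^(1 / 3)
}

# annotation array: voxel center inside ellipsoid => object id
voxelize_objects <- function(config, objects) {
  d <- config$grid_shape
  sp <- config$spacing_um
  org <- sp / 2
  arr <- array(0L, d)
  if (nrow(objects) == 0L) {
    return(label_volume(arr, sp))
  }
  ax_coord <- lapply(1:3, function(k) org[k] + (seq_len(d[k]) - 1) * sp[k])
  for (i in seq_len(nrow(objects))) {
    ctr <- as.numeric(objects[i, c("center_z_um", "center_y_um", "center_x_um")])
    rad <- as.numeric(objects[i, c("radius_z_um", "radius_y_um", "radius_x_um")])
    rng <- lapply(1:3, function(k) {
      which(abs(ax_coord[[k]] - ctr[k]) <= rad[k])
    })
    if (any(lengths(rng) == 0L)) next
    nz <- lengths(rng)
    uz <- (ax_coord[[1]][rng[[1]]] - ctr[1]) / rad[1]
    uy <- (ax_coord[[2]][rng[[2]]] - ctr[2]) / rad[2]
    ux <- (ax_coord[[3]][rng[[3]]] - ctr[3]) / rad[3]
    q <- outer(outer(uz^2, uy^2, "+"), ux^2, "+")
    inside <- q <= 1
    sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    sub[inside] <- objects$object_id[i]
    arr[rng[[1]], rng[[2]], rng[[3]]] <- sub
  }
  label_volume(arr, sp)
}

#' Apply the imaging model: depth attenuation plus additive noise
#'
#' Multiplies a clean intensity volume by `exp(-attenuation_per_um * depth)`
#' where depth is measured in µm from the entry surface along the chosen
#' axis (slice centers at `(i - 0.5) * spacing`), then adds zero-mean
#' Gaussian noise with sd `noise_sd`, clips at 0, and returns the result.
#' Output is a pure function of `(clean, config, axis, entry, stage)`:
#' the noise stream is seeded from `config$seed` and `stage`.
#'
#' @param clean a `volume_grid`.
#' @param config a [phantom_config()] providing `attenuation_per_um`,
#'   `noise_sd` and `seed`.
#' @param axis attenuation axis, `"z"` (default), `"y"` or `"x"`.
#' @param entry `"low"` (depth grows with index, default) or `"high"`.
#' @param stage integer noise sub-stream id; calls with different stages get
#'   independent noise under the same seed.
#' @return a `volume_grid` with the same geometry.
#' @export
apply_imaging_model <- function(clean, config, axis = "z", entry = "low",
                                stage = 0L) {
  stopifnot(inherits(clean, "volume_grid"))
  k <- axis_to_dim(axis)
  d <- dim(clean$data)
  depth <- (seq_len(d[k]) - 0.5) * clean$spacing_um[k]
  if (entry == "high") depth <- rev(depth)
  else if (entry != "low") stop("entry must be 'low' or 'high'", call. = FALSE)
  att <- exp(-config$attenuation_per_um * depth)
  out <- sweep(clean$data, k, att, "*")
  if (config$noise_sd > 0) {
    set.seed(sub_seed(config$seed, 100L + stage))
    out <- out + stats::rnorm(length(out), 0, config$noise_sd)
  }
  out <- pmax(out, 0)
  dim(out) <- d
  volume_grid(out, clean$spacing_um, clean$origin_um)
}

#' Generate a filament lattice phantom of known centerline length
#'
#' Builds a 3D cubic lattice of tubes emulating the enteric nerve plexus: a
#' regular network with nodes at pitch `lattice_pitch_um`, every edge a
#' straight tube of radius `tube_radius_um`. `dropout_fraction` removes
#' whole lattice edges independently at random, emulating the sparser,
#' disorganized network of germ-free animals; `dropout = 0` yields the full
#' lattice. The returned truth records the retained centerline polylines and
#' their exact total length.
#'
#' @param config a [phantom_config()] (grid shape, spacing and seed are used).
#' @param lattice_pitch_um distance between lattice nodes (µm); must exceed
#'   twice the largest voxel spacing to be resolvable.
#' @param dropout_fraction probability in `[0, 1)` that an edge is removed.
#' @param tube_radius_um tube radius (µm).
#' @return list with `mask` (binary `label_volume`) and `truth` (list with
#'   `filaments` data.frame of polyline vertices — `filament_id`, `vertex`,
#'   `z_um`, `y_um`, `x_um` —, `total_length_um`, and `config_echo`).
#' @export
generate_filament_phantom <- function(config, lattice_pitch_um,
                                      dropout_fraction = 0,
                                      tube_radius_um = 10) {
  validate_phantom_config(config)
  if (lattice_pitch_um <= 2 * max(config$spacing_um)) {
    stop("lattice_pitch_um must exceed 2 * max(spacing_um): structure unresolvable",
         call. = FALSE)
  }
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    stop("dropout_fraction must be in [0, 1)", call. = FALSE)
  }
  extent <- config$grid_shape * config$spacing_um
  # lattice nodes centered in the grid, at least one plane per axis
  nodes <- lapply(1:3, function(k) {
    margin <- 2 * max(config$spacing_um)  # keep tubes inside the grid
    m <- max(1L, floor((extent[k] - margin) / lattice_pitch_um) + 1L)
    start <- (extent[k] - (m - 1) * lattice_pitch_um) / 2
    start + (seq_len(m) - 1) * lattice_pitch_um
  })
  m <- lengths(nodes)
  # all axis-aligned unit edges between adjacent nodes
  segs <- list()
  grid_nodes <- as.matrix(expand.grid(z = nodes[[1]], y = nodes[[2]], x = nodes[[3]]))
  for (k in 1:3) {
    if (m[k] < 2L) next
    step <- c(0, 0, 0)
    step[k] <- lattice_pitch_um
    from <- grid_nodes[grid_nodes[, k] < max(nodes[[k]]) - 1e-9, , drop = FALSE]
    segs[[k]] <- cbind(from, sweep(from, 2, step, "+"))
  }
  segs <- do.call(rbind, segs)
  if (is.null(segs)) {
    stop("grid too small to host any lattice edge at this pitch", call. = FALSE)
  }
  set.seed(sub_seed(config$seed, 11L))
  keep <- stats::runif(nrow(segs)) >= dropout_fraction
  segs <- segs[keep, , drop = FALSE]

  mask <- voxelize_tubes(config$grid_shape, config$spacing_um, segs, tube_radius_um)
  lens <- sqrt(rowSums((segs[, 1:3, drop = FALSE] - segs[, 4:6, drop = FALSE])^2))
  fil <- if (nrow(segs)) {
    data.frame(
      filament_id = rep(seq_len(nrow(segs)), each = 2L),
      vertex = rep(1:2, nrow(segs)),
      z_um = as.vector(t(segs[, c(1, 4), drop = FALSE])),
      y_um = as.vector(t(segs[, c(2, 5), drop = FALSE])),
      x_um = as.vector(t(segs[, c(3, 6), drop = FALSE]))
    )
  } else {
    data.frame(filament_id = integer(0), vertex = integer(0),
               z_um = numeric(0), y_um = numeric(0), x_um = numeric(0))
  }
  list(
    mask = mask,
    truth = list(filaments = fil, total_length_um = sum(lens),
                 config_echo = config)
  )
}

#' Voxelize straight tube segments into a binary mask
#'
#' Marks every voxel whose center lies within `radius_um` of any of the
#' given line segments. Used by the filament phantom and handy for building
#' analytic test fixtures (a single straight or diagonal tube of known
#' centerline length).
#'
#' @param shape integer length-3 grid shape (z, y, x).
#' @param spacing_um voxel spacing (µm).
#' @param segments numeric matrix with 6 columns
#'   `(z0, y0, x0, z1, y1, x1)` in µm, one row per segment.
#' @param radius_um tube radius (µm).
#' @return binary `label_volume`.
#' @export
voxelize_tubes <- function(shape, spacing_um, segments, radius_um) {
  d <- as.integer(shape)
  sp <- as.numeric(spacing_um)
  org <- sp / 2
  arr <- array(0L, d)
  segments <- matrix(as.numeric(segments), ncol = 6L)
  ax_coord <- lapply(1:3, function(k) org[k] + (seq_len(d[k]) - 1) * sp[k])
  for (i in seq_len(nrow(segments))) {
    p0 <- segments[i, 1:3]
    p1 <- segments[i, 4:6]
    lo <- pmin(p0, p1) - radius_um
    hi <- pmax(p0, p1) + radius_um
    rng <- lapply(1:3, function(k) which(ax_coord[[k]] >= lo[k] & ax_coord[[k]] <= hi[k]))
    if (any(lengths(rng) == 0L)) next
    pts <- as.matrix(expand.grid(z = ax_coord[[1]][rng[[1]]],
                                 y = ax_coord[[2]][rng[[2]]],
                                 x = ax_coord[[3]][rng[[3]]]))
    dv <- p1 - p0
    len2 <- sum(dv^2)
    if (len2 == 0) {
      dist2 <- colSums((t(pts) - p0)^2)
    } else {
      t_par <- pmin(1, pmax(0, ((pts[, 1] - p0[1]) * dv[1] +
                                  (pts[, 2] - p0[2]) * dv[2] +
                                  (pts[, 3] - p0[3]) * dv[3]) / len2))
      proj <- cbind(p0[1] + t_par * dv[1], p0[2] + t_par * dv[2],
                    p0[3] + t_par * dv[3])
      dist2 <- rowSums((pts - proj)^2)
    }
    inside <- array(dist2 <= radius_um^2, lengths(rng))
    sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    sub[inside] <- 1L
    arr[rng[[1]], rng[[2]], rng[[3]]] <- sub
  }
  label_volume(arr, sp)
}
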
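#' Nearest-neighbor distances between object tables
#'
#' For every source object, finds the target object with minimal Euclidean
#' centroid distance in physical µm. Ties are broken toward the lower
#' target id; with an empty (or fully excluded) target set the distance is
#' missing, never a sentinel. When sources and targets are the same table,
#' `exclude_self = TRUE` is required so an object is never its own nearest
#' neighbor.
#'
#' The search is plain vectorized all-pairs evaluation: at the object counts
#' of whole-body scans (thousands) this is both fast in R and trivially
#' identical to the brute-force definition.
#'
#' @param sources,targets object tables from [measure_objects()].
#' @param exclude_self drop pairs with equal `object_id` (same-class NN).
#' @return NN table: `data.frame` with `source_id`, `source_class`,
#'   `source_volume_mm3`, `target_class`, `nearest_target_id`,
#'   `nearest_target_volume_mm3`, `distance_um`.
#' @export
nn_distances <- function(sources, targets, exclude_self = FALSE) {
  same_table <- nrow(sources) == nrow(targets) &&
    nrow(sources) > 0 &&
    identical(sources$object_id, targets$object_id) &&
    identical(sources$class, targets$class)
  if (same_table && !exclude_self) {
    stop("sources and targets are the same table: set exclude_self = TRUE",
         call. = FALSE)
  }
  cc <- c("centroid_z_um", "centroid_y_um", "centroid_x_um")
  if (nrow(sources) && any(!is.finite(as.matrix(sources[, cc])))) {
    stop("source centroids must be finite", call. = FALSE)
  }
  out <- data.frame(
    source_id = sources$object_id,
    source_class = sources$class,
    source_volume_mm3 = sources$volume_mm3,
    target_class = if (nrow(targets)) targets$class[1] else NA_character_,
    nearest_target_id = NA_integer_,
    nearest_target_volume_mm3 = NA_real_,
    distance_um = NA_real_,
    stringsAsFactors = FALSE
  )
  if (nrow(sources) == 0L || nrow(targets) == 0L) return(out)
  targets <- targets[order(targets$object_id), , drop = FALSE]
  S <- as.matrix(sources[, cc])
  T_ <- as.matrix(targets[, cc])
  d2 <- outer(S[, 1], T_[, 1], "-")^2 + outer(S[, 2], T_[, 2], "-")^2 +
    outer(S[, 3], T_[, 3], "-")^2
  if (exclude_self) {
    d2[outer(sources$object_id, targets$object_id, "==") &
         outer(sources$class, targets$class, "==")] <- Inf
  }
  j <- apply(d2, 1L, which.min)  # first minimum = lowest target_id
  dmin <- sqrt(d2[cbind(seq_len(nrow(S)), j)])
  ok <- is.finite(dmin)
  out$nearest_target_id[ok] <- targets$object_id[j[ok]]
  out$nearest_target_volume_mm3[ok] <- targets$volume_mm3[j[ok]]
  out$distance_um[ok] <- dmin[ok]
  out
}

#' Join metastasis volumes with their nearest-TLS distance
#'
#' One row per metastasis carrying its own volume, the nearest TLS and its
#' volume, and the centroid distance — the table behind
#' "metastasis volume vs. distance to the nearest TLS" plots.
#' `volume_distance_summary()` reduces it to the headline quantities: the
#' number of metastases with an eligible TLS neighbor, the mean volume of
#' metastases whose nearest TLS lies within `radius_um`, and the mean
#' metastasis volume adjacent to each TLS.
#'
#' @param metastases,tls object tables measured on the same geometry.
#' @param nn an NN table from `volume_distance_join()`.
#' @param radius_um eligibility radius for the volume summary (µm).
#' @return `volume_distance_join()`: an NN table (see [nn_distances()]).
#'   `volume_distance_summary()`: list with `n_eligible`, `n_excluded`,
#'   `mean_source_volume_mm3`, and `per_target` (mean adjacent source volume
#'   by nearest target).
#' @export
volume_distance_join <- function(metastases, tls) {
  nn <- nn_distances(metastases, tls)
  if (all(is.na(nn$distance_um)) && nrow(nn)) {
    message("volume_distance_join: 0 eligible rows (no TLS available); distances missing")
  }
  nn
}

#' @rdname volume_distance_join
#' @export
volume_distance_summary <- function(nn, radius_um = Inf) {
  elig <- !is.na(nn$distance_um) & nn$distance_um <= radius_um
  per_target <- if (any(elig)) {
    stats::aggregate(
      source_volume_mm3 ~ nearest_target_id,
      data = nn[elig, , drop = FALSE], FUN = mean
    )
  } else {
    data.frame(nearest_target_id = integer(0), source_volume_mm3 = numeric(0))
  }
  list(
    n_eligible = sum(elig),
    n_excluded = sum(!elig),
    mean_source_volume_mm3 = if (any(elig)) mean(nn$source_volume_mm3[elig]) else NA_real_,
    per_target = per_target
  )
}

#' Per-region counts, densities and fractions of objects
#'
#' Counts objects per organ region by centroid containment (an object
#' belongs to the region containing its centroid; outside all regions it is
#' assigned "none", never dropped), computes each region's physical volume
#' from its voxel count, and derives density (count / region volume) and
#' the fraction of the class total per region.
#'
#' @param objects an object table (its `region` column is recomputed from
#'   `regions` to guarantee consistency).
#' @param regions a `label_volume` of organ regions.
#' @param classes classes to tabulate; defaults to those present (or
#'   "generic" for an empty table).
#' @return region table: `data.frame` with `region`, `region_volume_mm3`,
#'   `class`, `count`, `density_per_mm3`, `fraction` (NA when the class
#'   total is 0); one row per region (including "none") and class.
#' @export
region_summary <- function(objects, regions, classes = NULL) {
  if (is.null(classes)) {
    classes <- if (nrow(objects)) unique(objects$class) else "generic"
  }
  if (nrow(objects)) {
    objects$region <- region_of_points(
      regions,
      as.matrix(objects[, c("centroid_z_um", "centroid_y_um", "centroid_x_um")])
    )
  }
  labs <- sort(unique(as.vector(regions$data)))
  labs <- labs[labs > 0L]
  region_names <- region_label_to_name(regions, labs)
  vox <- voxel_volume_mm3(regions)
  vol_named <- vapply(labs, function(l) sum(regions$data == l), 0) * vox
  vol_none <- sum(regions$data == 0L) * vox
  all_regions <- c(region_names, "none")
  all_vols <- c(vol_named, vol_none)
  rows <- list()
  for (cl in classes) {
    sub <- objects[objects$class == cl, , drop = FALSE]
    total <- nrow(sub)
    cnt <- vapply(all_regions, function(r) sum(sub$region == r), 0)
    rows[[cl]] <- data.frame(
      region = all_regions,
      region_volume_mm3 = all_vols,
      class = cl,
      count = as.integer(cnt),
      density_per_mm3 = ifelse(all_vols > 0, cnt / all_vols, NA_real_),
      fraction = if (total > 0) cnt / total else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation of two classes' densities across regions
#'
#' Pearson or Spearman correlation between the per-region densities of two
#' object classes — the statistic behind "TLS density is positively
#' correlated with metastasis density". The background region "none" is
#' excluded by default since its volume is not an organ.
#'
#' @param region_table output of [region_summary()] containing both classes.
#' @param class_a,class_b class names.
#' @param method `"pearson"` or `"spearman"`.
#' @param include_none include the "none" background region.
#' @return list with `estimate`, `p_value`, `method`, `n_regions`.
#' @export
density_correlation <- function(region_table, class_a, class_b,
                                method = c("pearson", "spearman"),
                                include_none = FALSE) {
  method <- match.arg(method)
  tab <- region_table
  if (!include_none) tab <- tab[tab$region != "none", , drop = FALSE]
  a <- tab[tab$class == class_a, , drop = FALSE]
  b <- tab[tab$class == class_b, , drop = FALSE]
  b <- b[match(a$region, b$region), , drop = FALSE]
  ok <- !is.na(a$density_per_mm3) & !is.na(b$density_per_mm3)
  da <- a$density_per_mm3[ok]
  db <- b$density_per_mm3[ok]
  if (length(da) < 3L) stop("need >= 3 regions with defined densities", call. = FALSE)
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    stop("correlation undefined: zero variance in a density vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(da, db, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method,
       n_regions = length(da))
}

#' Distribution summary with cutoff fractions
#'
#' Mean, s.d., median and the empirical CDF evaluated at the given cutoffs
#' (fraction of values <= cutoff), e.g. "fraction of micrometastases within
#' 0.02 mm³". Missing values are excluded and counted, never imputed.
#'
#' @param values numeric vector (NAs allowed, excluded with a count).
#' @param cutoffs numeric vector of cutoffs in the same units.
#' @return list with `n`, `n_excluded`, `mean`, `sd`, `median`, and
#'   `fraction_below` (named by cutoff).
#' @export
distribution_summary <- function(values, cutoffs = numeric(0)) {
  n_excluded <- sum(is.na(values) | !is.finite(values))
  v <- values[!is.na(values) & is.finite(values)]
  if (length(v) == 0L) stop("no finite values left to summarize", call. = FALSE)
  fb <- vapply(cutoffs, function(ct) mean(v <= ct), 0)
  names(fb) <- format(cutoffs)
  list(n = length(v), n_excluded = n_excluded,
       mean = mean(v), sd = stats::sd(v), median = stats::median(v),
       fraction_below = fb)
}

#' Colocalization ratio of two binary masks
#'
#' Fraction of foreground voxels of `mask_a` whose center lies within
#' `tolerance_um` (physical distance) of some foreground voxel center of
#' `mask_b`; tolerance 0 is the plain voxel-overlap fraction. Monotone
#' non-decreasing in the tolerance.
#'
#' @param mask_a,mask_b binary `label_volume`s sharing geometry.
#' @param tolerance_um physical tolerance in µm (>= 0).
#' @return proportion in `[0, 1]`.
#' @export
colocalization_ratio <- function(mask_a, mask_b, tolerance_um = 0) {
  if (!is_binary_mask(mask_a) || !is_binary_mask(mask_b)) {
    stop("both masks must be binary label_volumes", call. = FALSE)
  }
  assert_same_geometry(mask_a, mask_b, "mask_a and mask_b")
  if (tolerance_um < 0) stop("tolerance_um must be >= 0", call. = FALSE)
  n_a <- sum(mask_a$data)
  if (n_a == 0L) stop("colocalization undefined: mask_a has no foreground", call. = FALSE)
  if (tolerance_um == 0) {
    return(sum(mask_a$data == 1L & mask_b$data == 1L) / n_a)
  }
  if (sum(mask_b$data) == 0L) return(0)
  # exact anisotropic distance transform to mask_b foreground; a tiny
  # relative cushion absorbs floating-point noise at the tolerance boundary
  d2 <- edt_sq_3d(as.integer(mask_b$data), dim(mask_b$data), mask_b$spacing_um)
  dim(d2) <- dim(mask_b$data)
  sum(d2[mask_a$data == 1L] <= tolerance_um^2 * (1 + 1e-12)) / n_a
}
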
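# Independent oracles used across the suite. These deliberately share no
# code with the package: the flood fill is breadth-first over an explicit
# neighbor table, and the nearest-neighbor oracle is a double loop.

# neighbor linear-index table for a given shape/connectivity (0 = invalid)
neighbor_table <- function(shape, connectivity) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= c("6" = 1, "18" = 2, "26" = 3)[as.character(connectivity)], ,
               drop = FALSE]
  n <- prod(shape)
  idx <- arrayInd(seq_len(n), shape)
  nbr <- matrix(0L, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    p <- sweep(idx, 2L, offs[k, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= shape[1] & p[, 2] >= 1 & p[, 2] <= shape[2] &
      p[, 3] >= 1 & p[, 3] <= shape[3]
    lin <- (p[, 1] - 1) + shape[1] * ((p[, 2] - 1) + shape[2] * (p[, 3] - 1)) + 1
    nbr[ok, k] <- as.integer(lin[ok])
  }
  nbr
}

# breadth-first flood-fill labeling; labels in first-voxel raster order
flood_fill_labels <- function(mask_arr, connectivity, nbr = NULL) {
  shape <- dim(mask_arr)
  if (is.null(nbr)) nbr <- neighbor_table(shape, connectivity)
  fg <- as.vector(mask_arr) > 0
  lab <- integer(length(fg))
  cur <- 0L
  for (s in which(fg)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      nb <- as.vector(nbr[frontier, , drop = FALSE])
      nb <- nb[nb > 0L]
      nb <- unique(nb[fg[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  array(lab, shape)
}

# normalize a labeling to first-occurrence order so partitions compare
normalize_labels <- function(lab_arr) {
  v <- as.vector(lab_arr)
  fg <- v > 0
  first <- !duplicated(v[fg])
  map <- integer(max(v, 1L))
  map[v[fg][first]] <- seq_len(sum(first))
  v[fg] <- map[v[fg]]
  array(v, dim(lab_arr))
}

# all-pairs nearest-neighbor oracle: double loop, lowest-id tie break
nn_oracle <- function(sources, targets, exclude_self = FALSE) {
  res <- data.frame(nearest_target_id = rep(NA_integer_, nrow(sources)),
                    distance_um = NA_real_)
  for (i in seq_len(nrow(sources))) {
    best_d <- Inf
    best_id <- NA_integer_
    for (j in seq_len(nrow(targets))) {
      if (exclude_self && sources$object_id[i] == targets$object_id[j] &&
          sources$class[i] == targets$class[j]) next
      d <- sqrt((sources$centroid_z_um[i] - targets$centroid_z_um[j])^2 +
                  (sources$centroid_y_um[i] - targets$centroid_y_um[j])^2 +
                  (sources$centroid_x_um[i] - targets$centroid_x_um[j])^2)
      if (d < best_d || (d == best_d && !is.na(best_id) &&
                         targets$object_id[j] < best_id)) {
        best_d <- d
        best_id <- targets$object_id[j]
      }
    }
    if (is.finite(best_d)) {
      res$nearest_target_id[i] <- best_id
      res$distance_um[i] <- best_d
    }
  }
  res
}

# random fake object table with centroids in a box (µm)
random_object_table <- function(n, class = "generic", extent = c(1000, 1000, 1000)) {
  data.frame(
    object_id = seq_len(n), class = class,
    voxel_count = 1L, volume_mm3 = stats::runif(n, 1e-5, 1e-2),
    centroid_z_um = stats::runif(n, 0, extent[1]),
    centroid_y_um = stats::runif(n, 0, extent[2]),
    centroid_x_um = stats::runif(n, 0, extent[3]),
    stringsAsFactors = FALSE
  )
}

# two-sided 99% binomial interval for an empirical proportion
binom99 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(p - stats::qnorm(0.995) * se, p + stats::qnorm(0.995) * se)
}

# small anisotropic test spacing used throughout
SPACING <- c(10, 6.5, 6.5)
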
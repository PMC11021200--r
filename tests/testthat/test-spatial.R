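test_that("nearest-neighbor distances follow the definition on hand cases", {
  s <- random_object_table(1, "metastasis")
  s[1, c("centroid_z_um", "centroid_y_um", "centroid_x_um")] <- c(0, 0, 0)
  t1 <- random_object_table(1, "TLS")
  t1[1, c("centroid_z_um", "centroid_y_um", "centroid_x_um")] <- c(0, 3, 4)
  nn <- nn_distances(s, t1)
  expect_equal(nn$distance_um, 5)
  expect_equal(nn$nearest_target_id, 1L)
  expect_equal(nn$nearest_target_volume_mm3, t1$volume_mm3)

  # a single object against itself has no eligible neighbor
  nn_self <- nn_distances(s, s, exclude_self = TRUE)
  expect_true(is.na(nn_self$distance_um))
  expect_true(is.na(nn_self$nearest_target_id))
  expect_error(nn_distances(s, s), "exclude_self")

  # ties break toward the lower target id
  tt <- random_object_table(2, "TLS")
  tt$centroid_z_um <- c(0, 0)
  tt$centroid_y_um <- c(10, -10)
  tt$centroid_x_um <- c(0, 0)
  tt$object_id <- c(2L, 1L)
  nn_tie <- nn_distances(s, tt)
  expect_equal(nn_tie$nearest_target_id, 1L)
})

test_that("nearest neighbors match the brute-force oracle on random sets", {
  set.seed(10)
  for (rep in 1:3) {
    src <- random_object_table(60, "metastasis")
    tgt <- random_object_table(50, "TLS")
    got <- nn_distances(src, tgt)
    want <- nn_oracle(src, tgt)
    expect_identical(got$nearest_target_id, want$nearest_target_id)
    expect_lt(max(abs(got$distance_um - want$distance_um)), 1e-9)
  }
  # same-class with self exclusion
  src <- random_object_table(40, "TLS")
  got <- nn_distances(src, src, exclude_self = TRUE)
  want <- nn_oracle(src, src, exclude_self = TRUE)
  expect_identical(got$nearest_target_id, want$nearest_target_id)
  expect_lt(max(abs(got$distance_um - want$distance_um)), 1e-9)
})

test_that("distances are invariant under rigid translation", {
  set.seed(11)
  src <- random_object_table(30, "a")
  tgt <- random_object_table(25, "b")
  d0 <- nn_distances(src, tgt)$distance_um
  shift <- c(123.4, -56.7, 89.1)
  for (tab in c("src", "tgt")) {
    x <- get(tab)
    x$centroid_z_um <- x$centroid_z_um + shift[1]
    x$centroid_y_um <- x$centroid_y_um + shift[2]
    x$centroid_x_um <- x$centroid_x_um + shift[3]
    assign(tab, x)
  }
  d1 <- nn_distances(src, tgt)$distance_um
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("volume-distance join carries volumes and handles an empty TLS set", {
  met <- random_object_table(3, "metastasis")
  tls <- random_object_table(2, "TLS")
  nn <- volume_distance_join(met, tls)
  expect_equal(nrow(nn), 3L)
  expect_equal(nn$source_volume_mm3, met$volume_mm3)
  expect_false(any(is.na(nn$distance_um)))

  s <- volume_distance_summary(nn, radius_um = Inf)
  expect_equal(s$n_eligible, 3L)
  expect_equal(s$mean_source_volume_mm3, mean(met$volume_mm3))

  expect_message(nn0 <- volume_distance_join(met, tls[0, ]), "0 eligible")
  expect_true(all(is.na(nn0$distance_um)))
  s0 <- volume_distance_summary(nn0)
  expect_equal(s0$n_eligible, 0L)
  expect_true(is.na(s0$mean_source_volume_mm3))
})

test_that("region summaries count by centroid containment with fractions summing to 1", {
  # two slab regions along y
  arr <- array(0L, c(4, 8, 4))
  arr[, 1:4, ] <- 1L
  arr[, 5:8, ] <- 2L
  regions <- label_volume(arr, c(10, 10, 10),
                          label_names = list("1" = "lung", "2" = "gut"))
  obj <- random_object_table(5, "metastasis", extent = c(40, 40, 40))
  # place all five centroids in lung (y < 40) -> lung fraction 1
  obj$centroid_y_um <- stats::runif(5, 0, 39)
  rs <- region_summary(obj, regions)
  expect_equal(rs$fraction[rs$region == "lung"], 1)
  expect_equal(sum(rs$fraction), 1)
  expect_equal(sum(rs$count), 5L)
  # region volumes from voxel counts (4 x 4 x 4 voxels of 1000 µm³)
  expect_equal(rs$region_volume_mm3[rs$region == "lung"], 64 * 1e3 / 1e9)
  # an object outside all regions goes to "none", never dropped
  obj$centroid_y_um[1] <- 500  # outside the grid entirely
  rs2 <- region_summary(obj, regions)
  expect_equal(rs2$count[rs2$region == "none"], 1L)
  expect_equal(sum(rs2$fraction), 1)
  # empty table: counts 0 and NA fractions
  rs3 <- region_summary(obj[0, ], regions, classes = "metastasis")
  expect_true(all(rs3$count == 0L))
  # densities are 0 wherever a region has volume; "none" here has none
  with_vol <- rs3$region_volume_mm3 > 0
  expect_true(all(rs3$density_per_mm3[with_vol] == 0))
})

test_that("density correlation matches the textbook formulas", {
  tab <- data.frame(
    region = rep(letters[1:10], 2),
    region_volume_mm3 = 1,
    class = rep(c("metastasis", "TLS"), each = 10),
    count = 0L,
    density_per_mm3 = c(1:10, 2 * (1:10)),
    fraction = 0.1
  )
  r <- density_correlation(tab, "metastasis", "TLS", "pearson")
  expect_equal(r$estimate, 1)

  set.seed(12)
  da <- stats::rnorm(10)
  db <- stats::rnorm(10)
  tab$density_per_mm3 <- c(da, db)
  r2 <- density_correlation(tab, "metastasis", "TLS", "pearson")
  r_hand <- sum((da - mean(da)) * (db - mean(db))) /
    sqrt(sum((da - mean(da))^2) * sum((db - mean(db))^2))
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(r2$estimate, r_hand, tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * stats::pt(-abs(t_hand), 8), tolerance = 1e-12)

  # spearman: reversed ranks give -1
  tab$density_per_mm3 <- c(1:10, 10:1)
  r3 <- density_correlation(tab, "metastasis", "TLS", "spearman")
  expect_equal(r3$estimate, -1)

  tab$density_per_mm3 <- c(rep(1, 10), 1:10)
  expect_error(density_correlation(tab, "metastasis", "TLS"), "zero variance")
  expect_error(density_correlation(tab[c(1, 11), ], "metastasis", "TLS"), ">= 3")
})

test_that("distribution summaries evaluate the empirical CDF at cutoffs", {
  s <- distribution_summary(c(1, 2, 3, 4), cutoffs = 2)
  expect_equal(unname(s$fraction_below), 0.5)
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)

  s2 <- distribution_summary(rep(7, 5), cutoffs = 7)
  expect_equal(unname(s2$fraction_below), 1)

  s3 <- distribution_summary(c(1, NA, 3), cutoffs = c(0, 2, 5))
  expect_equal(s3$n_excluded, 1L)
  expect_equal(unname(s3$fraction_below), c(0, 0.5, 1))
  expect_error(distribution_summary(c(NA_real_, NA_real_)), "no finite")

  # log-normal sample vs analytic CDF
  set.seed(13)
  meanlog <- log(0.002)
  sdlog <- 0.8
  v <- stats::rlnorm(4000, meanlog, sdlog)
  s4 <- distribution_summary(v, cutoffs = 0.02)
  expect_equal(unname(s4$fraction_below),
               stats::plnorm(0.02, meanlog, sdlog), tolerance = 0.03)
})

test_that("colocalization ratios cover extremes, half overlap and tolerance growth", {
  full <- label_volume(array(1L, c(6, 6, 6)), c(10, 10, 10))
  empty <- label_volume(array(0L, c(6, 6, 6)), c(10, 10, 10))
  expect_equal(colocalization_ratio(full, full), 1)
  expect_error(colocalization_ratio(empty, full), "no foreground")

  # disjoint slabs beyond tolerance
  a <- array(0L, c(6, 6, 6)); a[1:2, , ] <- 1L
  b <- array(0L, c(6, 6, 6)); b[5:6, , ] <- 1L
  la <- label_volume(a, c(10, 10, 10)); lb <- label_volume(b, c(10, 10, 10))
  expect_equal(colocalization_ratio(la, lb, 0), 0)
  expect_equal(colocalization_ratio(la, lb, 15), 0)

  # half-overlapping slabs at tolerance 0
  h1 <- array(0L, c(4, 4, 4)); h1[1:2, , ] <- 1L
  h2 <- array(0L, c(4, 4, 4)); h2[2:3, , ] <- 1L
  expect_equal(colocalization_ratio(label_volume(h1, c(10, 10, 10)),
                                    label_volume(h2, c(10, 10, 10)), 0), 0.5)

  # monotone non-decreasing in tolerance on a nested fixture
  set.seed(14)
  m1 <- array(as.integer(stats::runif(6^3) < 0.3), c(6, 6, 6))
  m2 <- array(0L, c(6, 6, 6)); m2[3, 3, 3] <- 1L
  lv1 <- label_volume(m1, c(10, 6.5, 6.5)); lv2 <- label_volume(m2, c(10, 6.5, 6.5))
  ratios <- vapply(c(0, 7, 13, 20, 40, 80),
                   function(tol) colocalization_ratio(lv1, lv2, tol), 0)
  expect_true(all(diff(ratios) >= 0))
  expect_equal(ratios[length(ratios)], 1)
})

test_that("the distance transform behind tolerant colocalization is exact", {
  set.seed(15)
  sp <- c(10, 6.5, 6.5)
  b <- array(as.integer(stats::runif(10 * 12 * 14) < 0.05), c(10, 12, 14))
  d2 <- clearvol:::edt_sq_3d(as.integer(b), dim(b), sp)
  dim(d2) <- dim(b)
  idx <- which(b == 1L, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, sp, "*"), 2, sp / 2, "+")
  # brute-force minimal squared distance at 100 random voxels
  for (i in sample(prod(dim(b)), 100)) {
    ai <- arrayInd(i, dim(b))
    p <- as.numeric((ai - 1) * sp + sp / 2)
    want <- min(colSums((t(pts) - p)^2))
    expect_equal(d2[i], want, tolerance = 1e-9)
  }
})
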
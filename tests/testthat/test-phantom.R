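test_that("phantom configuration is validated", {
  expect_s3_class(phantom_config(), "phantom_config")
  expect_error(phantom_config(spacing_um = c(10, 0, 10)), "spacing")
  expect_error(phantom_config(n_metastases = -1), "counts")
  expect_error(phantom_config(met_volume_lognormal = c(0.002, -1)), "log_sd")
  expect_error(phantom_config(noise_sd = -0.1), "noise_sd")
  expect_error(phantom_config(attenuation_per_um = -1), "attenuation")
  expect_error(
    phantom_config(region_priors = list(metastasis = c(lung = 0.5, gut = 0.4),
                                        TLS = c(lung = 1))),
    "summing to 1"
  )
  # TLS prior naming a region absent from the region volume
  expect_error(
    generate_object_phantom(phantom_config(
      n_metastases = 0, n_tls = 0,
      region_priors = list(metastasis = c(lung = 1), TLS = c(brain = 1))
    )),
    "absent"
  )
})

test_that("empty phantom and determinism contracts hold", {
  cfg <- phantom_config(n_metastases = 0, n_tls = 0, seed = 5)
  ph <- generate_object_phantom(cfg)
  expect_equal(nrow(ph$truth$objects), 0L)
  expect_true(all(ph$annotation$metastasis$data == 0L))
  expect_true(all(ph$annotation$TLS$data == 0L))

  cfg <- phantom_config(grid_shape = c(32, 48, 48), n_metastases = 4, n_tls = 3,
                        met_volume_lognormal = c(2e-4, 0.3),
                        tls_volume_lognormal = c(1e-4, 0.3), seed = 11)
  ph1 <- generate_object_phantom(cfg)
  ph2 <- generate_object_phantom(cfg)
  expect_identical(ph1$annotation$metastasis$data, ph2$annotation$metastasis$data)
  expect_identical(ph1$intensity$TLS$data, ph2$intensity$TLS$data)
  expect_identical(ph1$truth$objects, ph2$truth$objects)

  cfg3 <- phantom_config(grid_shape = c(32, 48, 48), n_metastases = 4, n_tls = 3,
                         met_volume_lognormal = c(2e-4, 0.3),
                         tls_volume_lognormal = c(1e-4, 0.3), seed = 12)
  ph3 <- generate_object_phantom(cfg3)
  expect_false(identical(ph1$truth$objects, ph3$truth$objects))
})

test_that("a single isotropic ellipsoid recovers the analytic sphere volume", {
  # one metastasis, radius ~50 µm, spacing 10 µm: V = 4/3*pi*0.05^3 mm^3
  target_v <- 4 / 3 * pi * 0.05^3
  cfg <- phantom_config(grid_shape = c(24, 24, 24), spacing_um = c(10, 10, 10),
                        n_metastases = 1, n_tls = 0,
                        met_volume_lognormal = c(target_v, 0),
                        region_priors = list(metastasis = c(all = 1),
                                             TLS = c(all = 1)),
                        noise_sd = 0, seed = 3)
  ph <- generate_object_phantom(cfg)
  tr <- ph$truth$objects
  expect_equal(tr$true_volume_mm3, target_v, tolerance = 1e-12)
  vox_v <- sum(ph$annotation$metastasis$data > 0L) * 1e3 / 1e9
  # discretization tolerance at radius/spacing = 5
  expect_lt(abs(vox_v - target_v) / target_v, 0.10)
})

test_that("voxelized volume converges to truth as spacing shrinks", {
  target_v <- 4 / 3 * pi * 0.05^3
  errs <- vapply(c(20, 10, 5), function(sp) {
    cfg <- phantom_config(grid_shape = round(c(240, 240, 240) / sp),
                          spacing_um = rep(sp, 3),
                          n_metastases = 1, n_tls = 0,
                          met_volume_lognormal = c(target_v, 0),
                          region_priors = list(metastasis = c(all = 1),
                                               TLS = c(all = 1)),
                          noise_sd = 0, seed = 3)
    ph <- generate_object_phantom(cfg)
    vox_v <- sum(ph$annotation$metastasis$data > 0L) * sp^3 / 1e9
    abs(vox_v - target_v) / target_v
  }, 0)
  expect_lt(errs[3], 0.10)
  expect_lt(errs[3], errs[1])
})

test_that("same-class objects stay separated and recover exact counts", {
  for (seed in 1:5) {
    cfg <- phantom_config(grid_shape = c(48, 72, 72), n_metastases = 10,
                          n_tls = 8,
                          met_volume_lognormal = c(3e-4, 0.3),
                          tls_volume_lognormal = c(2e-4, 0.3),
                          noise_sd = 0, seed = seed)
    ph <- generate_object_phantom(cfg)
    for (cls in c("metastasis", "TLS")) {
      ann <- ph$annotation[[cls]]
      mask <- label_volume((ann$data > 0L) * 1L, ann$spacing_um)
      n <- label_components(mask, 26)$n_components
      expect_equal(n, sum(ph$truth$objects$class == cls))
    }
  }
})

test_that("placement failure reports the overcrowded class", {
  cfg <- phantom_config(grid_shape = c(16, 16, 16), n_metastases = 200,
                        met_volume_lognormal = c(5e-4, 0.1), seed = 1)
  expect_error(generate_object_phantom(cfg), "overcrowded.*metastasis")
})

test_that("region priors are recovered within a 99% binomial interval", {
  n <- 400L
  cfg <- phantom_config(grid_shape = c(100L, 160L, 160L),
                        n_metastases = n, n_tls = 0,
                        met_volume_lognormal = c(3e-5, 0.1),
                        seed = 17)
  ph <- generate_object_phantom(cfg)
  frac <- mean(ph$truth$objects$region == "lung")
  ci <- binom99(0.62, n)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("coupled TLS sit closer to metastases than uncoupled TLS", {
  med_dist <- function(coupling, seed) {
    cfg <- phantom_config(grid_shape = c(48, 72, 72), n_metastases = 12,
                          n_tls = 12,
                          met_volume_lognormal = c(3e-4, 0.2),
                          tls_volume_lognormal = c(2e-4, 0.2),
                          coupling_scale_um = coupling, noise_sd = 0,
                          seed = seed)
    tr <- generate_object_phantom(cfg)$truth$objects
    met <- tr[tr$class == "metastasis", ]
    tls <- tr[tr$class == "TLS", ]
    d2 <- outer(tls$center_z_um, met$center_z_um, "-")^2 +
      outer(tls$center_y_um, met$center_y_um, "-")^2 +
      outer(tls$center_x_um, met$center_x_um, "-")^2
    stats::median(sqrt(apply(d2, 1, min)))
  }
  wins <- sum(vapply(1:8, function(s) {
    med_dist(60, s) < med_dist("uncoupled", s)
  }, TRUE))
  expect_gte(wins, 7)
})

test_that("imaging model follows the closed form and its determinism contract", {
  sp <- c(10, 10, 10)
  v <- volume_grid(array(2.5, c(30, 6, 6)), sp)

  cfg0 <- phantom_config(noise_sd = 0, attenuation_per_um = 0, seed = 1)
  expect_identical(apply_imaging_model(v, cfg0)$data, v$data)

  lam <- 0.003
  cfg <- phantom_config(noise_sd = 0, attenuation_per_um = lam, seed = 1)
  out <- apply_imaging_model(v, cfg)
  depth <- (seq_len(30) - 0.5) * 10
  slice_means <- apply(out$data, 1, mean)
  expect_lt(max(abs(slice_means - 2.5 * exp(-lam * depth))), 1e-9)

  # entry = high attenuates from the other face
  out_hi <- apply_imaging_model(v, cfg, entry = "high")
  expect_equal(apply(out_hi$data, 1, mean), rev(slice_means), tolerance = 1e-12)

  cfgn1 <- phantom_config(noise_sd = 0.1, seed = 1)
  cfgn2 <- phantom_config(noise_sd = 0.1, seed = 2)
  expect_identical(apply_imaging_model(v, cfgn1)$data,
                   apply_imaging_model(v, cfgn1)$data)
  expect_false(identical(apply_imaging_model(v, cfgn1)$data,
                         apply_imaging_model(v, cfgn2)$data))
})

test_that("filament lattice length accounting and dropout behave as stated", {
  cfg <- phantom_config(grid_shape = c(40, 40, 40), spacing_um = c(10, 10, 10),
                        seed = 4)
  expect_error(generate_filament_phantom(cfg, lattice_pitch_um = 15), "unresolvable")
  expect_error(generate_filament_phantom(cfg, 100, dropout_fraction = 1), "dropout")

  full <- generate_filament_phantom(cfg, lattice_pitch_um = 100)
  # truth equals the sum of polyline segment lengths
  f <- full$truth$filaments
  seglen <- vapply(split(f, f$filament_id), function(p) {
    sqrt(sum((p[2, c("z_um", "y_um", "x_um")] - p[1, c("z_um", "y_um", "x_um")])^2))
  }, 0)
  expect_equal(sum(seglen), full$truth$total_length_um, tolerance = 1e-6)

  # dropout removes edges: shorter retained length for every common seed
  for (s in 1:5) {
    cfg_s <- phantom_config(grid_shape = c(40, 40, 40), spacing_um = c(10, 10, 10),
                            seed = s)
    l0 <- generate_filament_phantom(cfg_s, 100, 0)$truth$total_length_um
    l6 <- generate_filament_phantom(cfg_s, 100, 0.6)$truth$total_length_um
    expect_lt(l6, l0)
    expect_equal(l0, full$truth$total_length_um)  # dropout 0 = full lattice
  }
})

test_that("dropout retains the expected edge fraction over many seeds", {
  fracs <- vapply(1:50, function(s) {
    cfg <- phantom_config(grid_shape = c(30, 30, 30), spacing_um = c(10, 10, 10),
                          seed = s)
    l0 <- generate_filament_phantom(cfg, 90, 0)$truth$total_length_um
    l5 <- generate_filament_phantom(cfg, 90, 0.5)$truth$total_length_um
    l5 / l0
  }, 0)
  # mean retained fraction within a 99% interval around 0.5 (the per-edge
  # Bernoulli gives ~144 edges per seed at this geometry)
  n_edges <- 144
  se <- sqrt(0.25 / (n_edges * 50))
  expect_lt(abs(mean(fracs) - 0.5), stats::qnorm(0.995) * se * 1.5)
})

test_that("a single straight tube reports its exact centerline length", {
  cfg <- phantom_config(grid_shape = c(10, 10, 50), spacing_um = c(10, 10, 10),
                        seed = 1)
  # pitch 400 in a 100x100x500 µm grid leaves one lattice line along x
  fil <- generate_filament_phantom(cfg, lattice_pitch_um = 400,
                                   tube_radius_um = 12)
  expect_equal(fil$truth$total_length_um, 400)
  expect_gt(sum(fil$mask$data), 0)
})
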
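#' Default configuration for the end-to-end pipeline
#'
#' Returns the full configuration list the pipeline runs on, with every
#' tunable stated explicitly: the phantom (grid geometry, object counts,
#' volume distributions, coupling, region priors, imaging model), the
#' labeling connectivity, the volume cutoffs reported in distribution
#' summaries (0.02 mm³, the micrometastasis scale), and the filament stage
#' (200 µm cubes, five per condition). Values can be overridden by a YAML
#' file with the same keys.
#'
#' @param seed integer seed applied to every stochastic stage.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(
      grid_shape = c(64L, 128L, 128L),
      spacing_um = c(10, 6.5, 6.5),
      n_metastases = 25L,
      n_tls = 18L,
      met_volume_lognormal = c(0.0008, 0.4),
      tls_volume_lognormal = c(0.0004, 0.4),
      coupling_scale_um = 100,
      noise_sd = 0.02,
      attenuation_per_um = 0
    ),
    connectivity = 26L,
    volume_cutoffs_mm3 = c(0.02),
    filaments = list(
      enabled = TRUE,
      lattice_pitch_um = 100,
      dropout_fraction = 0,
      tube_radius_um = 12,
      edge_um = 200,
      n_cubes = 5L
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file and merges it over [default_pipeline_config()]; keys
#' absent from the file keep their defaults, unknown keys are an error so
#' typos never pass silently.
#'
#' @param path YAML file path.
#' @param seed fallback seed when the file does not set one.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config(seed = seed)
  merge_config(base, user)
}

merge_config <- function(base, user, prefix = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base)) {
      stop(sprintf("unknown config key: %s%s", prefix, nm), call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 prefix = paste0(prefix, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full quantification pipeline on a generated phantom
#'
#' Orchestrates simulate → label → measure → spatial statistics (and
#' optionally the filament density stage) into one reproducible run: all
#' intermediates are written to `out_dir` in the package's file formats,
#' every stochastic stage is seeded from the config seed, and a manifest
#' records each stage's outputs with MD5 content hashes so a rerun with the
#' same configuration can be verified hash-identical. The JSON summary
#' exposes the headline spatial quantities: nearest-neighbor distance
#' summaries (within TLS, within metastases, metastasis→nearest TLS),
#' per-region counts/densities/fractions, the TLS–metastasis density
#' correlation, and volume-distribution summaries.
#'
#' @param config a configuration list ([default_pipeline_config()]), a YAML
#'   file path, or NULL for defaults.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the config's.
#' @return the run manifest (invisibly also written to
#'   `out_dir/manifest.json`); its `summary` element holds the headline
#'   quantities.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  if (is.null(config)) config <- default_pipeline_config()
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- proc.time()[["elapsed"]]
  stages <- list()
  outputs <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages[[name]] <<- list(elapsed_s = proc.time()[["elapsed"]] - t0)
    res
  }
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }

  pc <- do.call(phantom_config, c(config$phantom, list(seed = config$seed)))

  phantom <- stage("simulate", {
    ph <- generate_object_phantom(pc)
    write_volume(ph$intensity$metastasis, emit(file.path(out_dir, "intensity_metastasis.tif")))
    write_volume(ph$intensity$TLS, emit(file.path(out_dir, "intensity_tls.tif")))
    write_volume(ph$annotation$metastasis, emit(file.path(out_dir, "annotation_metastasis.tif")))
    write_volume(ph$annotation$TLS, emit(file.path(out_dir, "annotation_tls.tif")))
    write_volume(ph$regions, emit(file.path(out_dir, "regions.tif")))
    write_table(ph$truth$objects, emit(file.path(out_dir, "truth_objects.csv")))
    ph
  })

  labeled <- stage("label", {
    lapply(phantom$annotation, function(ann) {
      mask <- label_volume((ann$data > 0L) * 1L, ann$spacing_um, ann$origin_um)
      label_components(mask, connectivity = config$connectivity)
    })
  })
  write_volume(labeled$metastasis$labels, emit(file.path(out_dir, "labels_metastasis.tif")))
  write_volume(labeled$TLS$labels, emit(file.path(out_dir, "labels_tls.tif")))

  measured <- stage("measure", {
    met <- measure_objects(labeled$metastasis$labels, "metastasis", phantom$regions)
    tls <- measure_objects(labeled$TLS$labels, "TLS", phantom$regions)
    write_table(met, emit(file.path(out_dir, "objects_metastasis.csv")))
    write_table(tls, emit(file.path(out_dir, "objects_tls.csv")))
    list(met = met, tls = tls)
  })

  summary <- stage("spatial", {
    met <- measured$met
    tls <- measured$tls
    nn_tls_tls <- if (nrow(tls)) nn_distances(tls, tls, exclude_self = TRUE) else NULL
    nn_met_met <- if (nrow(met)) nn_distances(met, met, exclude_self = TRUE) else NULL
    nn_met_tls <- volume_distance_join(met, tls)
    if (!is.null(nn_tls_tls)) write_table(nn_tls_tls, emit(file.path(out_dir, "nn_tls_to_tls.csv")))
    if (!is.null(nn_met_met)) write_table(nn_met_met, emit(file.path(out_dir, "nn_met_to_met.csv")))
    write_table(nn_met_tls, emit(file.path(out_dir, "nn_met_to_tls.csv")))
    regtab <- region_summary(rbind(met, tls), phantom$regions,
                             classes = c("metastasis", "TLS"))
    write_table(regtab, emit(file.path(out_dir, "region_summary.csv")))
    corr <- tryCatch(
      density_correlation(regtab, "metastasis", "TLS", method = "pearson"),
      error = function(e) list(estimate = NA_real_, p_value = NA_real_,
                               method = "pearson", note = conditionMessage(e))
    )
    vds <- volume_distance_summary(nn_met_tls)
    list(
      n_metastases = nrow(met),
      n_tls = nrow(tls),
      metastasis_volume = summarize_or_null(met$volume_mm3, config$volume_cutoffs_mm3),
      tls_volume = summarize_or_null(tls$volume_mm3, config$volume_cutoffs_mm3),
      nn_tls_to_tls_um = nn_summary(nn_tls_tls),
      nn_met_to_met_um = nn_summary(nn_met_met),
      nn_met_to_tls_um = nn_summary(nn_met_tls),
      nn_met_to_tls_mm = scale_nn_summary(nn_summary(nn_met_tls), 1e-3),
      volume_distance = list(n_eligible = vds$n_eligible,
                             n_excluded = vds$n_excluded,
                             mean_met_volume_mm3 = vds$mean_source_volume_mm3),
      region_fractions = split(
        stats::setNames(regtab$fraction, regtab$region), regtab$class),
      density_correlation = list(estimate = corr$estimate, p_value = corr$p_value,
                                 method = corr$method)
    )
  })

  if (isTRUE(config$filaments$enabled)) {
    summary$filaments <- stage("filaments", {
      fc <- config$filaments
      fil <- generate_filament_phantom(pc, lattice_pitch_um = fc$lattice_pitch_um,
                                       dropout_fraction = fc$dropout_fraction,
                                       tube_radius_um = fc$tube_radius_um)
      write_volume(fil$mask, emit(file.path(out_dir, "filament_mask.tif")))
      samples <- sample_subvolumes(fil$mask, edge_um = fc$edge_um,
                                   n = fc$n_cubes, seed = config$seed)
      q <- quantify_subvolumes(samples)
      write_table(q, emit(file.path(out_dir, "filament_samples.csv")))
      list(
        true_total_length_um = fil$truth$total_length_um,
        n_cubes = nrow(q),
        mean_density_mm_per_mm3 = mean(q$density_mm_per_mm3),
        sd_density_mm_per_mm3 = stats::sd(q$density_mm_per_mm3)
      )
    })
  }

  jsonlite::write_json(summary, emit(file.path(out_dir, "summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  sidecars <- paste0(outputs[grepl("\\.tif$", outputs)], ".json")
  all_files <- c(outputs, sidecars)
  manifest <- list(
    tool = "clearvol",
    version = as.character(utils::packageVersion("clearvol")),
    seed = config$seed,
    config_echo = config,
    stages = stages,
    outputs = data.frame(
      file = basename(all_files),
      md5 = unname(tools::md5sum(all_files)),
      stringsAsFactors = FALSE
    ),
    elapsed_s = proc.time()[["elapsed"]] - t_all,
    summary = summary
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
    dataframe = "rows"
  )
  invisible(manifest)
}

summarize_or_null <- function(values, cutoffs) {
  if (length(values) == 0L) return(list(n = 0))
  s <- distribution_summary(values, cutoffs)
  s$fraction_below <- as.list(s$fraction_below)
  s
}

nn_summary <- function(nn) {
  if (is.null(nn)) return(list(n = 0, n_missing = 0))
  d <- nn$distance_um
  miss <- sum(is.na(d))
  d <- d[!is.na(d)]
  if (length(d) == 0L) {
    return(list(n = 0, n_missing = miss, note = "0 eligible neighbors"))
  }
  list(n = length(d), n_missing = miss,
       mean = mean(d), sd = stats::sd(d), median = stats::median(d))
}

scale_nn_summary <- function(s, factor) {
  for (k in c("mean", "sd", "median")) {
    if (!is.null(s[[k]])) s[[k]] <- s[[k]] * factor
  }
  s
}
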
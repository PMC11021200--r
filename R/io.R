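#' Read and write volumes as multi-page TIFF with a geometry sidecar
#'
#' Volumes are stored as multi-page TIFF, one page per z-slice in ascending
#' z order, with page rows = y and columns = x (axis order (z, y, x) is
#' never silently reordered). Physical geometry — voxel spacing, origin,
#' kind, value scaling and region names — travels in a JSON sidecar at
#' `<path>.json`, written and read automatically.
#'
#' Label volumes round-trip exactly (stored as 16- or 32-bit integers).
#' Intensity volumes are stored as 32-bit samples with a recorded affine
#' rescaling to the TIFF unit range, so their round-trip is exact to about
#' 1e-9 of the value range (single-precision-grade); this is far below any
#' microscope's dynamic range and is documented rather than hidden.
#'
#' @param vol a `volume_grid` or `label_volume`.
#' @param path TIFF file path (sidecar written at `<path>.json`).
#' @param kind `"intensity"` or `"label"`; must match what was written.
#' @param spacing_um,origin_um geometry override when no sidecar exists;
#'   reading a file without sidecar and without an explicit spacing is an
#'   error (isotropy is never silently assumed).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a
#'   `volume_grid` or `label_volume`.
#' @export
write_volume <- function(vol, path) {
  d <- dim(vol$data)
  meta <- list(
    axis_order = "zyx",
    shape = d,
    spacing_um = vol$spacing_um,
    origin_um = vol$origin_um
  )
  if (inherits(vol, "label_volume")) {
    mx <- max(vol$data)
    bits <- if (mx <= 65535L) 16L else 32L
    denom <- 2^bits - 1
    pages <- lapply(seq_len(d[1]), function(k) {
      matrix(vol$data[k, , ], d[2], d[3]) / denom
    })
    meta$kind <- "label"
    meta$scale <- denom
    if (!is.null(vol$label_names)) meta$label_names <- vol$label_names
    tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  } else {
    vmin <- min(vol$data)
    vmax <- max(vol$data)
    rng <- if (vmax > vmin) vmax - vmin else 1
    pages <- lapply(seq_len(d[1]), function(k) {
      (matrix(vol$data[k, , ], d[2], d[3]) - vmin) / rng
    })
    meta$kind <- "intensity"
    meta$vmin <- vmin
    meta$vmax <- vmax
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, kind = c("intensity", "label"),
                        spacing_um = NULL, origin_um = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else NULL
  if (is.null(meta) && is.null(spacing_um)) {
    stop("no geometry sidecar found and no spacing_um given; refusing to assume voxel size",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2])
  arr <- array(0, d)
  for (k in seq_len(d[1])) arr[k, , ] <- pages[[k]]
  sp <- if (!is.null(spacing_um)) as.numeric(spacing_um) else as.numeric(meta$spacing_um)
  org <- if (!is.null(origin_um)) as.numeric(origin_um)
         else if (!is.null(meta$origin_um)) as.numeric(meta$origin_um)
         else sp / 2
  if (kind == "label") {
    denom <- if (!is.null(meta$scale)) meta$scale else 65535
    lab <- arr * denom
    if (max(abs(lab - round(lab))) > 1e-3) {
      stop("file does not contain integer labels: values must be non-negative integers for kind='label'",
           call. = FALSE)
    }
    lab <- round(lab)
    label_volume(array(as.integer(lab), d), sp, org,
                 label_names = meta$label_names)
  } else {
    if (!is.null(meta$vmin)) arr <- arr * (meta$vmax - meta$vmin) + meta$vmin
    volume_grid(arr, sp, org)
  }
}

#' Write and read analysis tables as CSV
#'
#' Tables (object morphometry, nearest-neighbor records, region summaries,
#' subvolume samples) are serialized as CSV with the column order of the
#' data frame, floats at full double precision (15 significant digits), and
#' missing values (e.g. a nearest-neighbor distance when the target class is
#' empty) as empty fields — never sentinel numbers.
#'
#' @param records a data.frame.
#' @param path CSV file path.
#' @return `write_table()` returns `path` invisibly; `read_table()` the
#'   data.frame.
#' @export
write_table <- function(records, path) {
  old <- options(digits = 15)
  on.exit(options(old))
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write table to %s: %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
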
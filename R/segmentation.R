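#' Threshold an intensity volume into a binary mask
#'
#' Fixed or Otsu thresholding; the mask is 1 where intensity >= threshold.
#' The Otsu threshold is computed on a 256-bin histogram of the finite
#' values (maximizing between-class variance), which makes it
#' bit-reproducible across platforms; the threshold actually used is
#' attached to the result as attribute `threshold`.
#'
#' @param volume a `volume_grid`.
#' @param method `"fixed"` or `"otsu"`.
#' @param value intensity threshold, required for `method = "fixed"`.
#' @return binary `label_volume` with attribute `threshold`.
#' @export
threshold_mask <- function(volume, method = c("fixed", "otsu"), value = NULL) {
  stopifnot(inherits(volume, "volume_grid"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || !is.finite(value)) {
      stop("method='fixed' requires a finite threshold value", call. = FALSE)
    }
    thr <- value
  } else {
    thr <- otsu_threshold(volume$data)
  }
  mask <- label_volume((volume$data >= thr) * 1L, volume$spacing_um,
                       volume$origin_um)
  attr(mask, "threshold") <- thr
  mask
}

# classic Otsu on a 256-bin histogram; returns the lower edge of the first
# bin assigned to the upper class
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("Otsu threshold undefined for a constant volume; use method='fixed'",
         call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance for a split after bin k
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b)
  edges[k + 1L]
}

#' Mean-intensity profile along an axis
#'
#' Computes one mean-intensity value per slice along the chosen axis,
#' optionally restricted to a region of interest, with positions measured in
#' µm from the designated entry surface (slice centers at
#' `(i - 0.5) * spacing`). This is the quantitative form of an ImageJ-style
#' profile plot through a stained volume.
#'
#' @param volume a `volume_grid`.
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param entry `"low"` (surface at index 0) or `"high"` (opposite face).
#' @param roi optional binary `label_volume` sharing the volume's geometry;
#'   slices where the ROI is empty get a missing value.
#' @return a `profile_curve`: list with `axis`, `entry`, `positions_um`
#'   (strictly increasing depths) and `values` (one mean per slice).
#' @export
axial_profile <- function(volume, axis = "z", entry = c("low", "high"),
                          roi = NULL) {
  stopifnot(inherits(volume, "volume_grid"))
  entry <- match.arg(entry)
  k <- axis_to_dim(axis)
  if (!is.null(roi)) {
    assert_same_geometry(volume, roi, "volume and roi")
    dat <- volume$data
    dat[roi$data == 0L] <- NA_real_
  } else {
    dat <- volume$data
  }
  means <- apply(dat, k, function(sl) {
    v <- sl[!is.na(sl)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  if (entry == "high") means <- rev(means)
  structure(
    list(axis = axis, entry = entry,
         positions_um = (seq_along(means) - 0.5) * volume$spacing_um[k],
         values = means),
    class = "profile_curve"
  )
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve> axis %s (entry %s), %d slices, depth up to %g um\n",
              x$axis, x$entry, length(x$values), max(x$positions_um)))
  invisible(x)
}

#' Staining penetration depth from a profile
#'
#' Returns the largest depth `d` such that every slice at depth <= `d`
#' stays at or above the threshold — the contiguous above-threshold run
#' from the entry surface, matching the physical notion of a staining
#' front. Returns 0 when the first slice is already below threshold and the
#' full axial extent when no slice is. Missing slice values break the run
#' (an unverifiable slice is not counted as stained).
#'
#' @param profile a `profile_curve` from [axial_profile()].
#' @param threshold intensity threshold (finite).
#' @return penetration depth in µm.
#' @export
penetration_depth <- function(profile, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  v <- profile$values
  pos <- profile$positions_um
  if (length(v) == 0L) stop("empty profile", call. = FALSE)
  below <- is.na(v) | v < threshold
  j <- which(below)[1]
  sp <- if (length(pos) > 1L) pos[2] - pos[1] else 2 * pos[1]
  if (is.na(j)) return(pos[length(pos)] + sp / 2)  # full extent
  if (j == 1L) return(0)
  pos[j - 1L]
}

#' Two-group comparison (unpaired t-test) and k-group ANOVA
#'
#' `group_compare()` performs the classical two-sided unpaired two-sample
#' t-test, pooled-variance by default (`var_equal = FALSE` switches to
#' Welch), and reports each group as mean ± s.d. The degenerate case of
#' zero variance in both groups is defined explicitly: t = 0, p = 1 when
#' the means are equal (no evidence of any difference), otherwise the
#' difference is infinitely many standard errors wide (t = ±Inf, p = 0).
#' `group_compare_anova()` is the one-way ANOVA analogue for more than two
#' groups.
#'
#' @param values_a,values_b numeric measurement vectors, length >= 2 each.
#' @param var_equal pool variances (classical t-test) if `TRUE` (default).
#' @param groups named list of numeric vectors (ANOVA).
#' @return `group_compare()`: list with `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `t`, `df`, `p_value`, `method`.
#'   `group_compare_anova()`: list with `f`, `df1`, `df2`, `p_value` and a
#'   per-group summary data.frame.
#' @export
group_compare <- function(values_a, values_b, var_equal = TRUE) {
  for (v in list(values_a, values_b)) {
    if (length(v) < 2L) stop("each group needs n >= 2", call. = FALSE)
    if (any(!is.finite(v))) stop("group values must be finite", call. = FALSE)
  }
  base <- list(
    n_a = length(values_a), n_b = length(values_b),
    mean_a = mean(values_a), mean_b = mean(values_b),
    sd_a = stats::sd(values_a), sd_b = stats::sd(values_b),
    method = if (var_equal) "pooled t-test" else "Welch t-test"
  )
  if (base$sd_a == 0 && base$sd_b == 0) {
    if (base$mean_a == base$mean_b) {
      return(c(base, list(t = 0, df = base$n_a + base$n_b - 2, p_value = 1)))
    }
    return(c(base, list(t = sign(base$mean_a - base$mean_b) * Inf,
                        df = base$n_a + base$n_b - 2, p_value = 0)))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  c(base, list(t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value))
}

#' @rdname group_compare
#' @export
group_compare_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("group_", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)))
  )
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  list(
    f = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
    p_value = s[["Pr(>F)"]][1],
    groups = data.frame(
      group = names(groups),
      n = lengths(groups),
      mean = vapply(groups, mean, 0),
      sd = vapply(groups, stats::sd, 0)
    )
  )
}
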
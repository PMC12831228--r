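#' Pixel-size calibration from a scale bar
#'
#' @param scale_bar_um Physical scale-bar length in microns.
#' @param scale_bar_px Scale-bar length in pixels.
#' @return A `wl_calibration` list with `um_per_px`.
#' @export
#' @examples
#' calibrate(10, 97.5)
calibrate <- function(scale_bar_um, scale_bar_px) {
  if (!is.numeric(scale_bar_um) || !is.numeric(scale_bar_px) ||
      scale_bar_um <= 0 || scale_bar_px <= 0) {
    abort("scale bar length and pixel count must be positive.")
  }
  structure(list(um_per_px = scale_bar_um / scale_bar_px),
            class = "wl_calibration")
}

#' Multi-channel microscopy image
#'
#' Images are named lists of 2-D numeric matrices (one per channel) sharing
#' dimensions. Pixel `(row, col)` has center coordinates
#' `(x, y) = (col - 0.5, row - 0.5)`, the frame in which ROIs and centers are
#' expressed.
#'
#' @param channels Named list of matrices.
#' @return A `wl_image`.
#' @export
as_image <- function(channels) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("all channels must share dimensions.")
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort("pixel intensities must be non-negative.")
  }
  structure(list(channels = channels, dim = dims[[1]]), class = "wl_image")
}

#' Read / write multi-channel TIFF images
#'
#' Channels are stored as 16-bit pages scaled by 1/65535; intensities are
#' rounded to integers in 0..65535 on write and rescaled on read. Channel
#' names go in a sidecar-free convention: page order is the channel order
#' given at write time, so pass `channel_names` on read.
#'
#' @param path TIFF path.
#' @param channel_names Names for the pages (default `channel_1`, ...).
#' @export
read_image <- function(path, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  mats <- lapply(pages, function(p) round(p * 65535))
  names(mats) <- channel_names %||% paste0("channel_", seq_along(mats))
  as_image(mats)
}

#' @rdname read_image
#' @param image A `wl_image` with integer intensities in 0..65535.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "wl_image"))
  pages <- lapply(image$channels, function(m) {
    if (any(m > 65535)) abort("intensities exceed the 16-bit range.")
    round(m) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Cell ROI polygons
#'
#' ROIs are simple closed polygons given as tibbles of `x`, `y` vertex
#' coordinates (pixel units, image frame of [as_image()]). `read_roi()` /
#' `write_roi()` use a two-column CSV.
#'
#' @param data Data frame with `x` and `y` columns.
#' @return Validated tibble.
#' @export
as_roi <- function(data) {
  data <- as_tibble(data)
  if (!all(c("x", "y") %in% names(data))) abort("ROI needs `x` and `y` columns.")
  if (nrow(data) < 3) abort("ROI polygon needs at least 3 vertices.")
  if (abs(polygon_area(data$x, data$y)) <= 0) abort("ROI polygon has zero area.")
  data
}

#' @rdname as_roi
#' @param path CSV path.
#' @export
read_roi <- function(path) as_roi(readr::read_csv(path, show_col_types = FALSE))

#' @rdname as_roi
#' @param roi ROI tibble.
#' @export
write_roi <- function(roi, path) {
  readr::write_csv(as_roi(roi), path)
  invisible(path)
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# logical mask of pixels whose centers lie inside the polygon
roi_mask <- function(roi, dim) {
  nr <- dim[1]; nc <- dim[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  bnd <- rbind(as.matrix(roi[, c("x", "y")]),
               as.matrix(roi[1, c("x", "y")]))
  inside <- mgcv::in.out(bnd, cbind(cx, cy))
  matrix(inside, nrow = nr, ncol = nc)
}

# normalized radius r = |pixel - center| / |boundary - center| along the
# pixel's own ray, computed by exact segment intersection on the polygon
# (avoids the staircase bias of rasterized boundaries). Parameterizing the
# ray as center + t * (pixel - center) gives r = 1 / t_boundary directly.
normalized_radius <- function(px, py, center, roi) {
  vx <- roi$x; vy <- roi$y
  n <- length(vx)
  ax <- vx; ay <- vy
  bx <- vx[c(2:n, 1)]; by <- vy[c(2:n, 1)]
  ex <- bx - ax; ey <- by - ay
  ux <- px - center[1]; uy <- py - center[2]
  np <- length(ux)
  t_near <- rep(Inf, np)   # min t among intersections at or beyond the pixel
  t_max <- rep(-Inf, np)   # furthest intersection (fallback, non-convex ROIs)
  wx0 <- ax - center[1]; wy0 <- ay - center[2]
  for (i in seq_len(n)) {
    denom <- ux * ey[i] - uy * ex[i]
    ok <- denom != 0
    t <- (wx0[i] * ey[i] - wy0[i] * ex[i]) / denom
    s <- (wx0[i] * uy - wy0[i] * ux) / denom
    valid <- ok & s >= 0 & s < 1 & t > 0
    upd <- valid & t >= 1 - 1e-9 & t < t_near
    t_near[upd] <- t[upd]
    updm <- valid & t > t_max
    t_max[updm] <- t[updm]
  }
  tb <- ifelse(is.finite(t_near), t_near, t_max)
  r <- ifelse(ux == 0 & uy == 0, 0, 1 / tb)
  pmin(r, 1)
}

# shortest distance from a point to any polygon edge
point_edge_distance <- function(p, roi) {
  vx <- roi$x; vy <- roi$y
  n <- length(vx)
  bx <- vx[c(2:n, 1)]; by <- vy[c(2:n, 1)]
  ex <- bx - vx; ey <- by - vy
  len2 <- ex^2 + ey^2
  t <- pmax(0, pmin(1, ((p[1] - vx) * ex + (p[2] - vy) * ey) / len2))
  min(sqrt((vx + t * ex - p[1])^2 + (vy + t * ey - p[2])^2))
}

#' Detect the nuclear center inside a ROI
#'
#' Otsu-thresholds the nuclear channel within the ROI and returns the
#' intensity-weighted centroid of the above-threshold mask. Errors when no
#' pixel exceeds the threshold or when a pathological mask puts the centroid
#' outside the ROI.
#'
#' @param image A `wl_image` or a single matrix.
#' @param roi ROI polygon (see [as_roi()]).
#' @param channel Channel name when `image` is a `wl_image` (default
#'   `"nuclear"`).
#' @return Numeric `c(x, y)` in pixel coordinates.
#' @export
detect_nucleus_center <- function(image, roi, channel = "nuclear") {
  m <- if (inherits(image, "wl_image")) image$channels[[channel]] else image
  if (is.null(m)) abort(sprintf("channel '%s' not found.", channel))
  roi <- as_roi(roi)
  mask <- roi_mask(roi, dim(m))
  v <- m[mask]
  if (length(v) == 0) abort("ROI contains no pixels.")
  rng <- range(v)
  if (diff(rng) == 0) abort("nuclear channel is flat inside the ROI; no signal.")
  v01 <- matrix((v - rng[1]) / diff(rng), ncol = 1)
  thr <- EBImage::otsu(v01, range = c(0, 1)) * diff(rng) + rng[1]
  sel <- mask & m > thr
  if (!any(sel)) abort("no pixel above the nuclear threshold.")
  idx <- which(sel, arr.ind = TRUE)
  w <- m[sel]
  ctr <- c(x = sum((idx[, 2] - 0.5) * w) / sum(w),
           y = sum((idx[, 1] - 0.5) * w) / sum(w))
  bnd <- rbind(as.matrix(roi[, c("x", "y")]), as.matrix(roi[1, c("x", "y")]))
  if (!mgcv::in.out(bnd, matrix(ctr, 1))) {
    abort("nuclear centroid falls outside the ROI (pathological mask).")
  }
  ctr
}

#' Radial intensity profile of one cell
#'
#' For every ROI pixel the normalized radius
#' `r = d(pixel, center) / d(center, boundary along the same ray)` is
#' computed by exact ray-polygon intersection, so non-circular cells map onto
#' `r` in \[0, 1\]. Pixels are then binned into `n_bins` equal-width radius
#' bins and the per-bin mean intensity reported. Empty bins are recorded as
#' missing, not zero. With `radius = "absolute"` binning uses plain Euclidean
#' distance instead (microns when a calibration is given), covering
#' \[0, max distance\].
#'
#' @param image `wl_image` or matrix (signal channel).
#' @param roi ROI polygon.
#' @param center Numeric `c(x, y)`, strictly inside the ROI (e.g. from
#'   [detect_nucleus_center()]).
#' @param n_bins Number of radius bins (default 20).
#' @param channel Channel name when `image` is a `wl_image` (default
#'   `"signal"`).
#' @param radius `"normalized"` (default) or `"absolute"`.
#' @param calibration Optional `wl_calibration`; scales absolute radii to
#'   microns.
#' @param background_percentile Optional percentile (0-100) of in-ROI
#'   intensity subtracted before binning; off by default.
#' @return A `wl_profile` tibble: `bin`, `r_lo`, `r_hi`, `r_mid`,
#'   `mean_intensity`, `n_pixels`; attributes `total_intensity` and
#'   `n_roi_pixels`.
#' @export
radial_profile <- function(image, roi, center, n_bins = 20,
                           channel = "signal",
                           radius = c("normalized", "absolute"),
                           calibration = NULL,
                           background_percentile = NULL) {
  radius <- match.arg(radius)
  m <- if (inherits(image, "wl_image")) image$channels[[channel]] else image
  if (is.null(m)) abort(sprintf("channel '%s' not found.", channel))
  roi <- as_roi(roi)
  bnd <- rbind(as.matrix(roi[, c("x", "y")]), as.matrix(roi[1, c("x", "y")]))
  if (!mgcv::in.out(bnd, matrix(center, 1)) ||
      point_edge_distance(center, roi) < 1e-9) {
    abort("center lies on or outside the ROI boundary.")
  }
  mask <- roi_mask(roi, dim(m))
  idx <- which(mask, arr.ind = TRUE)
  px <- idx[, 2] - 0.5; py <- idx[, 1] - 0.5
  vals <- m[mask]
  if (!is.null(background_percentile)) {
    vals <- vals - quantile(vals, background_percentile / 100)
  }

  if (radius == "normalized") {
    r <- normalized_radius(px, py, center, roi)
    r_max <- 1
  } else {
    r <- sqrt((px - center[1])^2 + (py - center[2])^2)
    if (!is.null(calibration)) r <- r * calibration$um_per_px
    r_max <- max(r)
  }
  bin <- pmax(1L, pmin(n_bins, ceiling(r / r_max * n_bins)))
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(vals[bin == b]), numeric(1))
  out <- tibble(
    bin = seq_len(n_bins),
    r_lo = (seq_len(n_bins) - 1) / n_bins * r_max,
    r_hi = seq_len(n_bins) / n_bins * r_max,
    r_mid = (seq_len(n_bins) - 0.5) / n_bins * r_max,
    mean_intensity = ifelse(counts > 0, sums / counts, NA_real_),
    n_pixels = counts
  )
  structure(out, class = c("wl_profile", class(out)),
            total_intensity = sum(vals), n_roi_pixels = length(vals),
            radius = radius)
}

#' Rotate an image / ROI / center by 90-degree steps
#'
#' Applies the isometry `(x, y) -> (y, W - x)` `k` times to the image matrix,
#' polygon and center together, useful for invariance checks: radial profiles
#' are unchanged under this transform.
#'
#' @param image Matrix or `wl_image`.
#' @param roi ROI polygon tibble.
#' @param center Numeric `c(x, y)`.
#' @param k Number of quarter turns (default 1).
#' @return List with rotated `image`, `roi`, `center`.
#' @export
rotate_cell <- function(image, roi, center, k = 1) {
  rot_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  rot_xy <- function(x, y, W) list(x = y, y = W - x)
  for (i in seq_len(k %% 4)) {
    if (inherits(image, "wl_image")) {
      W <- image$dim[2]
      image <- as_image(lapply(image$channels, rot_mat))
    } else {
      W <- ncol(image)
      image <- rot_mat(image)
    }
    p <- rot_xy(roi$x, roi$y, W)
    roi$x <- p$x; roi$y <- p$y
    cc <- rot_xy(center[1], center[2], W)
    center <- c(cc$x, cc$y)
  }
  list(image = image, roi = roi, center = center)
}

#' Aggregate radial profiles by group with replicate-aware s.e.m.
#'
#' Cell-level bin means are averaged over all cells of a group; the standard
#' error is computed over replicate means (cells nested in biological
#' replicates), matching the error bars of grouped profile plots.
#'
#' @param data Long tibble with one row per cell x bin.
#' @param value,group,replicate,bin Column specifications (tidy evaluation);
#'   defaults `mean_intensity`, `group`, `replicate`, `bin`.
#' @return A `wl_profile_group` tibble: `group`, `bin`, `mean`, `sem`,
#'   `n_cells`, `n_replicates`.
#' @export
aggregate_profiles <- function(data, value = mean_intensity, group = group,
                               replicate = replicate, bin = bin) {
  df <- tibble(
    value = pull(data, {{ value }}),
    group = as.character(pull(data, {{ group }})),
    replicate = pull(data, {{ replicate }}),
    bin = pull(data, {{ bin }})
  )
  rep_means <- df |>
    group_by(.data$group, .data$replicate, .data$bin) |>
    summarise(rep_mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  out <- df |>
    group_by(.data$group, .data$bin) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              n_cells = sum(!is.na(.data$value)), .groups = "drop") |>
    left_join(
      rep_means |>
        group_by(.data$group, .data$bin) |>
        summarise(sem = sd(.data$rep_mean) / sqrt(dplyr::n()),
                  n_replicates = dplyr::n(), .groups = "drop"),
      by = c("group", "bin")
    )
  structure(out, class = c("wl_profile_group", class(out)))
}

#' Normalize group profile curves to a negative control
#'
#' Divides every group's per-bin mean (and s.e.m.) by the control group's
#' per-bin mean, so the control curve is identically 1. Errors if any control
#' bin mean is zero, naming the bin.
#'
#' @param aggregated A `wl_profile_group` from [aggregate_profiles()].
#' @param control Name of the control group.
#' @return The input tibble with added `rel_mean` and `rel_sem` columns.
#' @export
normalize_to_control <- function(aggregated, control) {
  if (!control %in% aggregated$group) {
    abort(sprintf("control group '%s' not found.", control))
  }
  ctrl <- aggregated[aggregated$group == control, c("bin", "mean")]
  names(ctrl)[2] <- "control_mean"
  zero <- ctrl$bin[!is.na(ctrl$control_mean) & ctrl$control_mean == 0]
  if (length(zero)) {
    abort(sprintf("control mean is zero in bin %s.", zero[1]))
  }
  out <- left_join(as_tibble(aggregated), ctrl, by = "bin") |>
    mutate(rel_mean = mean / .data$control_mean,
           rel_sem = .data$sem / .data$control_mean) |>
    select(-"control_mean")
  structure(out, class = c("wl_profile_group", class(out)))
}

#' Per-bin group comparison of radial profiles
#'
#' Delegates to [two_way_anova_bonferroni()] on cell-level bin values:
#' two-way omnibus (group x bin) plus per-bin comparisons against the
#' reference group, Bonferroni-adjusted by the number of bins, with the
#' binary significance flags profile figures display.
#'
#' @inheritParams aggregate_profiles
#' @param ref Reference group (defaults to the first).
#' @return A `wl_anova2` object.
#' @export
compare_profile_groups <- function(data, value = mean_intensity,
                                   group = group, bin = bin, ref = NULL) {
  two_way_anova_bonferroni(data, {{ value }}, {{ group }}, {{ bin }},
                           ref = ref)
}
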
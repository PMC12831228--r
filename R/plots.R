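#' @importFrom ggplot2 ggplot aes geom_step geom_line geom_point geom_ribbon
#'   geom_violin labs theme_minimal autoplot
NULL

#' Plot a Kaplan-Meier curve
#'
#' @param object A `wl_km` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.wl_km <- function(object, ...) {
  d <- bind_rows(tibble(time = 0, survival = 1),
                 as_tibble(object)[, c("time", "survival")])
  ggplot(d, aes(x = .data$time, y = .data$survival)) +
    geom_step() +
    labs(x = "Day", y = "Fraction surviving") +
    theme_minimal()
}

#' Plot a TSS metaprofile comparison
#'
#' Mean signal curves across the TSS window for the two groups.
#' @param object A `wl_metaprofile` from [metaprofile_compare()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.wl_metaprofile <- function(object, ...) {
  ggplot(object$curves,
         aes(x = .data$position, y = .data$mean_signal, color = .data$group)) +
    geom_line() +
    labs(x = "Position relative to TSS (bp)", y = "Mean H3-normalized signal",
         color = NULL) +
    theme_minimal()
}

#' Plot grouped radial profile curves
#'
#' Mean +/- s.e.m. intensity from the nuclear center (r = 0) to the cell
#' periphery (r = 1).
#' @param object A `wl_profile_group` from [aggregate_profiles()] or
#'   [normalize_to_control()].
#' @param relative Plot control-normalized curves if present (default FALSE).
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.wl_profile_group <- function(object, relative = FALSE, ...) {
  d <- as_tibble(object)
  if (relative && "rel_mean" %in% names(d)) {
    d$mean <- d$rel_mean; d$sem <- d$rel_sem
    ylab <- "Intensity relative to control"
  } else ylab <- "Mean intensity"
  n_bins <- max(d$bin)
  d$r <- (d$bin - 0.5) / n_bins
  ggplot(d, aes(x = .data$r, y = .data$mean, color = .data$group,
                fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem),
                alpha = 0.2, color = NA) +
    geom_line() +
    labs(x = "Normalized radius (center → periphery)", y = ylab,
         color = NULL, fill = NULL) +
    theme_minimal()
}

#' Volcano-style plot of differential windows
#'
#' @param object A `wl_diff` from [call_differential_windows()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.wl_diff <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$log2_ratio, y = -log10(pmax(.data$p_value, 1e-300)),
                color = .data$called)) +
    geom_point(size = 0.8) +
    labs(x = "log2 ratio (treated / control)", y = "-log10 p", color = "called") +
    theme_minimal()
}
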
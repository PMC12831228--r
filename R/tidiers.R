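#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for test and analysis objects
#'
#' `tidy()` returns one row per comparison, `glance()` a one-row model
#' summary, following the broom convention.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name wormlegacy-tidiers
NULL

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::tidy
tidy.wl_test <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df[1],
         df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p_value, method = x$method)
}

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::tidy
tidy.wl_fisher <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p_value = x$p_value, k = x$k,
         method = x$method)
}

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::tidy
tidy.wl_anova <- function(x, ...) x$pairwise

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::glance
glance.wl_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df[1], df2 = x$df[2],
         p_value = x$p_value)
}

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::tidy
tidy.wl_anova2 <- function(x, ...) x$per_bin

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::glance
glance.wl_anova2 <- function(x, ...) {
  o <- x$omnibus
  tibble(f_group = o$statistic[o$term == "group"],
         p_group = o$p_value[o$term == "group"],
         n_bins = x$n_bins,
         n_significant = sum(x$per_bin$significant, na.rm = TRUE))
}

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::tidy
tidy.wl_lifespan <- function(x, ...) x$replicates

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::glance
glance.wl_lifespan <- function(x, ...) {
  tibble(treated = x$treated, control = x$control,
         n_replicates = nrow(x$replicates),
         mean_treated = x$mean_treated, mean_control = x$mean_control,
         mean_extension_pct = x$mean_extension_pct,
         mean_extension_pct_replicates = x$mean_extension_pct_replicates,
         chi2 = x$combined$chi2, df = x$combined$df,
         p_combined = x$combined$p_value)
}

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::tidy
tidy.wl_tss_matrix <- function(x, ...) {
  as_tibble(x$signal, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "bin", values_to = "signal") |>
    mutate(bin = as.integer(sub("^V", "", .data$bin)),
           position = x$positions[.data$bin])
}

#' @rdname wormlegacy-tidiers
#' @exportS3Method generics::tidy
tidy.wl_motif_scan <- function(x, ...) x$summary
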
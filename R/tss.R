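#' Validate a gene annotation table
#'
#' Annotations are BED-like tibbles with columns `gene_id`, `chrom`, `start`,
#' `end` (0-based half-open) and `strand` (`+`/`-`). The transcription start
#' site (TSS) is `start` for `+` genes and `end` for `-` genes.
#'
#' @param data Data frame.
#' @return Validated tibble.
#' @export
as_annotation <- function(data) {
  data <- as_tibble(data)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("annotation is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(data$start >= data$end)) abort("annotation requires start < end.")
  if (!all(data$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  if (anyDuplicated(data$gene_id)) abort("gene ids must be unique.")
  data
}

annotation_tss <- function(ann) {
  ifelse(ann$strand == "+", ann$start, ann$end)
}

#' TSS-centered signal matrix
#'
#' Bins the (typically H3-normalized) signal into fixed-width bins across a
#' window of `2 * half_width` bp centered on every gene's TSS. Windows of `-`
#' strand genes are reversed so that bin 1 is always biological upstream.
#' Genes whose window does not fit inside the chromosome are dropped (count
#' reported via a message and the `dropped` attribute).
#'
#' @param track Ratio (or raw) `wl_track`.
#' @param annotation Annotation tibble (see [as_annotation()]).
#' @param half_width Window half-width in bp (default 1000, i.e. TSS +/- 1 kb).
#' @param bin_width Bin width in bp (default 50); must divide `2 * half_width`.
#' @return A `wl_tss_matrix`: list with `signal` (genes x bins matrix of
#'   per-bin mean signal), `positions` (bin centers relative to the TSS,
#'   upstream negative), `half_width`, `bin_width`, `dropped`.
#' @export
tss_signal_matrix <- function(track, annotation, half_width = 1000,
                              bin_width = 50) {
  ann <- as_annotation(annotation)
  if (nrow(ann) == 0) abort("empty annotation.")
  n_bins <- 2 * half_width / bin_width
  if (n_bins != round(n_bins)) abort("`bin_width` must divide 2 * half_width.")
  n_bins <- as.integer(n_bins)
  sl <- track_seqlengths(track)
  vecs <- expand_track(track)

  tss <- annotation_tss(ann)
  ok <- ann$chrom %in% names(sl) &
    tss - half_width >= 0 &
    tss + half_width <= sl[ann$chrom]
  dropped <- sum(!ok)
  if (dropped > 0) inform(sprintf("%d gene(s) dropped: window outside chromosome.", dropped))
  ann <- ann[ok, ]; tss <- tss[ok]
  if (nrow(ann) == 0) abort("no gene window fits inside the genome.")

  sig <- matrix(NA_real_, nrow = nrow(ann), ncol = n_bins,
                dimnames = list(ann$gene_id, NULL))
  for (i in seq_len(nrow(ann))) {
    v <- vecs[[ann$chrom[i]]][(tss[i] - half_width + 1):(tss[i] + half_width)]
    bins <- colMeans(matrix(v, nrow = bin_width))
    if (ann$strand[i] == "-") bins <- rev(bins)
    sig[i, ] <- bins
  }
  structure(
    list(signal = sig,
         positions = seq(-half_width + bin_width / 2, half_width - bin_width / 2,
                         by = bin_width),
         half_width = half_width, bin_width = bin_width, dropped = dropped),
    class = "wl_tss_matrix"
  )
}

#' @export
print.wl_tss_matrix <- function(x, ...) {
  cat("TSS signal matrix:", nrow(x$signal), "genes x", ncol(x$signal),
      "bins (", x$bin_width, "bp bins, +/-", x$half_width, "bp )\n")
  invisible(x)
}

#' Compare two TSS metaprofiles
#'
#' Bin-wise mean curves for two TSS signal matrices (e.g. treated vs control)
#' plus per-gene window-mean signals compared with the two-sample rank-sum
#' test, the violin-plot comparison used for TSS-proximal mark deposition.
#'
#' @param a,b `wl_tss_matrix` objects with identical binning.
#' @param labels Length-2 character vector naming the two matrices.
#' @return A `wl_metaprofile`: `$curves` (tibble `position`, `group`,
#'   `mean_signal`), `$gene_means` (tibble `group`, `gene_id`, `mean_signal`),
#'   `$medians` (named), `$test` (`wl_test` from [rank_sum_test()]).
#' @export
metaprofile_compare <- function(a, b, labels = c("a", "b")) {
  stopifnot(inherits(a, "wl_tss_matrix"), inherits(b, "wl_tss_matrix"))
  if (a$half_width != b$half_width || a$bin_width != b$bin_width) {
    abort("matrices have different binning.")
  }
  ga <- rowMeans(a$signal); gb <- rowMeans(b$signal)
  curves <- bind_rows(
    tibble(position = a$positions, group = labels[1],
           mean_signal = colMeans(a$signal)),
    tibble(position = b$positions, group = labels[2],
           mean_signal = colMeans(b$signal))
  )
  gene_means <- bind_rows(
    tibble(group = labels[1], gene_id = names(ga), mean_signal = unname(ga)),
    tibble(group = labels[2], gene_id = names(gb), mean_signal = unname(gb))
  )
  structure(
    list(curves = curves, gene_means = gene_means,
         medians = setNames(c(median(ga), median(gb)), labels),
         test = rank_sum_test(ga, gb, exact_limit = 0), labels = labels),
    class = "wl_metaprofile"
  )
}

#' @export
print.wl_metaprofile <- function(x, ...) {
  cat("TSS metaprofile comparison (", paste(x$labels, collapse = " vs "), ")\n", sep = "")
  cat("  medians:", paste(sprintf("%s = %.4g", names(x$medians), x$medians),
                          collapse = ", "), "\n")
  print(x$test)
  invisible(x)
}
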
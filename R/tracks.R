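#' Coverage tracks
#'
#' A coverage track is a tibble of 0-based half-open intervals
#' (`chrom`, `start`, `end`, `depth`) with metadata attributes (`mark`,
#' `condition`, `replicate`, `seqlengths`). Intervals are kept sorted and
#' non-overlapping; adjacent runs of equal depth are merged, and zero-depth
#' runs are implicit (absent intervals read as depth 0 up to the chromosome
#' length).
#'
#' `as_track()` builds a track from a data frame; overlapping input intervals
#' are repaired (a later interval is trimmed to start where the previous one
#' ends) with a warning, and negative depths are an error. `load_track()` and
#' `write_track()` read/write 4-column bedGraph via rtracklayer.
#'
#' @param data Data frame with columns `chrom`, `start`, `end`, `depth` (or
#'   `score`).
#' @param mark,condition,replicate Metadata labels.
#' @param seqlengths Named vector of chromosome lengths; defaults to the
#'   maximum `end` per chromosome.
#' @return A `wl_track` tibble.
#' @export
as_track <- function(data, mark = NA_character_, condition = NA_character_,
                     replicate = NA_character_, seqlengths = NULL) {
  data <- as_tibble(data)
  if ("score" %in% names(data) && !"depth" %in% names(data)) {
    names(data)[names(data) == "score"] <- "depth"
  }
  need <- c("chrom", "start", "end", "depth")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("track is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(data$depth < 0)) abort("track depths must be non-negative.")
  if (any(data$end <= data$start)) abort("intervals must satisfy start < end.")
  data <- arrange(data, .data$chrom, .data$start, .data$end)

  # repair overlaps within each chromosome: trim the later interval
  repaired <- FALSE
  parts <- if (nrow(data)) split(data, data$chrom) else list(data)
  parts <- lapply(parts, function(d) {
    if (nrow(d) > 1) {
      hi <- cummax(c(0L, d$end[-nrow(d)]))
      bad <- d$start < hi
      if (any(bad)) {
        repaired <<- TRUE
        d$start[bad] <- pmin(hi[bad], d$end[bad])
        d <- d[d$start < d$end, ]
      }
    }
    d
  })
  data <- bind_rows(parts)
  if (repaired) warn("overlapping intervals repaired (later intervals trimmed).")

  data <- data[data$depth != 0, ]
  if (is.null(seqlengths)) {
    seqlengths <- tapply(data$end, data$chrom, max)
    seqlengths <- setNames(as.numeric(seqlengths), names(seqlengths))
  }

  # merge adjacent equal-depth runs (vectorized: first/last row of each run)
  if (nrow(data) > 1) {
    n <- nrow(data)
    same <- data$chrom[-1] == data$chrom[-n] &
      data$start[-1] == data$end[-n] &
      data$depth[-1] == data$depth[-n]
    first <- c(TRUE, !same)
    last <- c(!same, TRUE)
    data <- tibble(chrom = data$chrom[first], start = data$start[first],
                   end = data$end[last], depth = data$depth[first])
  }

  structure(data, class = c("wl_track", class(data)),
            mark = mark, condition = condition, replicate = replicate,
            seqlengths = seqlengths)
}

#' @rdname as_track
#' @param path bedGraph file path.
#' @export
load_track <- function(path, mark = NA_character_, condition = NA_character_,
                       replicate = NA_character_, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  as_track(
    tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr),
           depth = gr$score),
    mark = mark, condition = condition, replicate = replicate,
    seqlengths = seqlengths
  )
}

#' @rdname as_track
#' @param track A `wl_track`.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "wl_track"))
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

track_seqlengths <- function(track) attr(track, "seqlengths")

#' Expand a track to per-base depth vectors
#'
#' @param track A `wl_track`.
#' @return Named list (per chromosome) of per-base numeric depth vectors of
#'   length `seqlengths`.
#' @keywords internal
expand_track <- function(track) {
  sl <- track_seqlengths(track)
  out <- lapply(names(sl), function(ch) {
    v <- numeric(sl[[ch]])
    d <- track[track$chrom == ch, ]
    if (nrow(d)) {
      len <- d$end - d$start
      idx <- sequence(len, from = d$start + 1)
      v[idx] <- rep(d$depth, len)
    }
    v
  })
  setNames(out, names(sl))
}

per_base_to_track <- function(vectors, ...) {
  rows <- purrr::map_dfr(names(vectors), function(ch) {
    r <- rle(vectors[[ch]])
    ends <- cumsum(r$lengths)
    tibble(chrom = ch, start = ends - r$lengths, end = ends, depth = r$values)
  })
  sl <- vapply(vectors, length, numeric(1))
  as_track(rows[rows$depth != 0, ], seqlengths = sl, ...)
}

#' Genome-wide mean depth of a track
#'
#' Mean per-base depth over the whole genome (uncovered bases count as 0).
#' @param track A `wl_track`.
#' @return A single number.
#' @export
track_mean_depth <- function(track) {
  sum(track$depth * (track$end - track$start)) / sum(track_seqlengths(track))
}

#' Rescale a track to unit background depth
#'
#' Depth scaling used before ratio normalization so that conditions sequenced
#' to different depths are comparable (no spike-ins assumed). The default
#' `"background"` statistic divides by the median of 1-kb-window mean depths,
#' which is robust to localized enrichment: a mark with strong peaks over a
#' fraction of the genome would otherwise have its background diluted by its
#' own signal (composition bias), distorting cross-condition ratios.
#' `"mean"` divides by the plain genome-wide mean instead.
#'
#' @param track A `wl_track`.
#' @param stat `"background"` (default) or `"mean"`.
#' @param bg_window Window size in bp for the background statistic
#'   (default 1000).
#' @return The rescaled `wl_track`.
#' @export
scale_track <- function(track, stat = c("background", "mean"),
                        bg_window = 1000) {
  stat <- match.arg(stat)
  m <- if (stat == "mean") {
    track_mean_depth(track)
  } else {
    w <- tile_genome(track_seqlengths(track), bg_window)
    median(window_means(track, w))
  }
  if (m == 0) abort("cannot depth-scale an empty track.")
  out <- track
  out$depth <- out$depth / m
  out
}

#' Normalize a histone-mark track to total H3
#'
#' Per-base ratio `mark / (h3 + pseudocount)` after depth-scaling both tracks
#' to genome-wide mean 1. Bases with no mark signal get ratio 0 regardless of
#' the denominator; the pseudocount keeps uncovered-H3 bases from blowing up
#' the ratio.
#'
#' @param mark,h3 `wl_track` objects over the same chromosome universe.
#' @param pseudocount Positive pseudocount added to the (scaled) H3 depth
#'   (default 0.5).
#' @param rescale Depth-scale both tracks first with [scale_track()]
#'   (default `TRUE`, background statistic).
#' @return A ratio `wl_track` (mark label suffixed with "/H3").
#' @export
normalize_mark_to_h3 <- function(mark, h3, pseudocount = 0.5, rescale = TRUE) {
  stopifnot(inherits(mark, "wl_track"), inherits(h3, "wl_track"))
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  slm <- track_seqlengths(mark); slh <- track_seqlengths(h3)
  if (!identical(sort(names(slm)), sort(names(slh)))) {
    abort("mark and H3 tracks cover different chromosomes.")
  }
  if (rescale) {
    mark <- scale_track(mark)
    h3 <- scale_track(h3)
  }
  vm <- expand_track(mark); vh <- expand_track(h3)
  ratio <- lapply(names(vm), function(ch) vm[[ch]] / (vh[[ch]] + pseudocount))
  per_base_to_track(setNames(ratio, names(vm)),
                    mark = paste0(attr(mark, "mark"), "/H3"),
                    condition = attr(mark, "condition"),
                    replicate = attr(mark, "replicate"))
}
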
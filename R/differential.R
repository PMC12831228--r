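#' Tile a genome into fixed-width windows
#'
#' Non-overlapping windows covering each chromosome exactly once; the last
#' window of a chromosome is shortened when the length is not a multiple of
#' `window`.
#'
#' @param seqlengths Named vector of chromosome lengths.
#' @param window Window width in bp (default 200).
#' @return Tibble `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_genome <- function(seqlengths, window = 200) {
  stopifnot(window >= 1)
  purrr::map_dfr(names(seqlengths), function(ch) {
    L <- seqlengths[[ch]]
    starts <- seq(0, L - 1, by = window)
    tibble(chrom = ch, start = starts, end = pmin(starts + window, L))
  })
}

window_means <- function(track, windows) {
  vecs <- expand_track(track)
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    v <- vecs[[ch]]
    cs <- c(0, cumsum(v))
    w <- windows[idx, ]
    out[idx] <- (cs[w$end + 1] - cs[w$start + 1]) / (w$end - w$start)
  }
  out
}

#' Call differentially enriched windows between conditions
#'
#' Defines differential "sites" as fixed-width genome windows. Within each
#' window the mean H3-normalized signal is computed per replicate; replicated
#' designs are tested with Welch's t-test on the replicate window means and a
#' single-replicate design falls back to a conditional binomial (Poisson
#' ratio) test on the pooled, depth-scaled window sums. Raw p-values are
#' Benjamini-Hochberg adjusted over all tested windows. A window is called
#' when `p < p_max`, `q < q_max` and `|log2 ratio| >= lfc_min` — the
#' effect-size floor (default `log2(1.5)`, set `lfc_min = 0` to disable)
#' keeps vanishingly small but statistically resolvable differences out of
#' the site list, analogous to the fold-change threshold applied to
#' expression data.
#'
#' @param treated,control Lists of ratio `wl_track`s, one per replicate.
#' @param window Window width in bp (default 200).
#' @param p_max,q_max Strict thresholds on raw p and BH q (defaults 0.01 and
#'   0.05).
#' @param lfc_min Minimum absolute log2 ratio (default `log2(1.5)`).
#' @return A `wl_diff` tibble with one row per window: `chrom`, `start`,
#'   `end`, `mean_treated`, `mean_control`, `log2_ratio`, `p_value`,
#'   `q_value`, `direction`, `called`. Use [differential_sites()] for only
#'   the called windows.
#' @export
call_differential_windows <- function(treated, control, window = 200,
                                      p_max = 0.01, q_max = 0.05,
                                      lfc_min = log2(1.5)) {
  if (inherits(treated, "wl_track")) treated <- list(treated)
  if (inherits(control, "wl_track")) control <- list(control)
  if (length(treated) < 1 || length(control) < 1) {
    abort("need at least one replicate track per condition.")
  }
  sls <- lapply(c(treated, control), track_seqlengths)
  chroms <- Reduce(intersect, lapply(sls, names))
  if (length(chroms) == 0) abort("no chromosome shared by all tracks.")
  sl <- sls[[1]][chroms]
  windows <- tile_genome(sl, window)

  Tm <- vapply(treated, function(t) window_means(t, windows),
               numeric(nrow(windows)))
  Cm <- vapply(control, function(t) window_means(t, windows),
               numeric(nrow(windows)))
  Tm <- matrix(Tm, nrow = nrow(windows)); Cm <- matrix(Cm, nrow = nrow(windows))
  nt <- ncol(Tm); nc <- ncol(Cm)
  mT <- rowMeans(Tm); mC <- rowMeans(Cm)

  if (nt >= 2 && nc >= 2) {
    vT <- rowSums((Tm - mT)^2) / (nt - 1)
    vC <- rowSums((Cm - mC)^2) / (nc - 1)
    se2 <- vT / nt + vC / nc
    tstat <- ifelse(se2 > 0, (mT - mC) / sqrt(se2), ifelse(mT == mC, 0, Inf))
    df <- ifelse(se2 > 0,
                 se2^2 / ((vT / nt)^2 / (nt - 1) + (vC / nc)^2 / (nc - 1)),
                 nt + nc - 2)
    p <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), df), 0)
    p[se2 == 0 & mT == mC] <- 1
    method <- "welch_replicates"
  } else {
    # pooled mode: conditional binomial on depth-scaled window sums
    len <- windows$end - windows$start
    xT <- mT * len * nt; xC <- mC * len * nc
    tot <- round(xT) + round(xC)
    pr <- nt / (nt + nc)
    p <- vapply(seq_along(tot), function(i) {
      if (tot[i] == 0) return(1)
      stats::binom.test(round(xT[i]), tot[i], pr)$p.value
    }, numeric(1))
    method <- "pooled_binomial"
  }

  offset <- 1e-8  # keeps log2 finite on empty windows
  out <- windows |>
    mutate(mean_treated = mT, mean_control = mC,
           log2_ratio = log2((mT + offset) / (mC + offset)),
           p_value = pmin(1, p))
  out$q_value <- bh_fdr(out$p_value)
  out$direction <- ifelse(out$mean_treated >= out$mean_control,
                          "higher_in_treated", "higher_in_control")
  out$called <- out$p_value < p_max & out$q_value < q_max &
    abs(out$log2_ratio) >= lfc_min
  structure(out, class = c("wl_diff", class(out)),
            thresholds = list(p_max = p_max, q_max = q_max, lfc_min = lfc_min,
                              window = window, method = method))
}

#' Called windows of a differential analysis
#'
#' @param x A `wl_diff` table from [call_differential_windows()].
#' @return Tibble of windows passing all thresholds (BED-compatible first
#'   three columns).
#' @export
differential_sites <- function(x) {
  stopifnot(inherits(x, "wl_diff"))
  as_tibble(x)[x$called, setdiff(names(x), "called")]
}
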
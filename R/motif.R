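#' Build a position weight matrix
#'
#' Accepts a 4-row matrix (rows A, C, G, T) of counts or probabilities —
#' columns are normalized to sum to 1 — or an IUPAC consensus string, whose
#' allowed bases share each column's probability. A pseudo-probability keeps
#' log-odds finite for disallowed bases.
#'
#' @param x 4 x L numeric matrix or a single IUPAC consensus string.
#' @param background Background base frequencies (A, C, G, T); default
#'   uniform.
#' @param pseudo Small probability floor per cell (default 1e-4).
#' @return A `wl_pwm`: `$prob` (4 x L), `$background`, `$log_odds` (4 x L,
#'   natural log), `$max_score` (sum of column maxima).
#' @export
as_pwm <- function(x, background = rep(0.25, 4), pseudo = 1e-4) {
  bases <- c("A", "C", "G", "T")
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  if (is.character(x) && length(x) == 1) {
    iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = bases)
    letters_ <- strsplit(toupper(x), "")[[1]]
    if (!all(letters_ %in% names(iupac))) abort("unknown IUPAC code in consensus.")
    prob <- vapply(letters_, function(l) {
      p <- setNames(rep(0, 4), bases)
      p[iupac[[l]]] <- 1 / length(iupac[[l]])
      p
    }, numeric(4))
  } else {
    prob <- as.matrix(x)
    if (nrow(prob) != 4) abort("PWM matrix must have 4 rows (A, C, G, T).")
    cs <- colSums(prob)
    if (any(cs <= 0)) abort("PWM columns must have positive sums.")
    prob <- sweep(prob, 2, cs, "/")
  }
  rownames(prob) <- bases
  prob <- sweep(pmax(prob, pseudo), 2, colSums(pmax(prob, pseudo)), "/")
  lo <- log(prob / background)
  structure(
    list(prob = prob, background = setNames(background, bases),
         log_odds = lo, max_score = sum(apply(lo, 2, max)), width = ncol(prob)),
    class = "wl_pwm"
  )
}

#' Read a PWM from a 4-row tab-delimited file
#'
#' First column may name the bases (A/C/G/T); remaining columns are motif
#' positions (counts or probabilities).
#'
#' @param path File path.
#' @inheritParams as_pwm
#' @export
read_pwm <- function(path, background = rep(0.25, 4)) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.character(raw[[1]])) {
    rn <- toupper(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
    raw <- raw[match(c("A", "C", "G", "T"), rn), , drop = FALSE]
  }
  as_pwm(as.matrix(raw), background = background)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

score_windows <- function(seq, lo) {
  L <- ncol(lo)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars) - L + 1
  if (n < 1) return(numeric(0))
  idx <- match(chars, c("A", "C", "G", "T"))  # N and friends -> NA
  sc <- numeric(n)
  for (j in seq_len(L)) {
    col <- unname(lo[, j])[idx[j:(j + n - 1)]]
    col[is.na(col)] <- -Inf  # a window containing N cannot match
    sc <- sc + col
  }
  sc
}

#' Scan promoters for motif occurrences
#'
#' Slides the PWM over both strands of every promoter and records windows
#' whose log-odds score reaches the threshold. The threshold is given either
#' as a fraction of the maximum attainable score (default 0.8) or as an
#' absolute log-odds score. Hit positions are reported 1-based on the given
#' (promoter) sequence, `strand = "-"` meaning the match is on the reverse
#' complement. Sequences that are more than 50% N are skipped with a warning.
#'
#' @param pwm A `wl_pwm` (see [as_pwm()] / [read_pwm()]).
#' @param promoters A `wl_promoters` tibble or named character vector of
#'   sequences.
#' @param threshold Numeric threshold (default 0.8).
#' @param threshold_type `"fraction"` (of `max_score`) or `"score"`.
#' @return A `wl_motif_scan`: `$hits` (tibble `gene_id`, `position`,
#'   `strand`, `score`), `$summary` (per-promoter `best_score`,
#'   `best_position`, `n_hits`, `present`), `$n_present`.
#' @export
scan_motif <- function(pwm, promoters, threshold = 0.8,
                       threshold_type = c("fraction", "score")) {
  stopifnot(inherits(pwm, "wl_pwm"))
  threshold_type <- match.arg(threshold_type)
  thr <- if (threshold_type == "fraction") threshold * pwm$max_score else threshold
  if (inherits(promoters, "data.frame")) {
    seqs <- setNames(promoters$seq, promoters$gene_id)
  } else {
    seqs <- promoters
    if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  }
  L <- pwm$width
  hits <- list(); summ <- list()
  for (g in names(seqs)) {
    s <- toupper(seqs[[g]])
    if (mean(strsplit(s, "")[[1]] == "N") > 0.5) {
      warn(sprintf("promoter '%s' skipped: more than 50%% N.", g))
      next
    }
    if (nchar(s) < L) abort(sprintf("promoter '%s' is shorter than the motif.", g))
    fw <- score_windows(s, pwm$log_odds)
    rv <- score_windows(revcomp(s), pwm$log_odds)
    # map reverse-strand window j back to forward coordinates
    n <- nchar(s) - L + 1
    h <- bind_rows(
      tibble(position = which(fw >= thr), strand = "+",
             score = fw[fw >= thr]),
      tibble(position = n + 1 - which(rv >= thr), strand = "-",
             score = rv[rv >= thr])
    )
    if (nrow(h)) hits[[g]] <- mutate(h, gene_id = g, .before = 1)
    allsc <- unname(c(fw, rv))
    best <- which.max(allsc)
    best_pos <- if (best <= n) best else n + 1 - (best - n)
    summ[[g]] <- tibble(gene_id = g, best_score = max(allsc),
                        best_position = as.integer(best_pos),
                        n_hits = nrow(h), present = nrow(h) > 0)
  }
  hits <- if (length(hits)) bind_rows(hits) else
    tibble(gene_id = character(), position = integer(),
           strand = character(), score = numeric())
  summary <- if (length(summ)) bind_rows(summ) else
    tibble(gene_id = character(), best_score = numeric(),
           best_position = integer(), n_hits = integer(), present = logical())
  structure(
    list(hits = hits, summary = summary,
         n_present = sum(summary$present), threshold = thr),
    class = "wl_motif_scan"
  )
}

#' @export
print.wl_motif_scan <- function(x, ...) {
  cat("Motif scan:", nrow(x$summary), "promoters,", x$n_present,
      "with >= 1 hit (threshold", format(x$threshold, digits = 4), ")\n")
  invisible(x)
}

#' Motif presence vs shuffled-promoter background
#'
#' Optional enrichment check: the observed number of motif-containing
#' promoters is compared against the presence rate in column-shuffled
#' versions of the same promoters (binomial test).
#'
#' @inheritParams scan_motif
#' @param n_shuffle Shuffles per promoter (default 20).
#' @param seed Seed for the shuffles.
#' @return A list: `n_present`, `background_rate`, `p_value`.
#' @export
motif_enrichment_test <- function(pwm, promoters, threshold = 0.8,
                                  threshold_type = c("fraction", "score"),
                                  n_shuffle = 20, seed = 1) {
  threshold_type <- match.arg(threshold_type)
  obs <- scan_motif(pwm, promoters, threshold, threshold_type)
  if (inherits(promoters, "data.frame")) {
    seqs <- setNames(promoters$seq, promoters$gene_id)
  } else seqs <- promoters
  set.seed(seed)
  hits <- 0L; tot <- 0L
  for (s in seqs) {
    ch <- strsplit(toupper(s), "")[[1]]
    for (i in seq_len(n_shuffle)) {
      sh <- paste(sample(ch), collapse = "")
      sc <- scan_motif(pwm, c(x = sh), threshold, threshold_type)
      hits <- hits + sc$n_present; tot <- tot + 1L
    }
  }
  bg <- max(hits / tot, 1 / (2 * tot))  # avoid a zero-rate null
  bt <- stats::binom.test(obs$n_present, nrow(obs$summary), bg,
                          alternative = "greater")
  list(n_present = obs$n_present, background_rate = hits / tot,
       p_value = bt$p.value)
}
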
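#' Assign differential windows to genes
#'
#' A window is assigned to every gene whose body or upstream promoter
#' interval it overlaps by at least 1 bp (`mode = "all"`); with
#' `mode = "nearest"` a window overlapping several genes is assigned only to
#' the gene with the nearest TSS. Genes are then flagged up/down per the
#' windows' direction labels.
#'
#' @param sites Tibble of called windows with columns `chrom`, `start`,
#'   `end`, `direction` (see [differential_sites()]).
#' @param annotation Gene annotation (see [as_annotation()]).
#' @param promoter_upstream Promoter interval length upstream of the TSS in
#'   bp (default 1000).
#' @param mode `"all"` (default) or `"nearest"`.
#' @return A `wl_mark_calls` tibble: `gene_id`, `up`, `down` (logicals),
#'   `windows_up`, `windows_down` (list columns of window ids
#'   `chrom:start-end`). The number of windows assigned to no gene is in the
#'   `unassigned` attribute.
#' @export
map_sites_to_genes <- function(sites, annotation, promoter_upstream = 1000,
                               mode = c("all", "nearest")) {
  mode <- match.arg(mode)
  ann <- as_annotation(annotation)
  sites <- as_tibble(sites)
  if (!"direction" %in% names(sites)) {
    abort("`sites` needs a `direction` column.")
  }
  # gene interval extended by the promoter on the TSS side (contiguous span)
  ext_start <- ifelse(ann$strand == "+", pmax(0, ann$start - promoter_upstream),
                      ann$start)
  ext_end <- ifelse(ann$strand == "+", ann$end, ann$end + promoter_upstream)

  genes_gr <- GenomicRanges::GRanges(ann$chrom,
                                     IRanges::IRanges(ext_start + 1, ext_end))
  win_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$start + 1, sites$end))
  hits <- GenomicRanges::findOverlaps(win_gr, genes_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  if (mode == "nearest" && length(qh)) {
    tss <- annotation_tss(ann)
    mid <- (sites$start + sites$end) / 2
    d <- abs(mid[qh] - tss[sh])
    keep <- unlist(lapply(split(seq_along(qh), qh),
                          function(i) i[which.min(d[i])]), use.names = FALSE)
    qh <- qh[keep]; sh <- sh[keep]
  }

  win_id <- paste0(sites$chrom, ":", sites$start, "-", sites$end)
  assign <- tibble(gene_id = ann$gene_id[sh], window = win_id[qh],
                   direction = sites$direction[qh])
  calls <- purrr::map_dfr(ann$gene_id, function(g) {
    a <- assign[assign$gene_id == g, ]
    wu <- a$window[a$direction == "higher_in_treated"]
    wd <- a$window[a$direction == "higher_in_control"]
    tibble(gene_id = g, up = length(wu) > 0, down = length(wd) > 0,
           windows_up = list(wu), windows_down = list(wd))
  })
  structure(calls, class = c("wl_mark_calls", class(calls)),
            unassigned = nrow(sites) - length(unique(qh)))
}

#' Intersect up-called gene sets of two marks
#'
#' Venn-style tabulation of genes carrying increased deposition of each mark,
#' and the set with both (the two-mark enrichment step of the candidate
#' funnel).
#'
#' @param calls_me2,calls_me3 `wl_mark_calls` tables for the two marks.
#' @return A list: `both_up` (character vector), `me2_up`, `me3_up`, and
#'   `venn` (tibble with `region`, `n` for me2-only / me3-only / both).
#' @export
intersect_mark_sets <- function(calls_me2, calls_me3) {
  me2 <- calls_me2$gene_id[calls_me2$up]
  me3 <- calls_me3$gene_id[calls_me3$up]
  both <- intersect(me2, me3)
  structure(
    list(both_up = both, me2_up = me2, me3_up = me3,
         venn = tibble(
           region = c("me2_only", "me3_only", "both"),
           n = c(length(setdiff(me2, me3)), length(setdiff(me3, me2)),
                 length(both))
         )),
    class = "wl_marks"
  )
}

#' Filter a differential-expression table for up-regulated genes
#'
#' Strict thresholds: `fold_change > fc_min`, `p_value < p_max`,
#' `q_value < q_max` must all hold.
#'
#' @param de Tibble with columns `gene_id`, `fold_change` (linear
#'   treated/control), `p_value`, `q_value`.
#' @param fc_min,p_max,q_max Thresholds (defaults 1.5, 0.01, 0.05).
#' @return Character vector of gene ids.
#' @export
filter_upregulated <- function(de, fc_min = 1.5, p_max = 0.01, q_max = 0.05) {
  need <- c("gene_id", "fold_change", "p_value", "q_value")
  miss <- setdiff(need, names(de))
  if (length(miss)) abort(paste0("DE table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  de$gene_id[de$fold_change > fc_min & de$p_value < p_max & de$q_value < q_max]
}

#' Candidate genes: both marks enriched and transcriptionally up-regulated
#'
#' Intersection of the two-mark enrichment set with the up-regulated set,
#' carrying per-gene provenance (supporting windows and DE statistics) when
#' the source tables are supplied.
#'
#' @param both_marks Character vector (e.g. `intersect_mark_sets()$both_up`).
#' @param upregulated Character vector (from [filter_upregulated()]).
#' @param de Optional DE table to annotate fold change / p / q.
#' @param calls_me2,calls_me3 Optional `wl_mark_calls` to annotate supporting
#'   windows.
#' @return Candidate tibble, one row per gene.
#' @export
select_candidates <- function(both_marks, upregulated, de = NULL,
                              calls_me2 = NULL, calls_me3 = NULL) {
  genes <- intersect(both_marks, upregulated)
  out <- tibble(gene_id = genes)
  if (!is.null(de)) {
    out <- left_join(out, as_tibble(de)[, c("gene_id", "fold_change",
                                            "p_value", "q_value")],
                     by = "gene_id")
  }
  grab <- function(calls, col) {
    i <- match(out$gene_id, calls$gene_id)
    calls[[col]][i]
  }
  if (!is.null(calls_me2)) out$windows_me2 <- grab(calls_me2, "windows_up")
  if (!is.null(calls_me3)) out$windows_me3 <- grab(calls_me3, "windows_up")
  out
}

#' Extract promoter sequences
#'
#' The promoter of a gene is its upstream intergenic span: from the TSS back
#' to the nearest boundary of any other annotated gene (or the chromosome
#' edge). Genes whose span is strictly longer than `min_len` are retained and
#' the TSS-proximal `scan_len` bp are returned, reverse-complemented for `-`
#' strand genes so sequences read 5' to 3' toward the gene.
#'
#' @param annotation Gene annotation (see [as_annotation()]).
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param min_len Minimum upstream span in bp, strict (default 1000).
#' @param scan_len Length of returned sequence in bp (default 1000).
#' @return A `wl_promoters` tibble: `gene_id`, `chrom`, `start`, `end`
#'   (interval of the returned sequence on the + strand), `strand`, `span`,
#'   `seq`.
#' @export
extract_promoters <- function(annotation, genome, min_len = 1000,
                              scan_len = 1000) {
  ann <- as_annotation(annotation)
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  missing_chrom <- setdiff(unique(ann$chrom), names(genome))
  if (length(missing_chrom)) {
    bad <- ann$gene_id[ann$chrom %in% missing_chrom][1]
    abort(sprintf("gene '%s' lies on a chromosome absent from the genome.", bad))
  }
  tss <- annotation_tss(ann)
  rows <- purrr::map_dfr(seq_len(nrow(ann)), function(i) {
    same <- ann[ann$chrom == ann$chrom[i] & ann$gene_id != ann$gene_id[i], ]
    L <- nchar(genome[[ann$chrom[i]]])
    if (ann$strand[i] == "+") {
      bound <- max(c(0, same$end[same$end <= tss[i]]))
      span <- tss[i] - bound
      s0 <- max(bound, tss[i] - scan_len); e0 <- tss[i]
    } else {
      bound <- min(c(L, same$start[same$start >= tss[i]]))
      span <- bound - tss[i]
      s0 <- tss[i]; e0 <- min(bound, tss[i] + scan_len)
    }
    tibble(gene_id = ann$gene_id[i], chrom = ann$chrom[i],
           start = s0, end = e0, strand = ann$strand[i], span = span)
  })
  rows <- rows[rows$span > min_len, ]
  rows$seq <- vapply(seq_len(nrow(rows)), function(i) {
    s <- substr(genome[[rows$chrom[i]]], rows$start[i] + 1, rows$end[i])
    if (rows$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  structure(rows, class = c("wl_promoters", class(rows)))
}

#' Write promoters to FASTA
#' @param promoters A `wl_promoters` tibble.
#' @param path Output path.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(setNames(promoters$seq, promoters$gene_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
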
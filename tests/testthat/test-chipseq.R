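test_that("as_track validates, merges and repairs intervals", {
  sl <- c(chr1 = 100)
  t1 <- as_track(data.frame(chrom = "chr1", start = c(0, 50), end = c(10, 60),
                            depth = c(2, 3)), seqlengths = sl)
  expect_equal(nrow(t1), 2)

  # adjacent equal-depth intervals merge with total signal conserved
  t2 <- as_track(data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 30),
                            depth = 2), seqlengths = sl)
  expect_equal(nrow(t2), 1)
  expect_equal(t2$end - t2$start, 30)
  expect_equal(sum(t2$depth * (t2$end - t2$start)), 60)

  expect_error(as_track(data.frame(chrom = "chr1", start = 0, end = 10,
                                   depth = -1)), "non-negative")
  expect_warning(
    t3 <- as_track(data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15),
                              depth = c(1, 2)), seqlengths = sl),
    "repaired")
  v <- wormlegacy:::expand_track(t3)$chr1
  expect_equal(v[1:15], c(rep(1, 10), rep(2, 5)))
})

test_that("bedGraph round-trip preserves per-base depths", {
  sim <- gen_genome_and_tracks(genome_length = 20000, n_genes = 4,
                               n_enriched = 1, n_replicates = 1, seed = 2)
  tr <- sim$tracks$treated$H3K79me2[[1]]
  tmp <- tempfile(fileext = ".bedGraph")
  write_track(tr, tmp)
  back <- load_track(tmp, seqlengths = attr(tr, "seqlengths"))
  expect_equal(wormlegacy:::expand_track(back), wormlegacy:::expand_track(tr))
})

test_that("normalize_mark_to_h3 equals the per-base brute-force oracle", {
  toy <- toy_tracks()
  ratio <- normalize_mark_to_h3(toy$mark, toy$h3, pseudocount = 0.5,
                                rescale = FALSE)
  vm <- wormlegacy:::expand_track(toy$mark)$chrA
  vh <- wormlegacy:::expand_track(toy$h3)$chrA
  expect_equal(wormlegacy:::expand_track(ratio)$chrA, vm / (vh + 0.5))

  # mark identical to h3 with a small pseudocount: ratio near 1
  r1 <- normalize_mark_to_h3(toy$h3, toy$h3, pseudocount = 1e-6, rescale = FALSE)
  v <- wormlegacy:::expand_track(r1)$chrA
  expect_true(all(abs(v - 1) < 1e-5))

  # zero mark -> zero ratio everywhere
  zero <- as_track(data.frame(chrom = "chrA", start = 0, end = 1, depth = 0),
                   seqlengths = toy$sl)
  r0 <- normalize_mark_to_h3(zero, toy$h3, rescale = FALSE)
  expect_equal(sum(wormlegacy:::expand_track(r0)$chrA), 0)

  other <- as_track(data.frame(chrom = "chrB", start = 0, end = 10, depth = 1))
  expect_error(normalize_mark_to_h3(toy$mark, other), "different chromosomes")
})

test_that("ratio tracks are invariant to rescaling input depths", {
  sim <- gen_genome_and_tracks(genome_length = 20000, n_genes = 4,
                               n_enriched = 1, n_replicates = 1, seed = 3)
  mk <- sim$tracks$treated$H3K79me2[[1]]
  h3 <- sim$tracks$treated$H3[[1]]
  r1 <- normalize_mark_to_h3(mk, h3)
  mk7 <- mk; mk7$depth <- mk7$depth * 7
  h33 <- h3; h33$depth <- h33$depth * 3.2
  r2 <- normalize_mark_to_h3(mk7, h33)
  expect_equal(wormlegacy:::expand_track(r1), wormlegacy:::expand_track(r2),
               tolerance = 1e-12)
})

test_that("tss_signal_matrix does strand-aware coordinate arithmetic", {
  sl <- c(chr1 = 10000)
  # stepped track: depth = 1 below 5000, 3 at/after
  tr <- as_track(data.frame(chrom = "chr1", start = c(0, 5000),
                            end = c(5000, 10000), depth = c(1, 3)),
                 seqlengths = sl)
  ann <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                    start = c(5000, 4000), end = c(6000, 5000),
                    strand = c("+", "-"))
  m <- tss_signal_matrix(tr, ann, half_width = 1000, bin_width = 50)
  expect_equal(dim(m$signal), c(2, 40))
  # + gene: window [4000, 6000): first 20 bins at depth 1, last 20 at 3
  expect_equal(unname(m$signal["plus", ]), rep(c(1, 3), each = 20))
  # - gene TSS = end = 5000, same interval but reversed orientation
  expect_equal(unname(m$signal["minus", ]), rep(c(3, 1), each = 20))

  # per-base averaging oracle on a bin straddling the step
  m2 <- tss_signal_matrix(tr, ann[1, ], half_width = 1000, bin_width = 80)
  expect_equal(unname(m2$signal[1, 13]),
               oracle_interval_mean(tr, "chr1", 4960, 5040))

  # constant track: every bin equals the constant
  cst <- as_track(data.frame(chrom = "chr1", start = 0, end = 10000, depth = 2),
                  seqlengths = sl)
  mc <- tss_signal_matrix(cst, ann)
  expect_true(all(mc$signal == 2))

  # window falling off the chromosome is dropped with a message
  edge <- data.frame(gene_id = "edge", chrom = "chr1", start = 200, end = 900,
                     strand = "+")
  expect_message(m3 <- tss_signal_matrix(tr, rbind(ann, edge)), "dropped")
  expect_equal(nrow(m3$signal), 2)
  expect_error(tss_signal_matrix(tr, ann[0, ]), "empty")
})

test_that("metaprofile_compare reports curves, medians and the rank-sum test", {
  sim <- gen_genome_and_tracks(genome_length = 40000, n_genes = 8,
                               n_enriched = 2, n_replicates = 1, seed = 4)
  r <- normalize_mark_to_h3(sim$tracks$control$H3K79me2[[1]],
                            sim$tracks$control$H3[[1]])
  m <- tss_signal_matrix(r, sim$annotation)
  same <- metaprofile_compare(m, m)
  expect_equal(same$curves$mean_signal[same$curves$group == "a"],
               same$curves$mean_signal[same$curves$group == "b"])
  expect_gte(same$test$p_value, 0.99)

  m2 <- m; m2$signal <- 2 * m$signal
  r2 <- metaprofile_compare(m, m2)
  expect_equal(unname(r2$medians[2]), 2 * unname(r2$medians[1]))

  m3 <- tss_signal_matrix(r, sim$annotation, bin_width = 100)
  expect_error(metaprofile_compare(m, m3), "binning")
})

test_that("tile_genome covers every chromosome exactly once", {
  sl <- c(a = 1000, b = 1234)
  w <- tile_genome(sl, 200)
  for (ch in names(sl)) {
    ww <- w[w$chrom == ch, ]
    expect_equal(sum(ww$end - ww$start), unname(sl[ch]))
    expect_equal(ww$start[-1], ww$end[-nrow(ww)])
  }
})

test_that("call_differential_windows finds planted windows and nothing else", {
  sim <- gen_genome_and_tracks(genome_length = 40000, n_genes = 8,
                               n_enriched = 2, n_replicates = 3, seed = 6)
  ratio <- function(cond) lapply(1:3, function(r)
    normalize_mark_to_h3(sim$tracks[[cond]]$H3K79me2[[r]],
                         sim$tracks[[cond]]$H3[[r]]))
  d <- call_differential_windows(ratio("treated"), ratio("control"))
  expect_true(all(d$q_value >= d$p_value))
  called <- differential_sites(d)
  truth <- paste0(sim$truth$enriched_windows$chrom, ":",
                  sim$truth$enriched_windows$start)
  got <- paste0(called$chrom, ":", called$start)
  expect_setequal(got, truth)
  expect_true(all(called$direction == "higher_in_treated"))

  # identical inputs -> nothing called
  same <- call_differential_windows(ratio("control"), ratio("control"))
  expect_equal(sum(same$called), 0)

  # degenerate thresholds return every window
  all_w <- call_differential_windows(ratio("treated"), ratio("control"),
                                     p_max = 1.01, q_max = 1.01, lfc_min = 0)
  expect_true(all(all_w$called))
  expect_equal(nrow(all_w), 40000 / 200)
})

test_that("differential window means match the per-base oracle", {
  toy <- toy_tracks()
  r <- normalize_mark_to_h3(toy$mark, toy$h3, rescale = FALSE)
  w <- tile_genome(toy$sl, 20)
  means <- wormlegacy:::window_means(r, w)
  for (i in seq_len(nrow(w))) {
    expect_equal(means[i], oracle_interval_mean(r, w$chrom[i], w$start[i], w$end[i]),
                 tolerance = 1e-12)
  }
})
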
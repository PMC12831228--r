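test_that("map_sites_to_genes equals the all-pairs interval-overlap oracle", {
  set.seed(13)
  ann <- data.frame(
    gene_id = sprintf("g%02d", 1:30),
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    start = sample(seq(2000, 90000, by = 100), 30),
    strand = sample(c("+", "-"), 30, replace = TRUE)
  )
  ann$end <- ann$start + sample(500:3000, 30)
  sites <- data.frame(
    chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
    start = sample(0:99000, 200)
  )
  sites$end <- sites$start + 200
  sites$direction <- sample(c("higher_in_treated", "higher_in_control"),
                            200, replace = TRUE)

  calls <- map_sites_to_genes(sites, ann, promoter_upstream = 1000)
  o <- oracle_assign(sites, ann, 1000)
  for (g in ann$gene_id) {
    wins <- sort(o$win[o$gene == g])
    got <- sort(match(
      unlist(c(calls$windows_up[calls$gene_id == g],
               calls$windows_down[calls$gene_id == g])),
      paste0(sites$chrom, ":", sites$start, "-", sites$end)
    ))
    expect_equal(got, wins)
    expect_equal(calls$up[calls$gene_id == g],
                 any(sites$direction[wins] == "higher_in_treated"))
  }
})

test_that("map_sites_to_genes applies the promoter rule and nearest-TSS mode", {
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    start = c(5000, 7100), end = c(7000, 9000),
                    strand = c("+", "+"))
  inside <- data.frame(chrom = "chr1", start = 5500, end = 5700,
                       direction = "higher_in_treated")
  r <- map_sites_to_genes(inside, ann)
  expect_true(r$up[r$gene_id == "gA"])
  expect_false(r$up[r$gene_id == "gB"])

  upstream <- data.frame(chrom = "chr1", start = 4400, end = 4600,
                         direction = "higher_in_treated")
  r2 <- map_sites_to_genes(upstream, ann)
  expect_true(r2$up[r2$gene_id == "gA"])  # 500 bp upstream of the + TSS

  # a window overlapping both genes goes to both in "all", one in "nearest"
  shared <- data.frame(chrom = "chr1", start = 6900, end = 7200,
                       direction = "higher_in_treated")
  r3 <- map_sites_to_genes(shared, ann)
  expect_equal(sum(r3$up), 2)
  r4 <- map_sites_to_genes(shared, ann, mode = "nearest")
  expect_equal(r4$gene_id[r4$up], "gB")  # TSS 7100 is nearest to the window
})

test_that("intersect_mark_sets tabulates Venn regions exactly", {
  mk <- function(ids, up) tibble::tibble(gene_id = ids, up = up, down = FALSE)
  a <- mk(c("g1", "g2", "g3", "g4"), c(TRUE, TRUE, FALSE, TRUE))
  b <- mk(c("g1", "g2", "g3", "g4"), c(TRUE, FALSE, TRUE, TRUE))
  r <- intersect_mark_sets(a, b)
  expect_setequal(r$both_up, c("g1", "g4"))
  expect_equal(r$venn$n[r$venn$region == "me2_only"], 1)
  expect_equal(r$venn$n[r$venn$region == "me3_only"], 1)
  expect_equal(r$venn$n[r$venn$region == "both"], 2)
  expect_equal(sum(r$venn$n), length(union(r$me2_up, r$me3_up)))

  set.seed(8)
  ids <- sprintf("g%03d", 1:50)
  a <- mk(ids, runif(50) < 0.4); b <- mk(ids, runif(50) < 0.4)
  r <- intersect_mark_sets(a, b)
  expect_setequal(r$both_up, ids[a$up & b$up])
})

test_that("filter_upregulated applies strict thresholds", {
  de <- tibble::tibble(
    gene_id = c("at_fc", "ok", "bad_p", "bad_q"),
    fold_change = c(1.5, 2, 3, 3),
    p_value = c(0.001, 0.001, 0.02, 0.001),
    q_value = c(0.01, 0.01, 0.01, 0.06)
  )
  expect_equal(filter_upregulated(de), "ok")

  set.seed(14)
  rnd <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                        fold_change = exp(rnorm(300)),
                        p_value = runif(300))
  rnd$q_value <- bh_fdr(rnd$p_value)
  got <- filter_upregulated(rnd)
  manual <- rnd$gene_id[rnd$fold_change > 1.5 & rnd$p_value < 0.01 &
                          rnd$q_value < 0.05]
  expect_equal(got, manual)
})

test_that("select_candidates intersects with provenance and respects the funnel", {
  both <- c("g1", "g2", "g3")
  up <- c("g2", "g3", "g9")
  r <- select_candidates(both, up)
  expect_setequal(r$gene_id, c("g2", "g3"))
  expect_equal(nrow(select_candidates(both, character(0))), 0)
  expect_setequal(select_candidates(both, both)$gene_id, both)

  # funnel monotonicity: candidates never exceed either input set
  expect_lte(nrow(r), min(length(both), length(up)))
})

test_that("planted expression truth flows through the funnel exactly", {
  for (s in 1:3) {
    expr <- gen_expression(seed = s)  # 8 planted at FC 4 among 200
    up <- filter_upregulated(expr$de)
    expect_setequal(intersect(up, expr$truth), expr$truth)  # all planted pass
    cand <- select_candidates(expr$truth, up, de = expr$de)
    expect_setequal(cand$gene_id, expr$truth)
    # tightening the filter never grows the set
    tighter <- filter_upregulated(expr$de, fc_min = 2.5)
    expect_true(all(tighter %in% up))
  }
})

test_that("extract_promoters bounds spans by neighbors and strand-corrects", {
  genome <- c(chr1 = paste(rep("ACGT", 5000), collapse = ""))  # 20 kb
  ann <- data.frame(
    gene_id = c("clear", "blocked", "minus", "wall"),
    chrom = "chr1",
    start = c(8000, 15200, 2000, 14000),
    end = c(9000, 16000, 3000, 14400),
    strand = c("+", "+", "-", "+")
  )
  pr <- extract_promoters(ann, genome)
  # "clear": 5 kb of empty upstream (nearest end <= 8000 is minus at 3000)
  expect_true("clear" %in% pr$gene_id)
  expect_equal(pr$span[pr$gene_id == "clear"], 5000)
  expect_equal(nchar(pr$seq[pr$gene_id == "clear"]), 1000)
  # "blocked": wall ends 800 bp upstream -> span 800, excluded
  expect_false("blocked" %in% pr$gene_id)
  # "minus": TSS at end = 3000, upstream runs to the next start (8000)
  expect_equal(pr$span[pr$gene_id == "minus"], 5000)
  fw <- substr(genome[["chr1"]], 3001, 4000)
  expect_equal(pr$seq[pr$gene_id == "minus"],
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(fw))))

  bad <- ann; bad$chrom[1] <- "chrX"
  expect_error(extract_promoters(bad, genome), "absent from the genome")
})

test_that("as_pwm normalizes columns and consensus strings", {
  p <- as_pwm(matrix(c(2, 0, 0, 2), nrow = 4, ncol = 6))  # counts
  expect_equal(colSums(p$prob), rep(1, 6), tolerance = 1e-9)
  cons <- as_pwm("ACGT")
  expect_equal(unname(which.max(cons$prob[, 1])), 1L)
  expect_equal(unname(which.max(cons$prob[, 4])), 4L)
  expect_error(as_pwm("AXC"), "IUPAC")

  shipped <- read_pwm(system.file("extdata", "pwm_sknlike_synthetic.tsv",
                                  package = "wormlegacy"))
  expect_equal(ncol(shipped$prob), 10)
  expect_equal(unname(colSums(shipped$prob)), rep(1, 10), tolerance = 1e-9)
})

test_that("scan_motif finds a planted consensus exactly where planted", {
  set.seed(3)
  pwm <- as_pwm("TTTGTCATCA")
  bg <- paste(sample(c("A", "C"), 400, replace = TRUE), collapse = "")
  s <- paste0(substr(bg, 1, 136), "TTTGTCATCA", substr(bg, 147, 400))
  r <- scan_motif(pwm, c(gene1 = s), threshold = 0.99)
  expect_equal(r$hits$position, 137)
  expect_equal(r$hits$strand, "+")
  expect_equal(r$summary$best_score, pwm$max_score, tolerance = 1e-9)
  expect_equal(r$n_present, 1)

  # threshold above the maximum attainable score: no hits anywhere
  r2 <- scan_motif(pwm, c(gene1 = s), threshold = pwm$max_score + 1,
                   threshold_type = "score")
  expect_equal(r2$n_present, 0)

  # strand symmetry: the reverse complement scores identically
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  r3 <- scan_motif(pwm, c(gene1 = rc), threshold = 0.99)
  expect_equal(r3$summary$best_score, r$summary$best_score, tolerance = 1e-12)
  expect_equal(r3$hits$strand, "-")

  # exhaustive enumeration oracle agrees on the best forward-strand window
  o <- oracle_best_window(s, pwm$log_odds)
  expect_equal(r$summary$best_score, o$score, tolerance = 1e-9)
  expect_equal(r$summary$best_position, o$position)

  expect_warning(scan_motif(pwm, c(g = strrep("N", 100))), "50% N")
})

test_that("gen_promoters plants the 18-of-36 planted truth exactly", {
  for (s in 1:3) {
    prom <- gen_promoters(seed = s)
    pwm <- as_pwm(prom$consensus)
    r <- scan_motif(pwm, prom$promoters, threshold = 0.999)
    expect_equal(r$n_present, 18)
    expect_setequal(r$summary$gene_id[r$summary$present],
                    prom$truth$gene_id[prom$truth$planted])
    # hit positions match the recorded planting positions
    truth <- prom$truth[prom$truth$planted, ]
    for (g in truth$gene_id) {
      expect_true(truth$position[truth$gene_id == g] %in%
                    r$hits$position[r$hits$gene_id == g])
    }
  }
  none <- gen_promoters(n_planted = 0, seed = 5)
  expect_equal(scan_motif(as_pwm(none$consensus), none$promoters,
                          threshold = 0.999)$n_present, 0)
})
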
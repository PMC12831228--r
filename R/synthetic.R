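#' Gompertz rate for a target mean lifespan
#'
#' Solves for the Gompertz rate parameter `b` such that the distribution with
#' shape `a` has the requested mean, via the survival-function integral
#' `E[T] = int exp(-(b/a)(exp(a t) - 1)) dt`.
#'
#' @param mean_days Target mean lifespan in days.
#' @param shape Gompertz shape (per-day rate of aging).
#' @return The rate parameter.
#' @export
gompertz_rate_for_mean <- function(mean_days, shape) {
  stopifnot(mean_days > 0, shape > 0)
  mean_of <- function(log_b) {
    b <- exp(log_b)
    integrate(function(t) exp(-(b / shape) * (exp(shape * t) - 1)),
              0, Inf, rel.tol = 1e-10)$value
  }
  exp(uniroot(function(lb) mean_of(lb) - mean_days, c(-25, 5),
              tol = 1e-12)$root)
}

#' Simulate a replicated lifespan experiment
#'
#' Gompertz lifespans (a realistic model of worm mortality, with accelerating
#' hazard) rounded to whole days; the treated arm's lifespans are the
#' baseline draw scaled by `1 + extension_pct/100`, so the planted mean
#' extension holds in expectation. A `censor_rate` fraction of animals,
#' chosen at random (independently of lifespan, like plate escapers), is
#' censored at a uniform day before death.
#'
#' @param n_per_replicate Animals per cohort per replicate (default 90).
#' @param n_replicates Biological replicates (default 3).
#' @param mean_days Baseline (control) mean lifespan in days (default 20).
#' @param shape Gompertz shape per day (default 0.35; gives an s.d. of
#'   roughly 3.7 d at a 20 d mean).
#' @param extension_pct Planted percent mean-lifespan extension (default 35).
#' @param censor_rate Fraction censored (default 0.05).
#' @param seed Seed; the generator is a pure function of its arguments.
#' @return Lifespan tibble (see [read_lifespan()]) with a `truth` attribute
#'   recording the planted parameters.
#' @export
gen_survival <- function(n_per_replicate = 90, n_replicates = 3,
                         mean_days = 20, shape = 0.35, extension_pct = 35,
                         censor_rate = 0.05, seed = 1) {
  stopifnot(n_per_replicate > 0, n_replicates >= 1,
            censor_rate >= 0, censor_rate < 1, extension_pct > -100)
  set.seed(seed)
  rate <- gompertz_rate_for_mean(mean_days, shape)
  one_cohort <- function(cond, repl, scale) {
    t <- flexsurv::rgompertz(n_per_replicate, shape = shape, rate = rate) * scale
    day <- pmax(1, round(t))
    event <- rep(1, n_per_replicate)
    cen <- runif(n_per_replicate) < censor_rate
    day[cen] <- pmax(1, ceiling(runif(sum(cen)) * day[cen]))
    event[cen] <- 0
    tibble(id = sprintf("%s_r%s_%03d", cond, repl, seq_len(n_per_replicate)),
           condition = cond, replicate = repl, day = day, event = event)
  }
  out <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    bind_rows(one_cohort("control", r, 1),
              one_cohort("treated", r, 1 + extension_pct / 100))
  })
  structure(out,
            truth = list(extension_pct = extension_pct, mean_days = mean_days,
                         shape = shape, rate = rate,
                         censor_rate = censor_rate, seed = seed))
}

#' Simulate a genome with annotation, sequence and ChIP coverage tracks
#'
#' Places non-overlapping genes on a window-aligned grid, draws per-base
#' Poisson total-H3 coverage, and lays each histone mark down multiplicatively
#' on the expected H3 depth: within the TSS +/- `tss_halfwidth` region of the
#' enriched genes in the treated condition the mark's Poisson mean is
#' `mean_depth * enrichment_factor`, elsewhere `mean_depth`. The
#' H3-normalized ratio therefore carries the planted factor by construction.
#' Ground truth (enriched genes and the exact enriched windows) is returned
#' with the object.
#'
#' @param genome_length Chromosome length in bp (default 1e5).
#' @param n_chrom Number of chromosomes (default 1).
#' @param n_genes Genes per chromosome (default 20).
#' @param n_enriched Number of enriched genes (default 5), sampled from the
#'   gene universe.
#' @param enrichment_factor Mark enrichment factor in the treated condition
#'   (default 3).
#' @param mean_depth Mean per-base coverage (default 30).
#' @param n_replicates Replicates per condition (default 3).
#' @param gene_span Gene length in bp (default 1000).
#' @param tss_halfwidth Enriched half-window around the TSS (default 1000).
#' @param window Window width the gene grid aligns to (default 200).
#' @param marks Mark names (default H3K79me2 and H3K79me3; both share the
#'   enriched gene set).
#' @param seed Seed.
#' @return A list: `annotation`, `genome` (named character), `tracks`
#'   (nested list `tracks[[condition]][[mark]][[replicate]]` of `wl_track`,
#'   with mark `"H3"` holding total H3), and `truth` (`enriched_genes`,
#'   `enriched_windows` tibble).
#' @export
gen_genome_and_tracks <- function(genome_length = 1e5, n_chrom = 1,
                                  n_genes = 20, n_enriched = 5,
                                  enrichment_factor = 3, mean_depth = 30,
                                  n_replicates = 3, gene_span = 1000,
                                  tss_halfwidth = 1000, window = 200,
                                  marks = c("H3K79me2", "H3K79me3"),
                                  seed = 1) {
  set.seed(seed)
  spacing <- floor(genome_length / (n_genes + 1) / window) * window
  if (spacing < gene_span + 2 * tss_halfwidth) {
    abort("gene count infeasible for this genome length.")
  }
  chroms <- paste0("chr", seq_len(n_chrom))
  sl <- setNames(rep(genome_length, n_chrom), chroms)

  ann <- purrr::map_dfr(seq_len(n_chrom), function(ci) {
    tss <- spacing * seq_len(n_genes)
    strand <- rep(c("+", "-"), length.out = n_genes)
    tibble(
      gene_id = sprintf("g%s_%02d", ci, seq_len(n_genes)),
      chrom = chroms[ci],
      start = ifelse(strand == "+", tss, tss - gene_span),
      end = ifelse(strand == "+", tss + gene_span, tss),
      strand = strand
    )
  })
  ann <- as_annotation(ann)

  genome <- setNames(lapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE,
                 prob = c(0.32, 0.18, 0.18, 0.32)), collapse = "")
  }), chroms)

  enriched <- sort(sample(ann$gene_id, n_enriched))
  tss <- annotation_tss(ann)
  enr_idx <- match(enriched, ann$gene_id)

  factor_vec <- setNames(lapply(chroms, function(ch) rep(1, genome_length)), chroms)
  for (i in enr_idx) {
    lo <- max(0, tss[i] - tss_halfwidth); hi <- min(genome_length, tss[i] + tss_halfwidth)
    factor_vec[[ann$chrom[i]]][(lo + 1):hi] <- enrichment_factor
  }
  enriched_windows <- purrr::map_dfr(enr_idx, function(i) {
    lo <- max(0, tss[i] - tss_halfwidth); hi <- min(genome_length, tss[i] + tss_halfwidth)
    starts <- seq(lo, hi - 1, by = window)
    tibble(chrom = ann$chrom[i], start = starts,
           end = pmin(starts + window, hi), gene_id = ann$gene_id[i])
  })

  make_track <- function(lambda_by_chrom, mark, cond, repl) {
    v <- lapply(lambda_by_chrom, function(lam) as.numeric(rpois(length(lam), lam)))
    per_base_to_track(v, mark = mark, condition = cond,
                      replicate = as.character(repl))
  }
  flat <- setNames(lapply(chroms, function(ch) rep(mean_depth, genome_length)), chroms)
  tracks <- list()
  for (cond in c("treated", "control")) {
    tracks[[cond]] <- list()
    lam_mark <- if (cond == "treated") {
      lapply(chroms, function(ch) mean_depth * factor_vec[[ch]])
    } else flat
    lam_mark <- setNames(lam_mark, chroms)
    for (mk in c("H3", marks)) {
      tracks[[cond]][[mk]] <- lapply(seq_len(n_replicates), function(r) {
        make_track(if (mk == "H3") flat else lam_mark, mk, cond, r)
      })
    }
  }

  list(annotation = ann, genome = genome, tracks = tracks,
       truth = list(enriched_genes = enriched,
                    enriched_windows = enriched_windows,
                    enrichment_factor = enrichment_factor,
                    mean_depth = mean_depth, seed = seed))
}

#' Simulate an expression count table with planted up-regulation
#'
#' Negative-binomial counts around gene-specific baselines; a planted subset
#' of genes is scaled by `fold_change` in the treated samples. A simple
#' built-in differential test (Welch's t on log2(count + 1), BH adjustment,
#' fold change as the ratio of group mean counts) produces the DE table the
#' candidate funnel consumes.
#'
#' @param n_genes Gene universe size (default 200).
#' @param n_up Number of planted up-regulated genes (default 8).
#' @param fold_change Planted linear fold change (default 4).
#' @param n_per_group Samples per condition (default 6).
#' @param mu Median baseline mean count (default 100; gene baselines are
#'   log-normal around it).
#' @param dispersion NB dispersion (default 0.1; `size = 1/dispersion`).
#' @param gene_ids Optional gene ids (length `n_genes`); defaults to
#'   `gene_001` style names.
#' @param planted Optional character vector of planted gene ids (overrides
#'   `n_up`).
#' @param seed Seed.
#' @return A list: `counts` (tibble gene x samples), `de` (tibble `gene_id`,
#'   `fold_change`, `p_value`, `q_value`), `truth` (planted gene ids).
#' @export
gen_expression <- function(n_genes = 200, n_up = 8, fold_change = 4,
                           n_per_group = 6, mu = 100, dispersion = 0.1,
                           gene_ids = NULL, planted = NULL, seed = 1) {
  stopifnot(fold_change > 0, dispersion > 0, n_per_group >= 2)
  set.seed(seed)
  gene_ids <- gene_ids %||% sprintf("gene_%03d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  planted <- planted %||% sort(sample(gene_ids, n_up))
  stopifnot(all(planted %in% gene_ids))
  base_mu <- rlnorm(n_genes, log(mu), 0.5)
  size <- 1 / dispersion
  ctrl <- matrix(rnbinom(n_genes * n_per_group, mu = base_mu, size = size),
                 nrow = n_genes)
  mu_tr <- base_mu * ifelse(gene_ids %in% planted, fold_change, 1)
  trt <- matrix(rnbinom(n_genes * n_per_group, mu = mu_tr, size = size),
                nrow = n_genes)
  counts <- as_tibble(cbind(ctrl, trt), .name_repair = "minimal")
  names(counts) <- c(paste0("control_", seq_len(n_per_group)),
                     paste0("treated_", seq_len(n_per_group)))
  counts <- mutate(counts, gene_id = gene_ids, .before = 1)

  lc <- log2(ctrl + 1); lt <- log2(trt + 1)
  p <- vapply(seq_len(n_genes), function(i) {
    welch_t_test(lt[i, ], lc[i, ])$p_value
  }, numeric(1))
  de <- tibble(
    gene_id = gene_ids,
    fold_change = (rowMeans(trt) + 0.5) / (rowMeans(ctrl) + 0.5),
    p_value = p, q_value = bh_fdr(p)
  )
  list(counts = counts, de = de, truth = planted)
}

#' Simulate promoter sequences with a planted motif
#'
#' Background sequences drawn from the stated base composition are screened
#' so that neither strand contains a chance occurrence of the consensus
#' (offending draws are redrawn); the consensus is then planted once, at a
#' recorded uniform position and random strand, in the chosen subset. The
#' returned truth is therefore exact: a scan at consensus-level threshold
#' finds hits in precisely the planted promoters.
#'
#' @param n_promoters Number of promoters (default 36).
#' @param n_planted Promoters receiving the motif (default 18).
#' @param length Promoter length in bp (default 1000).
#' @param consensus Planted consensus (default `"TTTGTCATCA"`, a synthetic
#'   SKN-1-like site with the GTCAT core).
#' @param at_frac AT fraction of the background (default 0.64, worm-like).
#' @param seed Seed.
#' @return A list: `promoters` (tibble `gene_id`, `seq`, usable by
#'   [scan_motif()]), `truth` (tibble `gene_id`, `planted`, `position`,
#'   `strand`), `consensus`.
#' @export
gen_promoters <- function(n_promoters = 36, n_planted = 18, length = 1000,
                          consensus = "TTTGTCATCA", at_frac = 0.64, seed = 1) {
  L <- nchar(consensus)
  if (L > length) abort("motif is longer than the promoter.")
  stopifnot(n_planted <= n_promoters)
  set.seed(seed)
  probs <- c(A = at_frac / 2, C = (1 - at_frac) / 2,
             G = (1 - at_frac) / 2, T = at_frac / 2)
  has_motif <- function(s) {
    grepl(consensus, s, fixed = TRUE) || grepl(revcomp(consensus), s, fixed = TRUE)
  }
  draw_clean <- function() {
    repeat {
      s <- paste(sample(names(probs), length, replace = TRUE, prob = probs),
                 collapse = "")
      if (!has_motif(s)) return(s)
    }
  }
  ids <- sprintf("prom_%02d", seq_len(n_promoters))
  seqs <- vapply(ids, function(i) draw_clean(), character(1))
  planted_ids <- sort(sample(ids, n_planted))
  truth <- tibble(gene_id = ids, planted = ids %in% planted_ids,
                  position = NA_integer_, strand = NA_character_)
  for (g in planted_ids) {
    pos <- sample.int(length - L + 1, 1)
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") consensus else revcomp(consensus)
    s <- seqs[[g]]
    substr(s, pos, pos + L - 1) <- ins
    seqs[[g]] <- s
    truth$position[truth$gene_id == g] <- pos
    truth$strand[truth$gene_id == g] <- strand
  }
  list(promoters = tibble(gene_id = ids, seq = unname(seqs)),
       truth = truth, consensus = consensus)
}

#' Simulate a two-channel cell image with ROI and known radial pattern
#'
#' Builds an elliptical cell ROI with a Gaussian nuclear blob (nuclear
#' channel) and a signal channel following one of four patterns: `absent`
#' (baseline only), `uniform`, `nuclear` (Gaussian at the nucleus), or
#' `ring(r0, width)` — a Gaussian shell at normalized radius `r0`, where the
#' radius is normalized by the analytic ray-ellipse boundary distance from
#' the nucleus center (independent of the polygon-based profiling code).
#' Pixels get Poisson shot noise plus Gaussian read noise and are clamped to
#' non-negative integers.
#'
#' @param width,height Canvas size in pixels (default 120 x 120).
#' @param roi Ellipse parameters `list(cx, cy, rx, ry)`.
#' @param nucleus `list(dx, dy, radius)`: center offset from the ellipse
#'   center and Gaussian sigma.
#' @param pattern `list(type, r0, width)`; `type` one of `"absent"`,
#'   `"uniform"`, `"ring"`, `"nuclear"`.
#' @param amplitude Signal amplitude above baseline (default 80).
#' @param baseline Baseline intensity (default 10).
#' @param nuclear_amplitude Nuclear blob amplitude (default 150).
#' @param read_noise_sd Gaussian read noise s.d. (default 2).
#' @param n_vertices Polygon vertices for the ROI (default 64).
#' @param seed Seed.
#' @return A list: `image` (`wl_image` with channels `nuclear`, `signal`),
#'   `roi` (polygon tibble), `center` (true nucleus center), `truth`.
#' @export
gen_image <- function(width = 120, height = 120,
                      roi = list(cx = 60, cy = 60, rx = 45, ry = 32),
                      nucleus = list(dx = -8, dy = 5, radius = 7),
                      pattern = list(type = "ring", r0 = 0.5, width = 0.06),
                      amplitude = 80, baseline = 10, nuclear_amplitude = 150,
                      read_noise_sd = 2, n_vertices = 64, seed = 1) {
  set.seed(seed)
  ctr <- c(roi$cx + nucleus$dx, roi$cy + nucleus$dy)
  if (((ctr[1] - roi$cx) / roi$rx)^2 + ((ctr[2] - roi$cy) / roi$ry)^2 >= 1) {
    abort("nucleus center lies outside the ROI ellipse.")
  }
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  poly <- tibble(x = roi$cx + roi$rx * cos(th), y = roi$cy + roi$ry * sin(th))

  px <- rep(seq_len(width) - 0.5, each = height)
  py <- rep(seq_len(height) - 0.5, times = width)
  inside <- ((px - roi$cx) / roi$rx)^2 + ((py - roi$cy) / roi$ry)^2 <= 1
  d2n <- (px - ctr[1])^2 + (py - ctr[2])^2

  # analytic normalized radius: solve |(c + t u - e)| on the ellipse for t>0
  ux <- px - ctr[1]; uy <- py - ctr[2]
  X <- (ctr[1] - roi$cx) / roi$rx; Y <- (ctr[2] - roi$cy) / roi$ry
  A <- (ux / roi$rx)^2 + (uy / roi$ry)^2
  B <- 2 * (X * ux / roi$rx + Y * uy / roi$ry)
  C <- X^2 + Y^2 - 1
  tpos <- (-B + sqrt(pmax(0, B^2 - 4 * A * C))) / (2 * A)
  rnorm_ <- ifelse(A == 0, 0, 1 / tpos)

  lam_sig <- rep(baseline, width * height)
  lam_sig[inside] <- lam_sig[inside] + switch(
    pattern$type,
    absent = 0,
    uniform = amplitude,
    nuclear = amplitude * exp(-d2n[inside] / (2 * nucleus$radius^2)),
    ring = amplitude * exp(-(rnorm_[inside] - pattern$r0)^2 /
                             (2 * pattern$width^2)),
    abort("unknown pattern type.")
  )
  lam_nuc <- baseline + nuclear_amplitude * exp(-d2n / (2 * nucleus$radius^2))
  lam_nuc[!inside] <- baseline

  noisy <- function(lam) {
    v <- rpois(length(lam), lam) + rnorm(length(lam), 0, read_noise_sd)
    matrix(pmax(0, round(v)), nrow = height, ncol = width)
  }
  img <- as_image(list(nuclear = noisy(lam_nuc), signal = noisy(lam_sig)))
  list(image = img, roi = poly, center = ctr,
       truth = c(pattern, list(center = ctr, amplitude = amplitude,
                               baseline = baseline, seed = seed)))
}
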
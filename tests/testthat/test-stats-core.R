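test_that("welch_t_test matches the scalar formula and handles degenerate input", {
  r <- welch_t_test(c(10, 12, 14), c(11, 13, 15, 17))
  o <- oracle_welch(c(10, 12, 14), c(11, 13, 15, 17))
  expect_equal(r$statistic, o$t, tolerance = 1e-12)
  expect_equal(r$df, o$df, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)

  id <- welch_t_test(c(3, 5, 7), c(3, 5, 7))
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)

  expect_error(welch_t_test(1, c(2, 3)), "at least 2")
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p_value, 1)

  # symmetry up to the sign of the statistic
  a <- rnorm(6); b <- rnorm(8)
  expect_equal(welch_t_test(a, b)$p_value, welch_t_test(b, a)$p_value)
  expect_equal(welch_t_test(a, b)$statistic, -welch_t_test(b, a)$statistic)
})

test_that("welch_t_test equals the pooled t-test when variances and sizes are equal", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(7)
    y <- sample(x) + runif(1, -2, 2)  # same variance exactly, shifted
    r <- welch_t_test(x, y)
    pooled <- t.test(x, y, var.equal = TRUE)
    expect_equal(r$statistic, unname(pooled$statistic), tolerance = 1e-10)
    expect_equal(r$df, unname(pooled$parameter), tolerance = 1e-10)
    expect_equal(r$p_value, pooled$p.value, tolerance = 1e-10)
  }
})

test_that("rank_sum_test exact path equals the enumeration oracle for all small rank layouts", {
  # every assignment of distinct ranks for every (m, n) with m + n <= 8;
  # wilcox.test's exact mode is the independent oracle in the tie-free case
  for (N in 2:8) {
    for (m in 1:(N - 1)) {
      sets <- utils::combn(N, m)
      for (k in seq_len(ncol(sets))) {
        x <- sets[, k]
        y <- setdiff(seq_len(N), x)
        ours <- rank_sum_test(x, y)$p_value
        ref <- wilcox.test(x, y, exact = TRUE)$p.value
        expect_equal(ours, ref, tolerance = 1e-12)
      }
    }
  }
})

test_that("rank_sum_test handles ties, identity and the 3-vs-3 separation case", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)  # 2/20
  expect_gte(rank_sum_test(c(1, 2, 2, 5), c(1, 2, 2, 5))$p_value, 0.99)
  expect_equal(rank_sum_test(rep(3, 4), rep(3, 5))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "at least 1")
  # tie-corrected approximation stays close to the exact permutation p
  set.seed(7)
  x <- round(rnorm(9), 1); y <- round(rnorm(9), 1)
  exact <- rank_sum_test(x, y, exact_limit = 20)$p_value
  approx <- rank_sum_test(x, y, exact_limit = 0)$p_value
  expect_lt(abs(exact - approx), 0.05)
})

test_that("fishers_method matches its definition and the quadrature oracle", {
  r <- fishers_method(c(1, 1, 1))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 6L)

  p0 <- 0.037
  expect_equal(fishers_method(p0)$p_value, p0, tolerance = 1e-12)

  r <- fishers_method(c(0.01, 0.04, 0.20))
  expect_equal(r$chi2, -2 * (log(0.01) + log(0.04) + log(0.20)), tolerance = 1e-12)
  expect_equal(r$p_value, oracle_chisq_upper(r$chi2, 6), tolerance = 1e-8)

  expect_error(fishers_method(c(0.5, 0)), "p_floor")
  expect_equal(fishers_method(c(0.5, 0), p_floor = 1e-300)$df, 4L)
  expect_error(fishers_method(c(0.5, 1.2)), "probabilities")
})

test_that("fisher-combined p is uniform under a uniform null", {
  set.seed(123)
  k <- 4
  combined <- replicate(2000, fishers_method(runif(k))$p_value)
  ks <- suppressWarnings(ks.test(combined, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_fdr equals the brute-force step-up definition and is permutation-invariant", {
  p8 <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060, 0.074, 0.205)
  expect_equal(bh_fdr(p8), oracle_bh(p8), tolerance = 1e-12)

  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(0.2), 0.2)

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
})

test_that("one_way_anova_tukey matches the two-group identity and degenerates correctly", {
  d <- data.frame(y = rep(c(1, 2, 3), each = 3), g = rep(c("a", "b", "c"), each = 3))
  r0 <- one_way_anova_tukey(data.frame(y = rep(5, 9), g = d$g), y, g)
  expect_equal(r0$statistic, 0)
  expect_true(all(r0$pairwise$p_adj == 1))

  set.seed(3)
  d2 <- data.frame(y = rnorm(12), g = rep(c("a", "b"), each = 6))
  r2 <- one_way_anova_tukey(d2, y, g)
  t2 <- t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(r2$statistic, unname(t2$statistic)^2, tolerance = 1e-10)

  # Tukey-adjusted p never below the raw pairwise p
  d3 <- data.frame(y = rnorm(15), g = rep(c("a", "b", "c"), each = 5))
  r3 <- one_way_anova_tukey(d3, y, g)
  raw <- c(
    t.test(d3$y[d3$g == "b"], d3$y[d3$g == "a"], var.equal = TRUE)$p.value,
    t.test(d3$y[d3$g == "c"], d3$y[d3$g == "a"], var.equal = TRUE)$p.value,
    t.test(d3$y[d3$g == "c"], d3$y[d3$g == "b"], var.equal = TRUE)$p.value
  )
  expect_true(all(r3$pairwise$p_adj >= raw - 1e-10))

  expect_error(one_way_anova_tukey(data.frame(y = 1:2, g = c("a", "b")), y, g),
               ">= 2 values")
  expect_error(one_way_anova_tukey(data.frame(y = 1:3, g = "a"), y, g),
               "at least 2 groups")
})

test_that("two_way_anova_bonferroni applies the per-bin Bonferroni rule exactly", {
  set.seed(9)
  n_bins <- 6
  d <- expand.grid(bin = 1:n_bins, rep = 1:5, group = c("ctrl", "trt"))
  d$y <- rnorm(nrow(d)) + ifelse(d$group == "trt" & d$bin %in% 3:4, 3, 0)
  r <- two_way_anova_bonferroni(d, y, group, bin, ref = "ctrl")

  # per-bin p equals an independent Welch-with-Bonferroni oracle
  for (b in 1:n_bins) {
    o <- oracle_welch(d$y[d$group == "trt" & d$bin == b],
                      d$y[d$group == "ctrl" & d$bin == b])
    row <- r$per_bin[r$per_bin$bin == b, ]
    expect_equal(row$p_raw, o$p, tolerance = 1e-12)
    expect_equal(row$p_adj, min(1, o$p * n_bins), tolerance = 1e-12)
  }
  # the planted shift is flagged where planted
  expect_true(all(r$per_bin$significant[r$per_bin$bin %in% 3:4]))
  expect_false(any(r$per_bin$significant[!r$per_bin$bin %in% 3:4]))

  # identical groups -> all adjusted p = 1
  d$y2 <- rep(rnorm(n_bins * 5), times = 2)
  r1 <- two_way_anova_bonferroni(d, y2, group, bin)
  expect_true(all(r1$per_bin$p_adj == 1))

  expect_error(
    two_way_anova_bonferroni(d[!(d$group == "trt" & d$bin == 2), ], y, group, bin),
    "empty cell"
  )
})

test_that("two_way_anova_bonferroni with one bin reduces to the one-way comparison", {
  set.seed(4)
  d <- data.frame(y = rnorm(20), group = rep(c("a", "b"), each = 10), bin = 1)
  r <- two_way_anova_bonferroni(d, y, group, bin)
  expect_equal(r$per_bin$p_adj, r$per_bin$p_raw)  # no multiplicity inflation
  ow <- one_way_anova_tukey(d, y, group)
  expect_equal(r$omnibus$statistic[r$omnibus$term == "group"], ow$statistic,
               tolerance = 1e-10)
})

test_that("blot_ratio normalizes to H3 and matches a manual recomputation", {
  lanes <- data.frame(
    ptm = c(4, 5, 6, 8, 9, 10), h3 = c(2, 2, 2, 2, 2, 2),
    condition = rep(c("control", "treated"), each = 3),
    replicate = rep(1:3, 2)
  )
  r <- blot_ratio(lanes, ptm, h3, condition, replicate)
  expect_equal(r$ratio, mean(c(4, 4.5, 5)) / mean(c(2, 2.5, 3)))

  same <- within(lanes, ptm <- h3)
  expect_equal(blot_ratio(same, ptm, h3, condition, replicate)$ratio, 1)

  dbl <- lanes; dbl$ptm[4:6] <- 2 * dbl$ptm[1:3]
  expect_equal(blot_ratio(dbl, ptm, h3, condition, replicate)$ratio, 2)

  set.seed(2)
  rnd <- data.frame(ptm = runif(8, 1, 5), h3 = runif(8, 1, 3),
                    condition = rep(c("control", "treated"), 4),
                    replicate = rep(1:4, each = 2))
  rr <- blot_ratio(rnd, ptm, h3, condition, replicate)
  norm <- rnd$ptm / rnd$h3
  expect_equal(rr$ratio, mean(norm[rnd$condition == "treated"]) /
                 mean(norm[rnd$condition == "control"]), tolerance = 1e-12)
  expect_equal(rr$test$p_value,
               oracle_welch(norm[rnd$condition == "treated"],
                            norm[rnd$condition == "control"])$p, tolerance = 1e-12)

  bad <- lanes; bad$h3[1] <- 0
  expect_error(blot_ratio(bad, ptm, h3, condition, replicate), "positive")
})
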
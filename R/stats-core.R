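#' Welch's two-sample t-test
#'
#' Unpaired two-sample t-test with Welch's correction (unequal variances,
#' Welch-Satterthwaite degrees of freedom), the comparison used for western
#' blot quantifications and expression bar charts.
#'
#' When both samples have zero variance the test statistic is degenerate: equal
#' means return `statistic = 0, p = 1` by convention; unequal constant samples
#' return an infinite statistic with `p = 0`.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return A `wl_test` object with `statistic` (t), `df`
#'   (Welch-Satterthwaite), `p_value` (two-sided) and group mean estimates.
#'   Use [generics::tidy()] for a tibble.
#' @export
#' @examples
#' welch_t_test(c(10, 12, 14), c(11, 13, 15, 17))
welch_t_test <- function(x, y) {
  check_numeric_vector(x, "x", 2L)
  check_numeric_vector(y, "y", 2L)
  est <- c(mean_x = mean(x), mean_y = mean(y))
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(new_wl_test(0, length(x) + length(y) - 2, 1,
                         "Welch two-sample t-test", est))
    }
    return(new_wl_test(sign(mean(x) - mean(y)) * Inf,
                       length(x) + length(y) - 2, 0,
                       "Welch two-sample t-test", est))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  new_wl_test(ht$statistic, ht$parameter, ht$p.value,
              "Welch two-sample t-test", est)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) comparison of two samples, as used for per-gene
#' TSS-window signal distributions. Small samples (`m + n <= exact_limit`) are
#' tested exactly by enumerating every assignment of the observed values to
#' the two groups, which remains exact in the presence of ties; larger samples
#' use the normal approximation with the usual tie correction (no continuity
#' correction).
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_limit Largest combined size for which the exact permutation
#'   distribution is enumerated (default 20).
#' @param paired If `TRUE`, runs a paired signed-rank test via
#'   [stats::wilcox.test()] instead (normal approximation). The unpaired test
#'   is the default.
#' @return A `wl_test` with the Mann-Whitney `U` statistic (for `x`) and a
#'   two-sided p-value.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
rank_sum_test <- function(x, y, exact_limit = 20, paired = FALSE) {
  check_numeric_vector(x, "x")
  check_numeric_vector(y, "y")
  if (paired) {
    ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
    return(new_wl_test(ht$statistic, NA_real_, ht$p.value,
                       "Wilcoxon signed-rank test (paired, normal approximation)"))
  }
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])              # rank sum of x
  u <- w - m * (m + 1) / 2             # Mann-Whitney U
  mu_w <- m * (N + 1) / 2
  if (N <= exact_limit) {
    # exact permutation null: every C(N, m) assignment of the observed ranks
    sets <- utils::combn(N, m)
    w_null <- colSums(matrix(r[sets], nrow = m))
    p <- mean(abs(w_null - mu_w) >= abs(w - mu_w) - 1e-12)
    method <- "Wilcoxon rank-sum test (exact permutation)"
  } else {
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (w - mu_w) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "Wilcoxon rank-sum test (normal approximation, tie-corrected)"
  }
  new_wl_test(c(U = u), NA_real_, p, method,
              c(median_x = median(x), median_y = median(y)))
}

#' Combine independent p-values with Fisher's method
#'
#' Computes `chi2 = -2 * sum(log(p))` on `2k` degrees of freedom, the
#' combination applied to per-replicate log-rank p-values in replicated
#' lifespan assays.
#'
#' A zero p-value makes `-2 log p` undefined; rather than flooring silently,
#' the function errors unless an explicit `p_floor` is supplied (values below
#' the floor are raised to it). `1e-300` is a reasonable floor for p-values
#' that underflowed double precision.
#'
#' @param p Numeric vector of independent p-values in (0, 1].
#' @param p_floor Optional positive floor applied to `p` before combining.
#' @return A `wl_fisher` object: `chi2`, `df = 2k`, `p_value`, `k`.
#' @export
#' @examples
#' fishers_method(c(0.01, 0.04, 0.20))
fishers_method <- function(p, p_floor = NULL) {
  check_probabilities(p, "p")
  if (!is.null(p_floor)) {
    stopifnot(is.numeric(p_floor), length(p_floor) == 1, p_floor > 0)
    p <- pmax(p, p_floor)
  }
  if (any(p == 0)) {
    abort(paste0("`p` contains 0; -2*log(0) is undefined. Pass an explicit ",
                 "`p_floor` (e.g. 1e-300) to floor underflowed p-values."))
  }
  chi2 <- -2 * sum(log(p))
  k <- length(p)
  structure(
    list(chi2 = chi2, df = 2L * k, p_value = pchisq(chi2, df = 2 * k, lower.tail = FALSE),
         k = k, method = "Fisher's combined probability test"),
    class = "wl_fisher"
  )
}

#' @export
print.wl_fisher <- function(x, ...) {
  cat("Fisher's method:", "chi2 =", format(x$chi2, digits = 6),
      "df =", x$df, "p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Output order matches input order;
#' adjusted values never fall below the raw p-value.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of BH-adjusted values (q-values) in input order.
#' @export
bh_fdr <- function(p) {
  check_probabilities(p, "p")
  p.adjust(p, method = "BH")
}

#' One-way ANOVA with Tukey's HSD
#'
#' Omnibus F-test across labeled groups followed by Tukey honest significant
#' difference adjusted p-values for every pair, the procedure used for
#' multi-genotype blot quantifications.
#'
#' @param data Data frame with one row per measurement.
#' @param value,group Columns of `data` holding the measurement and its group
#'   label (tidy evaluation).
#' @return A `wl_anova` object: omnibus `statistic` (F), `df` (c(df1, df2)),
#'   `p_value`, and `$pairwise`, a tibble with one row per group pair
#'   (`comparison`, `diff`, `conf_low`, `conf_high`, `p_adj`).
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b", "c"), each = 2))
#' one_way_anova_tukey(d, y, g)
one_way_anova_tukey <- function(data, value, group) {
  df <- tibble(
    value = pull(data, {{ value }}),
    group = as.character(pull(data, {{ group }}))
  )
  check_numeric_vector(df$value, "value")
  sizes <- table(df$group)
  if (length(sizes) < 2) abort("one_way_anova_tukey() needs at least 2 groups.")
  if (any(sizes < 2)) {
    abort(sprintf("every group needs >= 2 values; too small: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  df$group <- factor(df$group)
  if (var(df$value) == 0) {
    pairs <- utils::combn(levels(df$group), 2)
    return(structure(
      list(statistic = 0, df = c(length(sizes) - 1, nrow(df) - length(sizes)),
           p_value = 1,
           pairwise = tibble(
             comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
             diff = 0, conf_low = 0, conf_high = 0, p_adj = 1),
           method = "One-way ANOVA with Tukey HSD"),
      class = c("wl_anova", "wl_test")))
  }
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"], conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  structure(
    list(statistic = an[["F value"]][1],
         df = c(an[["Df"]][1], an[["Df"]][2]),
         p_value = an[["Pr(>F)"]][1],
         pairwise = pairwise,
         method = "One-way ANOVA with Tukey HSD"),
    class = c("wl_anova", "wl_test")
  )
}

#' Two-way ANOVA with per-bin Bonferroni comparisons
#'
#' Group-by-bin factorial analysis used for radial-profile curves: a two-way
#' omnibus ANOVA (Type II sums of squares, robust to the unbalanced cell
#' counts typical of per-cell imaging data) plus, within every bin, a Welch
#' comparison of each group against a reference group, Bonferroni-adjusted by
#' the number of bins. The per-bin `significant` flag (adjusted p < 0.05)
#' mirrors the usual gray-dot display convention for profile plots.
#'
#' With a single bin the analysis reduces to the one-way comparison with no
#' multiplicity inflation.
#'
#' @param data Data frame of measurements.
#' @param value,group,bin Columns holding the measurement, group label and bin
#'   label (tidy evaluation).
#' @param ref Reference group for the per-bin comparisons; defaults to the
#'   first group level.
#' @param alpha Significance level for the per-bin flags (default 0.05).
#' @return A `wl_anova2` object with `$omnibus` (term-level tibble:
#'   `term`, `df`, `statistic`, `p_value`) and `$per_bin` (tibble:
#'   `bin`, `group`, `ref`, `p_raw`, `p_adj`, `significant`).
#' @export
two_way_anova_bonferroni <- function(data, value, group, bin, ref = NULL,
                                     alpha = 0.05) {
  df <- tibble(
    value = pull(data, {{ value }}),
    group = as.character(pull(data, {{ group }})),
    bin = pull(data, {{ bin }})
  )
  check_numeric_vector(df$value, "value")
  groups <- unique(df$group)
  bins <- sort(unique(df$bin))
  if (length(groups) < 2) abort("two_way_anova_bonferroni() needs >= 2 groups.")
  cells <- table(df$group, as.character(df$bin))
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty cell: group '%s' x bin '%s'.",
                  rownames(cells)[idx[1]], colnames(cells)[idx[2]]))
  }
  ref <- ref %||% groups[1]
  if (!ref %in% groups) abort(sprintf("`ref` group '%s' not present.", ref))
  n_bins <- length(bins)

  if (n_bins == 1) {
    ow <- one_way_anova_tukey(df, value, group)
    omnibus <- tibble(term = "group", df = ow$df[1],
                      statistic = ow$statistic, p_value = ow$p_value)
  } else {
    df$groupf <- factor(df$group)
    df$binf <- factor(df$bin)
    fit <- lm(value ~ groupf * binf, data = df)
    a2 <- car::Anova(fit, type = 2)
    keep <- rownames(a2) != "Residuals"
    omnibus <- tibble(
      term = c("group", "bin", "group:bin")[seq_len(sum(keep))],
      df = a2$Df[keep], statistic = a2$`F value`[keep],
      p_value = a2$`Pr(>F)`[keep]
    )
  }

  others <- setdiff(groups, ref)
  per_bin <- purrr::map_dfr(bins, function(b) {
    vb <- df[df$bin == b, ]
    purrr::map_dfr(others, function(g) {
      xg <- vb$value[vb$group == g]
      xr <- vb$value[vb$group == ref]
      p <- if (length(xg) >= 2 && length(xr) >= 2) {
        welch_t_test(xg, xr)$p_value
      } else {
        NA_real_  # singleton cells cannot be tested per bin
      }
      tibble(bin = b, group = g, ref = ref, p_raw = p,
             p_adj = pmin(1, p * n_bins))
    })
  })
  per_bin$significant <- !is.na(per_bin$p_adj) & per_bin$p_adj < alpha

  structure(
    list(omnibus = omnibus, per_bin = per_bin, n_bins = n_bins, ref = ref,
         method = "Two-way ANOVA (Type II) with per-bin Bonferroni comparisons"),
    class = "wl_anova2"
  )
}

#' @export
print.wl_anova2 <- function(x, ...) {
  cat(x$method, "\n")
  print(x$omnibus)
  cat("Significant bins:", sum(x$per_bin$significant, na.rm = TRUE),
      "of", nrow(x$per_bin), "comparisons\n")
  invisible(x)
}

#' Western-blot band ratios normalized to total H3
#'
#' Normalizes each lane's PTM band intensity by its matched total-H3
#' intensity, summarizes the treated-vs-control ratio of mean normalized
#' levels (the value displayed in blot-screen heatmaps), and tests the
#' normalized levels with Welch's t-test.
#'
#' @param data Data frame with one row per lane/replicate.
#' @param ptm,h3 Columns with the PTM and total-H3 band intensities (strictly
#'   positive).
#' @param condition,replicate Columns labeling condition and replicate.
#' @param control Label of the control condition (default `"control"`).
#' @return A `wl_blot` object: `$table` (per-lane tibble with
#'   `normalized = ptm / h3`), `$ratio` (mean treated / mean control), and
#'   `$test` (`wl_test`).
#' @export
blot_ratio <- function(data, ptm, h3, condition, replicate,
                       control = "control") {
  tab <- tibble(
    ptm = pull(data, {{ ptm }}),
    h3 = pull(data, {{ h3 }}),
    condition = as.character(pull(data, {{ condition }})),
    replicate = pull(data, {{ replicate }})
  )
  if (any(tab$ptm <= 0) || any(tab$h3 <= 0)) {
    abort("band intensities must be strictly positive.")
  }
  conds <- unique(tab$condition)
  if (length(conds) != 2 || !control %in% conds) {
    abort("`data` must contain exactly two conditions including `control`.")
  }
  treated <- setdiff(conds, control)
  tab$normalized <- tab$ptm / tab$h3
  x <- tab$normalized[tab$condition == treated]
  y <- tab$normalized[tab$condition == control]
  if (length(x) < 2 || length(y) < 2) {
    abort("each condition needs >= 2 replicates.")
  }
  structure(
    list(table = tab, ratio = mean(x) / mean(y),
         treated = treated, control = control,
         test = welch_t_test(x, y)),
    class = "wl_blot"
  )
}

#' @export
print.wl_blot <- function(x, ...) {
  cat("Blot ratio (", x$treated, " / ", x$control, "): ",
      format(x$ratio, digits = 4), "\n", sep = "")
  print(x$test)
  invisible(x)
}
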
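# Independent oracle implementations used across the suite. Each is a direct
# transcription of a definition, kept free of the package's code paths.

# Welch's t from the scalar formula
oracle_welch <- function(x, y) {
  m <- length(x); n <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / m + vy / n
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / m)^2 / (m - 1) + (vy / n)^2 / (n - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# BH step-up by the min-over-suffix definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  # min over suffix of m*p_(j)/j for j >= i
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(1, m * p[o][i:m] / seq(i, m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# chi-square upper tail by quadrature of the density
oracle_chisq_upper <- function(x, df) {
  dens <- function(t) t^(df / 2 - 1) * exp(-t / 2) / (2^(df / 2) * gamma(df / 2))
  integrate(dens, x, Inf, rel.tol = 1e-10)$value
}

# log-rank chi-square from the hand-built hypergeometric table
oracle_logrank <- function(day_a, event_a, day_b, event_b) {
  times <- sort(unique(c(day_a[event_a == 1], day_b[event_b == 1])))
  O <- E <- V <- 0
  for (t in times) {
    na <- sum(day_a >= t); nb <- sum(day_b >= t)
    da <- sum(day_a == t & event_a == 1); db <- sum(day_b == t & event_b == 1)
    n <- na + nb; d <- da + db
    O <- O + da
    E <- E + d * na / n
    if (n > 1) V <- V + d * (na / n) * (nb / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Kaplan-Meier by the hand product-limit recursion
oracle_km <- function(day, event) {
  times <- sort(unique(day[event == 1]))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    n_risk <- sum(day >= times[i])
    d <- sum(day == times[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  list(time = times, surv = out)
}

# per-base mean signal of an interval track over [start, end)
oracle_interval_mean <- function(track_df, chrom, start, end) {
  v <- numeric(end - start)
  for (i in seq_len(nrow(track_df))) {
    r <- track_df[i, ]
    if (r$chrom != chrom) next
    lo <- max(r$start, start); hi <- min(r$end, end)
    if (lo < hi) v[(lo - start + 1):(hi - start)] <- r$depth
  }
  mean(v)
}

# all-pairs window-to-gene assignment with the promoter-extension rule
oracle_assign <- function(sites, ann, upstream) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(ann))) {
      if (sites$chrom[i] != ann$chrom[j]) next
      lo <- if (ann$strand[j] == "+") max(0, ann$start[j] - upstream) else ann$start[j]
      hi <- if (ann$strand[j] == "+") ann$end[j] else ann$end[j] + upstream
      if (sites$start[i] < hi && sites$end[i] > lo) {
        out[[length(out) + 1]] <- data.frame(win = i, gene = ann$gene_id[j])
      }
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(win = integer(), gene = character())
}

# exhaustive sliding-window PWM score (forward strand)
oracle_best_window <- function(seq, log_odds) {
  L <- ncol(log_odds)
  chars <- strsplit(seq, "")[[1]]
  best <- -Inf; best_at <- NA
  for (i in seq_len(length(chars) - L + 1)) {
    sc <- 0
    for (j in seq_len(L)) {
      b <- match(chars[i + j - 1], c("A", "C", "G", "T"))
      sc <- sc + if (is.na(b)) -Inf else log_odds[b, j]
    }
    if (sc > best) { best <- sc; best_at <- i }
  }
  list(score = best, position = best_at)
}

# ratio-track fixture: two hand-written piecewise tracks on a 60-bp genome
toy_tracks <- function() {
  sl <- c(chrA = 60)
  mark <- as_track(data.frame(chrom = "chrA",
                              start = c(0, 10, 30), end = c(10, 30, 50),
                              depth = c(2, 4, 1)), seqlengths = sl)
  h3 <- as_track(data.frame(chrom = "chrA",
                            start = c(0, 20, 40), end = c(20, 40, 60),
                            depth = c(2, 2, 4)), seqlengths = sl)
  list(mark = mark, h3 = h3, sl = sl)
}
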
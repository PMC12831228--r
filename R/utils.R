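#' Derive a child seed from a run seed
#'
#' All generators in the package are pure functions of `spec + seed`. When one
#' run seeds several generators, child seeds are fanned out deterministically
#' with a counter: `child = (seed + 99991 * counter) mod (2^31 - 1)`.
#'
#' @param seed Integer run seed.
#' @param counter Non-negative integer counter (0 returns a value derived from
#'   the seed itself, so child seeds never collide with the raw seed stream).
#' @return A single integer usable with [set.seed()].
#' @export
#' @examples
#' child_seed(1, 0:3)
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(counter))
  as.integer((as.numeric(seed) + 99991 * (as.numeric(counter) + 1)) %% 2147483647)
}

# shared input checks ---------------------------------------------------------

check_numeric_vector <- function(x, arg, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric vector with at least %d non-missing value(s).",
                  arg, min_len))
  }
  invisible(x)
}

check_probabilities <- function(p, arg = "p") {
  check_numeric_vector(p, arg)
  if (any(p < 0 | p > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", arg))
  }
  invisible(p)
}

new_wl_test <- function(statistic, df, p_value, method, estimate = NULL) {
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), method = method, estimate = estimate),
    class = "wl_test"
  )
}

#' @export
print.wl_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 6),
      " df =", paste(format(x$df, digits = 5), collapse = ", "),
      " p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}
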
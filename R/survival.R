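#' Read / write lifespan tables
#'
#' Lifespan tables are tidy TSVs with one row per animal and columns
#' `id`, `condition`, `replicate`, `day` (positive; day of death or of
#' censoring) and `event` (1 = death observed, 0 = censored).
#'
#' @param path File path.
#' @return `read_lifespan()` returns a validated tibble.
#' @export
read_lifespan <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  validate_lifespan(tab)
}

#' @rdname read_lifespan
#' @param data Lifespan tibble.
#' @export
write_lifespan <- function(data, path) {
  readr::write_tsv(validate_lifespan(data), path)
  invisible(path)
}

validate_lifespan <- function(data) {
  need <- c("condition", "replicate", "day", "event")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("lifespan table is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(data$day <= 0)) abort("all `day` values must be positive.")
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  as_tibble(data)
}

#' Kaplan-Meier survival curve for one cohort
#'
#' Product-limit estimate of the survival function with right-censoring.
#' Survival starts at 1, is non-increasing and drops only at observed event
#' times.
#'
#' @param data Data frame for a single cohort.
#' @param day,event Columns holding follow-up day and the event flag
#'   (1 = death observed, 0 = censored).
#' @return A `wl_km` tibble with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (value of S after `time`), plus attributes `n`
#'   (cohort size) and `mean_observed` (mean of event lifespans).
#' @export
#' @examples
#' kaplan_meier(data.frame(day = c(10, 20, 30), event = 1))
kaplan_meier <- function(data, day = day, event = event) {
  d <- pull(data, {{ day }})
  e <- pull(data, {{ event }})
  if (length(d) == 0 || any(d <= 0)) abort("`day` must be positive and non-empty.")
  if (sum(e) == 0) abort("cohort has no observed events; cannot estimate survival.")
  fit <- survival::survfit(survival::Surv(d, e) ~ 1)
  out <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  structure(out, class = c("wl_km", class(out)),
            n = length(d), mean_observed = mean(d[e == 1]))
}

#' Log-rank test between two survival cohorts
#'
#' Observed-minus-expected event counts with hypergeometric variance over the
#' distinct event days (same-day events pooled into one risk-set update),
#' yielding a chi-square statistic on 1 degree of freedom.
#'
#' @param data Data frame covering exactly two conditions.
#' @param day,event,condition Columns holding follow-up day, event flag and
#'   the two-level condition label.
#' @return A `wl_test` with `statistic` (chi-square), `df = 1` and `p_value`.
#' @export
logrank_test <- function(data, day = day, event = event, condition = condition) {
  d <- pull(data, {{ day }})
  e <- pull(data, {{ event }})
  g <- as.character(pull(data, {{ condition }}))
  lv <- unique(g)
  if (length(lv) != 2) abort("logrank_test() needs exactly two conditions.")
  for (l in lv) {
    if (sum(e[g == l]) == 0) {
      abort(sprintf("condition '%s' has no observed events.", l))
    }
  }
  sd_ <- survival::survdiff(survival::Surv(d, e) ~ g)
  new_wl_test(sd_$chisq, 1, pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
              "Log-rank test")
}

#' Replicate-combined lifespan test
#'
#' The replicated lifespan analysis: a log-rank test within each biological
#' replicate (treated vs control), per-replicate p-values combined with
#' Fisher's method, and the percent mean-lifespan-extension summary
#' `100 * (mean treated - mean control) / mean control`.
#'
#' Means use observed-event lifespans only by default (censored animals, e.g.
#' escapers, are excluded); `mean_type = "restricted"` uses the restricted
#' mean survival time from the Kaplan-Meier estimate instead. The headline
#' extension pools animals across replicates; a mean of per-replicate
#' extensions is also reported.
#'
#' @param data Lifespan table (see [read_lifespan()]) with a two-level
#'   condition column and a replicate column; replicates are assumed
#'   independent biological runs.
#' @param control Label of the control condition.
#' @param day,event,condition,replicate Column specifications (tidy
#'   evaluation).
#' @param mean_type `"observed"` (default) or `"restricted"`.
#' @param p_floor Floor passed to [fishers_method()] so that per-replicate
#'   p-values that underflow to 0 remain combinable (default 1e-300).
#' @return A `wl_lifespan` object: `$replicates` (per-replicate tibble with
#'   cohort sizes, means, extension and log-rank results), `$combined`
#'   (`wl_fisher`), `$mean_extension_pct` (pooled),
#'   `$mean_extension_pct_replicates`, and pooled cohort means. `tidy()`
#'   returns the replicate table, `glance()` a one-row summary.
#' @export
combined_lifespan_test <- function(data, control, day = day, event = event,
                                   condition = condition, replicate = replicate,
                                   mean_type = c("observed", "restricted"),
                                   p_floor = 1e-300) {
  mean_type <- match.arg(mean_type)
  tab <- tibble(
    day = pull(data, {{ day }}),
    event = pull(data, {{ event }}),
    condition = as.character(pull(data, {{ condition }})),
    replicate = pull(data, {{ replicate }})
  )
  lv <- unique(tab$condition)
  if (length(lv) != 2 || !control %in% lv) {
    abort("`data` must contain exactly two conditions including `control`.")
  }
  treated <- setdiff(lv, control)

  cohort_mean <- function(d, e) {
    if (mean_type == "observed") return(mean(d[e == 1]))
    fit <- survival::survfit(survival::Surv(d, e) ~ 1)
    unname(summary(fit, rmean = max(d))$table["rmean"])
  }

  reps <- sort(unique(tab$replicate))
  replicates <- purrr::map_dfr(reps, function(r) {
    sub <- tab[tab$replicate == r, ]
    if (!all(c(treated, control) %in% sub$condition)) {
      abort(sprintf("replicate '%s' is missing one condition.", r))
    }
    lr <- logrank_test(sub)
    tr <- sub[sub$condition == treated, ]
    ct <- sub[sub$condition == control, ]
    mt <- cohort_mean(tr$day, tr$event)
    mc <- cohort_mean(ct$day, ct$event)
    tibble(
      replicate = r,
      n_treated = nrow(tr), n_control = nrow(ct),
      events_treated = sum(tr$event), events_control = sum(ct$event),
      mean_treated = mt, mean_control = mc,
      extension_pct = 100 * (mt - mc) / mc,
      statistic = lr$statistic, p_value = lr$p_value
    )
  })

  combined <- fishers_method(replicates$p_value, p_floor = p_floor)
  tr <- tab[tab$condition == treated, ]
  ct <- tab[tab$condition == control, ]
  mt <- cohort_mean(tr$day, tr$event)
  mc <- cohort_mean(ct$day, ct$event)

  structure(
    list(replicates = replicates, combined = combined,
         treated = treated, control = control, mean_type = mean_type,
         mean_treated = mt, mean_control = mc,
         mean_extension_pct = 100 * (mt - mc) / mc,
         mean_extension_pct_replicates = mean(replicates$extension_pct)),
    class = "wl_lifespan"
  )
}

#' @export
print.wl_lifespan <- function(x, ...) {
  cat("Replicate-combined lifespan test (", x$treated, " vs ", x$control,
      ", ", nrow(x$replicates), " replicates)\n", sep = "")
  cat("  mean lifespan: treated ", format(x$mean_treated, digits = 4),
      " d, control ", format(x$mean_control, digits = 4),
      " d  -> extension ", sprintf("%+.1f%%", x$mean_extension_pct), "\n", sep = "")
  print(x$combined)
  invisible(x)
}

#' Tabulate several lifespan experiments
#'
#' One row per experiment, mirroring the usual replicate-summary supplement
#' layout: cohort sizes, per-condition pooled means, extension percentage and
#' the Fisher-combined p-value.
#'
#' @param ... `wl_lifespan` objects, or a single (optionally named) list of
#'   them.
#' @return A tibble with one row per experiment.
#' @export
lifespan_report <- function(...) {
  objs <- list(...)
  if (length(objs) == 1 && is.list(objs[[1]]) && !inherits(objs[[1]], "wl_lifespan")) {
    objs <- objs[[1]]
  }
  if (length(objs) == 0) abort("no lifespan summaries supplied.")
  nm <- names(objs) %||% paste0("experiment_", seq_along(objs))
  if (is.null(names(objs)) || any(names(objs) == "")) {
    nm <- paste0("experiment_", seq_along(objs))
  }
  purrr::map2_dfr(objs, nm, function(x, name) {
    stopifnot(inherits(x, "wl_lifespan"))
    tibble(
      experiment = name,
      n_replicates = nrow(x$replicates),
      n_per_replicate = round(mean(x$replicates$n_treated + x$replicates$n_control) / 2),
      treated = x$treated, control = x$control,
      mean_treated = x$mean_treated, mean_control = x$mean_control,
      extension_pct = x$mean_extension_pct,
      chi2 = x$combined$chi2, df = x$combined$df,
      p_combined = x$combined$p_value
    )
  })
}
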
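#' Run a configured multi-stage analysis
#'
#' Drives simulate-then-analyze runs from a single flat configuration
#' document (a YAML file or an equivalent named list): selected stages are
#' executed in order, every table is written as TSV under the output
#' directory, and a manifest records package version, parameters, seeds and
#' an MD5 digest of every output, so two runs from one config are
#' digest-identical. Unknown configuration keys are fatal — there are no
#' silent typos.
#'
#' Config schema (all stages optional):
#' \preformatted{
#' version: 1
#' seed: 1
#' out_dir: runs/demo
#' stages:
#'   survival:  {n_per_replicate: 90, n_replicates: 3, extension_pct: 35}
#'   chip:      {genome_length: 100000, n_genes: 20, n_enriched: 5,
#'               enrichment_factor: 3, mean_depth: 30, n_replicates: 3}
#'   integrate: {n_genes: 200, n_up: 8, fold_change: 4,
#'               n_promoters: 36, n_planted: 18}
#'   radial:    {n_cells: 6, n_replicates: 2, r0: 0.5}
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @param out_dir Overrides `out_dir` from the config.
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  known_top <- c("version", "seed", "out_dir", "stages")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) abort(sprintf("unknown config key: '%s'.", unknown[1]))
  known_stages <- c("survival", "chip", "integrate", "radial")
  stages <- config$stages %||% list()
  unknown <- setdiff(names(stages), known_stages)
  if (length(unknown)) abort(sprintf("unknown stage: '%s'.", unknown[1]))

  seed <- config$seed %||% 1
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) abort("no output directory given.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "wormlegacy",
    version = as.character(utils::packageVersion("wormlegacy")),
    config_version = config$version %||% 1,
    seed = seed, stages = list(), outputs = list()
  )
  emit <- function(tab, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(as_tibble(tab), path)
    path
  }
  outputs <- character()

  if ("survival" %in% names(stages)) {
    p <- stages$survival %||% list()
    life <- do.call(gen_survival, c(p, list(seed = child_seed(seed, 1))))
    res <- combined_lifespan_test(life, control = "control")
    outputs <- c(outputs,
                 emit(life, "lifespan.tsv"),
                 emit(res$replicates, "survival_replicates.tsv"),
                 emit(lifespan_report(list(run = res)), "survival_summary.tsv"))
    manifest$stages$survival <- p
  }

  if ("chip" %in% names(stages)) {
    p <- stages$chip %||% list()
    sim <- do.call(gen_genome_and_tracks, c(p, list(seed = child_seed(seed, 2))))
    ratio <- function(cond, mk) {
      lapply(seq_along(sim$tracks[[cond]][[mk]]), function(r) {
        normalize_mark_to_h3(sim$tracks[[cond]][[mk]][[r]],
                             sim$tracks[[cond]]$H3[[r]])
      })
    }
    rt <- ratio("treated", "H3K79me2"); rc <- ratio("control", "H3K79me2")
    diff <- call_differential_windows(rt, rc)
    mt <- tss_signal_matrix(pool_tracks(rt), sim$annotation)
    mc <- tss_signal_matrix(pool_tracks(rc), sim$annotation)
    meta <- metaprofile_compare(mt, mc, labels = c("treated", "control"))
    outputs <- c(outputs,
                 emit(diff, "differential_windows.tsv"),
                 emit(differential_sites(diff), "differential_sites.tsv"),
                 emit(meta$curves, "metaprofile_curves.tsv"))
    manifest$stages$chip <- p
  }

  if ("integrate" %in% names(stages)) {
    p <- stages$integrate %||% list()
    pe <- p[intersect(names(p), c("n_genes", "n_up", "fold_change",
                                  "n_per_group", "mu", "dispersion"))]
    pp <- p[intersect(names(p), c("n_promoters", "n_planted", "length",
                                  "consensus"))]
    extra <- setdiff(names(p), c(names(pe), names(pp)))
    if (length(extra)) abort(sprintf("unknown config key: '%s'.", extra[1]))
    expr <- do.call(gen_expression, c(pe, list(seed = child_seed(seed, 3))))
    up <- filter_upregulated(expr$de)
    prom <- do.call(gen_promoters, c(pp, list(seed = child_seed(seed, 4))))
    scan <- scan_motif(as_pwm(prom$consensus), prom$promoters)
    outputs <- c(outputs,
                 emit(expr$de, "de_table.tsv"),
                 emit(tibble(gene_id = up), "upregulated_genes.tsv"),
                 emit(scan$summary, "motif_summary.tsv"))
    manifest$stages$integrate <- p
  }

  if ("radial" %in% names(stages)) {
    p <- stages$radial %||% list()
    n_cells <- p$n_cells %||% 6
    n_reps <- p$n_replicates %||% 2
    r0 <- p$r0 %||% 0.5
    extra <- setdiff(names(p), c("n_cells", "n_replicates", "r0"))
    if (length(extra)) abort(sprintf("unknown config key: '%s'.", extra[1]))
    cells <- purrr::map_dfr(seq_len(n_cells), function(i) {
      cell <- gen_image(pattern = list(type = "ring", r0 = r0, width = 0.06),
                        seed = child_seed(seed, 10 + i))
      ctr <- detect_nucleus_center(cell$image, cell$roi)
      prof <- radial_profile(cell$image, cell$roi, ctr)
      mutate(as_tibble(prof), cell = i,
             replicate = ((i - 1) %% n_reps) + 1, group = "ring")
    })
    agg <- aggregate_profiles(cells)
    outputs <- c(outputs,
                 emit(cells, "radial_cell_profiles.tsv"),
                 emit(agg, "radial_group_curves.tsv"))
    manifest$stages$radial <- p
  }

  manifest$outputs <- lapply(outputs, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Average replicate ratio tracks base-by-base
#'
#' @param tracks List of `wl_track`s over the same genome.
#' @return A single `wl_track` of per-base means.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  vs <- lapply(tracks, expand_track)
  chroms <- names(vs[[1]])
  pooled <- setNames(lapply(chroms, function(ch) {
    Reduce(`+`, lapply(vs, `[[`, ch)) / length(vs)
  }), chroms)
  per_base_to_track(pooled, mark = attr(tracks[[1]], "mark"),
                    condition = attr(tracks[[1]], "condition"))
}
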
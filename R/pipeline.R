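# Pipeline orchestration: one YAML-configurable entry point running
# simulate (optional) -> build-network -> mine-modules -> score-activity ->
# classify -> enrich (optional), with a manifest recording parameters,
# seeds and checksums.

#' Default pipeline configuration
#'
#' Thresholds default to the study's printed settings: module size k = 50,
#' connectivity strictly greater than 5, overlap and activity alpha = 0.05,
#' 5000 permutations. The single top-level `seed` fans out to fixed
#' per-stage offsets (simulation: seed, expression: seed + 1, permutation:
#' seed + 2) so stages rerun individually reproduce the pipeline run.
#'
#' @param seed Top-level integer seed.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE),
    network = list(tf_edges = NULL, ppi_edges = NULL, header = "auto"),
    expression = list(mtx = NULL, genes = NULL, cells = NULL,
                      orientation = "genes_by_cells", normalize = "none",
                      group_by = c("cell_type", "stage"),
                      min_cells_per_group = 10L, stage_levels = NULL),
    mining = list(k = 50L, restart_prob = 0.5, connectivity_threshold = 5L,
                  alpha = 0.05, connectivity_measure = "edges"),
    activity = list(n_perm = 5000L, alpha = 0.05, exclusion = "per_group",
                    tail = "two_sided", min_significant_groups = 1L),
    classify = list(stages = c("Normal", "I", "II", "III"), flat_tol = 0.01),
    enrich = list(enabled = FALSE, gene_set = NULL, background = NULL,
                  p_cutoff = 0.05, q_cutoff = 0.05)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_pipeline_config()] values.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_pipeline_config(), user)
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @param config Configuration list.
#' @export
validate_pipeline_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(is.numeric(config$seed) && config$seed == as.integer(config$seed),
      "seed must be an integer")
  chk(config$mining$k >= 1, "mining k must be >= 1")
  chk(config$mining$restart_prob > 0 && config$mining$restart_prob < 1,
      "restart_prob must lie in (0, 1)")
  chk(config$mining$alpha > 0 && config$mining$alpha < 1,
      "mining alpha must lie in (0, 1)")
  chk(config$mining$connectivity_threshold >= 0,
      "connectivity_threshold must be >= 0")
  chk(config$activity$alpha > 0 && config$activity$alpha < 1,
      "activity alpha must lie in (0, 1)")
  chk(config$activity$n_perm >= 1, "n_perm must be >= 1")
  chk(config$classify$flat_tol >= 0, "flat_tol must be >= 0")
  if (!isTRUE(config$simulate$enabled)) {
    chk(!is.null(config$network$tf_edges), "network$tf_edges path required")
    chk(!is.null(config$expression$mtx), "expression$mtx path required")
  }
  invisible(config)
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  message("[", name, "] starting")
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  el <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  message("[", name, "] done in ", el, "s")
  log$timings[[name]] <- el
  res
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> build-network -> mine-modules ->
#' score-activity -> classify -> enrich (optional) and writes
#' `modules.tsv`, `activity.tsv`, `categories.tsv`, optional `enrich.tsv`
#' and a `manifest.json` (package version, parameters, per-stage seeds and
#' timings, input/output checksums) under `out_dir`.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the in-memory results (`network`,
#'   `modules`, `activity`, `categories`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- new.env()
  log$timings <- list()
  inputs <- character(0)

  if (isTRUE(config$simulate$enabled)) {
    sim_cfg <- do.call(synthetic_config, c(
      config$simulate[setdiff(names(config$simulate), c("enabled", "seed"))],
      list(seed = config$seed)))
    dataset <- .stage("simulate", log, simulate_dataset(sim_cfg))
    network <- dataset$network
    # simulated counts share one baseline scale across cells, so they are
    # scored directly; library-size normalization is for real data
    expr <- grouped_expression(
      dataset$expr$counts, dataset$expr$genes, dataset$expr$cells$cell_id,
      dataset$expr$cells,
      group_by = config$expression$group_by,
      min_cells_per_group = config$expression$min_cells_per_group,
      stage_levels = sim_cfg$stages)
    stages <- sim_cfg$stages
  } else {
    network <- .stage("build-network", log, {
      tf <- read_edge_list(config$network$tf_edges, "tf_target",
                           header = config$network$header, quiet = TRUE)
      pp <- if (!is.null(config$network$ppi_edges)) {
        read_edge_list(config$network$ppi_edges, "ppi",
                       header = config$network$header, quiet = TRUE)
      }
      build_network(tf, pp)
    })
    expr <- .stage("load-expression", log, read_grouped_expression(
      config$expression$mtx, config$expression$genes,
      config$expression$cells,
      orientation = config$expression$orientation,
      normalize = config$expression$normalize,
      group_by = config$expression$group_by,
      min_cells_per_group = config$expression$min_cells_per_group,
      stage_levels = config$expression$stage_levels))
    inputs <- c(config$network$tf_edges, config$network$ppi_edges,
                config$expression$mtx, config$expression$genes,
                config$expression$cells)
    stages <- config$classify$stages
  }

  modules <- .stage("mine-modules", log, mine_tf_modules(
    network, k = config$mining$k,
    restart_prob = config$mining$restart_prob,
    connectivity_threshold = config$mining$connectivity_threshold,
    alpha = config$mining$alpha,
    connectivity_measure = config$mining$connectivity_measure))
  write_modules(modules, file.path(out_dir, "modules.tsv"))

  activity <- .stage("score-activity", log, permutation_significance(
    expr, modules, n_perm = config$activity$n_perm,
    seed = config$seed + 2L, alpha = config$activity$alpha,
    exclusion = config$activity$exclusion, tail = config$activity$tail))
  write_activity(activity, file.path(out_dir, "activity.tsv"))

  categories <- .stage("classify", log, classify_stage_trajectories(
    activity, stages = intersect(stages, unique(activity$stage)),
    flat_tol = config$classify$flat_tol))
  utils::write.table(categories, file.path(out_dir, "categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  enrichment <- NULL
  if (isTRUE(config$enrich$enabled)) {
    enrichment <- .stage("enrich", log, {
      gs <- readLines(config$enrich$gene_set)
      bg <- readLines(config$enrich$background)
      enrich_modules_in_gene_set(gs[nzchar(gs)], bg[nzchar(bg)], modules,
                                 p_cutoff = config$enrich$p_cutoff,
                                 q_cutoff = config$enrich$q_cutoff)
    })
    utils::write.table(enrichment, file.path(out_dir, "enrich.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    inputs <- c(inputs, config$enrich$gene_set, config$enrich$background)
  }

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "mptf",
    version = as.character(utils::packageVersion("mptf")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = list(simulate_network = config$seed,
                       simulate_expression = config$seed + 1L,
                       permutation = config$seed + 2L),
    parameters = config[c("mining", "activity", "classify")],
    stages = names(log$timings),
    timings_sec = log$timings,
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(network = network, modules = modules, activity = activity,
                 categories = categories, enrichment = enrichment,
                 manifest = manifest))
}
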
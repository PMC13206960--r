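# Synthetic study generator: a planted regulatory network plus grouped
# negative-binomial single-cell counts with known per-group activity shifts,
# so module mining and activity scoring can be validated end to end.

#' Configuration of the synthetic study
#'
#' Defaults describe the package's reference scenario: 5 TFs with 50
#' dedicated targets each, 150 bystander genes, 200 random PPI edges, one
#' cell type over four ordered disease stages (Normal, I, II, III) with 300
#' cells per group, negative-binomial counts, and a two-fold activation
#' planted for TFs 1-4 in stages I, II, III and Normal respectively (the
#' fifth TF carries no effect and serves as a negative control).
#'
#' @param n_tfs Number of TFs.
#' @param targets_per_tf Dedicated curated targets per TF (disjoint across
#'   TFs); these are also the TF's true module.
#' @param n_bystander_genes Extra genes with no TF attached.
#' @param ppi_edges Random undirected PPI edges among all nodes.
#' @param cell_types Cell-type labels.
#' @param stages Ordered disease-stage labels.
#' @param cells_per_group Cells per (cell type, stage) group (>= 10).
#' @param baseline_log_mean_range Gene-wise baseline log-mean is drawn
#'   uniformly from this interval.
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); ignored when `dist = "poisson"`.
#' @param dist `"nb"` (default) or `"poisson"` (the dispersion -> infinity
#'   limit).
#' @param planted_effects Data.frame with columns `tf`, `cell_type`,
#'   `stage`, `fold` (> 0): the TF's true module genes have their mean
#'   multiplied by `fold` in the cells of that group.
#' @param n_patients Patients assigned round-robin within each group.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_tfs = 5L, targets_per_tf = 50L,
                             n_bystander_genes = 150L, ppi_edges = 200L,
                             cell_types = "malignant",
                             stages = c("Normal", "I", "II", "III"),
                             cells_per_group = 300L,
                             baseline_log_mean_range = c(log(0.5), log(8)),
                             nb_dispersion = 2,
                             dist = c("nb", "poisson"),
                             planted_effects = NULL,
                             n_patients = 3L,
                             seed = 1L) {
  dist <- match.arg(dist)
  if (is.null(planted_effects)) {
    planted <- min(n_tfs, 4L)
    planted_effects <- data.frame(
      tf = sprintf("TF%02d", seq_len(planted)),
      cell_type = cell_types[1L],
      stage = c("I", "II", "III", "Normal")[seq_len(planted)],
      fold = 2,
      stringsAsFactors = FALSE)
    planted_effects <- planted_effects[planted_effects$stage %in% stages, ]
  }
  cfg <- list(n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              n_bystander_genes = as.integer(n_bystander_genes),
              ppi_edges = as.integer(ppi_edges),
              cell_types = cell_types, stages = stages,
              cells_per_group = as.integer(cells_per_group),
              baseline_log_mean_range = baseline_log_mean_range,
              nb_dispersion = nb_dispersion, dist = dist,
              planted_effects = planted_effects,
              n_patients = as.integer(n_patients),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @param config A `synthetic_config`.
#' @export
validate_synthetic_config <- function(config) {
  stopifnot(config$n_tfs >= 1L, config$targets_per_tf >= 1L,
            config$n_bystander_genes >= 0L, config$ppi_edges >= 0L,
            length(config$stages) >= 1L, config$n_patients >= 1L)
  if (config$cells_per_group < 10L) {
    stop("cells_per_group must be at least 10")
  }
  pe <- config$planted_effects
  if (nrow(pe)) {
    if (any(pe$fold <= 0)) stop("planted folds must be positive")
    tf_names <- sprintf("TF%02d", seq_len(config$n_tfs))
    if (!all(pe$tf %in% tf_names)) {
      stop("planted effect names a TF outside the simulated network")
    }
    if (!all(pe$stage %in% config$stages) ||
        !all(pe$cell_type %in% config$cell_types)) {
      stop("planted effect names a group outside the simulated design")
    }
  }
  invisible(config)
}

# distinct unordered node pairs, deterministic under the current RNG state
.sample_pairs <- function(n_nodes, n_pairs) {
  cap <- n_nodes * (n_nodes - 1) / 2
  if (n_pairs > cap) {
    stop("requested ", n_pairs, " PPI edges but a simple graph on ",
         n_nodes, " nodes holds at most ", cap)
  }
  seen <- character(0)
  out <- matrix(integer(0), 0L, 2L)
  while (nrow(out) < n_pairs) {
    m <- 2L * (n_pairs - nrow(out)) + 10L
    a <- sample.int(n_nodes, m, replace = TRUE)
    b <- sample.int(n_nodes, m, replace = TRUE)
    ok <- a != b
    lo <- pmin(a, b)[ok]
    hi <- pmax(a, b)[ok]
    key <- paste(lo, hi)
    new <- !duplicated(key) & !(key %in% seen)
    seen <- c(seen, key[new])
    out <- rbind(out, cbind(lo[new], hi[new]))
  }
  out[seq_len(n_pairs), , drop = FALSE]
}

#' Simulate the planted regulatory network
#'
#' Every TF receives `targets_per_tf` dedicated target genes (directed
#' TF->target edges), and `ppi_edges` random undirected interactions are
#' added among all nodes (no self-loops, no duplicate pairs). The TF's
#' target set is recorded as its true module in the returned truth.
#'
#' @param config A `synthetic_config`.
#' @return List with `network` (a `regulatory_network`), `tf_edges`,
#'   `ppi_edges` (edge lists) and `truth` (list with `true_modules` and
#'   `true_active`).
#' @export
simulate_network <- function(config) {
  validate_synthetic_config(config)
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  n_targets <- config$n_tfs * config$targets_per_tf
  genes <- sprintf("G%04d", seq_len(n_targets + config$n_bystander_genes))
  target_of <- split(genes[seq_len(n_targets)],
                     rep(tfs, each = config$targets_per_tf))

  tf_df <- data.frame(
    source = rep(tfs, each = config$targets_per_tf),
    target = genes[seq_len(n_targets)],
    stringsAsFactors = FALSE)
  nodes <- c(tfs, genes)

  ppi_df <- NULL
  if (config$ppi_edges > 0L) {
    pairs <- withr::with_seed(config$seed,
                              .sample_pairs(length(nodes), config$ppi_edges))
    ppi_df <- data.frame(source = nodes[pairs[, 1L]],
                         target = nodes[pairs[, 2L]],
                         stringsAsFactors = FALSE)
  }

  tf_el <- as_edge_list(tf_df, "tf_target", provenance = "simulated")
  ppi_el <- if (is.null(ppi_df)) NULL else {
    as_edge_list(ppi_df, "ppi", provenance = "simulated")
  }
  network <- build_network(tf_el, ppi_el)

  pe <- config$planted_effects
  true_active <- data.frame(tf = character(0), cell_type = character(0),
                            stage = character(0), fold = numeric(0),
                            direction = character(0), stringsAsFactors = FALSE)
  if (nrow(pe)) {
    true_active <- data.frame(pe[, c("tf", "cell_type", "stage", "fold")],
                              direction = ifelse(pe$fold > 1, "up",
                                                 ifelse(pe$fold < 1, "down", "none")),
                              stringsAsFactors = FALSE)
  }
  list(network = network, tf_edges = tf_el, ppi_edges = ppi_el,
       truth = list(true_modules = target_of[tfs], true_active = true_active))
}

#' Simulate grouped single-cell counts with planted activity shifts
#'
#' Counts for gene i in a cell of group g are drawn from a negative binomial
#' with mean `exp(baseline_i) * fold_{i,g}` and size `nb_dispersion`, where
#' `fold_{i,g}` differs from 1 only for the true module genes of a planted
#' (tf, cell_type, stage) effect. Cells carry cell-type, stage and
#' round-robin patient labels.
#'
#' @param sim Output of [simulate_network()].
#' @param config The same `synthetic_config`.
#' @return List with `counts` (genes x cells sparse dgCMatrix), `genes`,
#'   `cells` (data.frame `cell_id`, `cell_type`, `stage`, `patient`), and
#'   `baseline_mu` (named gene means at fold 1).
#' @export
simulate_expression <- function(sim, config) {
  validate_synthetic_config(config)
  genes <- sim$network$nodes
  n_genes <- length(genes)
  design <- expand.grid(stage = config$stages, cell_type = config$cell_types,
                        stringsAsFactors = FALSE)[, c("cell_type", "stage")]
  n_groups <- nrow(design)
  n_cells <- n_groups * config$cells_per_group

  cells <- data.frame(
    cell_id = sprintf("C%06d", seq_len(n_cells)),
    cell_type = rep(design$cell_type, each = config$cells_per_group),
    stage = rep(design$stage, each = config$cells_per_group),
    patient = sprintf("P%d", (seq_len(config$cells_per_group) - 1L) %%
                        config$n_patients + 1L),
    stringsAsFactors = FALSE)

  withr::with_seed(config$seed + 1L, {
    mu0 <- exp(stats::runif(n_genes, config$baseline_log_mean_range[1L],
                            config$baseline_log_mean_range[2L]))
    names(mu0) <- genes

    # genes x groups fold matrix from the planted effects
    fold <- matrix(1, n_genes, n_groups)
    pe <- config$planted_effects
    for (q in seq_len(nrow(pe))) {
      g <- which(design$cell_type == pe$cell_type[q] &
                   design$stage == pe$stage[q])
      rows <- match(sim$truth$true_modules[[pe$tf[q]]], genes)
      fold[rows, g] <- fold[rows, g] * pe$fold[q]
    }

    counts <- matrix(0L, n_genes, n_cells)
    for (g in seq_len(n_groups)) {
      cols <- which(cells$cell_type == design$cell_type[g] &
                      cells$stage == design$stage[g])
      mu <- mu0 * fold[, g]
      draw <- if (config$dist == "poisson") {
        stats::rpois(n_genes * length(cols), lambda = rep(mu, times = length(cols)))
      } else {
        stats::rnbinom(n_genes * length(cols), mu = rep(mu, times = length(cols)),
                       size = config$nb_dispersion)
      }
      counts[, cols] <- draw
    }
  })
  dimnames(counts) <- list(genes, cells$cell_id)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       genes = genes, cells = cells, baseline_mu = mu0)
}

#' Simulate the full study in one call
#'
#' @param config A `synthetic_config`.
#' @return List with `network`, `tf_edges`, `ppi_edges`, `truth`, `expr`
#'   (from [simulate_expression()]), and `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  sim <- simulate_network(config)
  expr <- simulate_expression(sim, config)
  c(sim, list(expr = expr, config = config))
}

#' Write a simulated dataset to disk
#'
#' Emits `tf_edges.tsv`, `ppi_edges.tsv`, `matrix.mtx` (genes x cells),
#' `genes.tsv`, `cells.tsv` and `truth.json` under `dir`.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(dataset$tf_edges),
                     file.path(dir, "tf_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$ppi_edges)) {
    utils::write.table(as.data.frame(dataset$ppi_edges),
                       file.path(dir, "ppi_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  Matrix::writeMM(dataset$expr$counts, file.path(dir, "matrix.mtx"))
  writeLines(dataset$expr$genes, file.path(dir, "genes.tsv"))
  utils::write.table(dataset$expr$cells, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(true_modules = dataset$truth$true_modules,
         true_active = dataset$truth$true_active),
    file.path(dir, "truth.json"))
  invisible(dir)
}
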
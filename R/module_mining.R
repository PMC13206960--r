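# Random-walk module mining: per-TF network propagation, top-k module
# extraction, induced-subnetwork connectivity filter, and hypergeometric
# overlap against the TF's curated targets.

# column-normalized walk matrix plus dangling-column indicator
.walk_matrix <- function(network) {
  A <- igraph::as_adjacency_matrix(network$graph, sparse = TRUE)
  A <- methods::as(A, "generalMatrix")
  deg <- Matrix::colSums(A)
  dangling <- deg == 0
  inv <- ifelse(dangling, 0, 1 / deg)
  W <- A %*% Matrix::Diagonal(x = inv)
  list(W = W, dangling = dangling)
}

.rwr_iterate <- function(W, dangling, seed_idx, restart_prob, tol, max_iter) {
  n <- nrow(W)
  p <- numeric(n)
  p[seed_idx] <- 1
  converged <- FALSE
  iter <- 0L
  r <- restart_prob
  while (iter < max_iter) {
    iter <- iter + 1L
    # degree-0 columns teleport their mass back to the seed so that the
    # walk conserves probability
    walk <- as.numeric(W %*% p)
    walk[seed_idx] <- walk[seed_idx] + sum(p[dangling])
    p_new <- (1 - r) * walk
    p_new[seed_idx] <- p_new[seed_idx] + r
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(scores = p, iterations = iter, converged = converged)
}

#' Random walk with restart from a seed transcription factor
#'
#' Iterates `p <- (1 - r) W p + r e_seed` on the column-normalized adjacency
#' matrix of the integrated network, starting with all mass on the seed TF,
#' until the L1 change drops below `tol`. Isolated (degree-0) nodes teleport
#' their mass back to the seed so probability is conserved. The stationary
#' vector measures each gene's network proximity to the seed; genes in
#' components disconnected from the seed score exactly 0.
#'
#' @param network A `regulatory_network` from [build_network()].
#' @param seed_tf Gene symbol of a TF node.
#' @param restart_prob Restart probability r in (0, 1); default 0.5.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE` and a warning.
#' @return An object of class `influence_vector`: list with `tf`, `scores`
#'   (named, nonnegative, summing to 1), `restart_prob`, `iterations`,
#'   `converged`.
#' @export
random_walk_with_restart <- function(network, seed_tf, restart_prob = 0.5,
                                     tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(network, "regulatory_network"))
  if (!(restart_prob > 0 && restart_prob < 1)) {
    stop("restart_prob must lie strictly between 0 and 1")
  }
  seed_idx <- match(seed_tf, network$nodes)
  if (is.na(seed_idx)) {
    stop("seed TF '", seed_tf, "' is not a node of the network")
  }
  wm <- .walk_matrix(network)
  res <- .rwr_iterate(wm$W, wm$dangling, seed_idx, restart_prob, tol, max_iter)
  if (!res$converged) {
    warning("random walk from '", seed_tf, "' did not converge in ",
            max_iter, " iterations")
  }
  scores <- res$scores
  names(scores) <- network$nodes
  structure(list(tf = seed_tf, scores = scores, restart_prob = restart_prob,
                 iterations = res$iterations, converged = res$converged),
            class = "influence_vector")
}

#' Extract the top-k gene module of an influence vector
#'
#' Ranks all nodes except the seed by descending influence score and keeps
#' the top `k`; ties (including at the k-th score) are broken by
#' lexicographic gene symbol for reproducibility. Nodes with zero score are
#' never included, so fewer than `k` genes may be returned.
#'
#' @param influence An `influence_vector`.
#' @param k Module size cap (the study uses 50).
#' @return Character vector of gene symbols, ordered by descending
#'   influence.
#' @export
top_k_module <- function(influence, k = 50L) {
  stopifnot(inherits(influence, "influence_vector"), k >= 1L)
  s <- influence$scores
  s <- s[names(s) != influence$tf]
  s <- s[s > 0]
  if (length(s) == 0L) return(character(0))
  ord <- order(-s, names(s), method = "radix")
  names(s)[ord][seq_len(min(k, length(s)))]
}

#' Connectivity of the TF-module induced subnetwork
#'
#' Measures the stability of the tie between a TF and its mined module on
#' the integrated network: by default the number of edges in the subgraph
#' induced by the TF together with its module genes; alternatively the size
#' of the largest connected component of that subgraph.
#'
#' @param network A `regulatory_network`.
#' @param tf Seed TF symbol.
#' @param module Character vector of module gene symbols.
#' @param measure `"edges"` (default) or `"component"`.
#' @return Integer connectivity.
#' @export
subnetwork_connectivity <- function(network, tf, module,
                                    measure = c("edges", "component")) {
  measure <- match.arg(measure)
  stopifnot(inherits(network, "regulatory_network"), length(module) >= 1L)
  verts <- intersect(unique(c(tf, module)), network$nodes)
  sub <- igraph::induced_subgraph(network$graph, verts)
  if (measure == "edges") {
    as.integer(igraph::ecount(sub))
  } else {
    as.integer(max(igraph::components(sub)$csize))
  }
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `x_overlap` of a TF's curated targets
#' inside a module of `n_module` genes drawn from a background of `N_total`
#' genes containing `M_targets` targets:
#' `p = P(X >= x) = 1 - sum_{k=0}^{x-1} C(M, k) C(N-M, n-k) / C(N, n)`.
#' Returns exactly 1 when `x_overlap = 0`.
#'
#' @param N_total Background size (all network genes except the seed TF).
#' @param M_targets Number of the TF's curated targets in the background.
#' @param n_module Module size.
#' @param x_overlap Observed overlap count.
#' @return Upper-tail probability in \[0, 1\].
#' @examples
#' hypergeometric_overlap_p(10, 5, 4, 4)  # 5/210
#' @export
hypergeometric_overlap_p <- function(N_total, M_targets, n_module, x_overlap) {
  if (any(N_total < 0 | M_targets < 0 | n_module < 0 | x_overlap < 0) ||
      any(M_targets > N_total) || any(n_module > N_total) ||
      any(x_overlap > pmin(M_targets, n_module))) {
    stop("infeasible hypergeometric parameters: need 0 <= x <= min(M, n), ",
         "M <= N, n <= N")
  }
  ifelse(x_overlap == 0, 1,
         stats::phyper(x_overlap - 1, M_targets, N_total - M_targets,
                       n_module, lower.tail = FALSE))
}

#' Mine the gene module of every transcription factor
#'
#' For each TF node: seed a random walk with restart, take the top-`k`
#' genes by influence as the module, compute the induced-subnetwork
#' connectivity, and test the module's overlap with the TF's curated targets
#' by an upper-tail hypergeometric test. The background for the test is all
#' network genes except the seed TF. A TF-module pair passes iff
#' connectivity is strictly greater than `connectivity_threshold` and the
#' overlap p-value is below `alpha`.
#'
#' @inheritParams random_walk_with_restart
#' @param k Module size (default 50).
#' @param connectivity_threshold Pass requires connectivity strictly above
#'   this (default 5).
#' @param alpha Overlap significance level (default 0.05).
#' @param connectivity_measure Passed to [subnetwork_connectivity()].
#' @return An object of class `tf_modules`: a data.frame with one row per
#'   TF (`tf`, `n_genes`, `connectivity`, `overlap_x`, `M_targets`,
#'   `N_total`, `overlap_p`, `passed`, `reason`) and an attribute `modules`,
#'   a named list of per-TF data.frames (`gene`, `rank`, `influence`).
#' @export
mine_tf_modules <- function(network, k = 50L, restart_prob = 0.5,
                            connectivity_threshold = 5L, alpha = 0.05,
                            connectivity_measure = c("edges", "component"),
                            tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(network, "regulatory_network"))
  connectivity_measure <- match.arg(connectivity_measure)
  tfs <- network$nodes[network$is_tf]
  wm <- .walk_matrix(network)
  n_nodes <- length(network$nodes)

  rows <- vector("list", length(tfs))
  mods <- vector("list", length(tfs))
  names(mods) <- tfs
  for (i in seq_along(tfs)) {
    tf <- tfs[i]
    seed_idx <- match(tf, network$nodes)
    res <- .rwr_iterate(wm$W, wm$dangling, seed_idx, restart_prob, tol, max_iter)
    scores <- res$scores
    names(scores) <- network$nodes
    inf <- structure(list(tf = tf, scores = scores,
                          restart_prob = restart_prob,
                          iterations = res$iterations,
                          converged = res$converged),
                     class = "influence_vector")
    module <- top_k_module(inf, k)
    mods[[i]] <- data.frame(gene = module,
                            rank = seq_along(module),
                            influence = unname(scores[module]),
                            stringsAsFactors = FALSE)

    targets_in_net <- setdiff(intersect(network$tf_targets[[tf]], network$nodes), tf)
    N_total <- n_nodes - 1L
    M_targets <- length(targets_in_net)
    x <- length(intersect(module, targets_in_net))
    conn <- if (length(module)) {
      subnetwork_connectivity(network, tf, module, connectivity_measure)
    } else 0L

    if (M_targets == 0L) {
      p <- NA_real_
      passed <- FALSE
      reason <- "no_in_network_targets"
    } else if (length(module) == 0L) {
      p <- NA_real_
      passed <- FALSE
      reason <- "empty_module"
    } else {
      p <- hypergeometric_overlap_p(N_total, M_targets, length(module), x)
      passed <- conn > connectivity_threshold && p < alpha
      reason <- if (passed) "ok" else if (conn <= connectivity_threshold) {
        "low_connectivity"
      } else "overlap_not_significant"
    }
    rows[[i]] <- data.frame(tf = tf, n_genes = length(module),
                            connectivity = conn, overlap_x = x,
                            M_targets = M_targets, N_total = N_total,
                            overlap_p = p, passed = passed, reason = reason,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, modules = mods,
            params = list(k = k, restart_prob = restart_prob,
                          connectivity_threshold = connectivity_threshold,
                          alpha = alpha,
                          connectivity_measure = connectivity_measure),
            class = c("tf_modules", "data.frame"))
}

#' Build a `tf_modules` object from a plain list of gene sets
#'
#' Lets the activity-scoring stage run on externally defined modules (for
#' example, the simulator's ground-truth target sets). All modules are
#' marked as passed.
#'
#' @param module_list Named list: TF symbol -> character vector of genes.
#' @return A `tf_modules` object.
#' @export
as_tf_modules <- function(module_list) {
  stopifnot(is.list(module_list), !is.null(names(module_list)))
  mods <- lapply(module_list, function(g) {
    data.frame(gene = as.character(g), rank = seq_along(g),
               influence = NA_real_, stringsAsFactors = FALSE)
  })
  out <- data.frame(tf = names(module_list),
                    n_genes = lengths(module_list),
                    connectivity = NA_integer_, overlap_x = NA_integer_,
                    M_targets = NA_integer_, N_total = NA_integer_,
                    overlap_p = NA_real_, passed = TRUE, reason = "external",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, modules = mods, params = list(),
            class = c("tf_modules", "data.frame"))
}

#' Genes of the passed modules
#'
#' @param modules A `tf_modules` object.
#' @return Named list TF -> character vector of module genes, restricted to
#'   modules with `passed = TRUE`.
#' @export
passed_module_genes <- function(modules) {
  stopifnot(inherits(modules, "tf_modules"))
  keep <- modules$tf[modules$passed]
  lapply(attr(modules, "modules")[keep], `[[`, "gene")
}

#' Write / read mined modules as a long-format TSV
#'
#' One row per (TF, member gene) with the module-level statistics repeated;
#' TFs whose module is empty are kept with an `NA` gene so no TF is lost on
#' round trip.
#'
#' @param modules A `tf_modules` object.
#' @param path Output TSV path.
#' @return `write_modules()` returns `path` invisibly; `read_modules()`
#'   returns a `tf_modules` object.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "tf_modules"))
  mods <- attr(modules, "modules")
  long <- do.call(rbind, lapply(seq_len(nrow(modules)), function(i) {
    m <- mods[[modules$tf[i]]]
    if (nrow(m) == 0L) {
      m <- data.frame(gene = NA_character_, rank = NA_integer_,
                      influence = NA_real_)
    }
    cbind(modules[rep(i, nrow(m)),
                  c("tf", "connectivity", "overlap_x", "M_targets",
                    "N_total", "overlap_p", "passed", "reason")],
          m)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  tfs <- unique(long$tf)
  mods <- list()
  rows <- list()
  for (tf in tfs) {
    sub <- long[long$tf == tf, ]
    genes <- sub[!is.na(sub$gene), c("gene", "rank", "influence")]
    rownames(genes) <- NULL
    mods[[tf]] <- genes
    rows[[tf]] <- data.frame(
      tf = tf, n_genes = nrow(genes),
      connectivity = sub$connectivity[1L], overlap_x = sub$overlap_x[1L],
      M_targets = sub$M_targets[1L], N_total = sub$N_total[1L],
      overlap_p = sub$overlap_p[1L], passed = sub$passed[1L],
      reason = sub$reason[1L], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, modules = mods, params = list(),
            class = c("tf_modules", "data.frame"))
}
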
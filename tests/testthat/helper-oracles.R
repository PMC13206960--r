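# Shared fixtures and independent oracles, built in code at test time.

tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# T -> a, T -> b plus PPI a - b: a closed triangle around one TF
toy_network <- function() {
  tf <- as_edge_list(data.frame(s = c("T", "T"), t = c("a", "b")),
                     "tf_target")
  ppi <- as_edge_list(data.frame(s = "a", t = "b"), "ppi")
  build_network(tf, ppi)
}

# exact upper-tail hypergeometric by term-by-term enumeration; binomial
# coefficients are exact in doubles for N <= 25, so this is an independent
# exact oracle for small parameters
oracle_hyper_upper <- function(N, M, n, x) {
  if (x == 0) return(1)
  ks <- x:min(M, n)
  ks <- ks[n - ks <= N - M]
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# dense linear-solve oracle for the stationary restart walk:
# p = r (I - (1 - r) W)^{-1} e_seed, W column-normalized adjacency with
# degree-0 columns teleporting to the seed
oracle_rwr_solve <- function(network, seed_tf, r) {
  A <- as.matrix(igraph::as_adjacency_matrix(network$graph))
  n <- nrow(A)
  seed <- match(seed_tf, network$nodes)
  W <- matrix(0, n, n)
  deg <- colSums(A)
  for (j in seq_len(n)) {
    if (deg[j] > 0) W[, j] <- A[, j] / deg[j] else W[seed, j] <- 1
  }
  e <- numeric(n)
  e[seed] <- 1
  p <- solve(diag(n) - (1 - r) * W, r * e)
  names(p) <- network$nodes
  p
}

# random connected network: spanning path plus random extra PPI edges; the
# first node is made a TF by giving it a handful of directed targets
random_connected_network <- function(n_nodes, extra_edges, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%03d", sample(seq_len(n_nodes)))
    path <- data.frame(s = nodes[-n_nodes], t = nodes[-1L])
    extra <- data.frame(
      s = nodes[sample.int(n_nodes, extra_edges, replace = TRUE)],
      t = nodes[sample.int(n_nodes, extra_edges, replace = TRUE)])
    extra <- extra[extra$s != extra$t, , drop = FALSE]
    tf <- data.frame(s = nodes[1L],
                     t = nodes[sample(2:n_nodes, min(5L, n_nodes - 1L))])
    build_network(as_edge_list(tf, "tf_target"),
                  as_edge_list(rbind(path, extra), "ppi"))
  })
}

# small grouped expression object from a dense matrix and a group label
# vector (one cell type per group label, single stage axis unused)
grouped_from_matrix <- function(X, groups, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(X)))
  cells <- sprintf("c%03d", seq_len(ncol(X)))
  ann <- data.frame(cell_id = cells, cell_type = as.character(groups),
                    stage = "s1", patient = "p1",
                    stringsAsFactors = FALSE)
  grouped_expression(X, gene_ids, cells, ann, group_by = "cell_type",
                     min_cells_per_group = 1L)
}

# textbook Benjamini-Hochberg, computed from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
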
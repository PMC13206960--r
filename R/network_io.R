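#' Read a TF-target or protein-protein interaction edge list
#'
#' Reads a tab-delimited two-or-more-column edge list (TRRUST-style for
#' `kind = "tf_target"`, HPRD-style for `kind = "ppi"`). Only the first two
#' columns are used. Duplicate (source, target) pairs are collapsed and
#' self-edges are dropped with a warning; endpoints are whitespace-trimmed,
#' case-preserved, and must be non-empty.
#'
#' @param path Path to a TSV file.
#' @param kind Either `"tf_target"` (directed regulator -> target) or
#'   `"ppi"` (undirected interaction).
#' @param header `"auto"` (default) detects a header row by looking for
#'   common column names (tf, target, source, gene, ...); `TRUE`/`FALSE`
#'   force the decision.
#' @param quiet Suppress the row-count message.
#' @return An object of class `edge_list`: a data.frame with columns
#'   `source` and `target`, attributes `kind` and `provenance`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("TP53\tCDKN1A", "TP53\tMDM2", "TP53\tCDKN1A"), tsv)
#' el <- read_edge_list(tsv, kind = "tf_target")
#' nrow(el)  # 2, the duplicate row is collapsed
#' @export
read_edge_list <- function(path, kind = c("tf_target", "ppi"),
                           header = "auto", quiet = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("edge list file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("edge list is empty: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop("edge list ", path, ": line ", bad, " has fewer than 2 fields")
  }
  src <- trimws(vapply(fields, `[[`, "", 1L))
  tgt <- trimws(vapply(fields, `[[`, "", 2L))

  drop_header <- isTRUE(header)
  if (identical(header, "auto")) {
    header_words <- c("tf", "target", "source", "gene", "genea", "geneb",
                      "regulator", "from", "to", "node1", "node2",
                      "protein1", "protein2")
    drop_header <- tolower(src[1L]) %in% header_words ||
      tolower(tgt[1L]) %in% header_words
  }
  if (drop_header) {
    src <- src[-1L]
    tgt <- tgt[-1L]
  }
  if (length(src) == 0L) {
    stop("edge list ", path, ": no data rows after header")
  }
  if (any(!nzchar(src)) || any(!nzchar(tgt))) {
    bad <- which(!nzchar(src) | !nzchar(tgt))[1L] + as.integer(drop_header)
    stop("edge list ", path, ": empty gene symbol on line ", bad)
  }

  n_raw <- length(src)
  self <- src == tgt
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped from ", path)
    src <- src[!self]
    tgt <- tgt[!self]
  }
  keep <- !duplicated(paste(src, tgt, sep = "\r"))[seq_along(src)]
  edges <- data.frame(source = src[keep], target = tgt[keep],
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    stop("edge list ", path, ": no edges remain after filtering")
  }
  if (!quiet) {
    message("read ", n_raw, " rows from ", basename(path), ": ",
            nrow(edges), " unique ", kind, " edges")
  }
  structure(edges, kind = kind, provenance = path, class = c("edge_list", "data.frame"))
}

#' Construct an edge list from a data.frame
#'
#' In-memory counterpart of [read_edge_list()], used by the simulator and in
#' tests. Applies the same invariants (no self-edges, no duplicates,
#' non-empty trimmed symbols).
#'
#' @param edges A data.frame whose first two columns are source and target
#'   gene symbols.
#' @inheritParams read_edge_list
#' @param provenance Free-text label recording where the edges came from.
#' @return An `edge_list` object.
#' @export
as_edge_list <- function(edges, kind = c("tf_target", "ppi"),
                         provenance = "in-memory") {
  kind <- match.arg(kind)
  src <- trimws(as.character(edges[[1L]]))
  tgt <- trimws(as.character(edges[[2L]]))
  if (any(!nzchar(src)) || any(!nzchar(tgt))) {
    stop("edge list contains empty gene symbols")
  }
  self <- src == tgt
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    src <- src[!self]
    tgt <- tgt[!self]
  }
  keep <- !duplicated(paste(src, tgt, sep = "\r"))[seq_along(src)]
  out <- data.frame(source = src[keep], target = tgt[keep],
                    stringsAsFactors = FALSE)
  structure(out, kind = kind, provenance = provenance,
            class = c("edge_list", "data.frame"))
}

#' Build the integrated gene regulatory network
#'
#' Merges a directed TF->target edge list with an undirected PPI edge list
#' into one undirected simple graph, the substrate of the random walk. The
#' directed TF->target map is retained separately for the target-overlap
#' test. A node is flagged as a TF iff it is the source of at least one
#' TF->target edge. Nodes are ordered lexicographically so that all
#' downstream results are reproducible.
#'
#' @param tf_edges An `edge_list` of kind `"tf_target"`.
#' @param ppi_edges An `edge_list` of kind `"ppi"`, or `NULL`.
#' @return An object of class `regulatory_network`: a list with elements
#'   `graph` (undirected simple [igraph::graph]), `nodes` (lexicographic
#'   character vector), `is_tf` (logical per node), `tf_targets` (named list
#'   TF -> character vector of targets), and the original `tf_edges` /
#'   `ppi_edges`.
#' @examples
#' tf <- as_edge_list(data.frame(tf = "T", target = c("a", "b")), "tf_target")
#' ppi <- as_edge_list(data.frame(a = "a", b = "b"), "ppi")
#' net <- build_network(tf, ppi)
#' net$nodes          # "T" "a" "b"  (C-locale lexicographic)
#' net$tf_targets$T   # "a" "b"
#' @export
build_network <- function(tf_edges, ppi_edges = NULL) {
  stopifnot(inherits(tf_edges, "edge_list"))
  if (!identical(attr(tf_edges, "kind"), "tf_target")) {
    stop("tf_edges must have kind 'tf_target'")
  }
  if (!is.null(ppi_edges)) {
    stopifnot(inherits(ppi_edges, "edge_list"))
    if (!identical(attr(ppi_edges, "kind"), "ppi")) {
      stop("ppi_edges must have kind 'ppi'")
    }
  }
  all_src <- c(tf_edges$source, if (!is.null(ppi_edges)) ppi_edges$source)
  all_tgt <- c(tf_edges$target, if (!is.null(ppi_edges)) ppi_edges$target)
  nodes <- sort(unique(c(all_src, all_tgt)), method = "radix")
  if (length(nodes) == 0L) {
    stop("no nodes: both edge lists are empty")
  }

  tfs <- unique(tf_edges$source)
  if (length(tfs) == 0L) {
    stop("no TFs found: every node must be reachable from at least one ",
         "TF->target source")
  }
  is_tf <- nodes %in% tfs

  # symmetrized union of both edge kinds; unordered pairs deduplicated
  a <- pmin(all_src, all_tgt)
  b <- pmax(all_src, all_tgt)
  keep <- !duplicated(paste(a, b, sep = "\r"))[seq_along(a)]
  pairs <- cbind(a[keep], b[keep])

  graph <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1L], to = pairs[, 2L]),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )

  tf_targets <- split(tf_edges$target, factor(tf_edges$source, levels = sort(tfs, method = "radix")))
  tf_targets <- lapply(tf_targets, function(x) sort(unique(x), method = "radix"))

  structure(
    list(graph = graph, nodes = nodes, is_tf = is_tf,
         tf_targets = tf_targets,
         tf_edges = as.data.frame(tf_edges),
         ppi_edges = if (is.null(ppi_edges)) NULL else as.data.frame(ppi_edges)),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:",
      length(x$nodes), "nodes,",
      igraph::ecount(x$graph), "undirected edges,",
      sum(x$is_tf), "TFs\n")
  invisible(x)
}

#' Write / read an integrated network
#'
#' The TSV has columns `source`, `target`, `kind` (one row per original
#' directed TF->target or undirected PPI edge); a JSON sidecar records node,
#' edge and TF counts. `read_network()` inverts `write_network()` exactly.
#'
#' @param network A `regulatory_network`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `regulatory_network`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  tf <- cbind(network$tf_edges, kind = "tf_target")
  pp <- if (is.null(network$ppi_edges)) NULL else cbind(network$ppi_edges, kind = "ppi")
  utils::write.table(rbind(tf, pp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(nodes = length(network$nodes),
                  edges = igraph::ecount(network$graph),
                  tfs = sum(network$is_tf))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "kind") %in% names(tab)))
  tf <- tab[tab$kind == "tf_target", c("source", "target")]
  pp <- tab[tab$kind == "ppi", c("source", "target")]
  build_network(
    as_edge_list(tf, "tf_target", provenance = path),
    if (nrow(pp)) as_edge_list(pp, "ppi", provenance = path) else NULL
  )
}
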
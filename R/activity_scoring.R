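# Per-group TF-module activity scoring.
#
# For gene i and group j (a cell-type or cell-type x stage group):
#   E[i,j] = mean expression of gene i over the n_j cells of group j
#   R[i,j] = E[i,j] / mean_j E[i,.]          (relative expression, mean 1)
#   M[t,j] = sum_i w_i R[i,j] / sum_i w_i    over module t's surviving genes,
# where w_i = 1 / (number of passed modules containing gene i) and genes
# with R > 3 or R < 1/3 in a group are excluded there as outliers.
# Significance comes from re-running the whole chain under shuffled group
# labels.

#' Assemble grouped single-cell expression
#'
#' Bundles a genes x cells expression matrix with per-cell annotations and a
#' grouping (by default cell type crossed with disease stage). Expression is
#' expected on a linear (not log) scale, since the downstream 3x / 1/3
#' outlier rule is a ratio rule.
#'
#' @param matrix Genes x cells numeric matrix (dense or `Matrix` sparse),
#'   nonnegative.
#' @param gene_ids Character vector, one per row.
#' @param cell_ids Character vector, one per column.
#' @param annotations Data.frame with columns `cell_id`, `cell_type`,
#'   `stage`, and optionally `patient`; one row per cell (matched by
#'   `cell_id`).
#' @param group_by Annotation columns defining the groups; default
#'   `c("cell_type", "stage")`, use `"cell_type"` for cell-type-only
#'   scoring.
#' @param min_cells_per_group Smallest admissible group (default 10).
#' @param stage_levels Optional ordered stage labels (controls group order).
#' @return An object of class `grouped_expression`: list with `matrix`,
#'   `genes`, `cells`, `annotations`, `group_by`, `group_index` (factor per
#'   cell), `groups` (data.frame of group labels), `group_sizes`.
#' @export
grouped_expression <- function(matrix, gene_ids, cell_ids, annotations,
                               group_by = c("cell_type", "stage"),
                               min_cells_per_group = 10L,
                               stage_levels = NULL) {
  stopifnot(nrow(matrix) == length(gene_ids),
            ncol(matrix) == length(cell_ids),
            all(c("cell_id", group_by) %in% names(annotations)))
  if (any(matrix < 0)) stop("expression must be nonnegative")
  ord <- match(cell_ids, annotations$cell_id)
  if (anyNA(ord)) {
    stop("cells missing from annotations: ",
         paste(utils::head(cell_ids[is.na(ord)], 3L), collapse = ", "))
  }
  ann <- annotations[ord, , drop = FALSE]
  rownames(ann) <- NULL
  if (!is.null(stage_levels) && "stage" %in% names(ann)) {
    ann$stage <- factor(ann$stage, levels = stage_levels)
    if (anyNA(ann$stage)) stop("stage label outside stage_levels")
  }
  parts <- lapply(group_by, function(v) factor(ann[[v]]))
  gfac <- interaction(parts, drop = TRUE, sep = "|", lex.order = TRUE)
  sizes <- table(gfac)
  if (any(sizes == 0L)) stop("empty group: ", names(sizes)[sizes == 0L][1L])
  if (any(sizes < min_cells_per_group)) {
    small <- names(sizes)[sizes < min_cells_per_group][1L]
    stop("group '", small, "' has fewer than ", min_cells_per_group,
         " cells")
  }
  groups <- unique(do.call(data.frame, c(stats::setNames(
    lapply(group_by, function(v) as.character(ann[[v]])), group_by),
    list(stringsAsFactors = FALSE))))
  groups <- groups[match(levels(gfac),
                         do.call(paste, c(groups, sep = "|"))), , drop = FALSE]
  rownames(groups) <- NULL
  groups$group <- levels(gfac)

  structure(list(matrix = matrix, genes = as.character(gene_ids),
                 cells = as.character(cell_ids), annotations = ann,
                 group_by = group_by, group_index = gfac, groups = groups,
                 group_sizes = as.integer(sizes)),
            class = "grouped_expression")
}

#' @export
print.grouped_expression <- function(x, ...) {
  cat("grouped_expression:", length(x$genes), "genes x", length(x$cells),
      "cells in", nlevels(x$group_index), "groups (",
      paste(x$group_by, collapse = " x "), ")\n")
  invisible(x)
}

#' Counts-per-10k library-size normalization
#'
#' Convenience scaling of raw counts to a common library size of 10,000 per
#' cell, on the linear scale (no log), as the ratio-based activity score
#' expects.
#'
#' @param counts Genes x cells count matrix.
#' @return Matrix of the same shape.
#' @export
normalize_cp10k <- function(counts) {
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  if (inherits(counts, "sparseMatrix")) {
    counts %*% Matrix::Diagonal(x = 1e4 / lib)
  } else {
    sweep(counts, 2L, lib / 1e4, "/")
  }
}

# cells x groups indicator scaled by 1/n_j, for one label permutation
.group_weight_matrix <- function(group_index) {
  j <- as.integer(group_index)
  n <- length(j)
  sizes <- tabulate(j, nbins = nlevels(group_index))
  Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1 / sizes[j],
                       dims = c(n, nlevels(group_index)))
}

#' Per-group mean expression
#'
#' `E[i, j]`: arithmetic mean of gene i over the cells of group j.
#'
#' @param expr A `grouped_expression`.
#' @return Genes x groups dense matrix with gene and group dimnames.
#' @export
group_mean_expression <- function(expr) {
  stopifnot(inherits(expr, "grouped_expression"))
  G <- .group_weight_matrix(expr$group_index)
  E <- as.matrix(expr$matrix %*% G)
  dimnames(E) <- list(expr$genes, levels(expr$group_index))
  E
}

#' Relative expression across groups
#'
#' `R[i, j] = E[i, j] / mean_j E[i, .]`; every defined row has mean exactly 1
#' across groups. Genes whose cross-group mean is 0 are undefined (`NA`
#' rows) and excluded downstream.
#'
#' @param E Genes x groups mean-expression matrix from
#'   [group_mean_expression()].
#' @return List with `R` (genes x groups) and `defined` (logical per gene).
#' @export
relative_expression <- function(E) {
  if (ncol(E) < 2L) stop("need at least 2 groups for relative expression")
  m <- rowMeans(E)
  defined <- m > 0
  R <- E / m
  R[!defined, ] <- NA_real_
  list(R = R, defined = defined)
}

#' Gene weights shared across modules
#'
#' `w_i = 1 / (number of passed modules containing gene i)`, so genes shared
#' by many modules are down-weighted in every module's score.
#'
#' @param modules A `tf_modules` object (only passed modules count) or a
#'   named list of gene vectors.
#' @return Named numeric vector of weights over the union of module genes.
#' @export
module_gene_weights <- function(modules) {
  sets <- if (inherits(modules, "tf_modules")) {
    passed_module_genes(modules)
  } else modules
  counts <- table(unlist(sets, use.names = FALSE))
  w <- 1 / as.numeric(counts)
  names(w) <- names(counts)
  w
}

# Core scorer shared by the observed pass and every permutation.
# mod_idx: list of integer row-index vectors into R; w_list: matching weights.
# Returns list(M = nTF x nGroup matrix, n_used = matching integer matrix).
.score_modules <- function(R, defined, mod_idx, w_list,
                           exclusion = "per_group") {
  n_groups <- ncol(R)
  M <- matrix(NA_real_, length(mod_idx), n_groups)
  n_used <- matrix(0L, length(mod_idx), n_groups)
  for (t in seq_along(mod_idx)) {
    idx <- mod_idx[[t]]
    if (length(idx) == 0L) next
    Rm <- R[idx, , drop = FALSE]
    keep <- defined[idx]
    mask <- Rm >= (1 / 3) & Rm <= 3
    mask[!keep, ] <- FALSE
    mask[is.na(mask)] <- FALSE
    if (exclusion == "per_gene") {
      # a gene out of band in any group is dropped from the module entirely
      row_ok <- rowSums(!mask & keep) == 0L & keep
      mask[] <- row_ok
    }
    w <- w_list[[t]]
    wm <- w * mask
    denom <- colSums(wm)
    num <- colSums(wm * ifelse(mask, Rm, 0))
    M[t, ] <- ifelse(denom > 0, num / denom, NA_real_)
    n_used[t, ] <- colSums(mask)
  }
  list(M = M, n_used = n_used)
}

#' Observed module activity scores
#'
#' Computes `M[t, j]`, the weighted mean relative expression of module t's
#' genes in group j, after dropping undefined genes and genes whose relative
#' expression in that group exceeds 3 or falls below 1/3 (outlier rule).
#' Scores above 1 indicate activation of the module in that group, below 1
#' inhibition.
#'
#' @param expr A `grouped_expression`.
#' @param modules A `tf_modules` object or named list of gene vectors; only
#'   passed modules are scored.
#' @param exclusion `"per_group"` (default; the outlier rule is applied to
#'   each (gene, group) entry of R) or `"per_gene"` (a gene out of band
#'   anywhere is dropped from the module in all groups).
#' @return Data.frame with one row per (tf, group): `tf`, the grouping
#'   columns, `M_score`, `n_genes_used`.
#' @export
module_activity <- function(expr, modules,
                            exclusion = c("per_group", "per_gene")) {
  exclusion <- match.arg(exclusion)
  stopifnot(inherits(expr, "grouped_expression"))
  sets <- if (inherits(modules, "tf_modules")) passed_module_genes(modules) else modules
  if (length(sets) == 0L) stop("no passed modules to score")
  w_all <- module_gene_weights(modules)
  E <- group_mean_expression(expr)
  rel <- relative_expression(E)
  prep <- .prepare_module_index(sets, w_all, expr$genes)
  sc <- .score_modules(rel$R, rel$defined, prep$idx, prep$w, exclusion)
  .activity_frame(expr, names(sets), sc)
}

.prepare_module_index <- function(sets, w_all, genes) {
  idx <- lapply(sets, function(g) {
    i <- match(g, genes)
    i[!is.na(i)]
  })
  w <- lapply(seq_along(sets), function(t) {
    g <- sets[[t]][!is.na(match(sets[[t]], genes))]
    unname(w_all[g])
  })
  list(idx = idx, w = w)
}

.activity_frame <- function(expr, tfs, sc, extra = NULL) {
  n_groups <- nlevels(expr$group_index)
  out <- data.frame(tf = rep(tfs, each = n_groups), stringsAsFactors = FALSE)
  for (v in expr$group_by) {
    out[[v]] <- rep(expr$groups[[v]], times = length(tfs))
  }
  out$group <- rep(expr$groups$group, times = length(tfs))
  out$M_score <- as.vector(t(sc$M))
  out$n_genes_used <- as.vector(t(sc$n_used))
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' Permutation significance of module activity
#'
#' Shuffles the group labels over all cells (preserving group sizes) and
#' recomputes the full mean -> relative-expression -> activity chain,
#' including the outlier exclusions, for each of `n_perm` permutations.
#' Both tail proportions are estimated with the add-one correction:
#' `p_up = (1 + #\{permuted M >= observed M\}) / (1 + n_perm)` and the
#' mirror image `p_low`. With `tail = "two_sided"` (default) the reported
#' p-value is `min(1, 2 min(p_up, p_low))`, which is super-uniform under a
#' label-exchangeable null so the nominal level equals the realized type-I
#' error. `tail = "directional"` instead reports the single tail in the
#' observed direction (`p_up` when M > 1, `p_low` when M < 1), i.e. the
#' plain proportion of permuted scores at least as extreme as the observed
#' one; note its two-direction type-I error is about twice the nominal
#' level. A score exactly 1 gets p = 1 either way. Scores with p below
#' `alpha` are called `activated` (M > 1) or `inhibited` (M < 1), otherwise
#' `ns`.
#'
#' @inheritParams module_activity
#' @param n_perm Number of label permutations (the study default is 5000).
#' @param seed Integer RNG seed; required, so runs are reproducible.
#' @param alpha Significance level for the activation/inhibition call.
#' @param tail `"two_sided"` (default) or `"directional"`; see Details.
#' @return An `activity_table`: data.frame with columns `tf`, the grouping
#'   columns, `group`, `M_score`, `n_genes_used`, `p_perm`, `z`, `call`;
#'   attributes `n_perm`, `seed`, `alpha`, `tail`, `weights`.
#' @export
permutation_significance <- function(expr, modules, n_perm = 5000L,
                                     seed = NULL, alpha = 0.05,
                                     exclusion = c("per_group", "per_gene"),
                                     tail = c("two_sided", "directional")) {
  exclusion <- match.arg(exclusion)
  tail <- match.arg(tail)
  stopifnot(inherits(expr, "grouped_expression"))
  if (is.null(seed)) stop("a seed is required for the permutation null")
  if (n_perm < 100L) {
    warning("n_perm = ", n_perm, " is very small; p-values will be coarse")
  }
  sets <- if (inherits(modules, "tf_modules")) passed_module_genes(modules) else modules
  if (length(sets) == 0L) stop("no passed modules to score")
  w_all <- module_gene_weights(modules)
  prep <- .prepare_module_index(sets, w_all, expr$genes)

  # restrict the expression matrix to module genes: group labels only enter
  # through E, so unused genes cannot change any score
  used <- sort(unique(unlist(prep$idx)))
  X <- expr$matrix[used, , drop = FALSE]
  remap <- match(seq_len(length(expr$genes)), used)
  idx_small <- lapply(prep$idx, function(i) remap[i])

  score_under <- function(gfac) {
    G <- .group_weight_matrix(gfac)
    E <- as.matrix(X %*% G)
    m <- rowMeans(E)
    defined <- m > 0
    R <- E / m
    R[!defined, ] <- NA_real_
    .score_modules(R, defined, idx_small, prep$w, exclusion)
  }

  obs <- score_under(expr$group_index)

  nT <- length(sets)
  nG <- nlevels(expr$group_index)
  cnt_ge <- matrix(0L, nT, nG)
  cnt_le <- matrix(0L, nT, nG)
  n_valid <- matrix(0L, nT, nG)
  sum_p <- matrix(0, nT, nG)
  sumsq_p <- matrix(0, nT, nG)

  gidx <- expr$group_index
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(length(gidx))
      sc <- score_under(gidx[perm])
      ok <- !is.na(sc$M)
      n_valid <- n_valid + ok
      cnt_ge <- cnt_ge + (ok & sc$M >= obs$M)
      cnt_le <- cnt_le + (ok & sc$M <= obs$M)
      sum_p <- sum_p + ifelse(ok, sc$M, 0)
      sumsq_p <- sumsq_p + ifelse(ok, sc$M^2, 0)
    }
  })

  p_up <- (1 + cnt_ge) / (1 + n_valid)
  p_lo <- (1 + cnt_le) / (1 + n_valid)
  p <- matrix(NA_real_, nT, nG)
  up <- !is.na(obs$M) & obs$M > 1
  dn <- !is.na(obs$M) & obs$M < 1
  eq <- !is.na(obs$M) & obs$M == 1
  if (tail == "directional") {
    p[up] <- p_up[up]
    p[dn] <- p_lo[dn]
  } else {
    two <- pmin(1, 2 * pmin(p_up, p_lo))
    p[up | dn] <- two[up | dn]
  }
  p[eq] <- 1

  mu <- ifelse(n_valid > 0, sum_p / n_valid, NA_real_)
  sdev <- ifelse(n_valid > 1,
                 sqrt(pmax(0, (sumsq_p - n_valid * mu^2) / (n_valid - 1))),
                 NA_real_)
  z <- ifelse(!is.na(obs$M) & !is.na(sdev) & sdev > 0,
              (obs$M - mu) / sdev, NA_real_)

  call <- matrix("ns", nT, nG)
  call[up & p < alpha] <- "activated"
  call[dn & p < alpha] <- "inhibited"
  call[is.na(obs$M)] <- NA_character_

  out <- .activity_frame(expr, names(sets), obs,
                         extra = data.frame(p_perm = as.vector(t(p)),
                                            z = as.vector(t(z)),
                                            call = as.vector(t(call)),
                                            stringsAsFactors = FALSE))
  structure(out, n_perm = n_perm, seed = seed, alpha = alpha, tail = tail,
            weights = w_all, class = c("activity_table", "data.frame"))
}

#' Progression-associated TFs from an activity table
#'
#' A TF qualifies when at least `min_significant_groups` of its (group)
#' scores are called activated or inhibited.
#'
#' @param activity An `activity_table` from [permutation_significance()].
#' @param min_significant_groups Minimum number of significant group calls
#'   (default 1).
#' @return Character vector of TF symbols.
#' @export
mp_tfs <- function(activity, min_significant_groups = 1L) {
  sig <- activity$call %in% c("activated", "inhibited")
  tab <- table(activity$tf[sig])
  sort(names(tab)[tab >= min_significant_groups])
}

#' Read an expression triplet (MatrixMarket + genes + cells)
#'
#' @param mtx Path to a MatrixMarket file.
#' @param genes_tsv One gene id per line (first column if multiple).
#' @param cells_tsv TSV with header: `cell_id`, `cell_type`, `stage`, and
#'   optionally `patient`.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`
#'   (transposed on load).
#' @param normalize `"none"` (default; matrix already normalized) or
#'   `"cp10k"`.
#' @inheritParams grouped_expression
#' @return A `grouped_expression`.
#' @export
read_grouped_expression <- function(mtx, genes_tsv, cells_tsv,
                                    orientation = c("genes_by_cells",
                                                    "cells_by_genes"),
                                    normalize = c("none", "cp10k"),
                                    group_by = c("cell_type", "stage"),
                                    min_cells_per_group = 10L,
                                    stage_levels = NULL) {
  orientation <- match.arg(orientation)
  normalize <- match.arg(normalize)
  X <- Matrix::readMM(mtx)
  if (orientation == "cells_by_genes") X <- Matrix::t(X)
  X <- methods::as(X, "CsparseMatrix")
  genes <- utils::read.delim(genes_tsv, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.delim(cells_tsv, stringsAsFactors = FALSE)
  if (normalize == "cp10k") X <- normalize_cp10k(X)
  grouped_expression(X, genes, cells$cell_id, cells,
                     group_by = group_by,
                     min_cells_per_group = min_cells_per_group,
                     stage_levels = stage_levels)
}

#' Write an activity table as TSV
#'
#' @param activity An `activity_table`.
#' @param path Output TSV path.
#' @export
write_activity <- function(activity, path) {
  utils::write.table(activity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
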
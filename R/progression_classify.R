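# Stage-trajectory classification of TF activity and module enrichment
# against trajectory-associated gene lists.

#' Classify one activity trajectory across ordered stages
#'
#' Five categories: `Increase` (non-decreasing up to a plateau tolerance,
#' with at least one strict rise), `Decrease` (mirror image), or
#' `"<stage> Max"` for single-peak or irregular profiles, named after the
#' stage with the highest score (earliest stage on ties). A constant
#' trajectory is `"<first stage> Max"`.
#'
#' @param scores Numeric activity scores, one per stage, in stage order.
#' @param stages Ordered stage labels (same length as `scores`).
#' @param flat_tol Plateau tolerance on the activity scale: steps with
#'   absolute size at most `flat_tol` do not break monotonicity and do not
#'   count as strict rises/falls. Default 0.01.
#' @return List with `category` (character, `NA` if any score is missing)
#'   and `reason`.
#' @examples
#' classify_trajectory(c(0.8, 1.0, 1.2), c("I", "II", "III"))$category
#' classify_trajectory(c(0.9, 1.4, 1.0), c("I", "II", "III"))$category
#' @export
classify_trajectory <- function(scores, stages, flat_tol = 0.01) {
  stopifnot(length(scores) == length(stages), length(stages) >= 2L)
  if (anyNA(scores)) {
    return(list(category = NA_character_, reason = "undefined_score"))
  }
  d <- diff(scores)
  nondec <- all(d >= -flat_tol) && any(d > flat_tol)
  noninc <- all(d <= flat_tol) && any(d < -flat_tol)
  category <- if (nondec) {
    "Increase"
  } else if (noninc) {
    "Decrease"
  } else {
    paste(stages[which.max(scores)], "Max")
  }
  list(category = category, reason = "ok")
}

#' Classify every (TF, cell type) trajectory in an activity table
#'
#' Orders each TF's scores along `stages` within each cell type and applies
#' [classify_trajectory()]. Trajectories with a missing stage or an
#' undefined score are withheld with a reason.
#'
#' @param activity An activity table (from [permutation_significance()] or
#'   [module_activity()]) with columns `tf`, `cell_type`, `stage`,
#'   `M_score`.
#' @param stages Ordered stage labels to use (e.g. `c("Normal", "I", "II",
#'   "III")`); stages absent from this list are ignored.
#' @inheritParams classify_trajectory
#' @return Data.frame with `tf`, `cell_type`, per-stage score columns,
#'   `category`, `reason`.
#' @export
classify_stage_trajectories <- function(activity, stages, flat_tol = 0.01) {
  stopifnot(all(c("tf", "cell_type", "stage", "M_score") %in% names(activity)))
  sub <- activity[activity$stage %in% stages, , drop = FALSE]
  key <- unique(sub[, c("tf", "cell_type")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    tr <- sub[sub$tf == key$tf[i] & sub$cell_type == key$cell_type[i], ]
    sc <- tr$M_score[match(stages, tr$stage)]
    res <- if (anyNA(sc)) {
      list(category = NA_character_,
           reason = if (any(!stages %in% tr$stage)) "missing_stage" else "undefined_score")
    } else {
      classify_trajectory(sc, stages, flat_tol)
    }
    out <- data.frame(tf = key$tf[i], cell_type = key$cell_type[i],
                      stringsAsFactors = FALSE)
    for (s in seq_along(stages)) out[[stages[s]]] <- sc[s]
    out$category <- res$category
    out$reason <- res$reason
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enrich TF modules in a trajectory-associated gene set
#'
#' Tests each passed module for over-representation of trajectory-associated
#' genes by an upper-tail hypergeometric test against the background gene
#' list, with Benjamini-Hochberg adjustment across the tested modules. A
#' module counts as significant when both the raw p-value and the adjusted
#' q-value fall below their cutoffs (default 0.05 / 0.05).
#'
#' @param gene_set Character vector of trajectory-associated genes; must be
#'   a subset of `background`.
#' @param background Background gene universe.
#' @param modules A `tf_modules` object or named list of gene vectors.
#' @param p_cutoff,q_cutoff Raw and adjusted significance cutoffs.
#' @param adjust Multiplicity correction method (default `"BH"`; any
#'   [stats::p.adjust()] method).
#' @return Data.frame with one row per tested module: `tf`, `x_overlap`,
#'   `n_module_in_bg`, `M_hits`, `N_bg`, `p_raw`, `q_adj`, `significant`;
#'   modules with no background overlap are returned with
#'   `reason = "no_background_overlap"` and no test. Attribute `skipped`
#'   lists them.
#' @export
enrich_modules_in_gene_set <- function(gene_set, background, modules,
                                       p_cutoff = 0.05, q_cutoff = 0.05,
                                       adjust = "BH") {
  gene_set <- unique(as.character(gene_set))
  background <- unique(as.character(background))
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of background")
  }
  sets <- if (inherits(modules, "tf_modules")) passed_module_genes(modules) else modules
  if (length(sets) == 0L) stop("no modules to test")
  N <- length(background)
  M <- length(gene_set)
  rows <- lapply(names(sets), function(tf) {
    in_bg <- intersect(sets[[tf]], background)
    n <- length(in_bg)
    if (n == 0L) {
      return(data.frame(tf = tf, x_overlap = 0L, n_module_in_bg = 0L,
                        M_hits = M, N_bg = N, p_raw = NA_real_,
                        q_adj = NA_real_, significant = FALSE,
                        reason = "no_background_overlap",
                        stringsAsFactors = FALSE))
    }
    x <- length(intersect(in_bg, gene_set))
    p <- hypergeometric_overlap_p(N, M, n, x)
    data.frame(tf = tf, x_overlap = x, n_module_in_bg = n, M_hits = M,
               N_bg = N, p_raw = p, q_adj = NA_real_, significant = FALSE,
               reason = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p_raw)
  out$q_adj[tested] <- stats::p.adjust(out$p_raw[tested], method = adjust)
  out$significant <- tested & out$p_raw < p_cutoff & out$q_adj < q_cutoff
  out$significant[is.na(out$significant)] <- FALSE
  rownames(out) <- NULL
  structure(out, skipped = out$tf[!tested])
}
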
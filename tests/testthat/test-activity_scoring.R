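test_that("group means equal a per-cell loop oracle", {
  withr::with_seed(42, {
    X <- matrix(rexp(20 * 50), 20, 50)
    groups <- sample(c("A", "B", "C"), 50, replace = TRUE)
  })
  expr <- grouped_from_matrix(X, groups)
  E <- group_mean_expression(expr)
  for (g in sort(unique(groups))) {
    for (i in 1:20) {
      expect_equal(E[i, g], mean(X[i, groups == g]))
    }
  }
  # hand case: values {2, 4} in a 2-cell group
  e2 <- group_mean_expression(grouped_from_matrix(
    matrix(c(2, 4, 0, 0), 1, 4), c("A", "A", "B", "B")))
  expect_equal(unname(e2[1, ]), c(3, 0))
})

test_that("relative expression is centered at 1 and flags zero genes", {
  E <- matrix(c(2, 2, 2,   # constant gene
                2, 0, 1,   # ordinary gene
                0, 0, 0),  # all-zero gene
              3, 3, byrow = TRUE)
  rel <- relative_expression(E)
  expect_equal(unname(rel$R[1, ]), c(1, 1, 1))
  expect_equal(unname(rel$R[2, ]), c(2, 0, 1))
  expect_true(all(is.na(rel$R[3, ])))
  expect_equal(rel$defined, c(TRUE, TRUE, FALSE))
  # E row (2, 0) over two groups: mean is 1 so R = (2, 0)
  r2 <- relative_expression(matrix(c(2, 0), 1, 2))
  expect_equal(unname(r2$R[1, ]), c(2, 0))
  expect_error(relative_expression(matrix(1, 2, 1)), "at least 2 groups")
})

test_that("defined rows of R always average to exactly 1 across groups", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      X <- matrix(rpois(30 * 40, lambda = 2), 30, 40)
      groups <- rep(c("g1", "g2", "g3", "g4"), each = 10)
    })
    rel <- relative_expression(group_mean_expression(
      grouped_from_matrix(X, groups)))
    means <- rowMeans(rel$R)[rel$defined]
    expect_true(all(abs(means - 1) < 1e-9))
  }
})

test_that("module activity applies weights and the 3x / one-third rule", {
  # three genes all at R = 1 in every group
  X <- matrix(5, 3, 8)
  expr <- grouped_from_matrix(X, rep(c("A", "B"), each = 4))
  act <- module_activity(expr, list(TFX = c("g001", "g002", "g003")))
  expect_equal(act$M_score, c(1, 1))
  expect_equal(act$n_genes_used, c(3L, 3L))

  # boundary: R exactly at 1/3 stays in band (exclusion is strict)
  X2 <- rbind(rep(1, 8), c(rep(5, 4), rep(1, 4)))
  expr2 <- grouped_from_matrix(X2, rep(c("A", "B"), each = 4))
  R2 <- relative_expression(group_mean_expression(expr2))$R
  expect_equal(unname(R2[2, ]), c(5 / 3, 1 / 3))
  act2 <- module_activity(expr2, list(TFX = c("g001", "g002")))
  expect_equal(act2$n_genes_used, c(2L, 2L))

  # out of band: 7 vs 1 -> R = (7/4, 1/4); 1/4 < 1/3 is excluded in B
  X3 <- rbind(rep(1, 8), c(rep(7, 4), rep(1, 4)))
  expr3 <- grouped_from_matrix(X3, rep(c("A", "B"), each = 4))
  act3 <- module_activity(expr3, list(TFX = c("g001", "g002")))
  # group A: R = (1, 7/4) both kept; group B: gene2 at 1/4 < 1/3 excluded
  expect_equal(act3$M_score[act3$cell_type == "A"], mean(c(1, 7 / 4)))
  expect_equal(act3$M_score[act3$cell_type == "B"], 1)
  expect_equal(act3$n_genes_used, c(2L, 1L))
})

test_that("weighted mean with shared-gene weights is computed as specified", {
  # two modules share one gene, so the shared gene carries weight 1/2
  w <- module_gene_weights(list(m1 = c("a", "b"), m2 = c("b", "c")))
  expect_equal(w[["a"]], 1)
  expect_equal(w[["b"]], 1 / 2)
  # hand-evaluated weighted mean: R = (2, 0.5), weights (1, 1/3)
  R <- matrix(c(2, 0.5), 2, 1)
  sc <- mptf:::.score_modules(R, c(TRUE, TRUE), list(c(1L, 2L)),
                              list(c(1, 1 / 3)))
  expect_equal(sc$M[1, 1], (1 * 2 + (1 / 3) * 0.5) / (4 / 3))
})

test_that("scale invariance: rescaling the matrix changes nothing", {
  withr::with_seed(7, X <- matrix(rpois(40 * 60, 3), 40, 60))
  groups <- rep(c("A", "B", "C"), each = 20)
  mods <- list(t1 = sprintf("g%03d", 1:10), t2 = sprintf("g%03d", 8:20))
  a1 <- permutation_significance(grouped_from_matrix(X, groups), mods,
                                 n_perm = 100, seed = 5)
  a2 <- permutation_significance(grouped_from_matrix(X * 37.5, groups),
                                 mods, n_perm = 100, seed = 5)
  expect_equal(a1$M_score, a2$M_score, tolerance = 1e-12)
  expect_equal(a1$p_perm, a2$p_perm)
  expect_equal(a1$call, a2$call)
})

test_that("constant expression gives unit scores and null p-values", {
  X <- matrix(4, 30, 40)
  expr <- grouped_from_matrix(X, rep(c("A", "B"), each = 20))
  mods <- list(t1 = sprintf("g%03d", 1:10), t2 = sprintf("g%03d", 11:25))
  act <- suppressWarnings(
    permutation_significance(expr, mods, n_perm = 50, seed = 1))
  expect_true(all(act$M_score == 1))
  expect_true(all(act$p_perm == 1))
  expect_true(all(act$call == "ns"))
})

test_that("permutation p-values are reproducible and need a seed", {
  withr::with_seed(11, X <- matrix(rnbinom(50 * 80, mu = 2, size = 2), 50, 80))
  groups <- rep(c("A", "B", "C", "D"), each = 20)
  expr <- grouped_from_matrix(X, groups)
  mods <- list(t1 = sprintf("g%03d", 1:12), t2 = sprintf("g%03d", 20:40))
  expect_error(permutation_significance(expr, mods, n_perm = 100),
               "seed")
  expect_warning(permutation_significance(expr, mods, n_perm = 50, seed = 2),
                 "very small")
  a1 <- permutation_significance(expr, mods, n_perm = 150, seed = 9)
  a2 <- permutation_significance(expr, mods, n_perm = 150, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1$p_perm > 0 & a1$p_perm <= 1))
})

test_that("the two-sided p doubles the smaller tail of the directional p", {
  withr::with_seed(19, X <- matrix(rnbinom(40 * 120, mu = 3, size = 2),
                                   40, 120))
  expr <- grouped_from_matrix(X, rep(c("A", "B", "C"), each = 40))
  mods <- list(t1 = sprintf("g%03d", 1:15), t2 = sprintf("g%03d", 16:35))
  two <- permutation_significance(expr, mods, n_perm = 200, seed = 4,
                                  tail = "two_sided")
  dir <- permutation_significance(expr, mods, n_perm = 200, seed = 4,
                                  tail = "directional")
  expect_identical(two$M_score, dir$M_score)
  # the directional tail never exceeds the two-sided p, and the two-sided p
  # never exceeds twice the directional one
  ok <- !is.na(two$p_perm) & two$M_score != 1
  expect_true(all(dir$p_perm[ok] <= two$p_perm[ok]))
  expect_true(all(two$p_perm[ok] <= pmin(1, 2 * dir$p_perm[ok])))
})

test_that("a planted two-fold shift is detected and called activated", {
  withr::with_seed(3, {
    X <- matrix(rnbinom(60 * 200, mu = 4, size = 2), 60, 200)
    groups <- rep(c("A", "B"), each = 100)
    X[1:15, groups == "B"] <- rnbinom(15 * 100, mu = 8, size = 2)
  })
  expr <- grouped_from_matrix(X, groups)
  act <- permutation_significance(expr, list(tf1 = sprintf("g%03d", 1:15),
                                             null_tf = sprintf("g%03d", 30:45)),
                                  n_perm = 500, seed = 21)
  hit <- act[act$tf == "tf1" & act$cell_type == "B", ]
  expect_equal(hit$call, "activated")
  expect_lt(hit$p_perm, 0.05)
  expect_gt(hit$M_score, 1)
  # the complementary group of a shifted module sits below 1
  expect_lt(act$M_score[act$tf == "tf1" & act$cell_type == "A"], 1)
})

test_that("grouping by cell_type x stage builds the expected groups", {
  withr::with_seed(5, X <- matrix(rpois(10 * 40, 3), 10, 40))
  ann <- data.frame(cell_id = sprintf("c%02d", 1:40),
                    cell_type = rep(c("T", "B"), each = 20),
                    stage = rep(c("I", "II"), times = 20),
                    patient = "p1", stringsAsFactors = FALSE)
  expr <- grouped_expression(X, sprintf("g%02d", 1:10), ann$cell_id, ann,
                             stage_levels = c("I", "II"))
  expect_equal(nlevels(expr$group_index), 4L)
  expect_equal(expr$group_sizes, rep(10L, 4))
  expect_error(grouped_expression(X, sprintf("g%02d", 1:10), ann$cell_id,
                                  ann, min_cells_per_group = 11L),
               "fewer than 11")
})

test_that("mp_tfs selects TFs with enough significant group calls", {
  act <- data.frame(tf = c("A", "A", "B", "B"),
                    call = c("activated", "inhibited", "ns", "activated"))
  expect_equal(mp_tfs(act), c("A", "B"))
  expect_equal(mp_tfs(act, min_significant_groups = 2L), "A")
})

test_that("expression triplet round-trips through MTX + TSV files", {
  cfg <- synthetic_config(n_tfs = 2L, targets_per_tf = 5L,
                          n_bystander_genes = 5L, ppi_edges = 10L,
                          cells_per_group = 12L, seed = 8L)
  ds <- simulate_dataset(cfg)
  dir <- tempfile()
  write_synthetic(ds, dir)
  expr <- read_grouped_expression(file.path(dir, "matrix.mtx"),
                                  file.path(dir, "genes.tsv"),
                                  file.path(dir, "cells.tsv"),
                                  normalize = "cp10k",
                                  stage_levels = cfg$stages)
  expect_equal(length(expr$genes), length(ds$expr$genes))
  expect_equal(nlevels(expr$group_index), 4L)
  direct <- normalize_cp10k(ds$expr$counts)
  expect_equal(as.matrix(expr$matrix), as.matrix(direct),
               tolerance = 1e-12, ignore_attr = TRUE)
})
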
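test_that("pearson_matrix matches hand values, symmetry and unit diagonal", {
  vals <- rbind(a = c(1, 2, 3), b = c(6, 4, 2), c = c(1, 2, 4))
  cm <- pearson_matrix(expr_fixture(vals), axis = "genes", min_obs = 3)
  expect_equal(cm$r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(cm$r["a", "c"], brute_pearson(c(1, 2, 3), c(1, 2, 4)),
               tolerance = 1e-12)
  expect_equal(cm$r["a", "c"], 0.981980506061966, tolerance = 1e-9)
  expect_true(all(diag(cm$r) == 1))
  expect_equal(cm$r, t(cm$r))
  expect_true(all(cm$r >= -1 - 1e-12 & cm$r <= 1 + 1e-12))
})

test_that("pearson_matrix agrees with the sum-formula oracle on random data with missingness", {
  set.seed(10)
  vals <- matrix(rnorm(15 * 30), 15, 30)
  vals[sample(length(vals), 60)] <- NA
  cm <- pearson_matrix(expr_fixture(vals), axis = "genes", min_obs = 3)
  rn <- rownames(cm$r)
  for (pick in list(c(1, 2), c(3, 9), c(10, 15))) {
    o <- brute_pearson(vals[pick[1], ], vals[pick[2], ])
    expect_equal(cm$r[rn[pick[1]], rn[pick[2]]], o, tolerance = 1e-12)
  }
  expect_equal(unname(cm$n_obs[1, 2]),
               sum(!is.na(vals[1, ]) & !is.na(vals[2, ])))
})

test_that("sparse pairs and zero-variance profiles yield NA, not edges", {
  vals <- rbind(a = c(1, 2, 3, 4, NA, NA), b = c(NA, NA, NA, 4, 5, 6),
                c = c(1, 1, 1, 1, 1, 1), d = c(1, 3, 2, 5, 4, 6))
  expect_warning(cm <- pearson_matrix(expr_fixture(vals), axis = "genes",
                                      min_obs = 3),
                 "zero-variance")
  expect_true(is.na(cm$r["a", "b"])) # only one shared observation
  expect_true(all(is.na(cm$r["c", ])))
  g <- graph_from_correlations(cm, threshold = -1, strict = FALSE)
  expect_false(any(g$edges$from == "c" | g$edges$to == "c"))
  expect_false(any((g$edges$from == "a" & g$edges$to == "b")))
})

test_that("graph construction reads off the threshold rule exactly", {
  r <- matrix(c(1, .6, .2, .6, 1, .7, .2, .7, 1), 3, 3,
              dimnames = list(c("n1", "n2", "n3"), c("n1", "n2", "n3")))
  cm <- structure(list(r = r, n_obs = matrix(50, 3, 3), axis = "cells",
                       min_obs = 10), class = "cor_matrix")
  g <- graph_from_correlations(cm, 0.5, strict = TRUE)
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$from, g$edges$to), c("n1 n2", "n2 n3"))
  empty <- graph_from_correlations(cm, 1.0, strict = TRUE)
  expect_equal(nrow(empty$edges), 0)
  # strict vs non-strict boundary
  gs <- graph_from_correlations(cm, 0.7, strict = TRUE)
  gn <- graph_from_correlations(cm, 0.7, strict = FALSE)
  expect_equal(nrow(gs$edges), 0)
  expect_equal(nrow(gn$edges), 1)
  expect_error(graph_from_correlations(cm, 1.5), "threshold")
})

test_that("degrees match a brute-force pair count and thresholds act monotonically", {
  set.seed(21)
  for (rep in 1:3) {
    vals <- matrix(rnorm(20 * 12), 20, 12)
    cm <- pearson_matrix(expr_fixture(vals), axis = "genes", min_obs = 3)
    thr <- 0.3
    g <- graph_from_correlations(cm, thr, strict = TRUE)
    deg <- graph_degrees(g)
    for (i in seq_len(nrow(cm$r))) {
      manual <- sum(cm$r[i, -i] > thr & cm$r[i, -i] > 0, na.rm = TRUE)
      expect_equal(deg$degree[deg$node == rownames(cm$r)[i]], manual)
    }
    e_low <- nrow(graph_from_correlations(cm, 0.2)$edges)
    e_mid <- nrow(graph_from_correlations(cm, 0.5)$edges)
    e_high <- nrow(graph_from_correlations(cm, 0.8)$edges)
    expect_true(e_low >= e_mid && e_mid >= e_high)
  }
})

test_that("permutation threshold is reproducible and separates planted structure from noise", {
  set.seed(31)
  # planted two-block structure: strong within-block correlation
  latent <- rnorm(40)
  block <- rbind(
    t(replicate(5, latent + rnorm(40, 0, 0.3))),
    t(replicate(5, -latent + rnorm(40, 0, 0.3)))
  )
  x <- expr_fixture(block)
  thr <- permutation_threshold(x, axis = "genes", n_perm = 100,
                               quantile = 0.95, seed = 99, min_obs = 3)
  thr2 <- permutation_threshold(x, axis = "genes", n_perm = 100,
                                quantile = 0.95, seed = 99, min_obs = 3)
  expect_identical(thr$threshold, thr2$threshold)
  cm <- pearson_matrix(x, axis = "genes", min_obs = 3)
  within <- c(cm$r[1:5, 1:5][upper.tri(diag(5))],
              cm$r[6:10, 6:10][upper.tri(diag(5))])
  expect_true(all(within > thr$threshold))
  expect_error(permutation_threshold(x, n_perm = 50), "100")
  expect_error(permutation_threshold(x, n_perm = 100, quantile = 1.2),
               "quantile")
})

test_that("family-wise permutation threshold controls false edges on iid noise", {
  set.seed(17)
  hits <- 0
  n_runs <- 30
  for (b in seq_len(n_runs)) {
    x <- expr_fixture(matrix(rnorm(8 * 25), 8, 25))
    thr <- permutation_threshold(x, axis = "genes", n_perm = 100,
                                 quantile = 0.95, mode = "familywise",
                                 seed = b, min_obs = 3)
    cm <- pearson_matrix(x, axis = "genes", min_obs = 3)
    if (max(cm$r[upper.tri(cm$r)], na.rm = TRUE) > thr$threshold) hits <- hits + 1
  }
  # expected family-wise error ~5%; allow generous binomial slack
  expect_lte(hits, qbinom(0.999, n_runs, 0.05) + 1)
})

test_that("conditional networks reduce to the unconditional graph under the all-cells filter", {
  set.seed(12)
  x <- expr_fixture(matrix(rnorm(12 * 30), 12, 30))
  g_all <- graph_from_correlations(pearson_matrix(x, axis = "genes", min_obs = 3),
                                   0.3, strict = TRUE)
  g_cond <- conditional_gene_network(x, colnames(x$values), threshold = 0.3,
                                     min_obs = 3, min_cells = 10)
  expect_equal(g_cond$edges, g_all$edges)
  expect_error(conditional_gene_network(x, character(0), min_cells = 10,
                                        filter_label = "empty set"),
               "empty set")
})

test_that("conditioning on a marker-positive subset collapses the marker's correlations", {
  # ligand bimodal across two cell states; within the positive state it is
  # near-constant while partner genes keep co-varying
  set.seed(13)
  n <- 60
  state <- rep(c(0, 1), each = n / 2)
  shared <- rnorm(n)
  vals <- rbind(
    Lig = state * 4 + rnorm(n, 0, 0.2),
    P1 = shared + state * 2 + rnorm(n, 0, 0.3),
    P2 = shared + state * 2 + rnorm(n, 0, 0.3),
    P3 = shared + state * 2 + rnorm(n, 0, 0.3)
  )
  x <- expr_fixture(vals, stage = "minus_ddct")
  full <- graph_from_correlations(pearson_matrix(x, axis = "genes", min_obs = 3),
                                  0.5, strict = TRUE)
  deg_full <- graph_degrees(full)
  pos <- colnames(x$values)[state == 1]
  cond <- conditional_gene_network(x, pos, threshold = 0.5, min_obs = 3)
  deg_cond <- graph_degrees(cond)
  expect_gte(deg_full$degree[deg_full$node == "Lig"], 3)
  expect_equal(deg_cond$degree[deg_cond$node == "Lig"], 0)
  # partners keep correlating within the subset
  expect_gte(deg_cond$degree[deg_cond$node == "P1"], 2)
})

test_that("minimum spanning tree matches examples and the exhaustive oracle", {
  d <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- min_spanning_tree(d)
  expect_setequal(paste(t3$edges$from, t3$edges$to), c("A B", "B C"))
  expect_equal(sum(t3$edges$weight), 3)

  set.seed(19)
  for (n in c(5, 6, 7)) {
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    tr <- min_spanning_tree(d)
    expect_equal(nrow(tr$edges), n - 1)
    expect_equal(sum(tr$edges$weight), brute_mst_weight(d), tolerance = 1e-12)
  }
})

test_that("disconnected dissimilarities give a forest with a warning", {
  d <- matrix(NA_real_, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["c", "d"] <- d["d", "c"] <- 1
  diag(d) <- 0
  expect_warning(f <- min_spanning_tree(d), "forest")
  expect_equal(nrow(f$edges), 2)
})
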
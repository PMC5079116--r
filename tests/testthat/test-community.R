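test_that("modularity matrix matches hand arithmetic and has zero row sums", {
  tri <- make_graph(c("a", "b", "c"),
                    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  bm <- modularity_matrix(tri)
  expect_equal(unname(bm$B["a", "b"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(diag(bm$B)), rep(-2 / 3, 3), tolerance = 1e-12)

  single <- make_graph(c("a", "b"), data.frame(from = "a", to = "b"))
  bs <- modularity_matrix(single)
  expect_equal(unname(bs$B), matrix(c(-0.5, 0.5, 0.5, -0.5), 2), tolerance = 1e-12)

  set.seed(2)
  g <- random_graph(8, 0.4)
  expect_true(all(abs(rowSums(modularity_matrix(g)$B)) < 1e-9))
  expect_error(modularity_matrix(make_graph(c("a", "b"))), "no edges")
})

test_that("leading-eigenvector split separates two cliques and matches sign-vector brute force", {
  nodes <- c(paste0("x", 1:5), paste0("y", 1:5))
  cl <- function(v) {
    p <- t(utils::combn(v, 2))
    data.frame(from = p[, 1], to = p[, 2])
  }
  edges <- rbind(cl(nodes[1:5]), cl(nodes[6:10]),
                 data.frame(from = "x1", to = "y1"))
  g <- make_graph(nodes, edges)
  bm <- modularity_matrix(g)
  sp <- leading_eigenvector_split(bm)
  expect_true(sp$divisible)
  side_x <- sp$sign[paste0("x", 1:5)]
  side_y <- sp$sign[paste0("y", 1:5)]
  expect_equal(length(unique(side_x)), 1)
  expect_equal(length(unique(side_y)), 1)
  expect_true(unique(side_x) != unique(side_y))
  # brute-force maximum of s'Bs over all 2^10 sign vectors
  best <- -Inf
  for (mask in 0:(2^10 - 1)) {
    s <- 2 * as.integer(intToBits(mask)[1:10]) - 1
    best <- max(best, as.numeric(s %*% bm$B %*% s) / (4 * bm$m))
  }
  expect_gt(sp$delta_q, 0)
  expect_equal(sp$delta_q, best, tolerance = 1e-9)
})

test_that("all-equal sign vectors carry zero modularity gain", {
  set.seed(3)
  g <- random_graph(7, 0.5)
  bm <- modularity_matrix(g)
  s <- rep(1, 7)
  expect_equal(as.numeric(s %*% bm$B %*% s) / (4 * bm$m), 0, tolerance = 1e-12)
})

test_that("complete graphs and single edges are indivisible", {
  k6 <- make_graph(paste0("n", 1:6), {
    p <- t(utils::combn(paste0("n", 1:6), 2))
    data.frame(from = p[, 1], to = p[, 2])
  })
  # exhaustive check: no bipartition of K6 improves modularity
  bm <- modularity_matrix(k6)
  gains <- sapply(1:(2^6 - 2), function(mask) {
    s <- 2 * as.integer(intToBits(mask)[1:6]) - 1
    as.numeric(s %*% bm$B %*% s) / (4 * bm$m)
  })
  expect_lte(max(gains), 1e-12)
  p6 <- detect_communities(k6)
  expect_equal(length(unique(p6$assignment$group)), 1)

  p2 <- detect_communities(make_graph(c("a", "b"), data.frame(from = "a", to = "b")))
  expect_equal(length(unique(p2$assignment$group)), 1)
})

test_that("two bridged cliques are recovered as two communities at the exhaustive optimum", {
  nodes <- c(paste0("x", 1:4), paste0("y", 1:4))
  cl <- function(v) {
    p <- t(utils::combn(v, 2))
    data.frame(from = p[, 1], to = p[, 2])
  }
  g <- make_graph(nodes, rbind(cl(nodes[1:4]), cl(nodes[5:8]),
                               data.frame(from = "x1", to = "y1")))
  part <- detect_communities(g)
  expect_equal(length(unique(part$assignment$group)), 2)
  grp_x <- part$assignment$group[part$assignment$node %in% paste0("x", 1:4)]
  expect_equal(length(unique(grp_x)), 1)
  expect_equal(part$q, exhaustive_max_modularity(g), tolerance = 1e-9)
})

test_that("partition modularity is non-negative versus the trivial partition and runs are deterministic", {
  set.seed(4)
  for (rep in 1:10) {
    g <- random_graph(sample(5:9, 1), runif(1, 0.3, 0.7))
    p1 <- detect_communities(g)
    expect_gte(p1$q, -1e-12)
    p2 <- detect_communities(g)
    expect_identical(p1$assignment, p2$assignment)
  }
})

test_that("node relabeling permutes the partition but not its structure", {
  set.seed(5)
  g <- random_graph(8, 0.45)
  p <- detect_communities(g)
  perm <- sample(8)
  relabel <- stats::setNames(sprintf("m%02d", seq_len(8)), g$nodes[perm])
  g2 <- make_graph(unname(relabel[g$nodes[perm]]),
                   data.frame(from = unname(relabel[g$edges$from]),
                              to = unname(relabel[g$edges$to]),
                              weight = g$edges$weight))
  p2 <- detect_communities(g2)
  expect_equal(p2$q, p$q, tolerance = 1e-9)
  a1 <- p$assignment$group[match(g$nodes, p$assignment$node)]
  a2 <- p2$assignment$group[match(unname(relabel[g$nodes]), p2$assignment$node)]
  # same partition up to label permutation
  expect_equal(length(unique(a1)), length(unique(a2)))
  expect_true(all(table(a1, a2) %in% c(0, table(a1))))
})

test_that("residual pooling moves isolated nodes and undersized groups, renumbering by size", {
  nodes <- c(paste0("a", 1:5), paste0("b", 1:3), "iso")
  cl <- function(v) {
    p <- t(utils::combn(v, 2))
    data.frame(from = p[, 1], to = p[, 2])
  }
  g <- make_graph(nodes, rbind(cl(paste0("a", 1:5)), cl(paste0("b", 1:3))))
  p <- detect_communities(g)
  pooled <- pool_residual(g, p, min_degree = 1, min_size = 5)
  tp <- tidy(pooled)
  expect_true(all(tp$residual[tp$node %in% c(paste0("b", 1:3), "iso")]))
  expect_true(all(!tp$residual[tp$node %in% paste0("a", 1:5)]))
  expect_equal(unique(tp$group[tp$node %in% paste0("a", 1:5)]), 1L)
  expect_equal(pooled$residual_group, 2L)

  # identity knobs: nothing pooled
  ident <- pool_residual(g, p, min_degree = 0, min_size = 1)
  expect_true(is.na(ident$residual_group))
  expect_equal(sort(table(ident$assignment$group), decreasing = TRUE),
               sort(table(p$assignment$group), decreasing = TRUE))
  expect_error(pool_residual(g, p, min_size = 0), "min_size")
})

test_that("planted four-block graphs are recovered with high agreement", {
  skip_if_not_installed("mclust")
  set.seed(6)
  aris <- replicate(5, {
    blocks <- rep(1:4, each = 25)
    n <- length(blocks)
    pairs <- t(utils::combn(n, 2))
    p_edge <- ifelse(blocks[pairs[, 1]] == blocks[pairs[, 2]], 0.8, 0.05)
    keep <- runif(nrow(pairs)) < p_edge
    nodes <- sprintf("n%03d", 1:n)
    g <- make_graph(nodes, data.frame(from = nodes[pairs[keep, 1]],
                                      to = nodes[pairs[keep, 2]]))
    part <- detect_communities(g)
    lab <- part$assignment$group[match(nodes, part$assignment$node)]
    mclust::adjustedRandIndex(lab, blocks)
  })
  expect_gte(median(aris), 0.95)
})

test_that("detected modularity tracks the exhaustive optimum on random small graphs", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_graph(sample(4:7, 1), runif(1, 0.3, 0.8))
    p <- detect_communities(g)
    q_star <- exhaustive_max_modularity(g)
    expect_lte(q_star - p$q, 0.02 + 1e-12)
  }
})

test_that("spectral partitions agree with an independent library implementation on clean graphs", {
  skip_if_not_installed("igraph")
  nodes <- c(paste0("x", 1:5), paste0("y", 1:5))
  cl <- function(v) {
    p <- t(utils::combn(v, 2))
    data.frame(from = p[, 1], to = p[, 2])
  }
  g <- make_graph(nodes, rbind(cl(nodes[1:5]), cl(nodes[6:10]),
                               data.frame(from = "x1", to = "y1")))
  p <- detect_communities(g)
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      directed = FALSE, vertices = g$nodes)
  ref <- igraph::cluster_leading_eigen(ig)
  ref_lab <- igraph::membership(ref)[g$nodes]
  our_lab <- p$assignment$group[match(g$nodes, p$assignment$node)]
  expect_equal(length(unique(our_lab)), length(unique(ref_lab)))
  expect_true(all(table(our_lab, ref_lab) %in% c(0, 5)))
  expect_equal(p$q, igraph::modularity(ig, ref_lab), tolerance = 1e-9)
})
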
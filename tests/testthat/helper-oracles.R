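# Independent brute-force oracles and fixture builders used across the suite.
# Oracles are deliberately written in the most literal way possible and share
# no code with the package internals they check.

# build a cor_graph by hand from an edge data frame
make_graph <- function(nodes, edges = NULL, threshold = NA_real_, strict = TRUE) {
  if (is.null(edges)) edges <- data.frame(from = character(), to = character(),
                                          weight = double())
  edges$weight <- if (is.null(edges$weight)) 1 else edges$weight
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges),
                 threshold = threshold, strict = strict, axis = "cells",
                 directed = FALSE),
            class = "cor_graph")
}

# Erdos-Renyi graph with guaranteed >= 1 edge
random_graph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  repeat {
    keep <- stats::runif(nrow(pairs)) < p
    if (any(keep)) break
  }
  make_graph(nodes, data.frame(from = nodes[pairs[keep, 1]],
                               to = nodes[pairs[keep, 2]], weight = 1))
}

adjacency_of <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    i <- match(g$edges$from, g$nodes); j <- match(g$edges$to, g$nodes)
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
  }
  A
}

# all set partitions of n items as restricted growth strings (rows);
# memoized because Bell(10) is large but reused across graphs
.partition_cache <- new.env(parent = emptyenv())
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  rows <- list()
  rgs <- integer(n)
  recurse <- function(i, max_used) {
    if (i > n) {
      rows[[length(rows) + 1]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(max_used + 1)) {
      rgs[i] <<- v
      recurse(i + 1, max(max_used, v))
    }
  }
  recurse(1, 0)
  out <- do.call(rbind, rows)
  .partition_cache[[key]] <- out
  out
}

# pair-equality indicator matrix (partitions x unordered pairs), memoized
.pair_cache <- new.env(parent = emptyenv())
partition_pair_indicator <- function(n) {
  key <- as.character(n)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  P <- all_partitions(n)
  pairs <- t(utils::combn(n, 2))
  E <- (P[, pairs[, 1], drop = FALSE] == P[, pairs[, 2], drop = FALSE]) * 1
  .pair_cache[[key]] <- E
  E
}

# exhaustive maximum modularity over all partitions of the graph's nodes
exhaustive_max_modularity <- function(g) {
  A <- adjacency_of(g)
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(A) / 2
  B <- A - outer(k, k) / (2 * m)
  pairs <- t(utils::combn(n, 2))
  b_off <- B[pairs] # upper-triangle entries in combn order
  E <- partition_pair_indicator(n)
  q_all <- (as.vector(E %*% b_off) * 2 + sum(diag(B))) / (2 * m)
  max(q_all)
}

# literal double-loop silhouette
brute_silhouette <- function(labels, d) {
  items <- names(labels)
  s <- numeric(length(items))
  for (i in seq_along(items)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) d[items[i], items[j]]))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      others <- which(labels == cl)
      b <- min(b, mean(sapply(others, function(j) d[items[i], items[j]])))
    }
    s[i] <- (b - a) / max(a, b)
  }
  stats::setNames(s, items)
}

# exhaustive minimum spanning tree weight (n <= 7): try all edge subsets of
# size n-1, keep those that connect the graph
brute_mst_weight <- function(d) {
  n <- nrow(d)
  pairs <- t(utils::combn(n, 2))
  w <- d[pairs]
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    # union-find connectivity check
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in sel) {
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}

# Pearson correlation from the textbook sum formula
brute_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# one-sided (over-representation) Fisher tail by explicit hypergeometric sum:
# P(X >= k) for X ~ Hypergeom(N, K, n)
brute_fisher_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# exact two-sided rank-sum p by enumerating all group-A rank assignments
brute_rank_sum_p <- function(a, b) {
  ranks <- rank(c(a, b))
  na <- length(a)
  w_obs <- sum(ranks[seq_len(na)])
  all_w <- apply(utils::combn(length(ranks), na), 2,
                 function(idx) sum(ranks[idx]))
  mu <- mean(all_w)
  min(1, 2 * min(mean(all_w <= w_obs + 1e-12), mean(all_w >= w_obs - 1e-12)))
}

# expression container straight from a matrix, for unit fixtures
expr_fixture <- function(values, stage = "minus_ddct", treatment = NULL) {
  if (is.null(colnames(values))) colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  cells <- tibble::tibble(cell = colnames(values),
                          treatment = treatment %||% rep("LP", ncol(values)))
  expr_data(values, stage, cells = cells)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small ct_data fixture
ct_fixture <- function(values, nondetect = NULL, housekeeping = character(),
                       treatment = NULL) {
  if (is.null(colnames(values))) colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (!is.null(nondetect)) dimnames(nondetect) <- dimnames(values)
  cells <- tibble::tibble(cell = colnames(values),
                          treatment = treatment %||% rep("LP", ncol(values)))
  ct_data(values, nondetect, cells = cells, housekeeping = housekeeping)
}
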
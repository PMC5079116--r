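#' Pairwise Pearson correlation over genes or cells
#'
#' Computes Pearson correlations on pairwise-complete observations, either
#' between gene profiles (across cells) or between cell profiles (across
#' genes). Pairs with fewer than `min_obs` shared observations, and pairs
#' involving a zero-variance profile, are `NA`. The number of complete
#' observations per pair is recorded.
#'
#' @param x an [expr_data()] object.
#' @param axis `"cells"` (similarity between transcriptional profiles of
#'   cells) or `"genes"`.
#' @param min_obs minimum pairwise-complete observations (hard floor 3;
#'   default 10 because non-detects can be frequent).
#' @return Object of class `cor_matrix`: list with `r` (symmetric matrix),
#'   `n_obs`, `axis`, `min_obs`.
#' @export
pearson_matrix <- function(x, axis = c("cells", "genes"), min_obs = 10) {
  stopifnot(inherits(x, "expr_data"))
  axis <- match.arg(axis)
  min_obs <- max(3L, as.integer(min_obs))
  m <- if (axis == "cells") x$values else t(x$values)
  # columns of m are the profiles to correlate
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  zero_var <- !is.na(sds) & sds == 0
  if (any(zero_var)) {
    warning("zero-variance ", sub("s$", "", axis), " profile(s): ",
            paste(utils::head(colnames(m)[zero_var], 5), collapse = ", "),
            call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  n_obs <- crossprod(!is.na(m))
  r[n_obs < min_obs] <- NA
  r[zero_var, ] <- NA
  r[, zero_var] <- NA
  diag(r) <- ifelse(zero_var | diag(n_obs) < 2, NA, 1)
  structure(list(r = r, n_obs = n_obs, axis = axis, min_obs = min_obs),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat("<cor_matrix> axis=", x$axis, ": ", nrow(x$r), " x ", ncol(x$r),
      " (", sum(is.na(x$r[upper.tri(x$r)])), " undefined pairs)\n", sep = "")
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy cor_matrix
#' @export
tidy.cor_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    item1 = rownames(x$r)[idx[, 1]],
    item2 = colnames(x$r)[idx[, 2]],
    r = x$r[idx],
    n_obs = x$n_obs[idx]
  )
}

#' Permutation-calibrated correlation threshold
#'
#' Builds a null distribution of pairwise correlations by repeatedly
#' shuffling every gene's values independently across cells (destroying all
#' covariance while preserving each gene's marginal distribution and
#' missingness) and recomputing the full set of pairwise correlations on the
#' requested axis. The threshold is the requested quantile of the pooled
#' null (default) or of the per-permutation maximum (family-wise mode).
#'
#' @inheritParams pearson_matrix
#' @param n_perm number of permutations (at least 100).
#' @param quantile probability in (0, 1).
#' @param mode `"pooled"` or `"familywise"`.
#' @param seed integer seed.
#' @return Object of class `null_threshold`: list with `threshold`,
#'   `quantile`, `n_perm`, `mode`, `per_perm` (tibble of per-permutation
#'   summaries), `seed`.
#' @export
permutation_threshold <- function(x, axis = c("cells", "genes"),
                                  n_perm = 200, quantile = 0.95,
                                  mode = c("pooled", "familywise"),
                                  seed = 1L, min_obs = 10) {
  stopifnot(inherits(x, "expr_data"))
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  if (quantile <= 0 || quantile >= 1) {
    stop("`quantile` must lie strictly between 0 and 1", call. = FALSE)
  }
  withr::local_seed(seed)
  vals <- x$values
  pooled <- if (mode == "pooled") vector("list", n_perm) else NULL
  per_perm <- vector("list", n_perm)
  xs <- x
  for (b in seq_len(n_perm)) {
    shuf <- t(apply(vals, 1, sample))
    dimnames(shuf) <- dimnames(vals)
    xs$values <- shuf
    r <- suppressWarnings(pearson_matrix(xs, axis = axis, min_obs = min_obs)$r)
    rv <- r[upper.tri(r)]
    rv <- rv[is.finite(rv)]
    per_perm[[b]] <- tibble::tibble(perm = b, n_pairs = length(rv),
                                    max_r = max(rv), q95 = stats::quantile(rv, 0.95,
                                                                           names = FALSE))
    if (mode == "pooled") pooled[[b]] <- rv
  }
  per_perm <- dplyr::bind_rows(per_perm)
  threshold <- if (mode == "pooled") {
    stats::quantile(unlist(pooled), quantile, names = FALSE)
  } else {
    stats::quantile(per_perm$max_r, quantile, names = FALSE)
  }
  structure(list(threshold = threshold, quantile = quantile, n_perm = n_perm,
                 mode = mode, axis = axis, per_perm = per_perm, seed = seed),
            class = "null_threshold")
}

#' @export
print.null_threshold <- function(x, ...) {
  cat("<null_threshold> axis=", x$axis, " mode=", x$mode, " q=", x$quantile,
      " over ", x$n_perm, " permutations: threshold = ",
      format(x$threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Thresholded correlation graph
#'
#' Builds an undirected graph whose edges are the supra-threshold positive
#' correlations. `NA` correlations never produce edges; self-loops are never
#' produced.
#'
#' @param c a `cor_matrix` from [pearson_matrix()].
#' @param threshold correlation threshold in \[-1, 1\].
#' @param strict edge rule `r > threshold` (`TRUE`) or `r >= threshold`.
#' @param positive_only drop negative supra-threshold correlations (default;
#'   set `FALSE` for a signed graph).
#' @return Object of class `cor_graph`: list with `nodes`, `edges` (tibble
#'   `from`, `to`, `weight` with `from < to`), `threshold`, `strict`, `axis`.
#' @export
graph_from_correlations <- function(c, threshold, strict = TRUE,
                                    positive_only = TRUE) {
  stopifnot(inherits(c, "cor_matrix"))
  if (threshold < -1 || threshold > 1) {
    stop("`threshold` must lie in [-1, 1]", call. = FALSE)
  }
  r <- c$r
  idx <- which(upper.tri(r), arr.ind = TRUE)
  w <- r[idx]
  pass <- !is.na(w) & (if (strict) w > threshold else w >= threshold)
  if (positive_only) pass <- pass & w > 0
  edges <- tibble::tibble(
    from = rownames(r)[idx[pass, 1]],
    to = colnames(r)[idx[pass, 2]],
    weight = w[pass]
  )
  edges <- edges[order(edges$from, edges$to), ]
  structure(list(nodes = rownames(r), edges = edges, threshold = threshold,
                 strict = strict, axis = c$axis, directed = FALSE),
            class = "cor_graph")
}

#' @export
print.cor_graph <- function(x, ...) {
  cat("<cor_graph> axis=", x$axis, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (r ", if (x$strict) ">" else ">=", " ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy cor_graph
#' @export
tidy.cor_graph <- function(x, ...) x$edges

#' Node degrees of a correlation graph
#'
#' @param g a `cor_graph`.
#' @return Tibble with columns `node`, `degree` (every node listed, isolated
#'   nodes with degree 0).
#' @export
graph_degrees <- function(g) {
  stopifnot(inherits(g, "cor_graph"))
  counts <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes))
  tibble::tibble(node = g$nodes, degree = as.integer(counts))
}

#' Gene correlation network within a cell subset
#'
#' Restricts the expression matrix to the cells passing a filter (e.g. the
#' cells called positive for a marker gene) and builds the gene graph over
#' that subset only. Mirrors conditioning a gene network on a cell type.
#'
#' @param x an [expr_data()] object.
#' @param cells character vector of cell ids to keep, or a logical vector
#'   over columns, or a tibble with columns `cell` and `positive` (as
#'   returned by [positive_call()]).
#' @param threshold,strict,positive_only,min_obs see
#'   [graph_from_correlations()] and [pearson_matrix()].
#' @param min_cells minimum subset size (default 10).
#' @param filter_label label used in error messages and provenance.
#' @return A `cor_graph` over genes with attribute `n_cells` recorded.
#' @export
conditional_gene_network <- function(x, cells, threshold = 0.5, strict = TRUE,
                                     positive_only = TRUE, min_obs = 10,
                                     min_cells = 10,
                                     filter_label = "cell filter") {
  stopifnot(inherits(x, "expr_data"))
  if (is.data.frame(cells)) {
    stopifnot(all(c("cell", "positive") %in% names(cells)))
    cells <- cells$cell[cells$positive]
  }
  if (is.logical(cells)) cells <- colnames(x$values)[cells]
  keep <- intersect(colnames(x$values), cells)
  if (length(keep) < min_cells) {
    stop("subset '", filter_label, "' retains ", length(keep),
         " cells (< ", min_cells, ")", call. = FALSE)
  }
  sub <- x
  sub$values <- x$values[, keep, drop = FALSE]
  sub$cells <- x$cells[x$cells$cell %in% keep, ]
  g <- graph_from_correlations(pearson_matrix(sub, axis = "genes",
                                              min_obs = min_obs),
                               threshold, strict = strict,
                               positive_only = positive_only)
  g$n_cells <- length(keep)
  g$filter <- filter_label
  g
}

#' Minimum spanning tree of a dissimilarity matrix
#'
#' Kruskal's algorithm with a deterministic lexicographic tie-break on node
#' pairs. `NA` dissimilarities are treated as absent edges; if the structure
#' is disconnected a spanning forest is returned with a warning.
#'
#' @param d symmetric dissimilarity matrix with dimnames (e.g. `1 - r`).
#' @return A `cor_graph` (tree/forest) whose edge weights are the
#'   dissimilarities used.
#' @export
min_spanning_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("N", seq_len(nrow(d)))
  }
  nodes <- rownames(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  cand <- tibble::tibble(
    from = nodes[idx[, 1]], to = nodes[idx[, 2]], weight = d[idx]
  )
  cand <- cand[!is.na(cand$weight), ]
  cand <- cand[order(cand$weight, cand$from, cand$to), ]
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    a <- find(match(cand$from[e], nodes))
    b <- find(match(cand$to[e], nodes))
    if (a != b) {
      parent[a] <- b
      keep[e] <- TRUE
    }
  }
  edges <- cand[keep, ]
  if (nrow(edges) < length(nodes) - 1) {
    warning("dissimilarity structure is disconnected; returning a spanning forest",
            call. = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), ]
  structure(list(nodes = nodes, edges = edges, threshold = NA_real_,
                 strict = NA, axis = "tree", directed = FALSE),
            class = "cor_graph")
}
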
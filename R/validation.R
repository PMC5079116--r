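#' Silhouette scores for a clustering
#'
#' For each item i in a cluster, `a(i)` is the mean dissimilarity to the
#' other members of its cluster, `b(i)` the lowest mean dissimilarity to the
#' members of any other cluster, and `s(i) = (b(i) - a(i)) / max(a(i), b(i))`
#' in \[-1, 1\]. Members of singleton clusters score 0. Per-cluster quality
#' is the arithmetic mean of the member scores.
#'
#' @param labels cluster assignment: named vector, or tibble with columns
#'   `node`/`item`/`cell` and `group`/`cluster`, or a `group_partition`.
#' @param d symmetric dissimilarity matrix with zero diagonal, rows/columns
#'   matching the labelled items.
#' @return Object of class `silhouette_result`: tibble with columns `item`,
#'   `cluster`, `a`, `b`, `s`; per-cluster means available via
#'   [glance.silhouette_result()].
#' @export
silhouette_scores <- function(labels, d) {
  if (inherits(labels, "group_partition")) labels <- labels$assignment
  if (is.data.frame(labels)) {
    id_col <- intersect(c("node", "item", "cell"), names(labels))[1]
    gr_col <- intersect(c("group", "cluster"), names(labels))[1]
    labels <- stats::setNames(labels[[gr_col]], labels[[id_col]])
  }
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- names(labels)
  items <- names(labels)
  stopifnot(!is.null(items), all(items %in% rownames(d)))
  d <- d[items, items]
  clusters <- unique(labels)
  if (length(clusters) < 2) {
    stop("silhouette undefined for a single cluster", call. = FALSE)
  }
  n <- length(items)
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { # singleton cluster
      a[i] <- 0; b[i] <- 0; s[i] <- 0
      next
    }
    a[i] <- mean(d[i, own])
    b[i] <- min(vapply(setdiff(clusters, labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  structure(tibble::tibble(item = items, cluster = labels, a = a, b = b, s = s),
            class = c("silhouette_result", "tbl_df", "tbl", "data.frame"))
}

#' Per-cluster silhouette summary
#'
#' @param x a `silhouette_result`.
#' @param ... unused.
#' @return Tibble with columns `cluster`, `n`, `mean_s`.
#' @method glance silhouette_result
#' @export
glance.silhouette_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(), mean_s = mean(.data$s), .groups = "drop")
}

#' Principal component analysis of an expression matrix
#'
#' Covariance PCA of cells over genes: gene-wise mean centering only (the
#' normalized cycle units are already comparable across genes), missing
#' values imputed by the gene mean (flagged in the result), deterministic
#' loading signs (the largest-magnitude loading of each component is
#' positive). Correlation-mode PCA (per-gene unit scaling) is available
#' behind `scale.`.
#'
#' @param x an [expr_data()] object.
#' @param scale. scale genes to unit variance before decomposition.
#' @return Object of class `pca_result`: list with `scores` (cells x
#'   components), `loadings` (genes x components), `variance_fraction`,
#'   `center`, `n_imputed`.
#' @export
run_pca <- function(x, scale. = FALSE) {
  stopifnot(inherits(x, "expr_data"))
  vals <- x$values
  if (nrow(vals) < 2 || ncol(vals) < 2) {
    stop("PCA needs at least 2 genes and 2 cells", call. = FALSE)
  }
  gene_means <- rowMeans(vals, na.rm = TRUE)
  n_imputed <- sum(is.na(vals))
  if (n_imputed > 0) {
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- gene_means[idx[, 1]]
  }
  sds <- apply(vals, 1, stats::sd)
  if (sum(sds > 0) < 2) {
    stop("PCA needs at least 2 non-degenerate genes", call. = FALSE)
  }
  keep <- if (scale.) sds > 0 else rep(TRUE, nrow(vals))
  vals <- vals[keep, , drop = FALSE]
  fit <- stats::prcomp(t(vals), center = TRUE, scale. = scale.)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, "*")
  loadings <- sweep(fit$rotation, 2, flip, "*")
  ev <- fit$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = ev / sum(ev),
                 center = fit$center, scaled = scale.,
                 n_imputed = n_imputed),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " cells x ", ncol(x$scores),
      " components; first three retain ",
      round(100 * sum(x$variance_fraction[1:min(3, length(x$variance_fraction))]), 1),
      "% of variance\n", sep = "")
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::tibble(
    cell = rep(rownames(x$scores), times = ncol(x$scores)),
    component = rep(seq_len(ncol(x$scores)), each = nrow(x$scores)),
    score = as.vector(x$scores)
  )
}

#' @rdname tidy.ct_data
#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance_fraction),
                 variance_fraction = unname(x$variance_fraction),
                 cumulative = cumsum(unname(x$variance_fraction)))
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson double-centering embedding of a dissimilarity matrix. Negative
#' eigenvalues are truncated (recorded in the diagnostic); if fewer than `k`
#' positive eigenvalues exist, the dimension is reduced with a warning.
#' Coordinates are centered at the origin.
#'
#' @param d symmetric dissimilarity matrix (zero diagonal) or `dist`.
#' @param k target dimension (default 2).
#' @return Object of class `mds_result`: list with `coordinates` (items x
#'   k), `eigenvalues`, `k`, and `gof` (fraction of absolute eigenvalue mass
#'   captured).
#' @export
run_mds <- function(d, k = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), k >= 1)
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, nrow(d) - 1), eig = TRUE)
  n_pos <- sum(fit$eig > 1e-9)
  if (n_pos < k) {
    warning("only ", n_pos, " positive eigenvalue(s); reducing k from ", k,
            call. = FALSE)
    k <- max(1, n_pos)
  }
  coords <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  coords <- sweep(coords, 2, colMeans(coords))
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = fit$eig, k = ncol(coords),
                 gof = sum(pmax(fit$eig[seq_len(ncol(coords))], 0)) /
                   sum(abs(fit$eig))),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("<mds_result> ", nrow(x$coordinates), " items embedded in ", x$k,
      " dimensions (gof ", round(x$gof, 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy mds_result
#' @export
tidy.mds_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(item = rownames(x$coordinates)),
                   tibble::as_tibble(x$coordinates))
}

#' Gene transcription modules by hierarchical clustering
#'
#' Agglomerative clustering of genes with dissimilarity `1 - r` (Pearson
#' across cells) and average linkage, cut at `k` modules. Genes are sorted
#' lexicographically before clustering so module membership does not depend
#' on input row order; constant genes are excluded with a warning.
#'
#' @param x an [expr_data()] object.
#' @param k number of modules (at least 2).
#' @param min_obs minimum pairwise-complete observations per gene pair.
#' @return Object of class `gene_modules`: list with `modules` (tibble
#'   `gene`, `module`), `tree` (hclust), `k`.
#' @export
gene_modules <- function(x, k, min_obs = 10) {
  stopifnot(inherits(x, "expr_data"), k >= 2)
  xs <- x
  xs$values <- x$values[order(rownames(x$values)), , drop = FALSE]
  sds <- apply(xs$values, 1, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const)) {
    warning("excluding ", sum(const), " constant gene(s): ",
            paste(rownames(xs$values)[const], collapse = ", "), call. = FALSE)
    xs$values <- xs$values[!const, , drop = FALSE]
  }
  r <- suppressWarnings(pearson_matrix(xs, axis = "genes", min_obs = min_obs)$r)
  d <- 1 - r
  if (anyNA(d)) d[is.na(d)] <- 2 # undefined pairs at maximal dissimilarity
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  modules <- stats::cutree(tree, k = min(k, nrow(d)))
  structure(list(modules = tibble::tibble(gene = names(modules),
                                          module = unname(modules)),
                 tree = tree, k = min(k, nrow(d))),
            class = "gene_modules")
}

#' @export
print.gene_modules <- function(x, ...) {
  cat("<gene_modules> ", nrow(x$modules), " genes in ", x$k, " modules\n", sep = "")
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy gene_modules
#' @export
tidy.gene_modules <- function(x, ...) x$modules

#' Wilcoxon rank-sum test for spatial positioning
#'
#' Two-sided rank-sum test comparing the positions (e.g. ventrodorsal grid
#' indices) of two groups of cells. Exact enumeration is used when the
#' combined sample is at most 20 with no ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b numeric position vectors for the two groups (non-empty).
#' @return Tibble with columns `statistic` (Mann-Whitney U of group a),
#'   `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(a, b))) == 1) {
    warning("all positions identical across both groups", call. = FALSE)
    return(tibble::tibble(statistic = length(a) * length(b) / 2, p_value = 1,
                          method = "degenerate"))
  }
  exact <- (length(a) + length(b) <= 20) && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = if (exact) "exact" else "normal approximation")
}
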
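#' Modularity matrix of an undirected graph
#'
#' `B[i, j] = A[i, j] - k_i * k_j / (2m)`: the observed adjacency minus the
#' expected number of edges between i and j under the degree-preserving
#' random null. Rows of the full matrix sum to zero. The graph is treated as
#' unweighted (edges have already been thresholded).
#'
#' @param g a `cor_graph` (undirected, no self-loops) with at least one edge.
#' @return Object of class `modularity_matrix`: list with `B`, `degrees`,
#'   `m` (edge count), `nodes`.
#' @export
modularity_matrix <- function(g) {
  stopifnot(inherits(g, "cor_graph"))
  nodes <- g$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(g$edges)) {
    i <- match(g$edges$from, nodes)
    j <- match(g$edges$to, nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  m <- sum(A) / 2
  if (m < 1) stop("modularity undefined: graph has no edges", call. = FALSE)
  k <- rowSums(A)
  B <- A - outer(k, k) / (2 * m)
  structure(list(B = B, degrees = k, m = m, nodes = nodes),
            class = "modularity_matrix")
}

# generalized modularity matrix for a subgraph: row-sum corrected
# B^(g)_ij = B_ij - delta_ij * sum_{k in g} B_ik
restrict_modularity <- function(B, members) {
  Bg <- B[members, members, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  Bg
}

delta_q <- function(Bg, s, m) as.numeric(s %*% Bg %*% s) / (4 * m)

#' Leading-eigenvector bisection of a node set
#'
#' Computes the leading eigenpair of the (generalized, row-sum-corrected)
#' modularity matrix restricted to `members` and splits the nodes by
#' eigenvector sign. Determinism conventions: the eigenvector sign is fixed
#' so its largest-magnitude component is positive; components smaller than
#' `1e-12` in magnitude are assigned sequentially to whichever side gives
#' the larger modularity gain, ties to the positive side. The set is
#' declared indivisible when the leading eigenvalue is not positive (up to
#' `eps`) or the gain is not positive.
#'
#' After the sign split, a deterministic single-vertex refinement sweep (the
#' fine-tuning stage of the spectral method) repeatedly moves the vertex
#' whose side-switch most increases the modularity gain until no move helps
#' (ties broken by vertex order); disable with `refine = FALSE` for the
#' plain eigenvector-sign split.
#'
#' @param bm a [modularity_matrix()].
#' @param members node labels (or indices) of the subset; default all nodes.
#' @param eps numerical tolerance on the leading eigenvalue.
#' @param refine apply the vertex-moving fine-tuning sweep (default `TRUE`).
#' @return List with `divisible` (logical), `sign` (named +/-1 vector),
#'   `delta_q` (modularity gain of the bisection), `leading_eigenvalue`.
#' @export
leading_eigenvector_split <- function(bm, members = NULL, eps = 1e-8,
                                      refine = TRUE) {
  stopifnot(inherits(bm, "modularity_matrix"))
  members <- members %||% bm$nodes
  if (is.numeric(members)) members <- bm$nodes[members]
  if (length(members) < 2) {
    return(list(divisible = FALSE, sign = stats::setNames(rep(1, length(members)),
                                                          members),
                delta_q = 0, leading_eigenvalue = NA_real_))
  }
  Bg <- restrict_modularity(bm$B, members)
  es <- eigen(Bg, symmetric = TRUE)
  lambda <- es$values[1]
  nmem <- length(members)

  sign_start <- function(v) {
    if (v[which.max(abs(v))] < 0) v <- -v
    s <- ifelse(v > 1e-12, 1, ifelse(v < -1e-12, -1, 0))
    for (i in which(s == 0)) {
      s_pos <- s; s_pos[i] <- 1
      s_neg <- s; s_neg[i] <- -1
      # remaining undecided entries contribute symmetrically; compare as-is
      s[i] <- if (delta_q(Bg, s_neg, bm$m) > delta_q(Bg, s_pos, bm$m)) -1 else 1
    }
    s
  }
  # Kernighan-Lin rounds on s'Bg s: within a round every vertex is flipped
  # at most once, always taking the best available flip (even if negative;
  # flipping i changes the form by 4 * (B_ii - s_i * (Bg s)_i)), and the
  # best intermediate state of the round is kept if it improves
  kl_rounds <- function(s) {
    quad <- as.numeric(s %*% Bg %*% s)
    for (round in seq_len(nmem)) {
      s_work <- s
      quad_work <- quad
      moved <- rep(FALSE, nmem)
      best_quad <- quad
      best_state <- s
      for (step in seq_len(nmem)) {
        bs <- as.vector(Bg %*% s_work)
        gains <- 4 * (diag(Bg) - s_work * bs)
        gains[moved] <- -Inf
        i <- which.max(gains)
        s_work[i] <- -s_work[i]
        moved[i] <- TRUE
        quad_work <- quad_work + gains[i]
        if (quad_work > best_quad + 1e-12) {
          best_quad <- quad_work
          best_state <- s_work
        }
      }
      if (best_quad > quad + 1e-12) {
        s <- best_state
        quad <- best_quad
      } else {
        break
      }
    }
    s
  }

  s <- sign_start(es$vectors[, 1])
  if (refine && nmem > 2) {
    # the modularity-contributing eigenvectors (positive eigenvalues) each
    # propose a candidate bisection; keep the best after fine-tuning
    n_starts <- min(sum(es$values > eps), 8L)
    best_dq <- -Inf
    for (j in seq_len(max(n_starts, 1L))) {
      cand <- kl_rounds(sign_start(es$vectors[, j]))
      cand_dq <- delta_q(Bg, cand, bm$m)
      if (cand_dq > best_dq + 1e-12) {
        best_dq <- cand_dq
        s <- cand
      }
    }
  }
  names(s) <- members
  dq <- delta_q(Bg, s, bm$m)
  divisible <- lambda > eps && dq > 0 && length(unique(s)) == 2
  list(divisible = divisible, sign = s, delta_q = dq,
       leading_eigenvalue = lambda)
}

# deterministic global fine-tuning: repeatedly apply the single best
# strictly-improving move of one node into another (or a new) community;
# ties broken by node order then target community id
refine_assignment <- function(bm, labels) {
  B <- bm$B
  n <- length(labels)
  for (iter in seq_len(n * n)) {
    groups <- sort(unique(labels))
    member <- vapply(groups, function(gid) as.numeric(labels == gid),
                     numeric(n))
    S <- B %*% member # S[i, g] = sum_{j in g} B_ij
    own <- S[cbind(seq_len(n), match(labels, groups))] - diag(B)
    gain <- S - own # gain of moving i into g (up to the 2/2m factor)
    gain[cbind(seq_len(n), match(labels, groups))] <- 0
    new_gain <- -own # moving i into a fresh singleton community
    # merging two whole communities: gain = sum of B over the cross pairs
    cross <- t(member) %*% B %*% member
    diag(cross) <- -Inf
    merge_gain <- if (length(groups) > 1) max(cross) else -Inf
    best <- max(max(gain), max(new_gain), merge_gain)
    if (best <= 1e-12) break
    if (merge_gain >= max(max(gain), max(new_gain))) {
      mi <- which(cross == merge_gain, arr.ind = TRUE)[1, ]
      labels[labels == groups[max(mi)]] <- groups[min(mi)]
    } else if (max(new_gain) > max(gain)) {
      i <- which.max(new_gain)
      labels[i] <- max(groups) + 1L
    } else {
      best_move <- which(gain == max(gain), arr.ind = TRUE)
      i <- best_move[1, 1]
      labels[i] <- groups[best_move[1, 2]]
    }
  }
  labels
}

#' Leading-eigenvector community detection
#'
#' Recursive spectral bisection: the graph is split by the sign pattern of
#' the leading eigenvector of the modularity matrix, each part is split
#' again using the generalized (row-sum-corrected) modularity matrix, and
#' recursion stops when no split increases modularity. A deterministic
#' fine-tuning pass then moves single nodes between the final communities
#' while modularity strictly increases (disable with `refine = FALSE` for
#' the plain bisection). Deterministic given the eigen-solver conventions
#' of [leading_eigenvector_split()]. Isolated nodes are allowed; they are
#' typically handed to [pool_residual()] afterwards.
#'
#' @param g a `cor_graph`.
#' @param refine apply single-vertex fine-tuning within each bisection and
#'   across the final communities (default `TRUE`).
#' @return Object of class `group_partition`: list with `assignment`
#'   (tibble `node`, `group` with groups numbered by decreasing size),
#'   `q` (modularity), `residual_group` (`NA` until [pool_residual()]),
#'   `provenance`.
#' @export
detect_communities <- function(g, refine = TRUE) {
  bm <- modularity_matrix(g)
  final <- list()
  queue <- list(bm$nodes)
  while (length(queue)) {
    members <- queue[[1]]
    queue <- queue[-1]
    sp <- leading_eigenvector_split(bm, members, refine = refine)
    if (!sp$divisible) {
      final <- c(final, list(members))
    } else {
      queue <- c(queue, list(members[sp$sign > 0]), list(members[sp$sign < 0]))
    }
  }
  if (refine && length(final) > 1) {
    labels <- integer(length(bm$nodes))
    names(labels) <- bm$nodes
    for (k in seq_along(final)) labels[final[[k]]] <- k
    labels <- refine_assignment(bm, labels)
    final <- lapply(sort(unique(labels)),
                    function(gid) bm$nodes[labels == gid])
  }
  # order groups by decreasing size, ties by smallest member label
  ord <- order(-vapply(final, length, integer(1)),
               vapply(final, function(x) min(x), character(1)))
  final <- final[ord]
  assignment <- tibble::tibble(
    node = unlist(final, use.names = FALSE),
    group = rep(seq_along(final), times = vapply(final, length, integer(1)))
  )
  assignment <- assignment[match(bm$nodes, assignment$node), ]
  q <- partition_modularity(bm, assignment)
  structure(list(assignment = assignment, q = q, residual_group = NA_integer_,
                 provenance = list(method = "leading_eigenvector",
                                   threshold = g$threshold, strict = g$strict)),
            class = "group_partition")
}

partition_modularity <- function(bm, assignment) {
  lab <- assignment$group[match(bm$nodes, assignment$node)]
  same <- outer(lab, lab, "==")
  sum(bm$B[same]) / (2 * bm$m)
}

#' Modularity of a partition
#'
#' @param g a `cor_graph`.
#' @param p a `group_partition` (or tibble with `node`, `group`).
#' @return Modularity Q.
#' @export
modularity_q <- function(g, p) {
  if (inherits(p, "group_partition")) p <- p$assignment
  partition_modularity(modularity_matrix(g), p)
}

#' Pool weakly connected cells into a residual group
#'
#' Nodes with graph degree below `min_degree`, and all members of
#' communities smaller than `min_size`, are reassigned to a residual group
#' (the analysis' "Group 5": cells with minimal or no supra-threshold
#' correlations to any other cell). Remaining groups are renumbered by
#' decreasing size; the residual group receives the last number.
#'
#' @param g the `cor_graph` the partition was detected on.
#' @param p a `group_partition`.
#' @param min_degree nodes with degree strictly below this are pooled
#'   (default 1: isolated nodes).
#' @param min_size minimum community size kept; defaults to 5% of the nodes.
#' @return An updated `group_partition` with `residual_group` set.
#' @export
pool_residual <- function(g, p, min_degree = 1,
                          min_size = ceiling(0.05 * length(g$nodes))) {
  stopifnot(inherits(g, "cor_graph"), inherits(p, "group_partition"))
  if (min_size < 1) stop("`min_size` must be at least 1", call. = FALSE)
  a <- p$assignment
  stopifnot(setequal(a$node, g$nodes))
  deg <- graph_degrees(g)
  a$degree <- deg$degree[match(a$node, deg$node)]
  sizes <- table(a$group)
  small <- as.integer(names(sizes)[sizes < min_size])
  residual <- a$degree < min_degree | a$group %in% small
  kept <- a[!residual, ]
  ord <- kept |>
    dplyr::count(.data$group, name = "size") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$group)
  relabel <- stats::setNames(seq_len(nrow(ord)), ord$group)
  new_group <- ifelse(residual, nrow(ord) + 1L,
                      relabel[as.character(a$group)])
  out <- p
  out$assignment <- tibble::tibble(node = a$node,
                                   group = as.integer(new_group))
  out$residual_group <- if (any(residual)) nrow(ord) + 1L else NA_integer_
  bm <- modularity_matrix(g)
  out$q <- partition_modularity(bm, out$assignment)
  out$provenance <- c(p$provenance,
                      list(min_degree = min_degree, min_size = min_size))
  out
}

#' @export
print.group_partition <- function(x, ...) {
  sizes <- table(x$assignment$group)
  cat("<group_partition> ", length(sizes), " groups over ",
      nrow(x$assignment), " nodes, Q = ", format(x$q, digits = 4), "\n", sep = "")
  for (gid in names(sizes)) {
    tag <- if (!is.na(x$residual_group) && as.integer(gid) == x$residual_group)
      " (residual)" else ""
    cat("  group ", gid, ": ", sizes[[gid]], " nodes", tag, "\n", sep = "")
  }
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy group_partition
#' @export
tidy.group_partition <- function(x, ...) {
  out <- x$assignment
  out$residual <- !is.na(x$residual_group) & out$group == x$residual_group
  out
}

#' @rdname tidy.ct_data
#' @method glance group_partition
#' @export
glance.group_partition <- function(x, ...) {
  sizes <- table(x$assignment$group)
  tibble::tibble(
    n_nodes = nrow(x$assignment),
    n_groups = length(sizes),
    n_residual = if (is.na(x$residual_group)) 0L else
      as.integer(sizes[as.character(x$residual_group)]),
    q = x$q
  )
}
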
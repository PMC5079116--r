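#' Ligand-receptor pair table
#'
#' @param ligand,receptor gene label vectors (pairwise distinct).
#' @return Tibble with columns `ligand`, `receptor`, `pair` (display name
#'   `"ligand-receptor"`).
#' @export
lr_pairs <- function(ligand, receptor) {
  stopifnot(length(ligand) == length(receptor), all(ligand != receptor))
  tibble::tibble(ligand = ligand, receptor = receptor,
                 pair = paste0(ligand, "-", receptor))
}

#' Per-cell signaling-regime classification
#'
#' Classifies each cell's role for each ligand-receptor pair from the sign
#' quadrant of its normalized (-ddCt) ligand and receptor expression:
#' paracrine `source` (ligand > 0, receptor <= 0), paracrine `target`
#' (ligand <= 0, receptor > 0), `autocrine` (both > 0), and `none` (both
#' <= 0; such cells are not considered to play a dominant signaling role).
#' Cells missing either measurement are `none` with `missing = TRUE`.
#'
#' @param x an [expr_data()] at stage `"minus_ddct"`.
#' @param pairs an [lr_pairs()] tibble (or data frame with `ligand`,
#'   `receptor` columns).
#' @return Tibble with columns `cell`, `pair`, `ligand_value`,
#'   `receptor_value`, `regime`, `missing`.
#' @export
classify_regime <- function(x, pairs) {
  stage_check(x, "minus_ddct", "classify_regime")
  pairs <- tibble::as_tibble(pairs)
  if (!"pair" %in% names(pairs)) {
    pairs$pair <- paste0(pairs$ligand, "-", pairs$receptor)
  }
  missing_genes <- setdiff(unique(c(pairs$ligand, pairs$receptor)),
                           rownames(x$values))
  if (length(missing_genes)) {
    stop("genes absent from expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    l <- x$values[pairs$ligand[i], ]
    r <- x$values[pairs$receptor[i], ]
    miss <- is.na(l) | is.na(r)
    regime <- dplyr::case_when(
      miss ~ "none",
      l > 0 & r <= 0 ~ "source",
      l <= 0 & r > 0 ~ "target",
      l > 0 & r > 0 ~ "autocrine",
      TRUE ~ "none"
    )
    tibble::tibble(cell = colnames(x$values), pair = pairs$pair[i],
                   ligand_value = unname(l), receptor_value = unname(r),
                   regime = regime, missing = unname(miss))
  })
}

#' Group-by-regime enrichment table
#'
#' For every (pair, group, regime in {source, target, autocrine}) the 2x2
#' table [group & regime, group & !regime; !group & regime, !group & !regime]
#' is tested for over-representation with the one-sided hypergeometric tail
#' (Fisher's exact test, greater). Cells with a missing measurement for the
#' pair are left out of that pair's table; the fraction is the share of the
#' group's complete-data cells in the regime. No multiplicity adjustment by
#' default, matching the presentation this analysis follows; set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted significance flags.
#'
#' @param regimes output of [classify_regime()].
#' @param partition a `group_partition` (or tibble `node`/`cell` + `group`).
#' @param alpha significance level for the `significant` flag.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble of class `enrichment_table` with columns `pair`, `group`,
#'   `regime`, `k` (group cells in regime), `n_group`, `n_regime`, `n_total`,
#'   `fraction`, `p_value`, `significant`.
#' @export
regime_enrichment <- function(regimes, partition, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(partition, "group_partition")) partition <- partition$assignment
  partition <- tibble::as_tibble(partition)
  id_col <- intersect(c("node", "cell", "item"), names(partition))[1]
  groups_of <- stats::setNames(partition$group, partition[[id_col]])
  unassigned <- setdiff(unique(regimes$cell), names(groups_of))
  if (length(unassigned)) {
    stop("cells without a group assignment: ",
         paste(utils::head(unassigned, 5), collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (pr in unique(regimes$pair)) {
    sub <- regimes[regimes$pair == pr & !regimes$missing, ]
    n_total <- nrow(sub)
    grp <- groups_of[sub$cell]
    for (g in sort(unique(groups_of))) {
      in_group <- grp == g
      n_group <- sum(in_group)
      if (n_group == 0) {
        warning("group ", g, " has no complete-data cells for pair ", pr,
                "; row omitted", call. = FALSE)
        next
      }
      for (reg in c("source", "target", "autocrine")) {
        in_reg <- sub$regime == reg
        k <- sum(in_group & in_reg)
        n_regime <- sum(in_reg)
        p <- stats::phyper(k - 1, n_regime, n_total - n_regime, n_group,
                           lower.tail = FALSE)
        rows[[length(rows) + 1]] <- tibble::tibble(
          pair = pr, group = g, regime = reg, k = k, n_group = n_group,
          n_regime = n_regime, n_total = n_total,
          fraction = k / n_group, p_value = p
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  p_eff <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_eff < alpha
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Permutation screen for dominant ligand-receptor interactions
#'
#' For each pair, the observed Pearson correlation between ligand and
#' receptor expression across all analyzed cells is compared with a null
#' distribution obtained by independently shuffling the receptor vector
#' across cells (`n_perm` times; the minimal permutation that destroys the
#' pairwise association while preserving both marginals). A pair is retained
#' as a dominant interaction iff its observed correlation exceeds the
#' requested quantile of its null.
#'
#' @param x an [expr_data()] object.
#' @param pairs an [lr_pairs()] tibble.
#' @param n_perm permutations per pair (at least 100).
#' @param quantile null quantile that must be exceeded (default 0.95).
#' @param seed integer seed.
#' @param min_obs minimum pairwise-complete observations.
#' @return Tibble with columns `pair`, `ligand`, `receptor`, `observed_r`,
#'   `null_quantile`, `retained`, `n_obs`.
#' @export
dominant_interaction_screen <- function(x, pairs, n_perm = 1000,
                                        quantile = 0.95, seed = 1L,
                                        min_obs = 10) {
  stopifnot(inherits(x, "expr_data"))
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  pairs <- tibble::as_tibble(pairs)
  if (!"pair" %in% names(pairs)) {
    pairs$pair <- paste0(pairs$ligand, "-", pairs$receptor)
  }
  withr::local_seed(seed)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    lig <- x$values[pairs$ligand[i], ]
    rec <- x$values[pairs$receptor[i], ]
    ok <- !is.na(lig) & !is.na(rec)
    if (sum(ok) < min_obs || stats::sd(lig[ok]) == 0 || stats::sd(rec[ok]) == 0) {
      warning("pair ", pairs$pair[i],
              " skipped (constant or insufficient data)", call. = FALSE)
      return(tibble::tibble(pair = pairs$pair[i], ligand = pairs$ligand[i],
                            receptor = pairs$receptor[i],
                            observed_r = NA_real_, null_quantile = NA_real_,
                            retained = FALSE, n_obs = sum(ok)))
    }
    lig <- lig[ok]; rec <- rec[ok]
    obs <- stats::cor(lig, rec)
    null_r <- vapply(seq_len(n_perm), function(b) {
      stats::cor(lig, sample(rec))
    }, numeric(1))
    qn <- stats::quantile(null_r, quantile, names = FALSE)
    tibble::tibble(pair = pairs$pair[i], ligand = pairs$ligand[i],
                   receptor = pairs$receptor[i], observed_r = obs,
                   null_quantile = qn, retained = obs > qn, n_obs = sum(ok))
  })
}

#' Directed group-interaction network
#'
#' For every retained ligand-receptor pair, adds a directed edge from each
#' group significantly enriched as paracrine source to each group
#' significantly enriched as paracrine target, and a self-loop for each
#' group significantly enriched in the autocrine regime. Edge annotations
#' carry the mediating pair and the enriched groups' regime fractions (the
#' quantity edge thickness encodes); `weight` is the source-side fraction
#' (the autocrine fraction for self-loops). Edges are ordered
#' deterministically by pair label then group ids.
#'
#' @param enrichment an `enrichment_table` from [regime_enrichment()]
#'   covering all retained pairs.
#' @param screen output of [dominant_interaction_screen()]; only pairs with
#'   `retained = TRUE` generate edges. `NULL` uses every pair in
#'   `enrichment`.
#' @param alpha significance level (defaults to the table's).
#' @return Object of class `interaction_network`: list with `nodes` (tibble
#'   `group`, `size`), `edges` (tibble `from`, `to`, `pair`,
#'   `source_fraction`, `target_fraction`, `weight`, `type`), `alpha`.
#' @export
build_interaction_network <- function(enrichment, screen = NULL, alpha = NULL) {
  stopifnot(inherits(enrichment, "enrichment_table"))
  alpha <- alpha %||% attr(enrichment, "alpha") %||% 0.05
  pairs_used <- if (is.null(screen)) unique(enrichment$pair) else
    screen$pair[screen$retained]
  missing_pairs <- setdiff(pairs_used, unique(enrichment$pair))
  if (length(missing_pairs)) {
    stop("enrichment not computed for retained pair(s): ",
         paste(missing_pairs, collapse = ", "), call. = FALSE)
  }
  sig <- enrichment[enrichment$p_value < alpha & enrichment$pair %in% pairs_used, ]
  edges <- list()
  for (pr in sort(unique(sig$pair))) {
    sp <- sig[sig$pair == pr, ]
    sources <- sp[sp$regime == "source", ]
    targets <- sp[sp$regime == "target", ]
    autos <- sp[sp$regime == "autocrine", ]
    for (i in seq_len(nrow(sources))) {
      for (j in seq_len(nrow(targets))) {
        edges[[length(edges) + 1]] <- tibble::tibble(
          from = sources$group[i], to = targets$group[j], pair = pr,
          source_fraction = sources$fraction[i],
          target_fraction = targets$fraction[j],
          weight = sources$fraction[i], type = "paracrine"
        )
      }
    }
    for (i in seq_len(nrow(autos))) {
      edges[[length(edges) + 1]] <- tibble::tibble(
        from = autos$group[i], to = autos$group[i], pair = pr,
        source_fraction = autos$fraction[i],
        target_fraction = autos$fraction[i],
        weight = autos$fraction[i], type = "autocrine"
      )
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(from = integer(), to = integer(), pair = character(),
                   source_fraction = double(), target_fraction = double(),
                   weight = double(), type = character())
  edges <- edges[order(edges$pair, edges$from, edges$to), ]
  nodes <- enrichment |>
    dplyr::distinct(.data$pair, .data$group, .data$n_group) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(size = max(.data$n_group), .groups = "drop")
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", nrow(x$nodes), " groups, ", nrow(x$edges),
      " directed edges (alpha = ", x$alpha, ")\n", sep = "")
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      e <- x$edges[i, ]
      arrow <- if (e$type == "autocrine") " (autocrine)" else
        paste0(" -> group ", e$to)
      cat("  group ", e$from, arrow, " via ", e$pair, "\n", sep = "")
    }
  }
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy interaction_network
#' @export
tidy.interaction_network <- function(x, ...) x$edges
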
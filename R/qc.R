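#' Quality-control rule set
#'
#' Thresholds for excluding cells and assays before normalization. A cell is
#' excluded when every assay failed (`loading`), when any housekeeping gene
#' is a non-detect or amplifies later than `hk_ct_max` (`failed_reaction`),
#' or when more than `max_cell_nondetect` of its assays are non-detects
#' (`signal`). A gene is excluded when it is a non-detect in more than
#' `max_gene_nondetect` of the retained cells (`signal`) or when listed in
#' `exclude_genes` (`contamination`).
#'
#' @param max_cell_nondetect maximum tolerated fraction of non-detect assays
#'   per cell.
#' @param require_housekeeping exclude cells whose housekeeping genes do not
#'   all amplify.
#' @param hk_ct_max housekeeping Ct ceiling (cycles).
#' @param max_gene_nondetect maximum tolerated fraction of non-detect cells
#'   per gene.
#' @param exclude_genes assays removed outright (e.g. contaminated probes).
#' @return A `qc_rules` list.
#' @export
qc_rules <- function(max_cell_nondetect = 0.7,
                     require_housekeeping = TRUE,
                     hk_ct_max = Inf,
                     max_gene_nondetect = 0.9,
                     exclude_genes = character()) {
  structure(list(max_cell_nondetect = max_cell_nondetect,
                 require_housekeeping = require_housekeeping,
                 hk_ct_max = hk_ct_max,
                 max_gene_nondetect = max_gene_nondetect,
                 exclude_genes = exclude_genes),
            class = "qc_rules")
}

#' Quality-control filtering of a Ct matrix
#'
#' Applies a [qc_rules()] set and returns the filtered container together
#' with a report whose retained/excluded counts reconcile exactly with the
#' input.
#'
#' @param ct a [ct_data()] object.
#' @param rules a [qc_rules()] set.
#' @return List of class `qc_result` with elements `ct` (filtered) and
#'   `report` (a `qc_report`: tibbles `excluded_cells`, `excluded_genes` with
#'   reason codes, and `retained` counts per treatment).
#' @export
qc_filter <- function(ct, rules = qc_rules()) {
  stopifnot(inherits(ct, "ct_data"), inherits(rules, "qc_rules"))
  nd <- ct$nondetect
  n_genes_in <- nrow(ct$values)
  n_cells_in <- ncol(ct$values)

  cell_reason <- character(0)
  cell_id <- character(0)
  all_failed <- colMeans(nd) >= 1
  hk <- ct$housekeeping
  hk_bad <- rep(FALSE, n_cells_in)
  if (rules$require_housekeeping && length(hk)) {
    hk_bad <- colSums(nd[hk, , drop = FALSE]) > 0 |
      apply(ct$values[hk, , drop = FALSE] > rules$hk_ct_max, 2, any)
  }
  frac_bad <- colMeans(nd) > rules$max_cell_nondetect
  for (j in seq_len(n_cells_in)) {
    if (all_failed[j]) {
      cell_id <- c(cell_id, colnames(nd)[j]); cell_reason <- c(cell_reason, "loading")
    } else if (hk_bad[j]) {
      cell_id <- c(cell_id, colnames(nd)[j]); cell_reason <- c(cell_reason, "failed_reaction")
    } else if (frac_bad[j]) {
      cell_id <- c(cell_id, colnames(nd)[j]); cell_reason <- c(cell_reason, "signal")
    }
  }
  keep_cells <- setdiff(colnames(nd), cell_id)
  if (!length(keep_cells)) stop("empty dataset: all cells excluded by QC", call. = FALSE)

  nd_kept <- nd[, keep_cells, drop = FALSE]
  gene_id <- character(0)
  gene_reason <- character(0)
  contam <- intersect(rules$exclude_genes, rownames(nd))
  if (length(contam)) {
    gene_id <- contam
    gene_reason <- rep("contamination", length(contam))
  }
  gene_frac <- rowMeans(nd_kept)
  sig_genes <- setdiff(rownames(nd)[gene_frac > rules$max_gene_nondetect], gene_id)
  gene_id <- c(gene_id, sig_genes)
  gene_reason <- c(gene_reason, rep("signal", length(sig_genes)))
  keep_genes <- setdiff(rownames(nd), gene_id)
  if (!length(keep_genes)) stop("empty dataset: all genes excluded by QC", call. = FALSE)

  out <- ct_data(ct$values[keep_genes, keep_cells, drop = FALSE],
                 ct$nondetect[keep_genes, keep_cells, drop = FALSE],
                 cells = ct$cells[ct$cells$cell %in% keep_cells, ],
                 housekeeping = intersect(ct$housekeeping, keep_genes))
  retained <- out$cells |>
    dplyr::count(.data$treatment, name = "n_cells")
  report <- structure(
    list(excluded_cells = tibble::tibble(cell = cell_id, reason = cell_reason),
         excluded_genes = tibble::tibble(gene = gene_id, reason = gene_reason),
         retained = retained,
         input = c(genes = n_genes_in, cells = n_cells_in)),
    class = "qc_report"
  )
  stopifnot(length(keep_cells) + nrow(report$excluded_cells) == n_cells_in,
            length(keep_genes) + nrow(report$excluded_genes) == n_genes_in)
  structure(list(ct = out, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> input ", x$input[["genes"]], " genes x ", x$input[["cells"]],
      " cells\n", sep = "")
  cat("  excluded cells: ", nrow(x$excluded_cells),
      " | excluded genes: ", nrow(x$excluded_genes), "\n", sep = "")
  print(x$retained)
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$excluded_cells, what = "cell", id = .data$cell, .keep = "none",
                  reason = x$excluded_cells$reason),
    dplyr::mutate(x$excluded_genes, what = "gene", id = .data$gene, .keep = "none",
                  reason = x$excluded_genes$reason)
  ) |> dplyr::select("what", "id", "reason")
}
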
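#' Rank candidate housekeeping genes by expression stability
#'
#' For each candidate gene j the stability measure M(j) is the mean, over the
#' other candidates k, of the standard deviation across cells of the pairwise
#' log-ratio proxy Ct(j, c) - Ct(k, c). A gene whose difference to every
#' other candidate is constant across cells is maximally stable (M = 0);
#' larger M means less stable. Non-detect entries are ignored pairwise.
#'
#' @param ct a [ct_data()] object.
#' @param candidates character vector of at least three candidate genes, each
#'   detected in at least `min_detected` cells.
#' @param min_detected minimum detected cells per candidate.
#' @return Tibble with columns `gene`, `m`, `rank` (ties broken by gene
#'   label) sorted most-stable first.
#' @export
rank_housekeeping_stability <- function(ct, candidates, min_detected = 10) {
  stopifnot(inherits(ct, "ct_data"))
  missing <- setdiff(candidates, rownames(ct$values))
  if (length(missing)) {
    stop("unknown candidate genes: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(candidates) < 3) {
    stop("need at least 3 candidate genes for a stability consensus", call. = FALSE)
  }
  vals <- ct$values[candidates, , drop = FALSE]
  vals[ct$nondetect[candidates, , drop = FALSE]] <- NA
  n_det <- rowSums(!is.na(vals))
  if (any(n_det < min_detected)) {
    stop("candidates detected in fewer than ", min_detected, " cells: ",
         paste(candidates[n_det < min_detected], collapse = ", "), call. = FALSE)
  }
  m <- vapply(seq_along(candidates), function(j) {
    sds <- vapply(seq_along(candidates)[-j], function(k) {
      stats::sd(vals[j, ] - vals[k, ], na.rm = TRUE)
    }, numeric(1))
    mean(sds)
  }, numeric(1))
  out <- tibble::tibble(gene = candidates, m = m)
  out <- out[order(out$m, out$gene), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Housekeeping-referenced expression (-dCt)
#'
#' First normalization step: expression of gene g in cell c relative to the
#' average of the housekeeping genes in that cell,
#' `-dCt(g, c) = mean_h Ct(h, c) - Ct(g, c)`. Higher values mean more
#' transcript. Non-detects either become missing (`policy = "missing"`, the
#' default, so correlations use pairwise-complete data) or keep their
#' detection-limit Ct (`policy = "floor"`).
#'
#' @param ct a [ct_data()] object.
#' @param housekeeping housekeeping gene set (default: the container's).
#' @param policy non-detect policy, `"missing"` or `"floor"`.
#' @param keep_housekeeping retain housekeeping rows in the output (default
#'   drops them; they are identically distributed around 0 by construction).
#' @return An [expr_data()] at stage `"minus_dct"`.
#' @export
to_minus_dct <- function(ct, housekeeping = NULL,
                         policy = c("missing", "floor"),
                         keep_housekeeping = FALSE) {
  stopifnot(inherits(ct, "ct_data"))
  policy <- match.arg(policy)
  hk <- housekeeping %||% ct$housekeeping
  if (!length(hk)) stop("no housekeeping genes given", call. = FALSE)
  missing_hk <- setdiff(hk, rownames(ct$values))
  if (length(missing_hk)) {
    stop("housekeeping genes absent: ", paste(missing_hk, collapse = ", "),
         call. = FALSE)
  }
  hk_vals <- ct$values[hk, , drop = FALSE]
  hk_vals[ct$nondetect[hk, , drop = FALSE]] <- NA
  hk_mean <- colMeans(hk_vals, na.rm = TRUE)
  bad_cells <- !is.finite(hk_mean)
  if (any(bad_cells)) {
    warning("dropping ", sum(bad_cells),
            " cell(s) with no valid housekeeping measurement: ",
            paste(utils::head(colnames(ct$values)[bad_cells], 5), collapse = ", "),
            call. = FALSE)
  }
  keep <- !bad_cells
  vals <- ct$values[, keep, drop = FALSE]
  nd <- ct$nondetect[, keep, drop = FALSE]
  out <- sweep(-vals, 2, hk_mean[keep], FUN = "+") # hk_mean - Ct
  if (policy == "missing") out[nd] <- NA
  if (!keep_housekeeping) out <- out[setdiff(rownames(out), hk), , drop = FALSE]
  expr_data(out, "minus_dct",
            cells = ct$cells[ct$cells$cell %in% colnames(out), ],
            provenance = list(housekeeping = hk, nondetect_policy = policy))
}

#' Per-gene median centering (-ddCt)
#'
#' Second normalization step: the per-gene median across all retained cells
#' (both treatment groups pooled, unless `by_treatment`) is subtracted, so
#' zero is the per-gene median and values are comparable across treatments.
#'
#' @param x an [expr_data()] at stage `"minus_dct"` (an object already at
#'   `"minus_ddct"` is re-centered, which is a no-op).
#' @param by_treatment center within each treatment group separately
#'   (non-default variant).
#' @return An [expr_data()] at stage `"minus_ddct"`.
#' @export
median_center <- function(x, by_treatment = FALSE) {
  if (!inherits(x, "expr_data") || !x$stage %in% c("minus_dct", "minus_ddct")) {
    stop("median_center requires an `expr_data` at stage 'minus_dct'", call. = FALSE)
  }
  vals <- x$values
  all_missing <- rowSums(!is.na(vals)) == 0
  if (any(all_missing)) {
    warning("excluding ", sum(all_missing), " gene(s) with no observed values: ",
            paste(rownames(vals)[all_missing], collapse = ", "), call. = FALSE)
    vals <- vals[!all_missing, , drop = FALSE]
  }
  if (by_treatment) {
    meds <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
    for (trt in unique(x$cells$treatment)) {
      cols <- x$cells$cell[x$cells$treatment == trt]
      cols <- intersect(colnames(vals), cols)
      meds[, cols] <- apply(vals[, cols, drop = FALSE], 1, stats::median,
                            na.rm = TRUE)
    }
    out <- vals - meds
    centers <- NULL
  } else {
    centers <- apply(vals, 1, stats::median, na.rm = TRUE)
    out <- sweep(vals, 1, centers)
  }
  expr_data(out, "minus_ddct", cells = x$cells,
            provenance = c(x$provenance,
                           list(median_centers = centers,
                                by_treatment = by_treatment)))
}

#' Modified z-values
#'
#' Display normalization: each gene's -ddCt values are divided by that
#' gene's standard deviation across all cells (population convention,
#' divisor n), so every gene has unit SD. Used for heat maps; correlations
#' are unchanged by this per-gene affine rescaling.
#'
#' @param x an [expr_data()] at stage `"minus_ddct"`.
#' @return An [expr_data()] at stage `"modified_z"`.
#' @export
modified_z <- function(x) {
  stage_check(x, "minus_ddct", "modified_z")
  vals <- x$values
  sd_pop <- apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  })
  bad <- !is.finite(sd_pop) | sd_pop == 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " zero-variance or unmeasurable gene(s): ",
            paste(rownames(vals)[bad], collapse = ", "), call. = FALSE)
    vals <- vals[!bad, , drop = FALSE]
    sd_pop <- sd_pop[!bad]
  }
  expr_data(sweep(vals, 1, sd_pop, FUN = "/"), "modified_z", cells = x$cells,
            provenance = c(x$provenance, list(gene_sd = sd_pop)))
}

#' Full two-step normalization
#'
#' Convenience wrapper: [to_minus_dct()] then [median_center()].
#'
#' @inheritParams to_minus_dct
#' @return An [expr_data()] at stage `"minus_ddct"`.
#' @export
normalize_expression <- function(ct, housekeeping = NULL,
                                 policy = c("missing", "floor")) {
  median_center(to_minus_dct(ct, housekeeping = housekeeping, policy = policy))
}

#' Positive/negative expression call
#'
#' A cell is called positive for a gene iff its -ddCt value is strictly
#' greater than 0 (equivalently, strictly above the per-gene median before
#' centering). Values at exactly 0 and missing values are negative.
#'
#' @param x an [expr_data()] at stage `"minus_ddct"`.
#' @param gene gene label.
#' @return Tibble with columns `cell`, `value`, `positive`.
#' @export
positive_call <- function(x, gene) {
  stage_check(x, "minus_ddct", "positive_call")
  if (!gene %in% rownames(x$values)) stop("unknown gene: ", gene, call. = FALSE)
  v <- x$values[gene, ]
  tibble::tibble(cell = colnames(x$values), value = unname(v),
                 positive = unname(!is.na(v) & v > 0))
}

#' Ternary composition over three genes
#'
#' For cells with strictly positive normalized expression of all three
#' genes, returns each value divided by the cell's sum over the three, so
#' the components sum to 1 (the coordinates of a ternary plot). Cells
#' failing the all-positive precondition are excluded.
#'
#' @param x an [expr_data()] at stage `"minus_ddct"`.
#' @param genes exactly three gene labels.
#' @return Tibble with columns `cell` and one proportion column per gene.
#' @export
ternary_proportions <- function(x, genes) {
  stage_check(x, "minus_ddct", "ternary_proportions")
  if (length(genes) != 3) stop("`genes` must name exactly 3 genes", call. = FALSE)
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  sub <- x$values[genes, , drop = FALSE]
  ok <- colSums(is.na(sub)) == 0 & colSums(sub > 0) == 3
  sub <- sub[, ok, drop = FALSE]
  props <- sweep(sub, 2, colSums(sub), FUN = "/")
  out <- tibble::as_tibble(t(props))
  dplyr::bind_cols(tibble::tibble(cell = colnames(sub)), out)
}
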
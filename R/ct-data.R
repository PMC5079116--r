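#' Single-cell qPCR Ct container
#'
#' Bundles a genes-by-cells matrix of raw cycle-threshold (Ct) values with a
#' non-detect mask, per-cell metadata (treatment, optional spatial grid
#' coordinates) and the housekeeping-gene designation. Lower Ct means more
#' transcript. Non-detect entries keep a numeric Ct (the detection-limit
#' cycle) alongside a `TRUE` mask entry, so both "treat as missing" and
#' "floor-impute" policies stay available downstream.
#'
#' @param values numeric matrix, genes in rows, cells in columns; dimnames
#'   required and unique.
#' @param nondetect logical matrix of the same shape (default: all `FALSE`).
#' @param cells tibble of per-cell metadata with a `cell` column and a
#'   `treatment` column (values `"DD"` or `"LP"`); optional integer columns
#'   `ml`, `vd` (grid indices 1-7) and `section`.
#' @param housekeeping character vector of housekeeping gene ids (subset of
#'   the row names).
#'
#' @return An object of class `ct_data`: a list with elements `values`,
#'   `nondetect`, `cells`, `housekeeping`.
#' @export
ct_data <- function(values, nondetect = NULL, cells = NULL,
                    housekeeping = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x cells)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and cell column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene labels: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate cell labels: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(nondetect)) {
    nondetect <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  stopifnot(is.logical(nondetect), all(dim(nondetect) == dim(values)))
  dimnames(nondetect) <- dimnames(values)
  if (is.null(cells)) {
    cells <- tibble::tibble(cell = colnames(values), treatment = "LP")
  }
  cells <- tibble::as_tibble(cells)
  if (!all(c("cell", "treatment") %in% names(cells))) {
    stop("`cells` metadata needs `cell` and `treatment` columns", call. = FALSE)
  }
  if (!setequal(cells$cell, colnames(values)) || anyDuplicated(cells$cell)) {
    stop("`cells$cell` must match the matrix columns exactly", call. = FALSE)
  }
  cells <- cells[match(colnames(values), cells$cell), ]
  bad_trt <- setdiff(unique(cells$treatment), c("DD", "LP"))
  if (length(bad_trt)) {
    stop("unknown treatment labels: ", paste(bad_trt, collapse = ", "), call. = FALSE)
  }
  for (ax in c("ml", "vd")) {
    if (ax %in% names(cells) &&
        !all(is.na(cells[[ax]]) | (cells[[ax]] %in% 1:7))) {
      stop("`", ax, "` grid indices must be in 1..7", call. = FALSE)
    }
  }
  missing_hk <- setdiff(housekeeping, rownames(values))
  if (length(missing_hk)) {
    stop("housekeeping genes not in matrix: ",
         paste(missing_hk, collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = values, nondetect = nondetect, cells = cells,
         housekeeping = as.character(housekeeping)),
    class = "ct_data"
  )
}

#' Assemble a Ct container from a long tibble
#'
#' @param x tibble with columns `gene`, `cell`, `ct` and optionally `nondetect`.
#' @param cells,housekeeping see [ct_data()].
#' @return A [ct_data()] object.
#' @export
as_ct_data <- function(x, cells = NULL, housekeeping = character()) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("gene", "cell", "ct") %in% names(x)))
  if (!"nondetect" %in% names(x)) x$nondetect <- FALSE
  genes <- unique(x$gene)
  cls <- unique(x$cell)
  if (anyDuplicated(paste(x$gene, x$cell))) {
    stop("duplicated (gene, cell) records in long table", call. = FALSE)
  }
  values <- matrix(NA_real_, length(genes), length(cls),
                   dimnames = list(genes, cls))
  nd <- matrix(FALSE, length(genes), length(cls), dimnames = list(genes, cls))
  values[cbind(match(x$gene, genes), match(x$cell, cls))] <- x$ct
  nd[cbind(match(x$gene, genes), match(x$cell, cls))] <- x$nondetect
  ct_data(values, nd, cells = cells, housekeeping = housekeeping)
}

#' @export
print.ct_data <- function(x, ...) {
  cat("<ct_data> ", nrow(x$values), " genes x ", ncol(x$values), " cells\n", sep = "")
  tr <- table(x$cells$treatment)
  cat("  treatments: ", paste(names(tr), tr, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  housekeeping: ", paste(x$housekeeping, collapse = ", "), "\n", sep = "")
  cat("  non-detect entries: ", sum(x$nondetect), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Ct container into a long tibble
#'
#' @param x a [ct_data()] object.
#' @param ... unused.
#' @return Tibble with columns `gene`, `cell`, `ct`, `nondetect` joined with
#'   the per-cell metadata.
#' @method tidy ct_data
#' @export
tidy.ct_data <- function(x, ...) {
  long <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    cell = rep(colnames(x$values), each = nrow(x$values)),
    ct = as.vector(x$values),
    nondetect = as.vector(x$nondetect)
  )
  dplyr::left_join(long, x$cells, by = "cell")
}

#' Normalized expression container
#'
#' Genes-by-cells matrix at one of the three normalization stages, with the
#' provenance (housekeeping set, centering statistics) that produced it.
#' Missing entries are `NA`.
#'
#' @param values numeric matrix (genes x cells) with dimnames.
#' @param stage one of `"minus_dct"`, `"minus_ddct"`, `"modified_z"`.
#' @param cells per-cell metadata tibble (as in [ct_data()]).
#' @param provenance list recording housekeeping genes, non-detect policy and
#'   centering/scaling statistics.
#' @return An object of class `expr_data`.
#' @export
expr_data <- function(values, stage, cells, provenance = list()) {
  stage <- match.arg(stage, c("minus_dct", "minus_ddct", "modified_z"))
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  structure(
    list(values = values, stage = stage, cells = tibble::as_tibble(cells),
         provenance = provenance),
    class = "expr_data"
  )
}

#' @export
print.expr_data <- function(x, ...) {
  cat("<expr_data> stage=", x$stage, ": ", nrow(x$values), " genes x ",
      ncol(x$values), " cells (", sum(is.na(x$values)), " missing)\n", sep = "")
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method tidy expr_data
#' @export
tidy.expr_data <- function(x, ...) {
  long <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    cell = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$cells, by = "cell")
}

stage_check <- function(x, stage, what) {
  if (!inherits(x, "expr_data") || x$stage != stage) {
    stop(what, " requires an `expr_data` object at stage '", stage, "'",
         call. = FALSE)
  }
  invisible(x)
}
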
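NONDETECT_TOKENS <- c("", "NA", "999", "Undetermined")

#' Read a Ct table from TSV/CSV
#'
#' Supports a wide dialect (first column = gene labels, remaining columns =
#' cells) and a long dialect (columns `gene`, `cell`, `ct`). The tokens
#' `""`, `"NA"`, `"999"` and `"Undetermined"` are read as non-detects (mask
#' set, Ct recorded at `detection_limit_ct`). An optional metadata sidecar
#' (TSV with columns `cell`, `treatment` and optionally `ml`, `vd`,
#' `section`) supplies per-cell annotations; without one, all cells are
#' labeled `LP`.
#'
#' @param path input file (TSV by default; `.csv` switches the delimiter).
#' @param dialect `"wide"` or `"long"`.
#' @param metadata_path optional cell-metadata sidecar TSV.
#' @param housekeeping housekeeping gene labels present in the table.
#' @param nondetect_tokens strings mapped to the non-detect mask.
#' @param detection_limit_ct numeric Ct stored for non-detects.
#' @return A [ct_data()] object.
#' @export
read_ct_table <- function(path, dialect = c("wide", "long"),
                          metadata_path = NULL, housekeeping = character(),
                          nondetect_tokens = NONDETECT_TOKENS,
                          detection_limit_ct = 40) {
  dialect <- match.arg(dialect)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE)
  parse_ct <- function(x) {
    nd <- x %in% nondetect_tokens | is.na(x)
    val <- suppressWarnings(as.numeric(x))
    bad <- !nd & is.na(val)
    if (any(bad)) {
      stop("unparseable Ct entries (mixed decimal conventions?): ",
           paste(utils::head(unique(x[bad]), 5), collapse = ", "), call. = FALSE)
    }
    val[nd] <- detection_limit_ct
    list(value = val, nondetect = nd)
  }
  cells_meta <- NULL
  if (!is.null(metadata_path)) {
    cells_meta <- readr::read_tsv(metadata_path, col_types = readr::cols(),
                                  progress = FALSE)
  }
  if (dialect == "wide") {
    genes <- raw[[1]]
    if (anyDuplicated(genes)) {
      stop("duplicate gene labels: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
    }
    cell_ids <- names(raw)[-1]
    if (anyDuplicated(cell_ids)) {
      stop("duplicate cell labels: ",
           paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
           call. = FALSE)
    }
    parsed <- lapply(raw[-1], parse_ct)
    values <- do.call(cbind, lapply(parsed, `[[`, "value"))
    nd <- do.call(cbind, lapply(parsed, `[[`, "nondetect"))
    dimnames(values) <- dimnames(nd) <- list(genes, cell_ids)
    ct_data(values, nd, cells = cells_meta, housekeeping = housekeeping)
  } else {
    stopifnot(all(c("gene", "cell", "ct") %in% names(raw)))
    p <- parse_ct(raw$ct)
    as_ct_data(tibble::tibble(gene = raw$gene, cell = raw$cell,
                              ct = p$value, nondetect = p$nondetect),
               cells = cells_meta, housekeeping = housekeeping)
  }
}

#' Write a Ct container as a wide TSV (plus metadata sidecar)
#'
#' Inverse of [read_ct_table()] for the wide dialect: non-detect entries are
#' written as `Undetermined`.
#'
#' @param ct a [ct_data()] object.
#' @param path output TSV path.
#' @param metadata_path optional sidecar path for the cell metadata.
#' @return Invisibly, `path`.
#' @export
write_ct_table <- function(ct, path, metadata_path = NULL) {
  stopifnot(inherits(ct, "ct_data"))
  out <- ct$values
  chr <- matrix(format(out, trim = TRUE, digits = 15), nrow(out), ncol(out))
  chr[ct$nondetect] <- "Undetermined"
  df <- dplyr::bind_cols(tibble::tibble(gene = rownames(out)),
                         tibble::as_tibble(chr, .name_repair = "minimal") |>
                           stats::setNames(colnames(out)))
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(metadata_path)) {
    readr::write_tsv(ct$cells, metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Write a graph to an edge-list TSV or GraphML file
#'
#' Edge lists carry columns `source`, `target`, `weight` plus any further
#' edge annotation columns, sorted deterministically; an empty graph writes
#' the header only. GraphML output declares typed attribute keys and can be
#' read back with [read_graph_file()].
#'
#' @param g a `cor_graph` or `interaction_network`.
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(g, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (inherits(g, "interaction_network")) {
    edges <- dplyr::rename(g$edges, source = "from", target = "to")
    nodes <- as.character(g$nodes$group)
    directed <- TRUE
  } else if (inherits(g, "cor_graph")) {
    edges <- dplyr::rename(g$edges, source = "from", target = "to")
    nodes <- g$nodes
    directed <- FALSE
  } else {
    stop("unsupported graph object", call. = FALSE)
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges <- edges[order(edges$source, edges$target), ]
  if (format == "tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  extra <- setdiff(names(edges), c("source", "target"))
  for (at in extra) {
    key <- xml2::xml_add_child(doc, "key", id = at, `for` = "edge",
                               attr.name = at,
                               attr.type = if (is.numeric(edges[[at]])) "double" else "string")
    invisible(key)
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = if (directed) "directed" else "undirected")
  for (nd in nodes) xml2::xml_add_child(graph, "node", id = nd)
  for (i in seq_len(nrow(edges))) {
    e <- xml2::xml_add_child(graph, "edge",
                             source = edges$source[i], target = edges$target[i])
    for (at in extra) {
      d <- xml2::xml_add_child(e, "data", key = at)
      xml2::xml_text(d) <- as.character(edges[[at]][i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a graph written by [write_graph_file()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return List with `nodes` (GraphML only; `NULL` for TSV), `edges` tibble,
#'   `directed`.
#' @export
read_graph_file <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    return(list(nodes = NULL, edges = tibble::as_tibble(edges), directed = NA))
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  key_types <- stats::setNames(xml2::xml_attr(keys, "attr.type"),
                               xml2::xml_attr(keys, "id"))
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  directed <- identical(xml2::xml_attr(graph, "edgedefault"), "directed")
  nodes <- xml2::xml_attr(xml2::xml_find_all(graph, ".//g:node", ns), "id")
  edge_nodes <- xml2::xml_find_all(graph, ".//g:edge", ns)
  edges <- purrr::map_dfr(edge_nodes, function(e) {
    row <- list(source = xml2::xml_attr(e, "source"),
                target = xml2::xml_attr(e, "target"))
    for (d in xml2::xml_find_all(e, "./g:data", ns)) {
      key <- xml2::xml_attr(d, "key")
      val <- xml2::xml_text(d)
      row[[key]] <- if (identical(key_types[[key]], "double"))
        as.numeric(val) else val
    }
    tibble::as_tibble(row)
  })
  list(nodes = nodes, edges = edges, directed = directed)
}

#' End-to-end analysis pipeline
#'
#' Chains the full analysis: QC filtering, two-step normalization,
#' cell-cell correlation, thresholded cell graph, leading-eigenvector
#' community detection with residual pooling, MDS + silhouette validation,
#' PCA, gene correlation graph, signaling-regime classification, enrichment
#' testing, the dominant-interaction permutation screen, and construction of
#' the directed group-interaction network. Identical inputs and seeds give
#' identical bundles.
#'
#' @param ct a [ct_data()] object.
#' @param pairs an [lr_pairs()] tibble (or `NULL` to skip interaction
#'   inference).
#' @param rules a [qc_rules()] set.
#' @param cell_threshold cell-cell correlation threshold (edges at
#'   `r >= cell_threshold`).
#' @param gene_threshold gene-gene correlation threshold (edges at
#'   `r > gene_threshold`).
#' @param min_degree,min_size residual-pooling knobs (see [pool_residual()];
#'   `min_size = NULL` uses 5% of cells).
#' @param silhouette_space `"mds"` (Euclidean distance in the 2-D MDS plane,
#'   default) or `"correlation"` (1 - r in full expression space).
#' @param alpha enrichment significance level.
#' @param n_perm permutations for the dominant-interaction screen.
#' @param screen_quantile null quantile for the screen.
#' @param min_obs minimum pairwise-complete observations for correlations.
#' @param seed integer seed covering all randomized stages.
#' @return Object of class `pipeline_result`: list with `qc_report`,
#'   `expression` (stage minus_ddct), `cell_cor`, `cell_graph`, `partition`,
#'   `mds`, `silhouette`, `pca`, `gene_graph`, `regimes`, `enrichment`,
#'   `screen`, `network`, `manifest`.
#' @export
run_pipeline <- function(ct, pairs = NULL, rules = qc_rules(),
                         cell_threshold = 0.5, gene_threshold = 0.5,
                         min_degree = 1, min_size = NULL,
                         silhouette_space = c("mds", "correlation"),
                         alpha = 0.05, n_perm = 1000, screen_quantile = 0.95,
                         min_obs = 10, seed = 1L) {
  stopifnot(inherits(ct, "ct_data"))
  silhouette_space <- match.arg(silhouette_space)
  qc <- qc_filter(ct, rules)
  expr <- normalize_expression(qc$ct)
  cell_cor <- suppressWarnings(pearson_matrix(expr, axis = "cells",
                                              min_obs = min_obs))
  cell_graph <- graph_from_correlations(cell_cor, cell_threshold,
                                        strict = FALSE)
  if (nrow(cell_graph$edges) == 0) {
    warning("cell graph has no edges at threshold ", cell_threshold,
            "; all cells pooled into the residual group", call. = FALSE)
    assignment <- tibble::tibble(node = cell_graph$nodes, group = 1L)
    partition <- structure(list(assignment = assignment, q = NA_real_,
                                residual_group = 1L,
                                provenance = list(degenerate = TRUE)),
                           class = "group_partition")
  } else {
    partition <- detect_communities(cell_graph)
    partition <- pool_residual(cell_graph, partition, min_degree = min_degree,
                               min_size = min_size %||%
                                 ceiling(0.05 * length(cell_graph$nodes)))
  }
  d_cells <- 1 - cell_cor$r
  d_cells[is.na(d_cells)] <- 2
  diag(d_cells) <- 0
  mds <- run_mds(d_cells, k = 2)
  sil_d <- if (silhouette_space == "mds") {
    as.matrix(stats::dist(mds$coordinates))
  } else {
    d_cells
  }
  sil <- if (length(unique(partition$assignment$group)) >= 2) {
    silhouette_scores(partition, sil_d)
  } else NULL
  pca <- run_pca(expr)
  gene_cor <- suppressWarnings(pearson_matrix(expr, axis = "genes",
                                              min_obs = min_obs))
  gene_graph <- graph_from_correlations(gene_cor, gene_threshold, strict = TRUE)

  regimes <- enrichment <- screen <- network <- NULL
  if (!is.null(pairs)) {
    pairs <- tibble::as_tibble(pairs)
    keep <- pairs$ligand %in% rownames(expr$values) &
      pairs$receptor %in% rownames(expr$values)
    pairs <- pairs[keep, ]
    if (nrow(pairs)) {
      regimes <- classify_regime(expr, pairs)
      enrichment <- suppressWarnings(
        regime_enrichment(regimes, partition, alpha = alpha)
      )
      screen <- suppressWarnings(
        dominant_interaction_screen(expr, pairs, n_perm = n_perm,
                                    quantile = screen_quantile, seed = seed,
                                    min_obs = min_obs)
      )
      network <- build_interaction_network(enrichment, screen, alpha = alpha)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenonet")),
    seed = seed,
    parameters = list(cell_threshold = cell_threshold,
                      gene_threshold = gene_threshold,
                      min_degree = min_degree,
                      min_size = min_size %||% ceiling(0.05 * length(cell_graph$nodes)),
                      silhouette_space = silhouette_space, alpha = alpha,
                      n_perm = n_perm, screen_quantile = screen_quantile,
                      min_obs = min_obs,
                      qc_rules = unclass(rules)),
    input = list(n_genes = nrow(ct$values), n_cells = ncol(ct$values))
  )
  structure(list(qc_report = qc$report, expression = expr,
                 cell_cor = cell_cor, cell_graph = cell_graph,
                 partition = partition, mds = mds, silhouette = sil,
                 pca = pca, gene_graph = gene_graph, regimes = regimes,
                 enrichment = enrichment, screen = screen, network = network,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$partition)
  if (!is.null(x$silhouette)) {
    cat("  silhouette (per group):\n")
    print(glance(x$silhouette))
  }
  if (!is.null(x$network)) print(x$network)
  invisible(x)
}

#' @rdname tidy.ct_data
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  g <- glance(x$partition)
  g$pc3_variance <- sum(x$pca$variance_fraction[1:min(3, length(x$pca$variance_fraction))])
  g$n_cell_edges <- nrow(x$cell_graph$edges)
  g$n_gene_edges <- nrow(x$gene_graph$edges)
  g$n_interactions <- if (is.null(x$network)) NA_integer_ else nrow(x$network$edges)
  g
}

#' Write every pipeline artifact to a directory
#'
#' Emits the QC report, the normalized matrix, cell/gene edge lists, the
#' partition, validation summaries, the enrichment table, the screen and the
#' interaction network (TSV + GraphML), plus a JSON manifest.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(tidy(result$qc_report), file.path(dir, "qc_exclusions.tsv"))
  expr_long <- tidy(result$expression)
  readr::write_tsv(expr_long, file.path(dir, "expression_minus_ddct.tsv"))
  write_graph_file(result$cell_graph, file.path(dir, "cell_graph.tsv"))
  write_graph_file(result$gene_graph, file.path(dir, "gene_graph.tsv"))
  readr::write_tsv(tidy(result$partition), file.path(dir, "partition.tsv"))
  if (!is.null(result$silhouette)) {
    readr::write_tsv(glance(result$silhouette), file.path(dir, "silhouette.tsv"))
  }
  readr::write_tsv(glance(result$pca), file.path(dir, "pca_variance.tsv"))
  if (!is.null(result$enrichment)) {
    readr::write_tsv(result$enrichment, file.path(dir, "enrichment.tsv"))
    readr::write_tsv(result$screen, file.path(dir, "dominant_screen.tsv"))
    write_graph_file(result$network, file.path(dir, "interaction_network.tsv"))
    write_graph_file(result$network, file.path(dir, "interaction_network.graphml"),
                     format = "graphml")
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
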
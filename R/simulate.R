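#' Configuration for the synthetic single-cell qPCR generator
#'
#' Describes a Ct-scale dataset with planted phenotype groups, housekeeping
#' genes, ligand-receptor signaling structure, per-group dropout, spatial bias
#' on a 7x7 grid and a treatment (DD vs LP) shift on immediate-early genes.
#' The defaults emulate the study conditions the pipeline is designed for:
#' 200 cells in four equally sized groups over 60 genes, group signatures of
#' eight genes shifted by 3 Ct cycles, unit Ct noise, two ligand-receptor
#' pairs wiring group 1 to group 2 and group 3 to group 4, a binary-like
#' dropout gene, ventral vs dorsal placement of groups 1 and 2, and a 2-cycle
#' immediate-early-gene induction in light-pulsed cells.
#'
#' @param n_cells number of cells.
#' @param n_genes total number of genes (labels are generated; must cover all
#'   referenced genes).
#' @param group_spec tibble with columns `group`, `proportion`, `signature`
#'   (list column of gene labels), `shift` (Ct cycles subtracted for the
#'   group's signature genes; positive = up-regulated).
#' @param housekeeping_genes labels of near-constant reference genes; they
#'   carry no group signature.
#' @param lr_pairs tibble with columns `ligand`, `receptor`, `source`,
#'   `target`, `autocrine` (list column of group labels, possibly empty) and
#'   `shift` (cycles). In source/autocrine groups the ligand is shifted up
#'   and elsewhere down; likewise the receptor in target/autocrine groups.
#' @param ieg_genes immediate-early gene labels induced by the light pulse.
#' @param treatment_effect Ct cycles subtracted from `ieg_genes` in LP cells.
#' @param dd_fraction fraction of cells labeled DD (the rest LP).
#' @param dropout named list: gene -> named numeric vector of per-group
#'   non-detect probabilities.
#' @param noise_sd Gaussian Ct noise SD (cycles); housekeeping genes use
#'   `0.2 * noise_sd`.
#' @param lr_latent_sd SD (cycles) of a shared per-cell latent added to both
#'   genes of each ligand-receptor pair, producing the positive pair
#'   co-expression across cells that a dominant-interaction screen detects.
#' @param baseline_ct baseline Ct of non-housekeeping genes.
#' @param housekeeping_ct baseline Ct of housekeeping genes.
#' @param detection_limit_ct cycle ceiling recorded for non-detects.
#' @param spatial_rules tibble with columns `group`, `ml_mean`, `vd_mean`,
#'   `sd` (truncated discrete Gaussian over grid indices 1-7), plus
#'   `n_sections` sections sampled uniformly.
#' @param n_sections number of rostrocaudal sections.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   config.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 200,
                       n_genes = 60,
                       group_spec = NULL,
                       housekeeping_genes = c("Hk1", "Hk2", "Hk3"),
                       lr_pairs = NULL,
                       ieg_genes = c("Ieg1", "Ieg2", "Ieg3"),
                       treatment_effect = 2,
                       dd_fraction = 0.27,
                       dropout = list(Lig1 = c(G2 = 0.45, G3 = 0.45, G4 = 0.45)),
                       noise_sd = 1,
                       lr_latent_sd = 2,
                       baseline_ct = 26,
                       housekeeping_ct = 20,
                       detection_limit_ct = 40,
                       spatial_rules = NULL,
                       n_sections = 3,
                       seed = 20161025) {
  if (is.null(group_spec)) {
    group_spec <- tibble::tibble(
      group = paste0("G", 1:4),
      proportion = rep(0.25, 4),
      signature = lapply(1:4, function(g) sprintf("S%d_%d", g, 1:8)),
      shift = rep(3, 4)
    )
  }
  group_spec <- tibble::as_tibble(group_spec)
  if (is.null(lr_pairs)) {
    lr_pairs <- tibble::tibble(
      ligand = c("Lig1", "Lig2"),
      receptor = c("Rec1", "Rec2"),
      source = c("G1", "G3"),
      target = c("G2", "G4"),
      autocrine = list("G3", "G1"),
      shift = c(3, 3)
    )
  }
  lr_pairs <- tibble::as_tibble(lr_pairs)
  if (!"autocrine" %in% names(lr_pairs)) lr_pairs$autocrine <- list(character())
  if (!"shift" %in% names(lr_pairs)) lr_pairs$shift <- 3

  named <- unique(c(housekeeping_genes,
                    unlist(group_spec$signature, use.names = FALSE),
                    lr_pairs$ligand, lr_pairs$receptor, ieg_genes))
  if (length(named) > n_genes) {
    stop("configuration error: ", length(named),
         " referenced genes exceed n_genes = ", n_genes, call. = FALSE)
  }
  n_bg <- n_genes - length(named)
  genes <- c(named, if (n_bg > 0) sprintf("Bg%02d", seq_len(n_bg)))

  if (is.null(spatial_rules)) {
    spatial_rules <- tibble::tibble(
      group = group_spec$group,
      ml_mean = rep(4, nrow(group_spec)),
      vd_mean = c(2, 6, rep(4, max(0, nrow(group_spec) - 2)))[seq_len(nrow(group_spec))],
      sd = rep(1.5, nrow(group_spec))
    )
  }
  spatial_rules <- tibble::as_tibble(spatial_rules)

  cfg <- structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         genes = genes, group_spec = group_spec,
         housekeeping_genes = housekeeping_genes, lr_pairs = lr_pairs,
         ieg_genes = ieg_genes, treatment_effect = treatment_effect,
         dd_fraction = dd_fraction, dropout = dropout, noise_sd = noise_sd,
         lr_latent_sd = lr_latent_sd,
         baseline_ct = baseline_ct, housekeeping_ct = housekeeping_ct,
         detection_limit_ct = detection_limit_ct,
         spatial_rules = spatial_rules, n_sections = as.integer(n_sections),
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  gs <- cfg$group_spec
  if (abs(sum(gs$proportion) - 1) > 1e-9) {
    stop("configuration error: group proportions sum to ", sum(gs$proportion),
         ", not 1", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd < 0", call. = FALSE)
  if (cfg$n_cells < 1) stop("configuration error: n_cells must be positive", call. = FALSE)
  referenced <- unique(c(unlist(gs$signature, use.names = FALSE),
                         cfg$lr_pairs$ligand, cfg$lr_pairs$receptor,
                         cfg$ieg_genes, names(cfg$dropout),
                         cfg$housekeeping_genes))
  missing <- setdiff(referenced, cfg$genes)
  if (length(missing)) {
    stop("configuration error: genes referenced but not generated: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hk_in_sig <- intersect(cfg$housekeeping_genes,
                         unlist(gs$signature, use.names = FALSE))
  if (length(hk_in_sig)) {
    stop("configuration error: housekeeping genes carry a group signature: ",
         paste(hk_in_sig, collapse = ", "), call. = FALSE)
  }
  groups_ref <- unique(c(cfg$lr_pairs$source, cfg$lr_pairs$target,
                         unlist(cfg$lr_pairs$autocrine, use.names = FALSE),
                         unlist(lapply(cfg$dropout, names), use.names = FALSE),
                         cfg$spatial_rules$group))
  bad_groups <- setdiff(groups_ref, gs$group)
  if (length(bad_groups)) {
    stop("configuration error: unknown groups referenced: ",
         paste(bad_groups, collapse = ", "), call. = FALSE)
  }
  cfg
}

# truncated discrete Gaussian over grid indices 1..7
draw_grid_index <- function(n, mean, sd) {
  idx <- 1:7
  w <- stats::dnorm(idx, mean = mean, sd = sd)
  sample(idx, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic single-cell qPCR dataset
#'
#' Draws a Ct-scale genes-by-cells matrix according to a [sim_config()]:
#' group signatures lower Ct by the configured shift, ligand/receptor genes
#' are bimodal across groups according to their source/target/autocrine
#' roles, immediate-early genes are induced in LP cells, dropout turns
#' entries into non-detects at the detection limit, and cells receive grid
#' coordinates from per-group truncated discrete Gaussians. Identical
#' configs (including seed) give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_result` with elements `ct` (a [ct_data()]) and
#'   `truth` (list of tibbles `groups`, `regimes`, `coordinates`).
#' @export
simulate_cells <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::local_seed(config$seed)

  n <- config$n_cells
  genes <- config$genes
  gs <- config$group_spec
  cells <- sprintf("C%03d", seq_len(n))

  # group sizes by largest-remainder rounding so proportions are honored
  raw <- gs$proportion * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_frac <- order(raw - floor(raw), decreasing = TRUE)
    sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1
  }
  group_of <- rep(gs$group, times = sizes)

  treatment <- ifelse(stats::runif(n) < config$dd_fraction, "DD", "LP")

  # mean Ct per gene per cell
  mu <- matrix(config$baseline_ct, length(genes), n, dimnames = list(genes, cells))
  mu[config$housekeeping_genes, ] <- config$housekeeping_ct
  for (i in seq_len(nrow(gs))) {
    in_grp <- group_of == gs$group[i]
    sig <- gs$signature[[i]]
    mu[sig, in_grp] <- mu[sig, in_grp] - gs$shift[i]
  }
  for (i in seq_len(nrow(config$lr_pairs))) {
    p <- config$lr_pairs[i, ]
    up_l <- group_of %in% c(p$source, p$autocrine[[1]])
    up_r <- group_of %in% c(p$target, p$autocrine[[1]])
    mu[p$ligand, ] <- mu[p$ligand, ] + ifelse(up_l, -p$shift, p$shift)
    mu[p$receptor, ] <- mu[p$receptor, ] + ifelse(up_r, -p$shift, p$shift)
    if (config$lr_latent_sd > 0) {
      z <- stats::rnorm(n, 0, config$lr_latent_sd)
      mu[p$ligand, ] <- mu[p$ligand, ] - z
      mu[p$receptor, ] <- mu[p$receptor, ] - z
    }
  }
  if (length(config$ieg_genes)) {
    lp <- treatment == "LP"
    mu[config$ieg_genes, lp] <- mu[config$ieg_genes, lp] - config$treatment_effect
  }

  noise <- matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
                  length(genes), n)
  hk_rows <- match(config$housekeeping_genes, genes)
  if (length(hk_rows)) noise[hk_rows, ] <- noise[hk_rows, ] * 0.2
  values <- mu + noise

  nondetect <- matrix(FALSE, length(genes), n, dimnames = list(genes, cells))
  for (g in names(config$dropout)) {
    probs <- config$dropout[[g]]
    pr <- probs[group_of]
    pr[is.na(pr)] <- 0
    hit <- stats::runif(n) < pr
    nondetect[g, hit] <- TRUE
  }
  values[nondetect] <- config$detection_limit_ct

  coords <- tibble::tibble(cell = cells, ml = NA_integer_, vd = NA_integer_,
                           section = sample.int(config$n_sections, n, replace = TRUE))
  for (i in seq_len(nrow(config$spatial_rules))) {
    r <- config$spatial_rules[i, ]
    in_grp <- which(group_of == r$group)
    coords$ml[in_grp] <- draw_grid_index(length(in_grp), r$ml_mean, r$sd)
    coords$vd[in_grp] <- draw_grid_index(length(in_grp), r$vd_mean, r$sd)
  }
  # groups without a spatial rule scatter uniformly
  miss <- is.na(coords$ml)
  coords$ml[miss] <- sample.int(7, sum(miss), replace = TRUE)
  miss <- is.na(coords$vd)
  coords$vd[miss] <- sample.int(7, sum(miss), replace = TRUE)

  meta <- tibble::tibble(cell = cells, treatment = treatment,
                         ml = coords$ml, vd = coords$vd, section = coords$section)
  ct <- ct_data(values, nondetect, cells = meta,
                housekeeping = config$housekeeping_genes)

  regimes <- purrr::map_dfr(seq_len(nrow(config$lr_pairs)), function(i) {
    p <- config$lr_pairs[i, ]
    regime <- dplyr::case_when(
      group_of %in% p$autocrine[[1]] ~ "autocrine",
      group_of == p$source ~ "source",
      group_of == p$target ~ "target",
      TRUE ~ "none"
    )
    tibble::tibble(cell = cells, pair = paste0(p$ligand, "-", p$receptor),
                   regime = regime)
  })

  structure(
    list(ct = ct,
         truth = list(
           groups = tibble::tibble(cell = cells, group = group_of),
           regimes = regimes,
           coordinates = coords
         ),
         config = config),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", x$config$n_genes, " genes x ", x$config$n_cells,
      " cells, ", nrow(x$config$group_spec), " planted groups (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Apply additional dropout to one gene
#'
#' Turns a random fraction of one gene's measurements into non-detects at the
#' container's detection-limit Ct, reproducibly for a given seed. Models
#' binary-like expression where a fraction of cells falls below the qPCR
#' detection limit.
#'
#' @param ct a [ct_data()] object.
#' @param gene gene label.
#' @param rate dropout probability in \[0, 1\].
#' @param seed integer seed.
#' @param detection_limit_ct Ct recorded for the new non-detects.
#' @return A modified [ct_data()].
#' @export
apply_dropout <- function(ct, gene, rate, seed, detection_limit_ct = 40) {
  stopifnot(inherits(ct, "ct_data"))
  if (!gene %in% rownames(ct$values)) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]", call. = FALSE)
  withr::local_seed(seed)
  hit <- stats::runif(ncol(ct$values)) < rate
  ct$nondetect[gene, hit] <- TRUE
  ct$values[gene, hit] <- detection_limit_ct
  ct
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits a wide genes-by-cells Ct TSV, a cell-metadata sidecar TSV and a JSON
#' ground-truth file.
#'
#' @param sim a `sim_result` from [simulate_cells()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ct_path <- file.path(dir, "ct_values.tsv")
  meta_path <- file.path(dir, "cell_metadata.tsv")
  truth_path <- file.path(dir, "ground_truth.json")
  write_ct_table(sim$ct, ct_path, metadata_path = meta_path)
  jsonlite::write_json(
    list(groups = sim$truth$groups, regimes = sim$truth$regimes,
         coordinates = sim$truth$coordinates),
    truth_path, dataframe = "columns", digits = NA
  )
  invisible(c(ct = ct_path, metadata = meta_path, truth = truth_path))
}
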
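test_that("the four sign quadrants map to the four regimes exactly", {
  vals <- rbind(L = c(1, -1, 1, -1, 0), R = c(-1, 1, 1, -1, 0))
  x <- expr_fixture(vals, stage = "minus_ddct")
  rg <- classify_regime(x, lr_pairs("L", "R"))
  expect_equal(rg$regime, c("source", "target", "autocrine", "none", "none"))
  expect_setequal(unique(rg$regime[1:4]),
                  c("source", "target", "autocrine", "none"))
  # boundaries are <=: (0, 0) is none, exactly one regime per cell
  expect_equal(sum(rg$cell == "c05" & rg$regime == "none"), 1)
  expect_true(all(table(rg$cell) == 1))
})

test_that("missing measurements classify as none with the missing flag", {
  vals <- rbind(L = c(1, NA), R = c(NA, 1))
  x <- expr_fixture(vals, stage = "minus_ddct")
  rg <- classify_regime(x, lr_pairs("L", "R"))
  expect_true(all(rg$regime == "none"))
  expect_true(all(rg$missing))
  expect_error(classify_regime(x, lr_pairs("L", "Nope")), "absent")
})

test_that("regime counts partition the complete-data cells", {
  set.seed(41)
  vals <- rbind(L = rnorm(50), R = rnorm(50))
  vals["L", 1:5] <- NA
  x <- expr_fixture(vals, stage = "minus_ddct")
  rg <- classify_regime(x, lr_pairs("L", "R"))
  expect_equal(sum(!rg$missing), 45)
  expect_equal(nrow(rg), 50)
})

test_that("enrichment p-values follow the hypergeometric closed form", {
  # group identical to the regime set, 10 of 100 cells
  cells <- sprintf("c%03d", 1:100)
  rg <- tibble::tibble(cell = cells, pair = "L-R",
                       regime = c(rep("source", 10), rep("none", 90)),
                       missing = FALSE)
  part <- tibble::tibble(node = cells, group = c(rep(1L, 10), rep(2L, 90)))
  et <- regime_enrichment(rg, part)
  row <- et[et$group == 1 & et$regime == "source", ]
  expect_equal(row$fraction, 1)
  expect_equal(row$p_value, 1 / choose(100, 10), tolerance = 1e-12)
})

test_that("enrichment matches brute-force tails and fisher.test on random tables", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    cells <- sprintf("c%03d", seq_len(n))
    rg <- tibble::tibble(cell = cells, pair = "L-R",
                         regime = sample(c("source", "target", "autocrine", "none"),
                                         n, replace = TRUE),
                         missing = FALSE)
    part <- tibble::tibble(node = cells,
                           group = sample(1:3, n, replace = TRUE))
    et <- suppressWarnings(regime_enrichment(rg, part))
    for (i in seq_len(nrow(et))) {
      r <- et[i, ]
      expect_equal(r$p_value,
                   brute_fisher_tail(r$k, r$n_regime, r$n_total, r$n_group),
                   tolerance = 1e-12)
      tab <- matrix(c(r$k, r$n_group - r$k,
                      r$n_regime - r$k,
                      r$n_total - r$n_group - r$n_regime + r$k), 2)
      ref <- stats::fisher.test(tab, alternative = "greater")$p.value
      expect_equal(r$p_value, ref, tolerance = 1e-9)
    }
  }
})

test_that("a group at the population regime rate is not significantly enriched", {
  cells <- sprintf("c%03d", 1:200)
  # regime rate 0.3 in the group and in the rest
  regime <- c(rep("source", 15), rep("none", 35), rep("source", 45), rep("none", 105))
  rg <- tibble::tibble(cell = cells, pair = "L-R", regime = regime,
                       missing = FALSE)
  part <- tibble::tibble(node = cells, group = c(rep(1L, 50), rep(2L, 150)))
  et <- regime_enrichment(rg, part)
  row <- et[et$group == 1 & et$regime == "source", ]
  expect_gt(row$p_value, 0.3)
  expect_false(row$significant)
})

test_that("adding a group member inside the regime never increases the p-value", {
  for (k in 2:9) {
    p_k <- brute_fisher_tail(k, 20, 100, 10)
    p_k1 <- brute_fisher_tail(k + 1, 20, 100, 10)
    expect_lte(p_k1, p_k + 1e-15)
  }
  # and the package agrees with the oracle on those tables
  expect_equal(stats::phyper(4, 20, 80, 10, lower.tail = FALSE),
               brute_fisher_tail(5, 20, 100, 10), tolerance = 1e-12)
})

test_that("screen retains a perfectly correlated pair and is seed-reproducible", {
  set.seed(43)
  v <- rnorm(60)
  vals <- rbind(L = v, R = v, X = rnorm(60), C = rep(1, 60))
  x <- expr_fixture(vals, stage = "minus_ddct")
  sc <- dominant_interaction_screen(x, lr_pairs(c("L", "L"), c("R", "X")),
                                    n_perm = 200, seed = 5)
  expect_true(sc$retained[sc$pair == "L-R"])
  expect_equal(sc$observed_r[sc$pair == "L-R"], 1, tolerance = 1e-12)
  sc2 <- dominant_interaction_screen(x, lr_pairs(c("L", "L"), c("R", "X")),
                                     n_perm = 200, seed = 5)
  expect_identical(sc, sc2)
  expect_warning(
    dominant_interaction_screen(x, lr_pairs("L", "C"), n_perm = 100, seed = 1),
    "skipped"
  )
  expect_error(dominant_interaction_screen(x, lr_pairs("L", "R"), n_perm = 10),
               "100")
})

test_that("interaction network construction wires significant sources to targets", {
  et <- structure(
    tibble::tibble(
      pair = rep("L-R", 6),
      group = rep(1:2, each = 3),
      regime = rep(c("source", "target", "autocrine"), 2),
      k = c(9, 0, 1, 0, 8, 0), n_group = rep(10, 6), n_regime = rep(9, 6),
      n_total = rep(20, 6),
      fraction = c(0.9, 0, 0.1, 0, 0.8, 0),
      p_value = c(1e-5, 1, 0.9, 1, 1e-4, 1),
      significant = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
    ),
    class = c("enrichment_table", class(tibble::tibble())), alpha = 0.05
  )
  screen <- tibble::tibble(pair = "L-R", retained = TRUE)
  net <- build_interaction_network(et, screen)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$from, 1)
  expect_equal(net$edges$to, 2)
  expect_equal(net$edges$source_fraction, 0.9)
  expect_equal(net$edges$target_fraction, 0.8)

  # nothing significant -> empty edge set; tightening alpha only removes edges
  net_tight <- build_interaction_network(et, screen, alpha = 1e-8)
  expect_equal(nrow(net_tight$edges), 0)
  # a screen that rejects the pair removes its edges
  net_rej <- build_interaction_network(
    et, tibble::tibble(pair = "L-R", retained = FALSE))
  expect_equal(nrow(net_rej$edges), 0)
  expect_error(build_interaction_network(
    et, tibble::tibble(pair = "Other", retained = TRUE)), "Other")
})

test_that("network edges are always justified by significant enrichment", {
  set.seed(44)
  sim <- simulate_cells(sim_config(n_cells = 150, seed = 44))
  res <- run_pipeline(sim$ct, pairs = sim$config$lr_pairs, n_perm = 200,
                      seed = 3)
  et <- res$enrichment
  for (i in seq_len(nrow(res$network$edges))) {
    e <- res$network$edges[i, ]
    if (e$type == "paracrine") {
      expect_true(any(et$pair == e$pair & et$group == e$from &
                        et$regime == "source" & et$significant))
      expect_true(any(et$pair == e$pair & et$group == e$to &
                        et$regime == "target" & et$significant))
    } else {
      expect_true(any(et$pair == e$pair & et$group == e$from &
                        et$regime == "autocrine" & et$significant))
    }
  }
})

test_that("planted source and target groups are recovered as a directed edge", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- sim_config(
      n_cells = 120, n_genes = 30,
      group_spec = tibble::tibble(
        group = c("A", "B"), proportion = c(0.5, 0.5),
        signature = list(paste0("SA", 1:6), paste0("SB", 1:6)),
        shift = c(3, 3)
      ),
      lr_pairs = tibble::tibble(ligand = "L", receptor = "R", source = "A",
                                target = "B", autocrine = list(character()),
                                shift = 3),
      ieg_genes = character(), dropout = list(), noise_sd = 0.5,
      lr_latent_sd = 2, spatial_rules = NULL, seed = seed
    )
    sim <- simulate_cells(cfg)
    expr <- normalize_expression(sim$ct)
    truth_part <- tibble::tibble(
      node = sim$truth$groups$cell,
      group = as.integer(factor(sim$truth$groups$group, levels = c("A", "B")))
    )
    rg <- classify_regime(expr, cfg$lr_pairs)
    et <- regime_enrichment(rg, truth_part)
    net <- build_interaction_network(et, screen = NULL)
    if (any(net$edges$from == 1 & net$edges$to == 2 &
              net$edges$type == "paracrine")) hits <- hits + 1
  }
  expect_equal(hits, 10)
})

test_that("source-role fidelity: planted sources classify as source at low noise", {
  cfg <- sim_config(n_cells = 400, noise_sd = 0.5, lr_latent_sd = 1,
                    dropout = list(), seed = 46)
  sim <- simulate_cells(cfg)
  expr <- normalize_expression(sim$ct)
  rg <- classify_regime(expr, cfg$lr_pairs)
  joined <- dplyr::inner_join(rg, sim$truth$regimes, by = c("cell", "pair"),
                              suffix = c("_obs", "_true"))
  src <- joined[joined$regime_true == "source", ]
  expect_gte(mean(src$regime_obs == "source"), 0.95)
})
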
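test_that("fixed seed makes every generator byte-identical", {
  cfg <- sim_config(n_background_genes = 50,
                    planted_modules = list(planted_module(10, "bell", 0.8)),
                    seed = 11)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$expression$spA$values, s2$expression$spA$values)
  expect_identical(s1$truth, s2$truth)
  h1 <- simulate_similarity_table(s1$truth, 0.3, seed = 5)
  h2 <- simulate_similarity_table(s2$truth, 0.3, seed = 5)
  expect_identical(h1, h2)
  expect_identical(simulate_fa_profiles(cfg), simulate_fa_profiles(cfg))
})

test_that("invalid designs are rejected", {
  expect_error(sim_config(planted_modules = list(planted_module(2, "bell"))),
               "size")
  expect_error(planted_module(10, cor = 1.2), "cor")
  cfg <- sim_config(n_background_genes = 20,
                    planted_modules = list(planted_module(5, "flat", 0.5)))
  truth <- simulate_expression(cfg)$truth
  expect_error(simulate_similarity_table(truth, decoy_rate = 1), "decoy_rate")
  bad <- sim_config(n_background_genes = 20,
                    planted_modules = list(planted_module(5, "bell", 0.5)),
                    omega6_de_target = 0, omega3_de_target = 0.5)
  expect_error(simulate_fa_profiles(bad), "substrate")
})

test_that("perfect within-module correlation with no noise gives exactly proportional profiles", {
  cfg <- sim_config(n_species = 2, n_background_genes = 0,
                    planted_modules = list(planted_module(5, "bell", 1)),
                    de_genes = tibble::tibble(gene = integer(),
                                              species = integer(),
                                              log2fc = numeric()),
                    paralog_events = tibble::tibble(ancestral = integer(),
                                                    children = integer(),
                                                    diverged = logical()),
                    noise_sd = 0)
  m <- simulate_expression(cfg)$expression$spA$values
  ratios <- m[-1, , drop = FALSE] / rep(m[1, ], each = nrow(m) - 1)
  expect_true(all(abs(ratios - ratios[, 1]) < 1e-9))
})

test_that("planted-module correlation matches its target over repeated draws", {
  rs <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_species = 2, n_background_genes = 0,
                      planted_modules = list(planted_module(40, "bell", 0.8)),
                      de_genes = tibble::tibble(gene = integer(),
                                                species = integer(),
                                                log2fc = numeric()),
                      paralog_events = tibble::tibble(ancestral = integer(),
                                                      children = integer(),
                                                      diverged = logical()),
                      seed = seed)
    m <- simulate_expression(cfg)$expression$spA$values
    cm <- cor(t(log2(m)))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_gt(mean(rs), 0.75)
  expect_lt(mean(rs), 0.85)
})

test_that("expression output has the promised geometry and truth bookkeeping", {
  cfg <- sim_config(n_background_genes = 30,
                    planted_modules = list(planted_module(8, "bell", 0.8),
                                           planted_module(5, "rising", 0.8)),
                    paralog_events = tibble::tibble(ancestral = 1L,
                                                    children = 2L,
                                                    diverged = FALSE))
  sim <- simulate_expression(cfg)
  m <- sim$expression$spA
  expect_equal(nrow(m$values), 30 + 8 + 5 + 2)
  expect_equal(ncol(m$values), length(cfg$stages) * cfg$n_replicates)
  expect_true(all(m$values >= 0))
  # every planted-module gene appears in exactly one module
  expect_false(anyDuplicated(sim$truth$modules$core_id) > 0)
  # truth references only generated ids
  expect_true(all(sim$truth$genes$gene_id %in%
                    unlist(lapply(sim$expression, gene_ids))))
  # DE genes carry the stated mean offset in the stated species
  de <- sim$truth$de_genes[1, ]
  g_a <- paste0("spA_", de$core_id)
  g_b <- paste0(de$species, "_", de$core_id)
  la <- mean(log2(sim$expression$spA$values[g_a, ]))
  lb <- mean(log2(sim$expression[[de$species]]$values[g_b, ]))
  expect_equal(lb - la, de$log2fc, tolerance = 0.5)
})

test_that("fatty-acid trajectories invert the desaturation targets at the final stage", {
  cfg <- sim_config(omega6_de_target = 0.75, omega3_de_target = 0.6,
                    c18_pool = 0.8)
  fa <- simulate_fa_profiles(cfg)
  final <- fa[fa$species == "spA" & fa$stage_daf == max(fa$stage_daf) &
                fa$replicate == 1, ]
  expect_equal(final$`C18:1`, 0.2, tolerance = 1e-12)
  expect_equal(final$`C18:2`, 0.24, tolerance = 1e-12)
  expect_equal(final$`C18:3`, 0.36, tolerance = 1e-12)
  keys <- fa_keys()
  expect_equal(rowSums(as.matrix(fa[, keys])), rep(1, nrow(fa)),
               tolerance = 1e-9)
  # full conversion leaves no 18:1 or 18:2
  full <- sim_config(omega6_de_target = 1, omega3_de_target = 1)
  fa2 <- simulate_fa_profiles(full)
  last <- fa2[fa2$stage_daf == max(fa2$stage_daf), ]
  expect_true(all(last$`C18:1` == 0) && all(last$`C18:2` == 0))
})

test_that("similarity tables are truthful: no decoys means exact RBH recovery", {
  cfg <- sim_config(n_background_genes = 40,
                    planted_modules = list(planted_module(10, "bell", 0.8)))
  truth <- simulate_expression(cfg)$truth
  hits <- simulate_similarity_table(truth, decoy_rate = 0, seed = 3)
  expect_true(all(hits$identity >= 0 & hits$identity <= 1))
  expect_true(all(hits$coverage >= 0 & hits$coverage <= 1))
  rbh <- reciprocal_best_hits(hits, "spA", "spB")
  expected <- truth$orthology |>
    tidyr::pivot_wider(names_from = "species", values_from = "gene_id")
  expect_setequal(paste(rbh$gene_a, rbh$gene_b),
                  paste(expected$spA, expected$spB))
})

test_that("RBH recall stays high in the presence of decoy hits", {
  recall <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_background_genes = 90,
                      planted_modules = list(planted_module(10, "bell", 0.8)),
                      seed = seed)
    truth <- simulate_expression(cfg)$truth
    hits <- simulate_similarity_table(truth, decoy_rate = 0.3, seed = seed)
    rbh <- reciprocal_best_hits(hits, "spA", "spB")
    n_fam <- dplyr::n_distinct(truth$orthology$family)
    nrow(rbh) / n_fam
  }, numeric(1))
  expect_gte(mean(recall), 0.95)
})
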
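test_that("FPKM normalisation matches the closed formula", {
  v <- matrix(c(100, 1e7 - 100,
                0, 1e7), nrow = 2, byrow = FALSE)
  rownames(v) <- c("G1", "G2")
  m <- make_expr(v, n_stages = 1, unit = "count",
                 gene_lengths = c(G1 = 2000, G2 = 1000))
  f <- fpkm_normalize(m)
  expect_equal(f$values["G1", 1], 100 * 1e9 / (2000 * 1e7), tolerance = 1e-12)
  expect_equal(f$values["G1", 1], 5)
  expect_equal(f$values["G1", 2], 0)
  # a gene carrying the whole sample at length 1000 nt maps to 1e6
  expect_equal(f$values["G2", 2], 1e6, tolerance = 1e-12)
  expect_equal(f$unit, "fpkm")
})

test_that("FPKM preserves within-sample order for genes of equal length", {
  set.seed(1)
  v <- matrix(rpois(60, 50) + 1, nrow = 10)
  m <- make_expr(v, n_stages = 2, unit = "count",
                 gene_lengths = setNames(rep(1500, 10), sprintf("G%03d", 1:10)))
  f <- fpkm_normalize(m)
  for (j in 1:ncol(v)) expect_equal(order(f$values[, j]), order(v[, j]))
})

test_that("transcript collapsing sums members under the longest id", {
  v <- matrix(c(5, 5, 3, 3, 7, 7), nrow = 3, byrow = TRUE)
  rownames(v) <- c("A", "B", "C")
  m <- make_expr(v, n_stages = 1,
                 gene_lengths = c(A = 1200, B = 900, C = 2000))
  pairs <- tibble::tibble(query = "A", subject = "B",
                          identity = 0.95, coverage = 0.85)
  res <- collapse_transcripts(m, pairs)
  expect_setequal(gene_ids(res$matrix), c("A", "C"))
  expect_equal(unname(res$matrix$values["A", ]), c(8, 8))
  expect_equal(res$clusters$representative, "A")
  # total expression mass is conserved
  expect_equal(colSums(res$matrix$values), colSums(m$values))

  # below the coverage threshold nothing collapses
  low <- tibble::tibble(query = "A", subject = "B",
                        identity = 0.95, coverage = 0.70)
  expect_equal(gene_ids(collapse_transcripts(m, low)$matrix),
               c("A", "B", "C"))
  # an empty pair table is the identity
  none <- collapse_transcripts(m, pairs[0, ])
  expect_identical(none$matrix$values, m$values)
})

test_that("identical groups produce no differential calls", {
  v <- matrix(rep(c(4, 7, 2, 9, 5), each = 6), nrow = 5, byrow = TRUE)
  m <- make_expr(v, n_stages = 1)
  degs <- suppressWarnings(
    screen_degs(m, rep(c("a", "b"), each = 3), n_permutations = 50, seed = 1))
  expect_true(all(degs$log2fc == 0))
  expect_false(any(degs$is_de))
  expect_warning(
    screen_degs(m, rep(c("a", "b"), each = 3), n_permutations = 50, seed = 1),
    "100 permutations")
})

test_that("a strong planted fold-change is detected against a quiet background", {
  set.seed(9)
  n <- 200
  v <- 2^matrix(rnorm(n * 6, mean = 6, sd = 0.3), nrow = n)
  v[1, 4:6] <- v[1, 4:6] * 4
  rownames(v) <- sprintf("G%03d", 1:n)
  m <- make_expr(v, n_stages = 1)
  degs <- screen_degs(m, rep(c("a", "b"), each = 3),
                      n_permutations = 200, seed = 2)
  expect_true(degs$is_de[degs$gene_id == "G001"])
  expect_lt(degs$q[degs$gene_id == "G001"], 0.05)
  expect_equal(degs$log2fc[1], -2, tolerance = 0.5)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(31)
  n <- 2000
  v <- 2^matrix(rnorm(n * 6, mean = 6, sd = 0.5), nrow = n)
  m <- make_expr(v, n_stages = 1)
  degs <- screen_degs(m, rep(c("a", "b"), each = 3),
                      n_permutations = 100, seed = 4)
  ks <- suppressWarnings(stats::ks.test(degs$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(degs$p < 0.05), 0.03)
  expect_lt(mean(degs$p < 0.05), 0.07)
})

test_that("profile clustering separates planted dynamics", {
  cfg <- sim_config(n_species = 2, n_background_genes = 0,
                    planted_modules = list(planted_module(20, "bell", 0.9),
                                           planted_module(20, "rising", 0.9),
                                           planted_module(20, "falling", 0.9)),
                    de_genes = tibble::tibble(gene = integer(),
                                              species = integer(),
                                              log2fc = numeric()),
                    paralog_events = tibble::tibble(ancestral = integer(),
                                                    children = integer(),
                                                    diverged = logical()),
                    seed = 5)
  sim <- simulate_expression(cfg)
  m <- sim$expression$spA
  cl <- cluster_profiles(m, k = 3)
  truth <- sim$truth$genes$module[match(cl$gene_id,
                                        sim$truth$genes$gene_id)]
  expect_gte(ari(cl$cluster, truth), 0.9)
  # k equal to the gene count puts every gene alone
  solo <- cluster_profiles(m, k = nrow(m$values))
  expect_equal(length(unique(solo$cluster)), nrow(m$values))
  expect_error(cluster_profiles(m, k = nrow(m$values) + 1), "exceeds")
})

test_that("two exact profile archetypes split perfectly at k = 2", {
  base1 <- c(1, 5, 9, 5, 1)
  base2 <- c(9, 5, 1, 5, 9)
  v <- rbind(base1 * 1, base1 * 2, base1 * 3,
             base2 * 1, base2 * 2, base2 * 3)
  m <- make_expr(v, n_stages = 5)
  cl <- cluster_profiles(m, k = 2)
  expect_equal(length(unique(cl$cluster[1:3])), 1)
  expect_equal(length(unique(cl$cluster[4:6])), 1)
  expect_false(cl$cluster[1] == cl$cluster[4])
})

test_that("CV stability ranks constant genes first and undefined last", {
  v <- rbind(c(5, 5, 5, 5), c(1, 2, 3, 2), c(0, 0, 0, 0), c(2, 2, 2, 2))
  rownames(v) <- c("steady", "wobbly", "silent", "alsoSteady")
  m <- make_expr(v, n_stages = 1)
  cvs <- cv_stability(m)
  expect_equal(cvs$gene_id[1:2], c("alsoSteady", "steady"))  # CV tie -> id order
  expect_equal(cvs$cv[cvs$gene_id == "steady"], 0)
  expect_equal(cvs$gene_id[4], "silent")
  expect_true(is.na(cvs$cv[4]))
  # sample sd over mean: [1,2,3] -> 1/2
  m2 <- make_expr(matrix(c(1, 2, 3), 1), n_stages = 1)
  expect_equal(cv_stability(m2)$cv, 0.5, tolerance = 1e-12)
})
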
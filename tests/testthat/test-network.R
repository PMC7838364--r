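test_that("correlation matrix matches a direct covariance computation", {
  x <- c(1, 4, 2, 8, 5)
  y <- c(2, 1, 7, 3, 9)
  v <- rbind(x, y, 10 - x)
  rownames(v) <- c("gx", "gy", "gneg")
  r <- correlation_matrix(make_expr(v, n_stages = 5))
  expect_equal(diag(r), setNames(rep(1, 3), rownames(v)))
  expect_equal(r["gx", "gneg"], -1)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["gx", "gy"], manual, tolerance = 1e-12)

  vz <- rbind(x, flatGene = rep(3, 5))
  rownames(vz) <- c("gx", "flatGene")
  expect_error(correlation_matrix(make_expr(vz, n_stages = 5)), "flatGene")
})

test_that("soft thresholding maps correlations through ((1+r)/2)^beta", {
  r <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  a <- soft_threshold(r, 6)
  expect_equal(a["a", "c"], 0)           # r = -1
  expect_equal(a["a", "b"], 0.5^6)        # r = 0
  expect_equal(a["a", "b"], 0.015625, tolerance = 1e-12)
  expect_equal(diag(unclass(a)), setNames(rep(1, 3), letters[1:3]))
  # monotone decreasing in beta for r < 1, fixed at r = 1
  for (beta in c(1, 2, 4, 8)) {
    a1 <- soft_threshold(r, beta)
    a2 <- soft_threshold(r, beta + 1)
    expect_true(all(a2[r < 1] <= a1[r < 1]))
    expect_true(all(a2[r == 1] == 1))
  }
  expect_error(soft_threshold(r, 0), "positive")
})

test_that("beta selection honours the smallest-qualifying rule and its fallback", {
  cfg <- sim_config(seed = 3)
  sim <- simulate_expression(cfg)
  r <- correlation_matrix(
    make_expr(log2(sim$expression$spA$values + 1), n_stages = 5))
  betas <- seq(2, 20, by = 2)
  fits <- vapply(betas, function(b)
    oilnet:::scale_free_fit(soft_threshold(r, b)), numeric(1))
  # low target: first qualifying candidate is returned
  target <- stats::quantile(fits, 0.5, names = FALSE)
  bf <- pick_beta(r, betas, r2_target = target)
  expect_false(bf$fallback)
  expect_equal(bf$beta, betas[which(fits >= target)[1]])
  # unreachable target: argmax fit with the fallback flag
  bf2 <- pick_beta(r, betas, r2_target = 0.999)
  expect_true(bf2$fallback)
  expect_equal(bf2$beta, betas[which.max(fits)])
  # a single candidate meeting the target is returned as-is
  bf3 <- pick_beta(r, betas = 6, r2_target = min(fits))
  expect_equal(bf3$beta, 6)
  expect_error(pick_beta(r[1:10, 1:10], betas), "20 genes")
})

test_that("topological overlap matches hand evaluation and the brute-force oracle", {
  a <- matrix(0.5, 3, 3)
  diag(a) <- 1
  dimnames(a) <- list(letters[1:3], letters[1:3])
  tom <- tom_similarity(a)
  # (0.5*0.5 + 0.5) / (min(1,1) + 1 - 0.5)
  expect_equal(tom["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(diag(unclass(tom)), setNames(rep(1, 3), letters[1:3]))

  # identical binary neighbourhoods with a_ij = 1 give maximal overlap
  a2 <- matrix(0, 6, 6)
  a2[1, c(2, 3, 4)] <- a2[2, c(1, 3, 4)] <- 1
  a2[3, 1:2] <- a2[4, 1:2] <- 1
  a2 <- pmax(a2, t(a2)); diag(a2) <- 1
  dimnames(a2) <- list(letters[1:6], letters[1:6])
  expect_equal(tom_similarity(a2)["a", "b"], 1, tolerance = 1e-12)

  for (seed in 1:3) {
    a3 <- random_adjacency(40, seed = seed)
    expect_equal(unclass(tom_similarity(a3)), tom_oracle(a3),
                 tolerance = 1e-10)
  }
})

test_that("two planted TOM blocks are cut into exactly two pure modules", {
  n <- 60
  tm <- matrix(0.05, n, n)
  tm[1:30, 1:30] <- 0.9
  tm[31:60, 31:60] <- 0.9
  diag(tm) <- 1
  dimnames(tm) <- list(sprintf("G%03d", 1:n), sprintf("G%03d", 1:n))
  part <- cut_modules(tm, min_module_size = 10, cut_height = 0.5)
  truth <- rep(1:2, each = 30)
  expect_equal(ari(part$membership$module, truth), 1)
  expect_equal(max(part$membership$module), 2)

  # an isolated gene stays unassigned
  tm2 <- rbind(cbind(tm, iso = 0.01), iso = c(rep(0.01, n), 1))
  rownames(tm2) <- colnames(tm2) <- c(rownames(tm), "iso")
  part2 <- cut_modules(tm2, min_module_size = 10, cut_height = 0.5)
  expect_equal(part2$membership$module[part2$membership$gene_id == "iso"], 0)

  # a cut near 1 pools everything into one module
  part3 <- cut_modules(tm, min_module_size = 10, cut_height = 0.999)
  expect_equal(max(part3$membership$module), 1)
  expect_equal(sum(part3$membership$module == 1), n)
  expect_error(cut_modules(tm, min_module_size = 10, cut_height = 1.5),
               "cut_height")
})

test_that("eigengenes are unit-norm, sign-anchored leading components", {
  prof <- c(1, 3, 7, 3, 1)
  v <- rbind(prof * 2 + 1, prof * 5 + 2, prof * 0.5)
  rownames(v) <- c("g1", "g2", "g3")
  m <- make_expr(v, n_stages = 5)
  part <- tibble::tibble(gene_id = rownames(v), module = 1L)
  es <- module_eigengene(m, part)
  e <- es$eigengenes[, 1]
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
  z <- scale(prof)[, 1]
  expect_equal(abs(cor(e, z)), 1, tolerance = 1e-9)
  expect_gte(cor(e, z), 0)  # anchored to the (rising-bell) mean profile

  # a profile and its negation: first component carries all variance
  v2 <- rbind(g1 = prof, g2 = -prof + 10)
  m2 <- make_expr(v2, n_stages = 5)
  es2 <- module_eigengene(m2, tibble::tibble(gene_id = c("g1", "g2"),
                                             module = 1L))
  expect_equal(unname(es2$var_explained), 1, tolerance = 1e-12)

  # SVD leading vector agrees with an independent eigen-decomposition
  set.seed(12)
  v3 <- matrix(rexp(100), 10)
  rownames(v3) <- sprintf("G%03d", 1:10)
  m3 <- make_expr(v3, n_stages = 5)
  es3 <- module_eigengene(m3, tibble::tibble(gene_id = rownames(v3),
                                             module = 1L))
  z3 <- t(scale(t(v3)))
  ev <- eigen(crossprod(z3))$vectors[, 1]
  expect_equal(abs(sum(es3$eigengenes[, 1] * ev)), 1, tolerance = 1e-8)
})

test_that("eigengene-similar modules merge transitively", {
  prof1 <- c(1, 2, 6, 2, 1)
  set.seed(3)
  mk <- function(base, n) t(replicate(n, base * runif(1, 0.5, 2) +
                                        rnorm(5, 0, 0.01)))
  v <- rbind(mk(prof1, 5), mk(prof1, 5), mk(rev(prof1) * c(1,1,0.1,1,1), 5))
  rownames(v) <- sprintf("G%03d", 1:15)
  m <- make_expr(v, n_stages = 5)
  part <- structure(list(
    membership = tibble::tibble(gene_id = rownames(v),
                                module = rep(1:3, each = 5)),
    sizes = tibble::tibble(module = 1:3, size = 5),
    hclust = NULL, cut_height = 0.93, min_module_size = 3
  ), class = "module_partition")
  # modules 1 and 2 share a profile; module 3 is unrelated
  merged <- merge_similar_modules(m, part, merge_correlation = 0.9)
  mm <- merged$membership$module
  expect_equal(mm[1:5], mm[6:10])
  expect_false(mm[1] == mm[11])
  expect_equal(max(mm), 2)

  # uncorrelated eigengenes stay apart at any threshold below 1
  merged2 <- merge_similar_modules(m, part, merge_correlation = 0.99)
  expect_equal(max(merged2$membership$module), 2)
})

test_that("module merging is transitive along a chain of similar eigengenes", {
  # three module profiles at 40 degrees apart in a centred plane:
  # cor(1,2) = cor(2,3) = cos(40) ~ 0.77, cor(1,3) = cos(80) ~ 0.17
  u <- c(-2, -1, 0, 1, 2) / sqrt(10)
  w <- c(1, -2, 0, 2, -1) / sqrt(10)
  th <- 40 * pi / 180
  profs <- list(u,
                cos(th) * u + sin(th) * w,
                cos(2 * th) * u + sin(2 * th) * w)
  set.seed(6)
  v <- do.call(rbind, lapply(profs, function(p) {
    t(replicate(4, 10 + p * runif(1, 2, 4)))
  }))
  rownames(v) <- sprintf("G%03d", 1:12)
  m <- make_expr(v, n_stages = 5)
  part <- structure(list(
    membership = tibble::tibble(gene_id = rownames(v),
                                module = rep(1:3, each = 4)),
    sizes = tibble::tibble(module = 1:3, size = 4),
    hclust = NULL, cut_height = 0.93, min_module_size = 3
  ), class = "module_partition")
  merged <- merge_similar_modules(m, part, merge_correlation = 0.7)
  expect_equal(max(merged$membership$module), 1)  # all three united
})

test_that("gene order does not change the network, only its labels", {
  cfg <- sim_config(n_species = 2, n_background_genes = 40,
                    planted_modules = list(planted_module(15, "bell", 0.9)),
                    seed = 21)
  m <- oilnet:::log_transform(simulate_expression(cfg)$expression$spA)
  r <- correlation_matrix(m)
  tom <- tom_similarity(soft_threshold(r, 18))
  part <- cut_modules(tom, min_module_size = 10, cut_height = 0.93)

  perm <- sample(nrow(m$values))
  mp <- expr_matrix(m$values[perm, ], m$samples, unit = m$unit)
  tomp <- tom_similarity(soft_threshold(correlation_matrix(mp), 18))
  expect_equal(unclass(tomp), unclass(tom)[perm, perm], tolerance = 1e-12)
  partp <- cut_modules(tomp, min_module_size = 10, cut_height = 0.93)
  j <- dplyr::inner_join(part$membership, partp$membership, by = "gene_id")
  expect_equal(ari(j$module.x, j$module.y), 1)
})

test_that("edge lists keep only the heavy upper-triangle edges", {
  a <- random_adjacency(6, seed = 2)
  tom <- tom_similarity(a)
  el <- edge_list(tom, weight_floor = 0.4)
  tm <- unclass(tom)
  expect_true(all(el$weight >= 0.4))
  expect_equal(nrow(el), sum(tm[upper.tri(tm)] >= 0.4))
})
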
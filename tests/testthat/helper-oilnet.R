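# fixture builders and independent oracles used across the suite

# small expr_matrix from a plain matrix; one species, stages 1..n_stages
make_expr <- function(values, n_stages = NULL, species = "spA",
                      unit = "fpkm", gene_lengths = NULL) {
  n <- ncol(values)
  n_stages <- n_stages %||% n
  reps <- n / n_stages
  stopifnot(reps == round(reps))
  stage <- rep(seq_len(n_stages) * 10, each = reps)
  repl <- rep(seq_len(reps), times = n_stages)
  ids <- paste(species, stage, repl, sep = ".")
  colnames(values) <- ids
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  }
  expr_matrix(values,
              tibble::tibble(sample = ids, species = species,
                             stage_daf = stage, replicate = repl),
              unit = unit, gene_lengths = gene_lengths)
}

# random symmetric adjacency with unit diagonal, entries in [0, 1]
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("G%03d", 1:n), sprintf("G%03d", 1:n))
  a
}

# brute-force topological overlap: element-by-element triple loop
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n, dimnames = dimnames(a))
  k <- numeric(n)
  for (i in 1:n) k[i] <- sum(a[i, -i])
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# brute-force reciprocal best hits: double argmax with identity tie-break,
# remaining ties disqualify the gene
rbh_oracle <- function(hits, sa, sb) {
  best_of <- function(qs, ss) {
    sub <- hits[hits$qspecies == qs & hits$sspecies == ss, ]
    res <- list()
    for (q in unique(sub$query)) {
      rows <- sub[sub$query == q, ]
      rows <- rows[rows$score == max(rows$score), ]
      rows <- rows[rows$identity == max(rows$identity), ]
      if (nrow(rows) == 1) res[[q]] <- rows$subject
    }
    res
  }
  ab <- best_of(sa, sb)
  ba <- best_of(sb, sa)
  pairs <- list()
  for (a in names(ab)) {
    b <- ab[[a]]
    if (!is.null(ba[[b]]) && ba[[b]] == a) pairs[[a]] <- b
  }
  if (!length(pairs)) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  out <- tibble::tibble(gene_a = names(pairs),
                        gene_b = unlist(pairs, use.names = FALSE))
  out[order(out$gene_a), ]
}

# exact combinatorial upper tail of the hypergeometric overlap
hyper_oracle <- function(overlap, N, K, n) {
  ks <- overlap:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# adjusted Rand index against planted truth (independent implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random directed cross-species score table (both directions, independent
# scores); rounding injects occasional ties
random_hits <- function(na, nb, seed, digits = 1) {
  set.seed(seed)
  a_ids <- sprintf("A%02d", 1:na)
  b_ids <- sprintf("B%02d", 1:nb)
  ab <- expand.grid(query = a_ids, subject = b_ids,
                    stringsAsFactors = FALSE)
  ba <- expand.grid(query = b_ids, subject = a_ids,
                    stringsAsFactors = FALSE)
  tibble::tibble(
    query = c(ab$query, ba$query),
    subject = c(ab$subject, ba$subject),
    qspecies = rep(c("a", "b"), c(nrow(ab), nrow(ba))),
    sspecies = rep(c("b", "a"), c(nrow(ab), nrow(ba))),
    score = round(runif(nrow(ab) + nrow(ba), 10, 100), digits),
    identity = round(runif(nrow(ab) + nrow(ba), 0.3, 1), 2),
    coverage = runif(nrow(ab) + nrow(ba), 0.3, 1)
  )
}

# orthology-truth skeleton for conservation fixtures: n one-to-one families
# across the given species
make_orthology_truth <- function(n, species = c("spA", "spB", "spC")) {
  fam <- sprintf("g%04d", seq_len(n))
  list(orthology = tidyr::expand_grid(family = fam, species = species) |>
         dplyr::mutate(gene_id = paste0(species, "_", family)))
}
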
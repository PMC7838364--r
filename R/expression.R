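#' FPKM normalisation of a count matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fpkm = count * 1e9 / (length_nt * sample_total_count)`.
#'
#' @param m An [expr_matrix()] with `unit = "count"` and gene lengths.
#' @return An `expr_matrix` with `unit = "fpkm"`.
#' @export
fpkm_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "count") stop_oilnet("`m` must have unit = \"count\"")
  if (is.null(m$gene_lengths)) stop_oilnet("gene lengths required for FPKM")
  if (any(m$gene_lengths <= 0)) stop_oilnet("zero-length gene")
  totals <- colSums(m$values)
  if (any(totals <= 0)) stop_oilnet("each sample needs total mapped count > 0")
  fpkm <- sweep(m$values, 1, m$gene_lengths, "/")
  fpkm <- sweep(fpkm, 2, totals, "/") * 1e9
  expr_matrix(fpkm, m$samples, unit = "fpkm", gene_lengths = m$gene_lengths)
}

#' Collapse near-identical transcripts into clusters
#'
#' Single-linkage connected components over similarity pairs passing the
#' identity and coverage thresholds become transcript clusters; each cluster
#' contributes one row — the element-wise sum of member expression — under
#' the longest member's id. Non-clustered genes pass through unchanged.
#'
#' @param m An [expr_matrix()] with gene lengths.
#' @param pairs Data frame of within-species similarity records with columns
#'   `query`, `subject`, `identity`, `coverage` (fractions in \[0, 1\]).
#' @param identity_min,coverage_min Thresholds a pair must reach to qualify;
#'   defaults 0.90 and 0.80.
#' @return List with `matrix` (collapsed `expr_matrix`) and `clusters`
#'   (tibble: `representative`, `members`, `n_members`).
#' @export
collapse_transcripts <- function(m, pairs, identity_min = 0.90,
                                 coverage_min = 0.80) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$gene_lengths)) {
    stop_oilnet("gene lengths required to pick cluster representatives")
  }
  pairs <- as_tibble(pairs)
  if (nrow(pairs)) {
    bad <- setdiff(unique(c(pairs$query, pairs$subject)), gene_ids(m))
    if (length(bad)) {
      stop_oilnet(paste0("pairs reference unknown genes: ",
                         paste(head(bad, 5), collapse = ", ")))
    }
  }
  keep <- pairs$identity >= identity_min & pairs$coverage >= coverage_min &
    pairs$query != pairs$subject
  edges <- pairs[keep, c("query", "subject")]
  if (!nrow(edges)) {
    return(list(matrix = m,
                clusters = tibble(representative = character(),
                                  members = list(), n_members = integer())))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)

  values <- m$values
  lengths <- m$gene_lengths
  drop_ids <- character()
  clusters <- purrr::map_dfr(membership, function(members) {
    members <- sort(members)
    rep_id <- members[which.max(lengths[members])]
    summed <- colSums(values[members, , drop = FALSE])
    values[rep_id, ] <<- summed
    drop_ids <<- c(drop_ids, setdiff(members, rep_id))
    tibble(representative = rep_id, members = list(members),
           n_members = length(members))
  })
  keep_ids <- setdiff(rownames(values), drop_ids)
  out <- expr_matrix(values[keep_ids, , drop = FALSE], m$samples,
                     unit = m$unit, gene_lengths = lengths[keep_ids])
  list(matrix = out, clusters = clusters)
}

#' Permutation screen for differentially expressed genes
#'
#' Per gene: log2 fold-change of group means on a pseudocounted scale, a
#' permutation p-value from shuffling group labels, Benjamini-Hochberg
#' adjusted q and a significance flag. The permutation null is pooled across
#' genes (the null statistics of all genes over all label shuffles form one
#' reference distribution), which is calibrated under a homogeneous null and
#' retains power at small replicate numbers where a per-gene label shuffle
#' has too few distinct values.
#'
#' @param m An [expr_matrix()].
#' @param groups Character (or factor) vector over the columns of `m` with
#'   exactly two non-NA levels; `NA` columns are dropped.
#' @param n_permutations Number of label shuffles; values below 100 trigger
#'   a warning but are still computed.
#' @param q_threshold BH-adjusted significance threshold for `is_de`.
#' @param pseudocount Added before log2 (stabilises fold-changes at zero).
#' @param seed Optional integer seed for the shuffles.
#' @return Tibble: `gene_id`, `log2fc`, `p`, `q`, `is_de`, with attribute
#'   `"contrast"` naming the two groups (A vs B; log2fc = A - B).
#' @export
screen_degs <- function(m, groups, n_permutations = 1000, q_threshold = 0.05,
                        pseudocount = 1, seed = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  groups <- as.character(groups)
  if (length(groups) != ncol(m$values)) {
    stop_oilnet("`groups` must have one entry per sample")
  }
  keep <- !is.na(groups)
  lev <- unique(groups[keep])
  if (length(lev) != 2) stop_oilnet("`groups` must have exactly two levels")
  ga <- which(keep & groups == lev[1])
  gb <- which(keep & groups == lev[2])
  if (length(ga) < 2 || length(gb) < 2) {
    stop_oilnet("each group needs >= 2 samples for the permutation screen")
  }
  if (n_permutations < 100) {
    warn("fewer than 100 permutations gives a coarse null; computing anyway")
  }
  if (!is.null(seed)) set.seed(seed)

  lm2 <- log2(m$values[, c(ga, gb), drop = FALSE] + pseudocount)
  na <- length(ga)
  nn <- ncol(lm2)
  obs <- rowMeans(lm2[, seq_len(na), drop = FALSE]) -
    rowMeans(lm2[, (na + 1):nn, drop = FALSE])

  # shuffles reproducing the observed grouping (or its complement) are
  # rejected: they would re-create every true effect inside the null pool
  # and put an artificial floor on the adjusted q of genuine signals
  orig_a <- seq_len(na)
  orig_b <- (na + 1):nn
  null_stats <- matrix(0, nrow(lm2), n_permutations)
  for (b in seq_len(n_permutations)) {
    repeat {
      idx <- sample.int(nn)
      grp_a <- sort(idx[seq_len(na)])
      if (!identical(grp_a, orig_a) &&
          !(na == nn - na && identical(grp_a, orig_b))) break
    }
    null_stats[, b] <- rowMeans(lm2[, idx[seq_len(na)], drop = FALSE]) -
      rowMeans(lm2[, idx[(na + 1):nn], drop = FALSE])
  }
  null_abs <- sort(abs(as.vector(null_stats)))
  n_null <- length(null_abs)
  # p = (1 + #{|null| >= |obs|}) / (n_null + 1), via binary search
  ge_count <- n_null - findInterval(abs(obs) - 1e-12, null_abs)
  p <- (1 + ge_count) / (n_null + 1)
  q <- p.adjust(p, method = "BH")
  out <- tibble(gene_id = rownames(lm2), log2fc = unname(obs),
                p = unname(p), q = unname(q), is_de = q < q_threshold)
  attr(out, "contrast") <- lev
  out
}

#' Cluster expression dynamics into k profile groups
#'
#' Per-gene stage-mean profiles are z-scored (shape, not level, drives the
#' grouping) and clustered agglomeratively with average linkage on
#' 1 - Pearson correlation distance, cut to exactly `k` clusters.
#'
#' @param m An [expr_matrix()].
#' @param k Number of clusters (1 <= k <= number of genes).
#' @return Tibble: `gene_id`, `cluster` (integer labels 1..k).
#' @export
cluster_profiles <- function(m, k) {
  stopifnot(inherits(m, "expr_matrix"))
  k <- check_count(k, "k", 1L)
  prof <- stage_means(m)
  if (k > nrow(prof)) stop_oilnet("k exceeds the number of genes")
  z <- t(scale(t(prof)))
  if (any(!is.finite(z))) {
    stop_oilnet("zero-variance gene profile cannot be standardised")
  }
  if (k == nrow(prof)) {
    return(tibble(gene_id = rownames(prof), cluster = seq_len(k)))
  }
  d <- as.dist(1 - cor(t(z)))
  hc <- hclust(d, method = "average")
  tibble(gene_id = rownames(prof), cluster = unname(cutree(hc, k = k)))
}

#' Rank genes by expression stability (coefficient of variation)
#'
#' CV = sample standard deviation / mean across all samples; candidates are
#' ranked ascending (most stable first). A zero-mean gene has undefined CV
#' and is ranked last. Ties break by gene id.
#'
#' @param m An [expr_matrix()].
#' @param candidates Gene ids to rank; default all genes.
#' @return Tibble: `gene_id`, `cv`, `rank`.
#' @export
cv_stability <- function(m, candidates = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  candidates <- candidates %||% gene_ids(m)
  absent <- setdiff(candidates, gene_ids(m))
  if (length(absent)) {
    stop_oilnet(paste0("candidates not in matrix: ",
                       paste(head(absent, 5), collapse = ", ")))
  }
  v <- m$values[candidates, , drop = FALSE]
  cvs <- apply(v, 1, cv)
  out <- tibble(gene_id = candidates, cv = unname(cvs)) |>
    dplyr::arrange(!is.finite(.data$cv) | is.na(.data$cv), .data$cv,
                   .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}
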
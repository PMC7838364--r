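#' Pairwise Pearson correlation matrix of genes
#'
#' @param m An [expr_matrix()] or a numeric genes-by-samples matrix.
#' @return Symmetric correlation matrix (genes x genes), diagonal 1.
#' @export
correlation_matrix <- function(m) {
  v <- if (inherits(m, "expr_matrix")) m$values else m
  if (ncol(v) < 3) stop_oilnet("need >= 3 samples for correlations")
  vars <- apply(v, 1, stats::var)
  if (any(vars == 0)) {
    stop_oilnet(paste0("zero-variance gene(s): ",
                       paste(head(rownames(v)[vars == 0], 5), collapse = ", ")))
  }
  r <- cor(t(v))
  diag(r) <- 1
  r
}

#' Soft-threshold a correlation matrix into a weighted adjacency
#'
#' The signed adjacency `a_ij = ((1 + r_ij) / 2) ^ beta`: perfect positive
#' correlation maps to 1, perfect anti-correlation to 0, and the
#' soft-thresholding power beta accentuates strong correlations while
#' preserving the continuous connectivity structure.
#'
#' @param r Correlation matrix in \[-1, 1\].
#' @param beta Soft-thresholding power (> 0).
#' @return Adjacency matrix (class `adjacency`, attribute `beta`), diagonal 1.
#' @export
soft_threshold <- function(r, beta) {
  if (beta <= 0) stop_oilnet("`beta` must be positive")
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  structure(a, beta = beta, class = c("adjacency", "matrix", "array"))
}

# scale-free topology fit: r^2 of the log-log regression of the binned
# connectivity distribution
scale_free_fit <- function(adj, n_bins = 10) {
  k <- colSums(adj) - 1
  if (length(unique(k)) < 3) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  summary(fit)$r.squared
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate beta the adjacency is formed and the scale-free fit
#' index computed (r^2 of the regression of log10 frequency on log10 mean
#' connectivity over binned connectivities). The smallest beta reaching
#' `r2_target` is chosen; if none qualifies, the beta with maximal fit is
#' returned with `fallback = TRUE`.
#'
#' @param r Correlation matrix (>= 20 genes).
#' @param betas Candidate powers; default 2, 4, ..., 20.
#' @param r2_target Scale-free fit target; default 0.8.
#' @param n_bins Connectivity bins for the fit.
#' @return Object of class `beta_fit`: list with `beta`, `fallback`, `fits`
#'   (tibble beta/r2/mean_k) and `r2_target`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
pick_beta <- function(r, betas = seq(2, 20, by = 2), r2_target = 0.8,
                      n_bins = 10) {
  if (length(betas) < 1) stop_oilnet("need >= 1 candidate beta")
  if (nrow(r) < 20) stop_oilnet("scale-free fit unreliable below 20 genes")
  betas <- sort(betas)
  fits <- purrr::map_dfr(betas, function(b) {
    a <- soft_threshold(r, b)
    tibble(beta = b, r2 = scale_free_fit(a, n_bins),
           mean_k = mean(colSums(a) - 1))
  })
  ok <- which(!is.na(fits$r2) & fits$r2 >= r2_target)
  if (length(ok)) {
    beta <- fits$beta[ok[1]]
    fallback <- FALSE
  } else {
    beta <- fits$beta[which.max(fits$r2)]
    fallback <- TRUE
  }
  structure(list(beta = beta, fallback = fallback, fits = fits,
                 r2_target = r2_target),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("<beta_fit> chosen beta = %g%s (target r2 = %g)\n", x$beta,
              if (x$fallback) " [fallback: no candidate met the target]" else "",
              x$r2_target))
  invisible(x)
}

#' Topological overlap matrix
#'
#' Converts a weighted adjacency into topological-overlap similarity:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu` and the sum running over
#' `u != i, j`. Two genes score high when they share the same network
#' neighbourhood, not merely when they correlate directly. Diagonal is 1.
#'
#' @param a Adjacency matrix (entries in \[0, 1\], symmetric).
#' @return TOM similarity matrix (class `tom`).
#' @export
tom_similarity <- function(a) {
  a <- unclass(a)
  n <- nrow(a)
  if (n == 1) {
    return(structure(matrix(1, 1, 1, dimnames = dimnames(a)), class = c("tom", "matrix", "array")))
  }
  a0 <- a
  diag(a0) <- 0
  k <- colSums(a0)
  shared <- a0 %*% a0            # (i,j): sum over u != i, j of a_iu a_uj
  num <- shared + a0
  den <- outer(k, k, pmin) + 1 - a0
  tom <- matrix(num / den, n, n, dimnames = dimnames(a))
  diag(tom) <- 1
  structure(tom, class = c("tom", "matrix", "array"))
}

#' Cut a TOM dendrogram into modules
#'
#' Genes are clustered by average linkage on the dissimilarity 1 - TOM and
#' the tree is cut statically at `cut_height`; branches smaller than
#' `min_module_size` are left unassigned (module 0). This is a deterministic
#' simplification of dynamic tree cutting: a fixed cut plus a minimum-size
#' filter. Modules are labelled 1, 2, ... in decreasing size order.
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size Smallest branch kept as a module (>= 3); default 30.
#' @param cut_height Dissimilarity cut in (0, 1); default 0.93, just below
#'   the heights at which unstructured genes agglomerate in sparse
#'   high-power networks.
#' @return Object of class `module_partition`: list with `membership`
#'   (tibble `gene_id`, `module`), `sizes`, `hclust`, `cut_height`,
#'   `min_module_size`.
#' @export
cut_modules <- function(tom, min_module_size = 30, cut_height = 0.93) {
  min_module_size <- check_count(min_module_size, "min_module_size", 3L)
  cut_height <- cut_height %||% 0.93
  d <- 1 - unclass(tom)
  hc <- hclust(as.dist(d), method = "average")
  # average linkage is monotone; sorting only removes floating-point
  # inversions between tied merge heights
  if (is.unsorted(hc$height)) hc$height <- sort(hc$height)
  if (cut_height <= 0 || cut_height >= 1) {
    stop_oilnet("`cut_height` must be in (0, 1)")
  }
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  # decreasing size, ties by first appearance, labels 1..K
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  membership <- tibble(gene_id = rownames(unclass(tom)), module = labels)
  structure(list(
    membership = membership,
    sizes = membership |> dplyr::count(.data$module, name = "size"),
    hclust = hc, cut_height = cut_height, min_module_size = min_module_size
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  nz <- dplyr::filter(x$sizes, .data$module != 0)
  cat(sprintf("<module_partition> %d modules over %d genes (%d unassigned)\n",
              nrow(nz), nrow(x$membership),
              sum(x$membership$module == 0)))
  invisible(x)
}

# internal: named list module label -> gene ids (module 0 dropped)
module_gene_list <- function(partition) {
  mm <- dplyr::filter(partition$membership, .data$module != 0)
  split(mm$gene_id, mm$module)
}

#' Module eigengenes
#'
#' The eigengene of a module is the leading left-singular direction over
#' samples of the module's gene-standardised expression submatrix — its
#' representative profile. Each eigengene has unit Euclidean norm and its
#' sign is anchored so that it correlates non-negatively with the module's
#' mean standardised profile.
#'
#' @param m An [expr_matrix()] covering the partitioned genes.
#' @param partition A `module_partition` (or a tibble `gene_id`/`module`).
#' @return Object of class `eigengene_set`: list with `eigengenes` (samples
#'   x modules matrix), `var_explained` (per module) and `samples`.
#' @export
module_eigengene <- function(m, partition) {
  stopifnot(inherits(m, "expr_matrix"))
  mods <- if (inherits(partition, "module_partition")) {
    module_gene_list(partition)
  } else {
    mm <- dplyr::filter(as_tibble(partition), .data$module != 0)
    split(mm$gene_id, mm$module)
  }
  if (!length(mods)) stop_oilnet("partition has no modules")
  eg <- matrix(0, ncol(m$values), length(mods),
               dimnames = list(colnames(m$values), names(mods)))
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    genes <- mods[[i]]
    if (length(genes) < 2) stop_oilnet("module size must be >= 2")
    x <- m$values[genes, , drop = FALSE]
    z <- t(scale(t(x)))
    if (any(!is.finite(z))) {
      stop_oilnet("module contains a zero-variance gene")
    }
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    cm <- colMeans(z)
    s <- if (sd(cm) > 0) cor(e, cm) else e[which.max(abs(e))]
    if (!is.na(s) && s < 0) e <- -e
    eg[, i] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = eg, var_explained = setNames(ve, names(mods)),
                 samples = m$samples),
            class = "eigengene_set")
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengenes correlate at or above `merge_correlation` are
#' merged, transitively (connected components of the eigengene-correlation
#' graph). Eigengenes of merged modules are recomputed. Merged modules are
#' relabelled 1, 2, ... in decreasing size order.
#'
#' @param m An [expr_matrix()].
#' @param partition A `module_partition`.
#' @param merge_correlation Correlation threshold; default 0.75.
#' @return A `module_partition` with an `eigengenes` element holding the
#'   recomputed [module_eigengene()] set and a `merge_map` tibble
#'   (`old_module` -> `module`).
#' @export
merge_similar_modules <- function(m, partition, merge_correlation = 0.75) {
  stopifnot(inherits(partition, "module_partition"))
  check_fraction(merge_correlation, "merge_correlation")
  es <- module_eigengene(m, partition)
  labels <- colnames(es$eigengenes)
  if (length(labels) > 1) {
    ec <- cor(es$eigengenes)
    adj <- (ec >= merge_correlation)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
  } else {
    comp <- setNames(1L, labels)
  }
  old <- partition$membership
  new_label_of <- setNames(comp[match(as.character(old$module), labels)],
                           NULL)
  new_label_of[old$module == 0] <- 0L
  merged <- dplyr::mutate(old, module = as.integer(new_label_of))
  # relabel by decreasing size
  sz <- merged |> dplyr::filter(.data$module != 0) |>
    dplyr::count(.data$module, sort = TRUE)
  relab <- setNames(seq_len(nrow(sz)), sz$module)
  merged$module <- ifelse(merged$module == 0, 0L,
                          as.integer(relab[as.character(merged$module)]))
  out <- structure(list(
    membership = merged,
    sizes = merged |> dplyr::count(.data$module, name = "size"),
    hclust = partition$hclust, cut_height = partition$cut_height,
    min_module_size = partition$min_module_size
  ), class = "module_partition")
  out$eigengenes <- module_eigengene(m, out)
  out$merge_map <- tibble(old_module = old$module, module = merged$module) |>
    dplyr::distinct()
  out
}

#' Export a weighted edge list from a TOM
#'
#' Writes (or returns) the upper-triangle edges with TOM weight at or above
#' `weight_floor`, the form external network viewers ingest.
#'
#' @param tom TOM matrix.
#' @param weight_floor Minimum weight retained.
#' @param path Optional TSV path; when given, the tibble is also written.
#' @return Tibble `gene1`, `gene2`, `weight` (invisibly when written).
#' @export
edge_list <- function(tom, weight_floor = 0.1, path = NULL) {
  tm <- unclass(tom)
  idx <- which(upper.tri(tm) & tm >= weight_floor, arr.ind = TRUE)
  out <- tibble(gene1 = rownames(tm)[idx[, 1]],
                gene2 = colnames(tm)[idx[, 2]],
                weight = tm[idx]) |>
    dplyr::arrange(dplyr::desc(.data$weight))
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}
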
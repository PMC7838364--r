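#' Select and merge the oil-biosynthesis module
#'
#' Modules that contain at least one pathway seed gene (core fatty-acid
#' synthesis enzymes) and whose eigengene correlates at or above
#' `pattern_correlation` with the eigengene of the seed-richest module are
#' united into a single oil-biosynthesis gene set.
#'
#' @param partition A `module_partition`.
#' @param eigengenes Matching [module_eigengene()] set.
#' @param seed_genes Character vector of pathway seed gene ids.
#' @param pattern_correlation Eigengene-correlation threshold; default 0.75.
#' @return Tibble `gene_id`, `module` of the merged oil module; attribute
#'   `"selected_modules"` lists the module labels united.
#' @export
select_oil_module <- function(partition, eigengenes, seed_genes,
                              pattern_correlation = 0.75) {
  stopifnot(inherits(partition, "module_partition"))
  mm <- partition$membership
  seeded <- dplyr::filter(mm, .data$gene_id %in% seed_genes,
                          .data$module != 0)
  if (!nrow(seeded)) {
    stop_oilnet("no seed gene is assigned to any module")
  }
  seed_counts <- dplyr::count(seeded, .data$module, sort = TRUE)
  anchor <- seed_counts$module[1]
  candidates <- seed_counts$module
  eg <- eigengenes$eigengenes
  keep <- vapply(candidates, function(mod) {
    mod == anchor ||
      cor(eg[, as.character(mod)], eg[, as.character(anchor)]) >=
        pattern_correlation
  }, logical(1))
  selected <- candidates[keep]
  out <- dplyr::filter(mm, .data$module %in% selected)
  attr(out, "selected_modules") <- selected
  out
}

#' Permutation test of module cohesion
#'
#' The observed statistic is the mean (or median) off-diagonal TOM within
#' the module; the null distribution is the same statistic on random gene
#' sets of equal size drawn from the network. The p-value uses the add-one
#' rule `p = (1 + #{null >= observed}) / (n_permutations + 1)`, so it is
#' never exactly zero.
#'
#' @param tom TOM matrix of the full network.
#' @param module Character vector of module gene ids (>= 2, all in the TOM).
#' @param n_permutations Number of random draws; default 5000.
#' @param seed Integer seed.
#' @param statistic `"mean"` (default) or `"median"` intramodular TOM.
#' @return Object of class `module_validation`: list with `statistic`,
#'   `statistic_name`, `p`, `n_permutations`, `module_size`, `null_mean`.
#' @export
permutation_robustness <- function(tom, module, n_permutations = 5000,
                                   seed = 1, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  tm <- unclass(tom)
  absent <- setdiff(module, rownames(tm))
  if (length(absent)) {
    stop_oilnet(paste0("module genes absent from network: ",
                       paste(head(absent, 5), collapse = ", ")))
  }
  if (length(module) < 2) stop_oilnet("module size must be >= 2")
  n_permutations <- check_count(n_permutations, "n_permutations", 1L)
  stat_fun <- if (statistic == "mean") mean else stats::median
  intra <- function(ids) {
    sub <- tm[ids, ids]
    stat_fun(sub[upper.tri(sub)])
  }
  observed <- intra(module)
  set.seed(seed)
  k <- length(module)
  all_ids <- rownames(tm)
  null_stats <- vapply(seq_len(n_permutations), function(i) {
    intra(sample(all_ids, k))
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (n_permutations + 1)
  structure(list(statistic = observed, statistic_name = statistic, p = p,
                 n_permutations = n_permutations, module_size = k,
                 null_mean = mean(null_stats)),
            class = "module_validation")
}

#' @export
print.module_validation <- function(x, ...) {
  cat(sprintf(
    "<module_validation> %s intramodular TOM = %.4f (null mean %.4f), p = %.3g [%d permutations]\n",
    x$statistic_name, x$statistic, x$null_mean, x$p, x$n_permutations))
  invisible(x)
}

#' Hypergeometric gene-set test
#'
#' Upper-tail probability of observing at least the given overlap between a
#' module and an annotated gene set drawn from a background of
#' `background_size` genes: `P(X >= overlap)` with X hypergeometric.
#'
#' @param module Character vector of module gene ids.
#' @param annotated Character vector of annotated gene ids.
#' @param background_size Total background gene count (>= union size).
#' @return Single numeric p-value.
#' @export
hypergeometric_test <- function(module, annotated, background_size) {
  module <- unique(module)
  annotated <- unique(annotated)
  background_size <- check_count(background_size, "background_size", 1L)
  if (background_size < length(union(module, annotated))) {
    stop_oilnet("background smaller than the union of the two sets")
  }
  overlap <- length(intersect(module, annotated))
  phyper(overlap - 1, length(annotated),
         background_size - length(annotated), length(module),
         lower.tail = FALSE)
}

#' Term enrichment over a collection of gene sets
#'
#' Applies [hypergeometric_test()] to each term of a caller-supplied
#' term-to-genes map and corrects across terms by Benjamini-Hochberg.
#'
#' @param module Character vector of module gene ids.
#' @param term_sets Named list: term -> character vector of gene ids.
#' @param background_size Total background gene count.
#' @return Tibble: `term`, `term_size`, `overlap`, `p`, `q`, sorted by `p`.
#' @export
enrich_gene_sets <- function(module, term_sets, background_size) {
  if (!length(term_sets) || is.null(names(term_sets))) {
    stop_oilnet("`term_sets` must be a non-empty named list")
  }
  out <- purrr::imap_dfr(term_sets, function(genes, term) {
    tibble(term = term, term_size = length(unique(genes)),
           overlap = length(intersect(module, genes)),
           p = hypergeometric_test(module, genes, background_size))
  })
  dplyr::arrange(dplyr::mutate(out, q = p.adjust(.data$p, "BH")), .data$p)
}
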
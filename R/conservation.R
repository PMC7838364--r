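#' Genes conservatively co-expressed across species
#'
#' Starting from each species' oil-module gene set and the orthogroup
#' clustering, returns the focal-species module genes whose orthogroup also
#' contains oil-module members from every other species — the genes whose
#' pathway co-expression is conserved across the species compared.
#'
#' @param modules Named list: species -> character vector of oil-module
#'   gene ids.
#' @param groups Orthogroup tibble from [build_orthogroups()].
#' @param focal Focal species name (must be in `modules`).
#' @return Character vector of focal-species gene ids, sorted.
#' @export
conserved_coexpressed <- function(modules, groups, focal) {
  if (!focal %in% names(modules)) {
    stop_oilnet("`focal` must name one of the module sets")
  }
  groups <- as_tibble(groups)
  missing_sp <- setdiff(names(modules), unique(groups$species))
  if (length(missing_sp)) {
    stop_oilnet(paste0("orthogroups lack coverage for species: ",
                       paste(missing_sp, collapse = ", ")))
  }
  mapped <- map_gene_sets(groups, modules)
  conserved <- mapped$flags |>
    dplyr::filter(.data$species == focal, .data$conserved) |>
    dplyr::pull(.data$gene_id)
  sort(unique(conserved))
}

#' Intersect a conserved gene set with interspecific DEGs
#'
#' @param conserved Character vector of gene ids.
#' @param degs DEG tibble from [screen_degs()] (columns `gene_id`, `is_de`).
#' @return Character vector: conserved genes flagged differentially
#'   expressed, sorted.
#' @export
intersect_with_degs <- function(conserved, degs) {
  degs <- as_tibble(degs)
  uncovered <- setdiff(conserved, degs$gene_id)
  if (length(uncovered)) {
    stop_oilnet(paste0("DEG results do not cover: ",
                       paste(head(uncovered, 5), collapse = ", ")))
  }
  de <- degs$gene_id[degs$is_de]
  sort(intersect(conserved, de))
}

#' Network neighbours of anchor (desaturase) genes
#'
#' For each anchor gene, the genes whose topological overlap with it reaches
#' `weight_floor` (default: the 99th percentile of the network's
#' off-diagonal TOM) or, alternatively, its `top_k` strongest TOM partners.
#'
#' @param tom TOM matrix of one species' network.
#' @param anchors Character vector of anchor gene ids (e.g. FAD2/FAD3).
#' @param top_k Number of top partners per anchor (exclusive with
#'   `weight_floor`).
#' @param weight_floor TOM floor; default the network's 99th percentile.
#' @return Named list: anchor -> character vector of neighbour gene ids.
#' @export
fad_neighbors <- function(tom, anchors, top_k = NULL, weight_floor = NULL) {
  tm <- unclass(tom)
  absent <- setdiff(anchors, rownames(tm))
  if (length(absent)) {
    stop_oilnet(paste0("anchor gene(s) absent from the network: ",
                       paste(absent, collapse = ", ")))
  }
  if (!is.null(top_k) && !is.null(weight_floor)) {
    stop_oilnet("give either `top_k` or `weight_floor`, not both")
  }
  if (is.null(top_k) && is.null(weight_floor)) {
    off <- tm[upper.tri(tm)]
    weight_floor <- stats::quantile(off, 0.99, names = FALSE)
  }
  out <- lapply(anchors, function(a) {
    w <- tm[a, ]
    w <- w[names(w) != a]
    if (!is.null(top_k)) {
      k <- min(top_k, length(w))
      names(sort(w, decreasing = TRUE))[seq_len(k)]
    } else {
      names(w)[w >= weight_floor]
    }
  })
  setNames(out, anchors)
}

#' Cross-species consensus of anchor neighbourhoods
#'
#' A focal-species neighbour is in the consensus iff its orthogroup
#' intersects every other species' neighbour union — i.e. the gene is
#' co-expressed with the anchors (at orthogroup resolution) in all species.
#'
#' @param neighbors_by_species Named list: species -> character vector, the
#'   union of that species' anchor neighbourhoods (see [fad_neighbors()]).
#' @param groups Orthogroup tibble.
#' @param focal Focal species name.
#' @return Character vector of focal-species gene ids, sorted.
#' @export
fad_consensus <- function(neighbors_by_species, groups, focal) {
  if (!focal %in% names(neighbors_by_species)) {
    stop_oilnet("`focal` must name one of the neighbour sets")
  }
  conserved_coexpressed(neighbors_by_species, groups, focal)
}

#' Assemble the cross-species conservation report
#'
#' Runs [conserved_coexpressed()] and [intersect_with_degs()] and asserts
#' the containment chain conserved-and-DE subset-of conserved subset-of
#' focal oil module on every construction.
#'
#' @param modules Named list: species -> oil-module gene ids.
#' @param groups Orthogroup tibble.
#' @param focal Focal species.
#' @param degs DEG tibble covering the focal module genes.
#' @param fad_neighbor_sets Optional named list (species -> neighbour union)
#'   for the anchor-consensus component.
#' @return Object of class `conservation_report`: list with `modules`,
#'   `shared_orthogroups`, `conserved`, `conserved_and_de`, `fad_consensus`,
#'   `focal`.
#' @export
conservation_report <- function(modules, groups, focal, degs,
                                fad_neighbor_sets = NULL) {
  conserved <- conserved_coexpressed(modules, groups, focal)
  conserved_and_de <- intersect_with_degs(conserved, degs)
  mapped <- map_gene_sets(groups, modules)
  stopifnot(all(conserved_and_de %in% conserved),
            all(conserved %in% modules[[focal]]))
  consensus <- if (!is.null(fad_neighbor_sets)) {
    fad_consensus(fad_neighbor_sets, groups, focal)
  } else character()
  structure(list(
    modules = modules, shared_orthogroups = mapped$shared,
    conserved = conserved, conserved_and_de = conserved_and_de,
    fad_consensus = consensus, focal = focal
  ), class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> focal species: %s\n", x$focal))
  cat(sprintf("  oil-module sizes: %s\n",
              paste(sprintf("%s=%d", names(x$modules),
                            lengths(x$modules)), collapse = ", ")))
  cat(sprintf("  shared orthogroups: %d\n", length(x$shared_orthogroups)))
  cat(sprintf("  conserved co-expressed: %d\n", length(x$conserved)))
  cat(sprintf("  conserved and DE: %d\n", length(x$conserved_and_de)))
  invisible(x)
}
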
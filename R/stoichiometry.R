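#' Pathway expression-stoichiometry fractions
#'
#' Per species and stage, each pathway gene's share of the combined pathway
#' transcript sum: `fraction = mean expr(gene) / sum over pathway of mean
#' expr`, with replicate means taken per stage. The pathway is the union of
#' the fatty-acid-synthesis and TAG-assembly sets; fractions at a stage sum
#' to one. Transcripts mapping to the same enzyme can be summed first via
#' `enzyme_map`.
#'
#' @param m An [expr_matrix()] (one species, or filtered to one species).
#' @param pathway Named list of gene sets, e.g.
#'   `list(fas = ..., tag = ...)`; names become the `pathway` column.
#' @param enzyme_map Optional tibble `gene_id`/`enzyme`: transcripts are
#'   summed to the enzyme symbol before fractions are computed.
#' @return Tibble (class `stoich_table`): `species`, `stage_daf`, `pathway`,
#'   `gene` (enzyme symbol or gene id), `fraction`.
#' @export
stoichiometry_fractions <- function(m, pathway, enzyme_map = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(names(pathway)) || !length(pathway)) {
    stop_oilnet("`pathway` must be a named list of gene sets")
  }
  all_genes <- unlist(pathway, use.names = FALSE)
  absent <- setdiff(all_genes, gene_ids(m))
  if (length(absent)) {
    stop_oilnet(paste0("pathway genes absent from matrix: ",
                       paste(head(absent, 5), collapse = ", ")))
  }
  sp <- unique(m$samples$species)
  if (length(sp) != 1) {
    stop_oilnet("`m` must contain a single species; subset first")
  }
  sm <- stage_means(subset_expr(m, genes = unique(all_genes)))
  pw <- purrr::imap_dfr(pathway, function(genes, pname) {
    tibble(gene_id = unique(genes), pathway = pname)
  })
  long <- as_tibble(sm, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "stage_daf",
                        values_to = "expr") |>
    dplyr::mutate(stage_daf = as.numeric(.data$stage_daf)) |>
    dplyr::inner_join(pw, by = "gene_id")
  if (!is.null(enzyme_map)) {
    enzyme_map <- as_tibble(enzyme_map)
    long <- long |>
      dplyr::left_join(enzyme_map, by = "gene_id") |>
      dplyr::mutate(gene = dplyr::coalesce(.data$enzyme, .data$gene_id)) |>
      dplyr::group_by(.data$stage_daf, .data$pathway, .data$gene) |>
      dplyr::summarise(expr = sum(.data$expr), .groups = "drop")
  } else {
    long <- dplyr::rename(long, gene = "gene_id")
  }
  out <- long |>
    dplyr::group_by(.data$stage_daf) |>
    dplyr::mutate(total = sum(.data$expr)) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) {
    stop_oilnet("zero pathway transcript sum at a stage")
  }
  out <- out |>
    dplyr::transmute(species = sp, stage_daf = .data$stage_daf,
                     pathway = .data$pathway, gene = .data$gene,
                     fraction = .data$expr / .data$total) |>
    dplyr::arrange(.data$stage_daf, .data$pathway, .data$gene)
  class(out) <- c("stoich_table", class(out))
  out
}

#' Inter-species coefficient of variation of stoichiometry
#'
#' Per gene, the CV (sample sd / mean) of the pooled fractions across the
#' stages of both species' tables — small for genes whose pathway share is
#' conserved between species, large for diverged ones.
#'
#' @param a,b `stoich_table`s for the two species (same stages, shared
#'   gene symbols).
#' @param genes Optional gene subset; default the genes common to both.
#' @return Tibble `gene`, `cv`; attribute `"mean_cv"` holds the average.
#' @export
stoichiometry_cv <- function(a, b, genes = NULL) {
  a <- as_tibble(a); b <- as_tibble(b)
  if (!setequal(unique(a$stage_daf), unique(b$stage_daf))) {
    stop_oilnet("the two tables must cover the same stages")
  }
  genes <- genes %||% intersect(unique(a$gene), unique(b$gene))
  for (tbl in list(a, b)) {
    absent <- setdiff(genes, tbl$gene)
    if (length(absent)) {
      stop_oilnet(paste0("gene(s) absent from a table: ",
                         paste(head(absent, 5), collapse = ", ")))
    }
  }
  pooled <- dplyr::bind_rows(a, b) |>
    dplyr::filter(.data$gene %in% genes)
  out <- pooled |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(cv = cv(.data$fraction), .groups = "drop")
  attr(out, "mean_cv") <- mean(out$cv, na.rm = TRUE)
  out
}

#' Per-stage cross-species correlation of stoichiometries
#'
#' At each stage, the squared Pearson correlation between the two species'
#' fraction vectors over the gene subset. Zero variance in either vector
#' makes r-squared undefined (NA, flagged).
#'
#' @param a,b `stoich_table`s for the two species.
#' @param genes Gene subset (>= 3 genes); default the common genes.
#' @return Tibble `stage_daf`, `r2`, `undefined`.
#' @export
stage_correlation <- function(a, b, genes = NULL) {
  a <- as_tibble(a); b <- as_tibble(b)
  genes <- genes %||% intersect(unique(a$gene), unique(b$gene))
  if (length(genes) < 3) stop_oilnet("need >= 3 genes for stage correlations")
  stages <- sort(intersect(unique(a$stage_daf), unique(b$stage_daf)))
  purrr::map_dfr(stages, function(s) {
    va <- a |> dplyr::filter(.data$stage_daf == s, .data$gene %in% genes) |>
      dplyr::arrange(.data$gene)
    vb <- b |> dplyr::filter(.data$stage_daf == s, .data$gene %in% genes) |>
      dplyr::arrange(.data$gene)
    if (!identical(va$gene, vb$gene)) {
      stop_oilnet("gene sets differ between tables at a stage")
    }
    if (sd(va$fraction) == 0 || sd(vb$fraction) == 0) {
      tibble(stage_daf = s, r2 = NA_real_, undefined = TRUE)
    } else {
      tibble(stage_daf = s, r2 = cor(va$fraction, vb$fraction)^2,
             undefined = FALSE)
    }
  })
}
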
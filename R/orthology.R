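#' Reciprocal best hits between two species
#'
#' A pair (a, b) is reported iff b is a's unique top-scoring hit among
#' species-B subjects and a is b's unique top-scoring hit among species-A
#' subjects. Best hits are ranked by score with identity as a deterministic
#' tie-breaker; a gene whose best hit remains tied after both criteria is
#' disqualified — ambiguous orthology never seeds a one-to-one pair.
#'
#' @param hits Similarity table: tibble with columns `query`, `subject`,
#'   `qspecies`, `sspecies`, `score` and optionally `identity`.
#' @param species_a,species_b The two species labels.
#' @return Tibble `gene_a`, `gene_b`, `score_ab`, `score_ba`, sorted by
#'   `gene_a`. Symmetric in the species arguments (up to column naming).
#' @export
reciprocal_best_hits <- function(hits, species_a, species_b) {
  hits <- as_tibble(hits)
  if (!nrow(hits)) {
    return(tibble(gene_a = character(), gene_b = character(),
                  score_ab = numeric(), score_ba = numeric()))
  }
  if (!"identity" %in% names(hits)) hits$identity <- 0
  best <- function(qs, ss) {
    sub <- dplyr::filter(hits, .data$qspecies == qs, .data$sspecies == ss)
    if (!nrow(sub)) {
      return(tibble(query = character(), subject = character(),
                    score = numeric()))
    }
    sub |>
      dplyr::group_by(.data$query) |>
      dplyr::filter(.data$score == max(.data$score)) |>
      dplyr::filter(.data$identity == max(.data$identity)) |>
      dplyr::filter(dplyr::n() == 1) |>   # still tied -> disqualified
      dplyr::ungroup() |>
      dplyr::select("query", "subject", "score")
  }
  ab <- best(species_a, species_b)
  ba <- best(species_b, species_a)
  out <- dplyr::inner_join(
    ab, ba, by = c(query = "subject", subject = "query"),
    suffix = c("_ab", "_ba")
  )
  tibble(gene_a = out$query, gene_b = out$subject,
         score_ab = out$score_ab, score_ba = out$score_ba) |>
    dplyr::arrange(.data$gene_a)
}

#' Cluster genes into orthogroups from similarity hits
#'
#' Scores are normalised per query (divided by the query's own best score)
#' and hits at or above `score_floor` become undirected edges; connected
#' components of the resulting graph are the orthogroups. Genes present in
#' the table but without a qualifying edge are emitted as singleton groups,
#' so the output partitions every gene the table mentions.
#'
#' @param hits Similarity table (see [reciprocal_best_hits()]).
#' @param species_map Optional tibble `gene_id`/`species`; defaults to the
#'   species annotations carried in `hits`.
#' @param score_floor Normalised-score floor in \[0, 1\]; default 0.5 of each
#'   query's best score.
#' @return Tibble `orthogroup`, `gene_id`, `species`; group ids are
#'   `OG0001`, ... ordered by decreasing size then first member.
#' @export
build_orthogroups <- function(hits, species_map = NULL, score_floor = 0.5) {
  if (score_floor < 0) stop_oilnet("`score_floor` must be non-negative")
  hits <- as_tibble(hits)
  gene_species <- if (!is.null(species_map)) {
    as_tibble(species_map)
  } else {
    dplyr::bind_rows(
      dplyr::distinct(hits, gene_id = .data$query, species = .data$qspecies),
      dplyr::distinct(hits, gene_id = .data$subject, species = .data$sspecies)
    ) |> dplyr::distinct()
  }
  if (anyDuplicated(gene_species$gene_id)) {
    stop_oilnet("conflicting species assignments in the hit table")
  }
  edges <- hits |>
    dplyr::group_by(.data$query) |>
    dplyr::mutate(norm_score = .data$score / max(.data$score)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$norm_score >= score_floor,
                  .data$query != .data$subject) |>
    dplyr::select("query", "subject")
  all_genes <- gene_species$gene_id
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = all_genes)
  comp <- igraph::components(g)$membership
  out <- tibble(gene_id = names(comp), group = unname(comp)) |>
    dplyr::left_join(gene_species, by = "gene_id")
  ord <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(size = dplyr::n(), first = min(.data$gene_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first)
  relab <- setNames(sprintf("OG%04d", seq_len(nrow(ord))), ord$group)
  out |>
    dplyr::mutate(orthogroup = relab[as.character(.data$group)]) |>
    dplyr::select("orthogroup", "gene_id", "species") |>
    dplyr::arrange(.data$orthogroup, .data$gene_id)
}

#' Map per-species gene sets onto orthogroups
#'
#' An orthogroup is "shared" iff it contains at least one member of every
#' species' gene set; genes lying in shared orthogroups are flagged
#' conserved.
#'
#' @param groups Orthogroup tibble from [build_orthogroups()].
#' @param sets Named list: species -> character vector of gene ids (for
#'   example, each species' oil-module genes).
#' @return List with `shared` (character vector of shared orthogroup ids)
#'   and `flags` (tibble `gene_id`, `species`, `orthogroup`, `conserved`,
#'   covering the set members found in groups).
#' @export
map_gene_sets <- function(groups, sets) {
  groups <- as_tibble(groups)
  missing_sp <- setdiff(names(sets), unique(groups$species))
  if (length(missing_sp)) {
    stop_oilnet(paste0("species absent from orthogroups: ",
                       paste(missing_sp, collapse = ", ")))
  }
  members <- purrr::imap_dfr(sets, function(genes, sp) {
    tibble(species = sp, gene_id = unique(genes))
  })
  hit <- dplyr::inner_join(members, groups,
                           by = c("gene_id", "species"))
  shared <- hit |>
    dplyr::distinct(.data$orthogroup, .data$species) |>
    dplyr::count(.data$orthogroup) |>
    dplyr::filter(.data$n == length(sets)) |>
    dplyr::pull(.data$orthogroup)
  flags <- dplyr::mutate(hit, conserved = .data$orthogroup %in% shared) |>
    dplyr::select("gene_id", "species", "orthogroup", "conserved")
  list(shared = shared, flags = flags)
}
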
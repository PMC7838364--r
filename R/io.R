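#' Write / read an expression matrix as TSV
#'
#' Genes-by-samples TSV with a `gene_id` header column followed by sample
#' ids of the form `species.stage.rep`. Gene lengths, when present, travel
#' in a `<path>.lengths.tsv` sidecar.
#'
#' @param m An [expr_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- as_tibble(m$values, rownames = "gene_id")
  readr::write_tsv(df, path)
  if (!is.null(m$gene_lengths)) {
    readr::write_tsv(
      tibble(gene_id = names(m$gene_lengths), length = m$gene_lengths),
      paste0(path, ".lengths.tsv")
    )
  }
  invisible(path)
}

#' @rdname write_expr_tsv
#' @param unit Unit of the stored values.
#' @return For the reader, an `expr_matrix`; sample metadata is parsed from
#'   the `species.stage.rep` column ids.
#' @export
read_expr_tsv <- function(path, unit = "fpkm") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  values <- as.matrix(df[, -1])
  rownames(values) <- df$gene_id
  parts <- strsplit(colnames(values), ".", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop_oilnet("sample ids must have the form species.stage.rep")
  }
  samples <- tibble(
    sample = colnames(values),
    species = vapply(parts, `[[`, "", 1),
    stage_daf = as.numeric(vapply(parts, `[[`, "", 2)),
    replicate = as.integer(vapply(parts, `[[`, "", 3))
  )
  lengths_path <- paste0(path, ".lengths.tsv")
  gl <- NULL
  if (file.exists(lengths_path)) {
    ldf <- readr::read_tsv(lengths_path, show_col_types = FALSE)
    gl <- setNames(ldf$length, ldf$gene_id)
  }
  expr_matrix(values, samples, unit = unit, gene_lengths = gl)
}

#' Write / read fatty-acid composition CSV
#'
#' Columns `species`, `stage_daf`, `replicate`, then one column per
#' fatty-acid key.
#'
#' @param fa Fatty-acid tibble (see [simulate_fa_profiles()]).
#' @param path CSV path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_fa_csv <- function(fa, path) {
  readr::write_csv(fa, path)
  invisible(path)
}

#' @rdname write_fa_csv
#' @export
read_fa_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a similarity hit table
#'
#' Tabular search output with columns `qseqid`, `sseqid`, `pident` (percent),
#' `length`, `bitscore`, `qcovs` (percent), plus a two-column species map
#' sidecar (`gene_id`, `species`). The reader converts percents to fractions
#' and attaches query/subject species.
#'
#' @param hits Internal hit tibble (`query`, `subject`, `qspecies`,
#'   `sspecies`, `score`, `identity`, `coverage`).
#' @param path Hit-table TSV path; species map goes to `<path>.species.tsv`.
#' @param aln_length Alignment length column to write; defaults to 0.
#' @return `path` invisibly (writer); the internal hit tibble (reader).
#' @export
write_hit_table <- function(hits, path, aln_length = 0L) {
  out <- tibble(
    qseqid = hits$query, sseqid = hits$subject,
    pident = round(hits$identity * 100, 2),
    length = aln_length,
    bitscore = round(hits$score, 3),
    qcovs = round(hits$coverage * 100, 2)
  )
  readr::write_tsv(out, path)
  species_map <- dplyr::distinct(dplyr::bind_rows(
    tibble(gene_id = hits$query, species = hits$qspecies),
    tibble(gene_id = hits$subject, species = hits$sspecies)
  ))
  readr::write_tsv(species_map, paste0(path, ".species.tsv"))
  invisible(path)
}

#' @rdname write_hit_table
#' @param species_map_path Optional explicit species-map path.
#' @export
read_hit_table <- function(path, species_map_path = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  species_map_path <- species_map_path %||% paste0(path, ".species.tsv")
  sm <- readr::read_tsv(species_map_path, show_col_types = FALSE)
  sp <- setNames(sm$species, sm$gene_id)
  tibble(
    query = df$qseqid, subject = df$sseqid,
    qspecies = unname(sp[df$qseqid]), sspecies = unname(sp[df$sseqid]),
    score = df$bitscore, identity = df$pident / 100,
    coverage = df$qcovs / 100
  )
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path GMT path.
#' @param description Per-set description (recycled).
#' @return `path` invisibly (writer); a named list (reader).
#' @export
write_gmt <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  lines <- purrr::imap_chr(sets, function(genes, name) {
    paste(c(name, description[match(name, names(sets))], genes),
          collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  setNames(sets, vapply(parts, `[[`, "", 1))
}
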
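#' Expression matrix with sample metadata
#'
#' Light container for a gene-by-sample expression matrix together with the
#' sample descriptors the comparative analysis needs (species, tissue,
#' developmental stage in days after flowering, replicate). Values are
#' non-negative; when `unit = "count"` per-gene transcript lengths (nt) are
#' required so [fpkm_normalize()] can be applied.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param samples Data frame with one row per column of `values`; must contain
#'   columns `sample`, `species`, `stage_daf`, `replicate` (a `tissue` column
#'   is carried along when present).
#' @param unit `"fpkm"` or `"count"`.
#' @param gene_lengths Named numeric vector of transcript lengths in
#'   nucleotides; required when `unit = "count"`, optional otherwise.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples, unit = c("fpkm", "count"),
                        gene_lengths = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_oilnet("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop_oilnet("`values` must have unique rownames (gene ids)")
  }
  if (any(values < 0)) stop_oilnet("expression values must be non-negative")
  samples <- as_tibble(samples)
  required <- c("sample", "species", "stage_daf", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop_oilnet(paste0("`samples` lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(samples) != ncol(values)) {
    stop_oilnet("`samples` must have one row per column of `values`")
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  if (!identical(colnames(values), as.character(samples$sample))) {
    stop_oilnet("colnames(values) must match samples$sample, in order")
  }
  if (unit == "count" && is.null(gene_lengths)) {
    stop_oilnet("`gene_lengths` is required when unit = \"count\"")
  }
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths))) {
      stop_oilnet("`gene_lengths` must be named by gene id")
    }
    absent <- setdiff(rownames(values), names(gene_lengths))
    if (length(absent)) {
      stop_oilnet(paste0("gene_lengths missing for: ",
                         paste(head(absent, 5), collapse = ", ")))
    }
    if (any(gene_lengths <= 0)) stop_oilnet("gene lengths must be positive")
    gene_lengths <- gene_lengths[rownames(values)]
  }
  structure(
    list(values = values, samples = samples, unit = unit,
         gene_lengths = gene_lengths),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("species:", paste(unique(x$samples$species), collapse = ", "), "\n")
  cat("stages (DAF):", paste(sort(unique(x$samples$stage_daf)), collapse = ", "), "\n")
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Turn an expression matrix into a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `sample`, `species`, `stage_daf`,
#'   `replicate`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample", values_to = "value")
  dplyr::left_join(long, x$samples, by = "sample") |>
    dplyr::select("gene_id", "sample", "species", "stage_daf", "replicate",
                  "value")
}

#' Build an expression matrix from a long tibble
#'
#' Inverse of [tidy.expr_matrix()]: expects columns `gene_id`, `sample`,
#' `species`, `stage_daf`, `replicate`, `value`.
#'
#' @param data Long-format tibble.
#' @inheritParams expr_matrix
#' @return An `expr_matrix`.
#' @export
as_expr_matrix <- function(data, unit = "fpkm", gene_lengths = NULL) {
  wide <- tidyr::pivot_wider(data, id_cols = "gene_id", names_from = "sample",
                             values_from = "value")
  values <- as.matrix(wide[, -1])
  rownames(values) <- wide$gene_id
  samples <- dplyr::distinct(
    data, .data$sample, .data$species, .data$stage_daf, .data$replicate
  )
  samples <- samples[match(colnames(values), samples$sample), ]
  expr_matrix(values, samples, unit = unit, gene_lengths = gene_lengths)
}

# internal: subset an expr_matrix by gene ids and/or sample ids
subset_expr <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  s <- m$samples
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    s <- s[match(samples, s$sample), ]
  }
  expr_matrix(v, s, unit = m$unit,
              gene_lengths = if (is.null(m$gene_lengths)) NULL else
                m$gene_lengths[rownames(v)])
}

# internal: per-gene stage means for one species (or the whole matrix)
stage_means <- function(m) {
  stg <- m$samples$stage_daf
  stages <- sort(unique(stg))
  out <- matrix(0, nrow(m$values), length(stages),
                dimnames = list(rownames(m$values), as.character(stages)))
  for (i in seq_along(stages)) {
    out[, i] <- rowMeans(m$values[, stg == stages[i], drop = FALSE])
  }
  out
}
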
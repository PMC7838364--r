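#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the scale-free fit table of a beta choice
#' @param x A `beta_fit` from [pick_beta()].
#' @param ... Unused.
#' @return Tibble `beta`, `r2`, `mean_k`, `chosen`.
#' @export
tidy.beta_fit <- function(x, ...) {
  dplyr::mutate(x$fits, chosen = .data$beta == x$beta)
}

#' @rdname tidy.beta_fit
#' @return For `glance`: one row with `beta`, `r2`, `fallback`, `r2_target`.
#' @export
glance.beta_fit <- function(x, ...) {
  tibble(beta = x$beta,
         r2 = x$fits$r2[match(x$beta, x$fits$beta)],
         fallback = x$fallback, r2_target = x$r2_target)
}

#' Tidy a module partition
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return The gene-to-module membership tibble.
#' @export
tidy.module_partition <- function(x, ...) x$membership

#' @rdname tidy.module_partition
#' @return For `glance`: `n_genes`, `n_modules`, `n_unassigned`,
#'   `largest_module`, `cut_height`, `min_module_size`.
#' @export
glance.module_partition <- function(x, ...) {
  nz <- dplyr::filter(x$sizes, .data$module != 0)
  tibble(
    n_genes = nrow(x$membership),
    n_modules = nrow(nz),
    n_unassigned = sum(x$membership$module == 0),
    largest_module = if (nrow(nz)) max(nz$size) else 0L,
    cut_height = x$cut_height,
    min_module_size = x$min_module_size
  )
}

#' Tidy an eigengene set into a long tibble
#' @param x An `eigengene_set`.
#' @param ... Unused.
#' @return Tibble `sample`, `species`, `stage_daf`, `replicate`, `module`,
#'   `eigengene`.
#' @export
tidy.eigengene_set <- function(x, ...) {
  as_tibble(x$eigengenes, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "module",
                        values_to = "eigengene") |>
    dplyr::left_join(x$samples, by = "sample") |>
    dplyr::select("sample", "species", "stage_daf", "replicate", "module",
                  "eigengene")
}

#' Tidy a module-validation result
#' @param x A `module_validation` from [permutation_robustness()].
#' @param ... Unused.
#' @return One-row tibble with the statistic, null mean, p and settings.
#' @export
tidy.module_validation <- function(x, ...) {
  tibble(statistic = x$statistic, statistic_name = x$statistic_name,
         null_mean = x$null_mean, p = x$p,
         n_permutations = x$n_permutations, module_size = x$module_size)
}

#' @rdname tidy.module_validation
#' @export
glance.module_validation <- function(x, ...) tidy.module_validation(x)

#' Tidy a conservation report
#' @param x A `conservation_report`.
#' @param ... Unused.
#' @return Per-gene tibble over the focal oil module: `gene_id`,
#'   `conserved`, `conserved_and_de`.
#' @export
tidy.conservation_report <- function(x, ...) {
  tibble(gene_id = sort(x$modules[[x$focal]])) |>
    dplyr::mutate(conserved = .data$gene_id %in% x$conserved,
                  conserved_and_de = .data$gene_id %in% x$conserved_and_de)
}

#' @rdname tidy.conservation_report
#' @return For `glance`: one row of the report's headline counts.
#' @export
glance.conservation_report <- function(x, ...) {
  tibble(focal = x$focal,
         focal_module_size = length(x$modules[[x$focal]]),
         shared_orthogroups = length(x$shared_orthogroups),
         conserved = length(x$conserved),
         conserved_and_de = length(x$conserved_and_de))
}
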
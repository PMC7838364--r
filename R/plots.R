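#' Plot the scale-free topology fit across candidate powers
#'
#' @param object A `beta_fit` from [pick_beta()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beta_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$r2)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::geom_hline(yintercept = object$r2_target, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = expression(beta), y = expression(r^2),
                  title = "Scale-free topology fit") +
    ggplot2::theme_minimal()
}

#' Plot module sizes of a partition
#'
#' @param object A `module_partition`.
#' @param ... Unused.
#' @return A ggplot (bar chart of module sizes; unassigned genes shown as
#'   module 0).
#' @export
autoplot.module_partition <- function(object, ...) {
  df <- dplyr::mutate(object$sizes, module = factor(.data$module))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "module", y = "genes",
                  title = "Co-expression module sizes") +
    ggplot2::theme_minimal()
}

#' Plot eigengene profiles over development
#'
#' @param object An `eigengene_set`.
#' @param ... Unused.
#' @return A ggplot of per-module eigengene trajectories (stage means).
#' @export
autoplot.eigengene_set <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$module, .data$stage_daf) |>
    dplyr::summarise(eigengene = mean(.data$eigengene), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage_daf, y = .data$eigengene,
                                   colour = .data$module)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stage (DAF)", y = "eigengene",
                  title = "Module eigengene trajectories") +
    ggplot2::theme_minimal()
}

#' Stacked fatty-acid composition over development
#'
#' @param fa Fatty-acid tibble (columns `species`, `stage_daf`, `replicate`
#'   and the [fa_keys()] fractions).
#' @param group_minor Collapse C20:0/C22:0 into `other` first.
#' @return A ggplot (stacked bars per stage, facetted by species).
#' @export
plot_fa_composition <- function(fa, group_minor = TRUE) {
  if (group_minor) fa <- group_minor_fas(fa)
  keys <- intersect(fa_keys(), names(fa))
  df <- fa |>
    dplyr::group_by(.data$species, .data$stage_daf) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(keys), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(keys), names_to = "fatty_acid",
                        values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$stage_daf),
                                   y = .data$fraction,
                                   fill = .data$fatty_acid)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "stage (DAF)", y = "mass fraction", fill = NULL,
                  title = "Fatty-acid composition") +
    ggplot2::theme_minimal()
}

#' Expression-stoichiometry grid across species
#'
#' The comparative stoichiometry heat grid: one tile per pathway gene and
#' stage, coloured by the gene's fraction of the pathway transcript sum,
#' facetted by species and pathway.
#'
#' @param tables Named list of `stoich_table`s (one per species), e.g. the
#'   `stoichiometry$tables` element of an `oilnet_run`.
#' @return A ggplot.
#' @export
plot_stoichiometry <- function(tables) {
  df <- dplyr::bind_rows(lapply(tables, as_tibble))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$stage_daf),
                                   y = .data$gene,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(pathway ~ species, scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "stage (DAF)", y = NULL, fill = "fraction",
                  title = "Pathway expression stoichiometry") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a DEG screen
#'
#' @param degs Tibble from [screen_degs()].
#' @return A ggplot of log2 fold-change against -log10 q.
#' @export
plot_volcano <- function(degs) {
  ggplot2::ggplot(degs, ggplot2::aes(x = .data$log2fc,
                                     y = -log10(.data$q),
                                     colour = .data$is_de)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                            `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 q",
                  title = "Interspecific differential expression") +
    ggplot2::theme_minimal()
}
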
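#' Configuration for an end-to-end pipeline run
#'
#' Bundles the synthetic-study design with every analysis threshold, each
#' defaulting to its conventional value: transcript collapsing at identity
#' 0.90 / coverage 0.80, module robustness by 5,000 permutations judged at
#' p < 1e-3, hypergeometric validation at p < 1e-6, BH q < 0.05 for the DEG
#' screen. The whole config is serialised verbatim into the run manifest.
#'
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param seed Master seed for the run (all stage seeds derive from it).
#' @param q_threshold DEG significance threshold on BH-adjusted q.
#' @param deg_permutations Label shuffles for the DEG screen.
#' @param identity_min,coverage_min Transcript-collapsing thresholds.
#' @param beta Fixed soft-thresholding power; the default 18 is the
#'   conventional choice for signed networks built from fewer than 20
#'   samples. Set to `NULL` to select the power automatically with
#'   [pick_beta()] over `betas`.
#' @param betas Candidate powers for automatic selection.
#' @param r2_target Scale-free fit target for [pick_beta()].
#' @param min_module_size,cut_height Tree-cut parameters ([cut_modules()]).
#' @param merge_correlation Eigengene-merge threshold.
#' @param pattern_correlation Oil-module selection threshold.
#' @param n_permutations Module-robustness permutations.
#' @param permutation_alpha,hypergeometric_alpha Validation cut-offs.
#' @param score_floor Normalised-score floor for orthogroup edges.
#' @param decoy_rate Decoy fraction for the simulated hit table.
#' @param n_seed_genes Oil-pathway seed genes taken from the planted oil
#'   module (first `n_fas` act as the FA-synthesis set, the rest as the
#'   TAG-assembly set).
#' @param n_fas FA-synthesis enzymes among the seed genes.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       seed = 1,
                       q_threshold = 0.05,
                       deg_permutations = 1000,
                       identity_min = 0.90,
                       coverage_min = 0.80,
                       beta = 18,
                       betas = seq(2, 20, by = 2),
                       r2_target = 0.8,
                       min_module_size = 30,
                       cut_height = 0.93,
                       merge_correlation = 0.75,
                       pattern_correlation = 0.75,
                       n_permutations = 5000,
                       permutation_alpha = 1e-3,
                       hypergeometric_alpha = 1e-6,
                       score_floor = 0.5,
                       decoy_rate = 0.2,
                       n_seed_genes = 24,
                       n_fas = 14) {
  check_fraction(q_threshold, "q_threshold")
  check_fraction(identity_min, "identity_min")
  check_fraction(coverage_min, "coverage_min")
  check_fraction(r2_target, "r2_target")
  check_fraction(merge_correlation, "merge_correlation")
  check_fraction(pattern_correlation, "pattern_correlation")
  check_fraction(permutation_alpha, "permutation_alpha")
  check_fraction(hypergeometric_alpha, "hypergeometric_alpha")
  seed <- as.integer(seed)
  sim$seed <- seed
  structure(list(
    sim = sim, seed = seed, q_threshold = q_threshold,
    deg_permutations = deg_permutations,
    identity_min = identity_min, coverage_min = coverage_min,
    beta = beta, betas = betas, r2_target = r2_target,
    min_module_size = min_module_size, cut_height = cut_height,
    merge_correlation = merge_correlation,
    pattern_correlation = pattern_correlation,
    n_permutations = n_permutations,
    permutation_alpha = permutation_alpha,
    hypergeometric_alpha = hypergeometric_alpha,
    score_floor = score_floor, decoy_rate = decoy_rate,
    n_seed_genes = n_seed_genes, n_fas = n_fas
  ), class = "run_config")
}

# log2(x + 1) copy of an expr_matrix, dropping zero-variance genes — the
# scale on which correlations and networks are computed
log_transform <- function(m) {
  lv <- log2(m$values + 1)
  keep <- apply(lv, 1, stats::var) > 0
  expr_matrix(lv[keep, , drop = FALSE], m$samples, unit = m$unit,
              gene_lengths = if (is.null(m$gene_lengths)) NULL else
                m$gene_lengths[keep])
}

# network construction for one species: beta choice, adjacency, TOM,
# modules, eigengene merge
build_network <- function(mlog, cfg) {
  r <- correlation_matrix(mlog)
  if (is.null(cfg$beta)) {
    bf <- pick_beta(r, betas = cfg$betas, r2_target = cfg$r2_target)
    beta <- bf$beta
  } else {
    bf <- NULL
    beta <- cfg$beta
  }
  adj <- soft_threshold(r, beta)
  tom <- tom_similarity(adj)
  part <- cut_modules(tom, min_module_size = cfg$min_module_size,
                      cut_height = cfg$cut_height)
  part <- merge_similar_modules(mlog, part,
                                merge_correlation = cfg$merge_correlation)
  list(beta = beta, beta_fit = bf, tom = tom, partition = part,
       eigengenes = part$eigengenes)
}

#' Run the full comparative pipeline on a synthetic study
#'
#' Simulate -> fatty-acid statistics -> per-species co-expression networks
#' -> oil-module selection and validation -> orthology -> cross-species
#' conservation -> interspecific DEG intersection -> expression
#' stoichiometry. Reruns with the same config are byte-identical. When
#' `out_dir` is given, every stage artifact plus a run manifest (config,
#' seeds, file digests, gene counts per stage) is written there.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for stage artifacts.
#' @return Object of class `oilnet_run`; see elements in Details.
#' @details Elements: `fa` (profiles with recovered desaturation
#'   efficiencies), `degs`, `networks` (per species), `oil_modules`,
#'   `validation` (permutation + hypergeometric), `orthogroups`, `rbh`,
#'   `report` ([conservation_report()]), `stoichiometry` (fractions, CV,
#'   stage r2), `config`, `counts`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  t0 <- Sys.time()

  # --- simulate ------------------------------------------------------
  sim <- simulate_expression(cfg$sim)
  fa <- simulate_fa_profiles(cfg$sim)
  hits <- simulate_similarity_table(sim$truth, decoy_rate = cfg$decoy_rate,
                                    seed = cfg$seed + 1L)
  species <- names(sim$expression)
  focal <- species[1]

  # --- fatty-acid statistics ----------------------------------------
  fa_de <- desaturation_efficiency(fa) |> saturation_ratios()

  # --- per-species networks -----------------------------------------
  logs <- lapply(sim$expression, log_transform)
  networks <- lapply(logs, build_network, cfg = cfg)

  # --- oil-module selection + validation ----------------------------
  oil_core <- sim$truth$modules$core_id[sim$truth$modules$module == "M1"]
  seeds_core <- head(oil_core, cfg$n_seed_genes)
  oil_modules <- list()
  validation <- list()
  for (sp in species) {
    seeds_sp <- paste0(sp, "_", seeds_core)
    sel <- select_oil_module(networks[[sp]]$partition,
                             networks[[sp]]$eigengenes, seeds_sp,
                             pattern_correlation = cfg$pattern_correlation)
    oil_modules[[sp]] <- sel$gene_id
  }
  validation$permutation <- permutation_robustness(
    networks[[focal]]$tom, oil_modules[[focal]],
    n_permutations = cfg$n_permutations, seed = cfg$seed + 2L
  )
  validation$hypergeometric <- hypergeometric_test(
    oil_modules[[focal]], paste0(focal, "_", seeds_core),
    background_size = nrow(networks[[focal]]$tom)
  )

  # --- orthology -----------------------------------------------------
  rbh <- reciprocal_best_hits(hits, species[1], species[2])
  groups <- build_orthogroups(hits, score_floor = cfg$score_floor)

  # --- interspecific DEG screen on RBH-matched genes ----------------
  m1 <- sim$expression[[species[1]]]
  m2 <- sim$expression[[species[2]]]
  pairs <- dplyr::filter(rbh, .data$gene_a %in% gene_ids(m1),
                         .data$gene_b %in% gene_ids(m2))
  v <- cbind(m1$values[pairs$gene_a, , drop = FALSE],
             m2$values[pairs$gene_b, , drop = FALSE])
  rownames(v) <- pairs$gene_a
  samples <- dplyr::bind_rows(m1$samples, m2$samples)
  combined <- expr_matrix(v, samples, unit = "fpkm")
  degs <- screen_degs(combined, samples$species,
                      n_permutations = cfg$deg_permutations,
                      q_threshold = cfg$q_threshold,
                      seed = cfg$seed + 3L)

  # --- cross-species conservation -----------------------------------
  # conservation is assessed over the genes the DEG screen covers
  modules_rbh <- oil_modules
  modules_rbh[[focal]] <- intersect(oil_modules[[focal]], degs$gene_id)
  report <- conservation_report(modules_rbh, groups, focal, degs)

  # --- stoichiometry -------------------------------------------------
  fas_core <- seeds_core[seq_len(min(cfg$n_fas, length(seeds_core)))]
  tag_core <- setdiff(seeds_core, fas_core)
  stoich <- lapply(species[1:2], function(sp) {
    stoichiometry_fractions(
      sim$expression[[sp]],
      list(fas = paste0(sp, "_", fas_core), tag = paste0(sp, "_", tag_core))
    ) |>
      dplyr::mutate(gene = sub("^[^_]+_", "", .data$gene))
  })
  names(stoich) <- species[1:2]
  stoich_cv <- stoichiometry_cv(stoich[[1]], stoich[[2]])
  stage_r2 <- stage_correlation(stoich[[1]], stoich[[2]], genes = fas_core)

  counts <- tibble(
    stage = c("genes_per_species", "rbh_pairs", "orthogroups",
              "degs_flagged", "oil_module_focal", "conserved",
              "conserved_and_de"),
    n = c(nrow(m1$values), nrow(rbh),
          dplyr::n_distinct(groups$orthogroup), sum(degs$is_de),
          length(oil_modules[[focal]]), length(report$conserved),
          length(report$conserved_and_de))
  )

  run <- structure(list(
    fa = fa_de, degs = degs, networks = networks,
    oil_modules = oil_modules, validation = validation,
    orthogroups = groups, rbh = rbh, report = report,
    stoichiometry = list(tables = stoich, cv = stoich_cv,
                         stage_r2 = stage_r2),
    truth = sim$truth, expression = sim$expression,
    config = cfg, counts = counts,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "oilnet_run")

  if (!is.null(out_dir)) write_run(run, hits, out_dir)
  run
}

# write stage artifacts + manifest; deterministic content for fixed config
write_run <- function(run, hits, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (sp in names(run$expression)) {
    p <- file.path(out_dir, paste0("expression_", sp, ".tsv"))
    write_expr_tsv(run$expression[[sp]], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "fa_profiles.csv")
  write_fa_csv(run$fa, p); paths <- c(paths, p)
  p <- file.path(out_dir, "hits.tsv")
  write_hit_table(hits, p); paths <- c(paths, p)
  p <- file.path(out_dir, "degs.tsv")
  readr::write_tsv(run$degs, p); paths <- c(paths, p)
  for (sp in names(run$networks)) {
    p <- file.path(out_dir, paste0("modules_", sp, ".tsv"))
    readr::write_tsv(run$networks[[sp]]$partition$membership, p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "orthogroups.tsv")
  readr::write_tsv(run$orthogroups, p); paths <- c(paths, p)
  p <- file.path(out_dir, "oil_modules.gmt")
  write_gmt(run$oil_modules, p); paths <- c(paths, p)
  p <- file.path(out_dir, "conserved.tsv")
  readr::write_tsv(tibble(gene_id = run$report$conserved,
                          de = run$report$conserved %in%
                            run$report$conserved_and_de), p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "stoichiometry_cv.tsv")
  readr::write_tsv(run$stoichiometry$cv, p); paths <- c(paths, p)
  p <- file.path(out_dir, "stage_r2.tsv")
  readr::write_tsv(run$stoichiometry$stage_r2, p); paths <- c(paths, p)

  manifest <- c(
    "# oilnet run manifest",
    paste0("seed: ", run$config$seed),
    paste0("q_threshold: ", run$config$q_threshold),
    paste0("identity_min: ", run$config$identity_min),
    paste0("coverage_min: ", run$config$coverage_min),
    paste0("beta: ", run$config$beta %||% "auto"),
    paste0("betas: ", paste(run$config$betas, collapse = ",")),
    paste0("r2_target: ", run$config$r2_target),
    paste0("min_module_size: ", run$config$min_module_size),
    paste0("cut_height: ", run$config$cut_height %||% "auto"),
    paste0("merge_correlation: ", run$config$merge_correlation),
    paste0("pattern_correlation: ", run$config$pattern_correlation),
    paste0("n_permutations: ", run$config$n_permutations),
    paste0("permutation_alpha: ", run$config$permutation_alpha),
    paste0("hypergeometric_alpha: ", run$config$hypergeometric_alpha),
    paste0("score_floor: ", run$config$score_floor),
    paste0("decoy_rate: ", run$config$decoy_rate),
    "# stage counts",
    sprintf("%s: %d", run$counts$stage, run$counts$n),
    "# file digests (md5)",
    sprintf("%s: %s", basename(paths), unname(tools::md5sum(paths)))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.oilnet_run <- function(x, ...) {
  cat("<oilnet_run>\n")
  cat(sprintf("  species: %s (focal %s)\n",
              paste(names(x$expression), collapse = ", "), x$report$focal))
  print(x$counts, n = nrow(x$counts))
  cat(sprintf("  oil-module permutation p = %.3g, hypergeometric p = %.3g\n",
              x$validation$permutation$p, x$validation$hypergeometric))
  invisible(x)
}
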
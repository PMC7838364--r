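#' Describe a planted co-expression module
#'
#' @param size Number of genes (>= 3).
#' @param shape Latent stage profile: `"bell"` (peaks mid-development, the
#'   pattern oil-biosynthesis genes follow), `"rising"`, `"falling"` or
#'   `"flat"`.
#' @param cor Target expected pairwise Pearson correlation (on the log2
#'   scale) between member genes, in \[0, 1\].
#' @return A list describing the module.
#' @export
planted_module <- function(size, shape = c("bell", "rising", "falling", "flat"),
                           cor = 0.8) {
  shape <- match.arg(shape)
  size <- check_count(size, "size", min = 3L)
  check_fraction(cor, "cor")
  list(size = size, shape = shape, cor = cor)
}

#' Configuration for the synthetic multi-species study
#'
#' Emulates the design of a multi-species seed-development time course:
#' by default three species sampled at five stages (0, 40, 50, 60 and 100
#' days after flowering) with three biological replicates, a bell-shaped
#' planted oil-biosynthesis module plus two further planted modules,
#' interspecific differentially expressed genes, a one-to-one-plus-paralog
#' orthology structure, and fatty-acid composition trajectories constructed
#' from chosen desaturation efficiencies.
#'
#' @param n_species Number of species (2 or 3).
#' @param stages Developmental stages in days after flowering.
#' @param n_replicates Replicates per stage.
#' @param n_background_genes Unstructured background genes.
#' @param planted_modules List of [planted_module()] descriptions; the first
#'   module is the planted oil-biosynthesis module.
#' @param de_genes Tibble with columns `gene` (core gene index), `species`
#'   (species index) and `log2fc`: genes given an expression offset in that
#'   species. `NULL` plants the default set (15 oil-module genes and 10
#'   background genes, 4-fold up in species 2).
#' @param paralog_events Tibble with columns `ancestral` (core gene index),
#'   `children` (count) and `diverged` (logical: children get a stage-shifted
#'   profile, mimicking subfunctionalised desaturase duplicates). `NULL`
#'   plants two single-child events on oil-module genes, one diverged.
#' @param omega6_de_target,omega3_de_target Per-species desaturation
#'   efficiency targets in (0, 1], recycled to `n_species`. Defaults follow
#'   the contrast between an ALA-rich and an oleic-rich species.
#' @param c18_pool Total mass fraction of the C18 unsaturated pool
#'   (18:1 + 18:2 + 18:3) at the final stage.
#' @param noise_sd Log2-scale standard deviation of unstructured expression
#'   noise.
#' @param amplitude Log2-scale amplitude of the planted stage profiles.
#' @param baseline_range Log2 range of per-gene baseline expression.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_species = 3,
                       stages = c(0, 40, 50, 60, 100),
                       n_replicates = 3,
                       n_background_genes = 500,
                       planted_modules = list(
                         planted_module(60, "bell", 0.8),
                         planted_module(40, "rising", 0.8),
                         planted_module(30, "falling", 0.8)
                       ),
                       de_genes = NULL,
                       paralog_events = NULL,
                       omega6_de_target = c(0.80, 0.40, 0.75),
                       omega3_de_target = c(0.60, 0.55, 0.60),
                       c18_pool = 0.90,
                       noise_sd = 0.4,
                       amplitude = 3,
                       baseline_range = c(2, 8),
                       seed = 1) {
  n_species <- check_count(n_species, "n_species", 2L)
  n_replicates <- check_count(n_replicates, "n_replicates", 1L)
  n_background_genes <- check_count(n_background_genes, "n_background_genes", 0L)
  if (length(stages) < 2 || is.unsorted(stages, strictly = TRUE)) {
    stop_oilnet("`stages` must be strictly increasing with >= 2 stages")
  }
  if (!length(planted_modules)) stop_oilnet("need >= 1 planted module")
  for (pm in planted_modules) {
    if (pm$size < 3) stop_oilnet("planted module size < 3 cannot form a correlated block")
  }
  if (noise_sd < 0) stop_oilnet("`noise_sd` must be non-negative")
  omega6 <- rep_len(omega6_de_target, n_species)
  omega3 <- rep_len(omega3_de_target, n_species)
  check_fraction(omega6, "omega6_de_target")
  check_fraction(omega3, "omega3_de_target")
  check_fraction(c18_pool, "c18_pool", open_left = TRUE)
  n_module_genes <- sum(vapply(planted_modules, `[[`, 1, "size"))
  n_core <- n_module_genes + n_background_genes

  if (is.null(de_genes)) {
    oil_idx <- seq_len(min(15L, planted_modules[[1]]$size))
    bg_idx <- if (n_background_genes >= 10) n_module_genes + 1:10 else integer()
    de_genes <- tibble(gene = c(oil_idx, bg_idx),
                       species = 2L, log2fc = 2)
  }
  de_genes <- as_tibble(de_genes)
  if (nrow(de_genes)) {
    stopifnot(all(c("gene", "species", "log2fc") %in% names(de_genes)))
    if (any(de_genes$gene < 1 | de_genes$gene > n_core) ||
        any(de_genes$species < 1 | de_genes$species > n_species)) {
      stop_oilnet("`de_genes` references genes or species outside the design")
    }
  }
  if (is.null(paralog_events)) {
    anc <- head(seq(planted_modules[[1]]$size, 1L), 2L)
    paralog_events <- tibble(ancestral = anc, children = 1L,
                             diverged = c(FALSE, TRUE)[seq_along(anc)])
  }
  paralog_events <- as_tibble(paralog_events)
  if (nrow(paralog_events) &&
      any(paralog_events$ancestral < 1 | paralog_events$ancestral > n_core)) {
    stop_oilnet("`paralog_events` references genes outside the design")
  }

  structure(list(
    n_species = n_species,
    species = paste0("sp", LETTERS[seq_len(n_species)]),
    stages = stages, n_replicates = n_replicates,
    n_background_genes = n_background_genes,
    planted_modules = planted_modules,
    de_genes = de_genes, paralog_events = paralog_events,
    omega6_de_target = omega6, omega3_de_target = omega3,
    c18_pool = c18_pool, noise_sd = noise_sd, amplitude = amplitude,
    baseline_range = baseline_range, seed = as.integer(seed)
  ), class = "sim_config")
}

# latent stage profile on the log2 scale, one value per stage
shape_profile <- function(shape, n_stages, amplitude) {
  i <- seq_len(n_stages)
  base <- switch(shape,
    bell = exp(-((i - (n_stages + 1) / 2)^2) / (2 * (n_stages / 4)^2)),
    rising = (i - 1) / (n_stages - 1),
    falling = (n_stages - i) / (n_stages - 1),
    flat = rep(0, n_stages)
  )
  amplitude * base
}

#' Simulate multi-species time-course expression matrices
#'
#' Generates, per species, a gene-by-sample FPKM-like matrix with planted
#' co-expression modules, interspecific differentially expressed genes and
#' paralog duplications, together with the ground truth needed to score
#' downstream recovery. Expression is generated on the log2 scale (a shared
#' latent profile per module plus Gaussian noise calibrated so the expected
#' pairwise log-scale correlation of module members equals the module's
#' target) and then exponentiated, which yields the positivity and right
#' skew typical of FPKM data.
#'
#' @param config A [sim_config()].
#' @return A list with `expression` (named list of [expr_matrix()], one per
#'   species) and `truth` (list with tibbles `modules`, `genes`, `de_genes`,
#'   `orthology`; see Details).
#' @details `truth$modules` maps each core gene id to its planted module
#'   ("M1" is the oil module, "0" background). `truth$orthology` assigns
#'   every per-species gene id to a cross-species family; genes of the same
#'   family are true orthologs. Paralog children carry the suffix `p<j>` and
#'   form their own family. Diverged children are labelled module "0".
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_stages <- length(config$stages)
  n_samp <- n_stages * config$n_replicates
  sizes <- vapply(config$planted_modules, `[[`, 1, "size")
  n_module <- sum(sizes)
  n_core <- n_module + config$n_background_genes
  core_ids <- sprintf("g%04d", seq_len(n_core))
  module_of <- rep("0", n_core)
  module_of[seq_len(n_module)] <-
    rep(paste0("M", seq_along(sizes)), times = sizes)

  # families: one per core gene, plus one per paralog child
  pe <- config$paralog_events
  child_rows <- if (nrow(pe)) {
    purrr::pmap_dfr(pe, function(ancestral, children, diverged) {
      tibble(ancestral = ancestral,
             family = paste0(core_ids[ancestral], "p", seq_len(children)),
             diverged = diverged)
    })
  } else tibble(ancestral = integer(), family = character(),
                diverged = logical())

  # per-gene shared baselines and lengths (shared across species so that
  # only planted DE genes differ in expected level between species)
  baseline <- runif(n_core, config$baseline_range[1], config$baseline_range[2])
  lengths_core <- sample(500:3000, n_core, replace = TRUE)
  lengths_child <- if (nrow(child_rows))
    setNames(sample(500:3000, nrow(child_rows), replace = TRUE),
             child_rows$family) else numeric()

  stage_of_sample <- rep(config$stages, each = config$n_replicates)
  rep_of_sample <- rep(seq_len(config$n_replicates), times = n_stages)

  expression <- list()
  genes_truth <- list()
  for (si in seq_len(config$n_species)) {
    sp <- config$species[si]
    logm <- matrix(0, n_core + nrow(child_rows), n_samp)
    ids <- c(paste0(sp, "_", core_ids),
             if (nrow(child_rows)) paste0(sp, "_", child_rows$family))
    rownames(logm) <- ids

    # planted modules: shared latent per module, noise calibrated to the
    # correlation target; background: i.i.d. noise
    latents <- list()
    offset <- 0L
    for (mi in seq_along(config$planted_modules)) {
      pm <- config$planted_modules[[mi]]
      shp <- shape_profile(pm$shape, n_stages, config$amplitude)
      latent <- shp[match(stage_of_sample, config$stages)] +
        rnorm(n_samp, 0, config$noise_sd)
      latents[[mi]] <- latent
      rows <- offset + seq_len(pm$size)
      if (pm$cor <= 0) {
        noise_sd_g <- config$noise_sd
        for (g in rows) logm[g, ] <- baseline[g] + rnorm(n_samp, 0, noise_sd_g)
      } else {
        v <- stats::var(latent)
        noise_sd_g <- sqrt(v * (1 - pm$cor) / pm$cor)
        for (g in rows) {
          logm[g, ] <- baseline[g] + latent + rnorm(n_samp, 0, noise_sd_g)
        }
      }
      offset <- offset + pm$size
    }
    if (config$n_background_genes > 0) {
      bg <- (n_module + 1):n_core
      logm[bg, ] <- baseline[bg] +
        matrix(rnorm(length(bg) * n_samp, 0, config$noise_sd),
               length(bg), n_samp)
    }

    # paralog children copy the ancestral expected profile; diverged children
    # get a stage-shifted latent (subfunctionalisation)
    if (nrow(child_rows)) {
      for (ci in seq_len(nrow(child_rows))) {
        anc <- child_rows$ancestral[ci]
        mi <- match(module_of[anc], paste0("M", seq_along(sizes)))
        if (!is.na(mi)) {
          pm <- config$planted_modules[[mi]]
          latent <- latents[[mi]]
          if (child_rows$diverged[ci]) {
            shp <- shape_profile(pm$shape, n_stages, config$amplitude)
            shifted <- shp[(seq_len(n_stages) + floor(n_stages / 2) - 1) %%
                             n_stages + 1]
            latent <- shifted[match(stage_of_sample, config$stages)] +
              rnorm(n_samp, 0, config$noise_sd)
          }
          v <- stats::var(latent)
          nsd <- if (pm$cor > 0) sqrt(v * (1 - pm$cor) / pm$cor) else config$noise_sd
          logm[n_core + ci, ] <- baseline[anc] + latent + rnorm(n_samp, 0, nsd)
        } else {
          logm[n_core + ci, ] <- baseline[anc] + rnorm(n_samp, 0, config$noise_sd)
        }
      }
    }

    de_sp <- dplyr::filter(config$de_genes, .data$species == si)
    if (nrow(de_sp)) {
      logm[de_sp$gene, ] <- logm[de_sp$gene, , drop = FALSE] + de_sp$log2fc
    }

    sample_ids <- paste(sp, stage_of_sample, rep_of_sample, sep = ".")
    colnames(logm) <- sample_ids
    samples <- tibble(sample = sample_ids, species = sp, tissue = "seed",
                      stage_daf = stage_of_sample, replicate = rep_of_sample)
    gl <- setNames(c(lengths_core, unname(lengths_child)), ids)
    expression[[sp]] <- expr_matrix(2^logm, samples, unit = "fpkm",
                                    gene_lengths = gl)
    genes_truth[[sp]] <- tibble(
      species = sp, gene_id = ids,
      family = c(core_ids, child_rows$family),
      module = c(module_of,
                 ifelse(child_rows$diverged, "0",
                        module_of[child_rows$ancestral])),
      length = unname(gl)
    )
  }

  genes <- dplyr::bind_rows(genes_truth)
  truth <- list(
    modules = tibble(core_id = core_ids, module = module_of),
    genes = genes,
    de_genes = dplyr::mutate(config$de_genes,
                             core_id = core_ids[.data$gene],
                             species = config$species[.data$species]),
    orthology = dplyr::select(genes, "family", "species", "gene_id")
  )
  list(expression = expression, truth = truth)
}

#' Simulate fatty-acid composition trajectories
#'
#' Builds per-species, per-stage fatty-acid mass-fraction profiles whose
#' final-stage composition satisfies the chosen omega-6 and omega-3
#' desaturation efficiencies exactly, by constructive inversion: given the
#' C18 unsaturated pool T, 18:3 = T * DE6 * DE3, 18:2 = T * DE6 * (1 - DE3),
#' 18:1 = T * (1 - DE6). Earlier stages interpolate linearly from a uniform
#' composition, mirroring the emergence of interspecific differences during
#' oil accumulation.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `species`, `stage_daf`, `replicate` and one
#'   column per [fa_keys()] entry; attribute `"targets"` holds the per-species
#'   efficiency targets.
#' @export
simulate_fa_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  keys <- fa_keys()
  n_stages <- length(config$stages)
  out <- purrr::map_dfr(seq_len(config$n_species), function(si) {
    de6 <- config$omega6_de_target[si]
    de3 <- config$omega3_de_target[si]
    if (de6 <= 0 && de3 > 0) {
      stop_oilnet("omega6 target of 0 with a positive omega3 target has no substrate path")
    }
    final <- fa_final_composition(de6, de3, config$c18_pool)
    start <- setNames(rep(1 / length(keys), length(keys)), keys)
    purrr::map_dfr(seq_len(n_stages), function(i) {
      w <- (i - 1) / (n_stages - 1)
      comp <- (1 - w) * start + w * final
      purrr::map_dfr(seq_len(config$n_replicates), function(r) {
        tibble(species = config$species[si], stage_daf = config$stages[i],
               replicate = r, !!!as.list(comp))
      })
    })
  })
  attr(out, "targets") <- tibble(
    species = config$species,
    omega6_de = config$omega6_de_target,
    omega3_de = config$omega3_de_target
  )
  out
}

# constructive inversion of the desaturation-efficiency formulas; the
# saturated remainder (1 - pool) is split in fixed proportions
fa_final_composition <- function(de6, de3, pool) {
  unsat <- c("C18:1" = pool * (1 - de6),
             "C18:2" = pool * de6 * (1 - de3),
             "C18:3" = pool * de6 * de3)
  rest <- 1 - pool
  sat <- rest * c("C16:0" = 0.45, "C18:0" = 0.25, "C20:0" = 0.15,
                  "C22:0" = 0.10, "other" = 0.05)
  comp <- c(sat[c("C16:0", "C18:0")], unsat, sat[c("C20:0", "C22:0", "other")])
  comp[fa_keys()]
}

#' Simulate a cross-species similarity hit table
#'
#' Emulates the tabular output of a sequence-similarity search between the
#' species' transcript sets: every true ortholog pair (same family in
#' `truth$orthology`) receives the top reciprocal score, and a configurable
#' fraction of decoy hits receives strictly lower scores, so reciprocal-best-
#' hit inference can be exercised at known truth.
#'
#' @param truth The `truth` element returned by [simulate_expression()].
#' @param decoy_rate Decoy hits as a fraction of the number of true directed
#'   hits, in \[0, 1).
#' @param seed Integer seed.
#' @return Tibble with columns `query`, `subject`, `qspecies`, `sspecies`,
#'   `score`, `identity`, `coverage` (both directions for every hit).
#' @export
simulate_similarity_table <- function(truth, decoy_rate = 0.2, seed = 1) {
  if (!nrow(truth$orthology)) stop_oilnet("`truth` has no orthology records")
  if (decoy_rate >= 1 || decoy_rate < 0) {
    stop_oilnet("`decoy_rate` must be in [0, 1)")
  }
  set.seed(seed)
  orth <- truth$orthology
  species <- unique(orth$species)
  pairs <- utils::combn(species, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    a <- dplyr::filter(orth, .data$species == pr[1])
    b <- dplyr::filter(orth, .data$species == pr[2])
    m <- dplyr::inner_join(a, b, by = "family", suffix = c("_a", "_b"))
    true_hits <- tibble(
      query = m$gene_id_a, subject = m$gene_id_b,
      qspecies = pr[1], sspecies = pr[2],
      score = runif(nrow(m), 150, 200),
      identity = runif(nrow(m), 0.85, 0.99),
      coverage = runif(nrow(m), 0.85, 0.99)
    )
    n_decoy <- floor(decoy_rate * nrow(m))
    decoys <- if (n_decoy > 0) {
      qi <- sample(nrow(a), n_decoy, replace = TRUE)
      si <- sample(nrow(b), n_decoy, replace = TRUE)
      keep <- a$family[qi] != b$family[si]
      tibble(
        query = a$gene_id[qi][keep], subject = b$gene_id[si][keep],
        qspecies = pr[1], sspecies = pr[2],
        score = runif(sum(keep), 20, 70),
        identity = runif(sum(keep), 0.30, 0.80),
        coverage = runif(sum(keep), 0.30, 0.80)
      )
    } else NULL
    dplyr::bind_rows(true_hits, decoys)
  })
  # symmetrize: emit the reverse direction for every record
  rev_rows <- tibble(
    query = rows$subject, subject = rows$query,
    qspecies = rows$sspecies, sspecies = rows$qspecies,
    score = rows$score, identity = rows$identity, coverage = rows$coverage
  )
  dplyr::distinct(dplyr::bind_rows(rows, rev_rows))
}
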
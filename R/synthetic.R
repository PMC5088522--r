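#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generator. Defaults emulate a
#' down-scaled multi-tissue FPKM study: 10 tissues with 3 biological
#' replicates each, 2000 genes of which a fraction are planted house-keeping
#' (HK, expressed in every sample) or tissue-enriched (TE, expressed in at
#' most three tissues), plus coexpressed modules sharing a latent per-tissue
#' profile. Full-size 32-tissue designs with 2-5 replicates are supported by
#' passing the corresponding vectors.
#'
#' @param n_tissues Number of tissues.
#' @param replicates_per_tissue Integer vector (length `n_tissues`) of
#'   biological replicates per tissue, each in 2..5 for realistic designs
#'   (values outside are allowed but warned about).
#' @param n_genes Total genes.
#' @param frac_hk,frac_te Fractions of planted HK and TE genes
#'   (`frac_hk + frac_te <= 1`).
#' @param n_modules,module_size Number and size of planted coexpression
#'   modules (module genes are drawn from the background class).
#' @param module_age_stage Integer vector (length `n_modules`) giving the
#'   hallmark stage (1-8) each module's genes are planted at.
#' @param noise_sd Per-sample log2-scale noise standard deviation.
#' @param seed Integer seed controlling all randomness downstream.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_tissues = 10L,
                              replicates_per_tissue = rep(3L, n_tissues),
                              n_genes = 2000L,
                              frac_hk = 0.20,
                              frac_te = 0.15,
                              n_modules = 5L,
                              module_size = 20L,
                              module_age_stage = c(1L, 2L, 5L, 7L, 8L)[seq_len(n_modules)],
                              noise_sd = 0.25,
                              seed = 1L) {
  if (length(replicates_per_tissue) != n_tissues) {
    abort("replicates_per_tissue must have length n_tissues")
  }
  if (frac_hk + frac_te > 1) abort("frac_hk + frac_te must be <= 1")
  if (any(c(n_tissues, replicates_per_tissue, n_genes, module_size) < 1) || n_modules < 0) {
    abort("all counts must be >= 1 (n_modules may be 0)")
  }
  if (length(module_age_stage) != n_modules ||
      (n_modules > 0 && (anyNA(module_age_stage) || any(module_age_stage < 1 | module_age_stage > 8)))) {
    abort("module_age_stage must give a stage in 1-8 for each module")
  }
  if (any(replicates_per_tissue < 2 | replicates_per_tissue > 5)) {
    warn("replicates_per_tissue outside 2-5 departs from the emulated design")
  }
  structure(
    list(
      n_tissues = as.integer(n_tissues),
      replicates_per_tissue = as.integer(replicates_per_tissue),
      n_genes = as.integer(n_genes),
      frac_hk = frac_hk, frac_te = frac_te,
      n_modules = as.integer(n_modules),
      module_size = as.integer(module_size),
      module_age_stage = as.integer(module_age_stage),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# default stage-level planting weights; HK old-skewed and TE young-skewed as
# in real tissue transcriptomes, background roughly follows the genome-wide
# hallmark distribution
stage_weights <- function(class) {
  switch(class,
    HK = c(25, 30, 10, 15, 10, 5, 4, 1),
    TE = c(2, 3, 5, 10, 15, 20, 37, 8),
    background = c(1178, 2178, 1395, 2333, 5070, 1953, 2821, 509)
  )
}

#' Plant ground-truth gene classes, ages and modules
#'
#' Assigns every simulated gene a class (HK, TE or background), a planted
#' lineage clade index (via stage-level weights: HK genes skew ancient, TE
#' genes skew recent, background follows a genome-wide hallmark profile),
#' and, for module genes, a module id and the module's planted stage.
#'
#' @param config A [simulation_config()].
#' @param lineage Lineage tibble (default [human_lineage()]).
#' @param scheme Stage scheme over `lineage` (default [human_stage_scheme()]).
#' @return A tibble (`gene_id`, `class`, `clade_index`, `module_id`).
#' @export
simulate_truth <- function(config, lineage = human_lineage(),
                           scheme = human_stage_scheme(lineage)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  n_hk <- round(config$frac_hk * n)
  n_te <- round(config$frac_te * n)
  n_mod <- config$n_modules * config$module_size
  if (n_hk + n_te + n_mod > n) abort("planted classes and modules exceed n_genes")
  gene_id <- sprintf("g%05d", seq_len(n))
  class <- rep("background", n)
  class[seq_len(n_hk)] <- "HK"
  class[n_hk + seq_len(n_te)] <- "TE"
  module_id <- rep(NA_character_, n)
  mod_idx <- n_hk + n_te + seq_len(n_mod)
  module_id[mod_idx] <- rep(sprintf("m%02d", seq_len(config$n_modules)),
                            each = config$module_size)

  sample_clade <- function(class_label, k) {
    w_stage <- stage_weights(class_label)
    stages <- sample(seq_len(8), k, replace = TRUE, prob = w_stage)
    vapply(stages, function(s) {
      idx <- scheme$clade_index[scheme$stage == s]
      if (length(idx) == 1) idx else sample(idx, 1L)
    }, integer(1))
  }
  clade <- integer(n)
  clade[class == "HK"] <- sample_clade("HK", sum(class == "HK"))
  clade[class == "TE"] <- sample_clade("TE", sum(class == "TE"))
  bg <- class == "background" & is.na(module_id)
  clade[bg] <- sample_clade("background", sum(bg))
  for (m in seq_len(config$n_modules)) {
    rows <- which(module_id == sprintf("m%02d", m))
    idx <- scheme$clade_index[scheme$stage == config$module_age_stage[m]]
    clade[rows] <- if (length(idx) == 1) idx else sample(idx, length(rows), replace = TRUE)
  }
  tibble(gene_id = gene_id, class = class, clade_index = clade, module_id = module_id)
}

#' Generate ortholog groups whose LCA equals each gene's planted clade
#'
#' The inverse of gene dating: for each gene with planted clade index k, the
#' group contains the focal species, at least one species attached at clade
#' k, and possibly further species attached at or below k, so that the
#' group's LCA projected on the lineage is exactly clade k. A gene planted at
#' the focal clade yields the degenerate single-member group (focal species
#' only).
#'
#' @param taxonomy A taxonomy from [generate_taxonomy()] (needs the
#'   `attachment` attribute).
#' @param truth Ground-truth tibble from [simulate_truth()].
#' @param seed Integer seed.
#' @return A tibble (`group_id`, `gene_id`, `species` list-column of leaf
#'   node ids).
#' @export
generate_ortholog_groups <- function(taxonomy, truth, seed = 1L) {
  attachment <- attr(taxonomy, "attachment")
  focal <- attr(taxonomy, "focal_id")
  if (is.null(attachment) || is.null(focal)) {
    abort("taxonomy lacks attachment/focal metadata; use generate_taxonomy()")
  }
  set.seed(seed)
  n_lineage <- max(attachment)
  leaves_at <- split(names(attachment), attachment)
  leaves_at <- lapply(leaves_at, setdiff, y = focal)
  species <- lapply(seq_len(nrow(truth)), function(i) {
    k <- truth$clade_index[i]
    if (k == n_lineage) return(focal)
    at_k <- leaves_at[[as.character(k)]]
    if (is.null(at_k) || length(at_k) == 0) {
      abort(sprintf("no off-path species available at clade %d", k))
    }
    core <- sample(at_k, sample(seq_len(min(2L, length(at_k))), 1L))
    deeper_idx <- names(leaves_at)[as.integer(names(leaves_at)) > k]
    deeper <- unlist(leaves_at[deeper_idx], use.names = FALSE)
    n_extra <- if (length(deeper) > 0) sample(0:min(3L, length(deeper)), 1L) else 0L
    extra <- if (n_extra > 0) sample(deeper, n_extra) else character(0)
    unique(c(focal, core, extra))
  })
  tibble(
    group_id = sprintf("og%05d", seq_len(nrow(truth))),
    gene_id = truth$gene_id,
    species = species
  )
}

#' Generate a synthetic FPKM expression matrix with planted structure
#'
#' Values are generated in log2(FPKM + 1) space and transformed back to FPKM.
#' HK genes get a gene-level baseline (mean 5 log2 units) and are clamped to
#' stay at or above FPKM 1 in every sample; TE genes are expressed (>= FPKM 1,
#' mean 3 log2 units) in all replicates of 1-3 randomly chosen tissues and
#' drawn uniform on [0, 0.5) FPKM elsewhere; module genes share a latent
#' per-tissue profile (per-tissue N(5, 2) truncated at 0 in log2, broadcast
#' to replicates) plus a nonnegative gene-level offset, so pairwise Spearman
#' correlation within a module is high by construction and exactly 1 at
#' `noise_sd = 0`; background genes are
#' independent noise around a gene-level baseline (mean 3 log2 units).
#'
#' @param config A [simulation_config()].
#' @param truth Ground-truth tibble from [simulate_truth()].
#' @return A list with `expression` (tibble: `gene_id` + one column per
#'   sample, FPKM scale) and `design` (tibble: `sample_id`, `tissue`,
#'   `replicate`).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  design <- purrr::map_dfr(seq_len(config$n_tissues), function(t) {
    tibble(
      sample_id = sprintf("%s_r%d", tissues[t], seq_len(config$replicates_per_tissue[t])),
      tissue = tissues[t],
      replicate = seq_len(config$replicates_per_tissue[t])
    )
  })
  n_samp <- nrow(design)
  tissue_of <- match(design$tissue, tissues)
  n <- config$n_genes
  log2v <- matrix(0, nrow = n, ncol = n_samp,
                  dimnames = list(truth$gene_id, design$sample_id))

  hk <- which(truth$class == "HK")
  if (length(hk) > 0) {
    base <- rnorm(length(hk), mean = 5, sd = 1)
    noise <- matrix(rnorm(length(hk) * n_samp, 0, config$noise_sd), ncol = n_samp)
    log2v[hk, ] <- pmax(base + noise, 1)
  }

  te <- which(truth$class == "TE")
  for (i in te) {
    k <- sample(1:3, 1L)
    on <- sample(tissues, k)
    on_cols <- design$tissue %in% on
    level <- 3 + rnorm(1)
    log2v[i, on_cols] <- pmax(level + rnorm(sum(on_cols), 0, config$noise_sd), 1)
    log2v[i, !on_cols] <- log2(runif(sum(!on_cols), 0, 0.5) + 1)
  }

  mod_ids <- sort(unique(truth$module_id[!is.na(truth$module_id)]))
  for (m in mod_ids) {
    rows <- which(truth$module_id %in% m)
    # nonnegative latent + offset by construction, so the rank pattern of a
    # noise-free module is shared exactly by all its genes
    latent <- pmax(rnorm(config$n_tissues, mean = 5, sd = 2), 0)
    offs <- abs(rnorm(length(rows), 0, 1))
    prof <- latent[tissue_of]
    noise <- matrix(rnorm(length(rows) * n_samp, 0, config$noise_sd), ncol = n_samp)
    log2v[rows, ] <- pmax(sweep(noise, 2, prof, "+") + offs, 0)
  }

  bg <- which(truth$class == "background" & is.na(truth$module_id))
  if (length(bg) > 0) {
    base <- rnorm(length(bg), mean = 3, sd = 1)
    noise <- matrix(rnorm(length(bg) * n_samp, 0, config$noise_sd), ncol = n_samp)
    log2v[bg, ] <- pmax(base + noise, 0)
  }

  fpkm <- 2^log2v - 1
  list(expression = expr_from_matrix(fpkm, scale = "fpkm"), design = design)
}

#' Run the whole synthetic-data generator
#'
#' Convenience wrapper producing a coherent simulated study: lineage, stage
#' scheme, taxonomy, ground truth, ortholog groups, expression matrix, design
#' and the planted HK reference list.
#'
#' @param config A [simulation_config()].
#' @param lineage,scheme Lineage and stage scheme (defaults: human 31-clade
#'   lineage with the eight-hallmark scheme).
#' @param species_per_clade Off-path species per lineage clade in the
#'   generated taxonomy.
#' @return A list of class `sim_dataset` with components `config`, `lineage`,
#'   `scheme`, `taxonomy`, `truth`, `groups`, `expression`, `design`,
#'   `hk_reference`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             lineage = human_lineage(),
                             scheme = human_stage_scheme(lineage),
                             species_per_clade = 2L) {
  truth <- simulate_truth(config, lineage, scheme)
  taxonomy <- generate_taxonomy(lineage, species_per_clade, seed = config$seed)
  groups <- generate_ortholog_groups(taxonomy, truth, seed = config$seed + 2L)
  ex <- generate_expression(config, truth)
  structure(
    list(
      config = config, lineage = lineage, scheme = scheme, taxonomy = taxonomy,
      truth = truth, groups = groups,
      expression = ex$expression, design = ex$design,
      hk_reference = truth$gene_id[truth$class == "HK"]
    ),
    class = "sim_dataset"
  )
}
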
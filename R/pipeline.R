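#' Run the full analysis pipeline on a simulated or loaded dataset
#'
#' Orchestrates the pipeline end to end: synthetic-data generation (or
#' user-supplied inputs), expression filtering and calls, house-keeping /
#' tissue-enriched classification with overlap statistics, ortholog-group
#' gene dating and stage profiles, the resampling-validated coexpression
#' network with MCODE modules and their age composition, and (optionally)
#' term enrichment of the recovered modules. All thresholds sit in `config`;
#' every stochastic step derives its stream from the single run seed.
#'
#' @param config Named list (or path to a YAML file) with any of:
#'   `fpkm_threshold` (1), `r_min` (0.85), `n_iter` (100),
#'   `reps_per_tissue` (2), `max_te_tissues` (3), `min_group` (5), `seed`
#'   (1), and a `simulation` sublist passed to [simulation_config()]. Unknown
#'   entries are rejected.
#' @param data Optional `sim_dataset` (from [simulate_dataset()]); when
#'   absent one is simulated from `config$simulation`.
#' @param annotations Optional annotation tibble for module enrichment.
#' @param out_dir Optional directory; when given, all stage outputs
#'   (expression, design, calls, classes, assignment, edge list, GraphML,
#'   module membership, summary JSON and a reproducibility manifest) are
#'   written there.
#' @return A list of class `phylomark_run` with the stage results and a
#'   `summary` list of headline counts.
#' @export
run_pipeline <- function(config = list(), data = NULL, annotations = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    fpkm_threshold = 1, r_min = 0.85, n_iter = 100L, reps_per_tissue = 2L,
    max_te_tissues = 3L, min_group = 5L, seed = 1L, simulation = list()
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste("unknown config entries:", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config)

  if (is.null(data)) {
    sim_args <- cfg$simulation
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    data <- simulate_dataset(sim_cfg)
  }

  expr <- filter_expressed_genes(data$expression, data$design,
                                 threshold = cfg$fpkm_threshold)
  calls <- detect_expressed(expr, data$design, threshold = cfg$fpkm_threshold)
  log_expr <- log_transform(expr)

  hk <- classify_housekeeping(calls, data$hk_reference)
  te <- classify_tissue_enriched(calls, max_tissues = cfg$max_te_tissues)
  overlap <- overlap_odds_ratio(nrow(expr), calls$gene_id[calls$expressed_in_all_samples],
                                intersect(data$hk_reference, expr$gene_id))
  contrast <- if (length(hk) >= 2 && length(te) >= 2) {
    compare_class_expression(log_expr, hk, te)
  } else NULL

  assignment <- assign_gene_ages(data$groups, data$taxonomy, data$lineage,
                                 scheme = data$scheme)
  profile_all <- stage_profile(assignment, data$scheme, label = "all")
  profile_hk <- if (length(intersect(hk, assignment$gene_id)) > 0) {
    stage_profile(assignment, data$scheme, subset = intersect(hk, assignment$gene_id), label = "HK")
  } else NULL
  profile_te <- if (length(intersect(te, assignment$gene_id)) > 0) {
    stage_profile(assignment, data$scheme, subset = intersect(te, assignment$gene_id), label = "TE")
  } else NULL

  candidates <- candidate_edges(log_expr, r_min = cfg$r_min)
  validated <- resample_validate(log_expr, data$design, candidates,
                                 n_iter = cfg$n_iter,
                                 reps_per_tissue = cfg$reps_per_tissue,
                                 r_min = cfg$r_min, seed = cfg$seed + 10L)
  network <- build_network(validated)
  network_min <- filter_min_group(network, min_size = cfg$min_group)
  modules <- mcode_modules(network_min)
  composition <- if (nrow(modules$modules) > 0) {
    module_age_composition(modules, assignment)
  } else NULL
  homogeneity <- if (nrow(modules$modules) > 0 &&
                     length(unique(assignment$stage)) > 1) {
    age_homogeneity_test(modules, assignment,
                         network_genes = igraph::V(network_min)$name,
                         seed = cfg$seed + 20L)
  } else NULL
  module_enrichment <- if (!is.null(annotations) && nrow(modules$modules) > 0) {
    purrr::map_dfr(seq_len(nrow(modules$modules)), function(i) {
      hypergeom_enrich(intersect(modules$modules$members[[i]], expr$gene_id),
                       expr$gene_id, annotations) |>
        mutate(module_id = modules$modules$module_id[i], .before = 1)
    })
  } else NULL

  summary <- list(
    n_genes_expressed = nrow(expr),
    n_expressed_in_all_samples = sum(calls$expressed_in_all_samples),
    n_ubiquitous = sum(calls$expressed_in_all_tissues),
    n_hk = length(hk),
    n_te = length(te),
    overlap_or = overlap$odds_ratio,
    mean_hk_te_diff = if (!is.null(contrast)) contrast$mean_diff else NA_real_,
    n_genes_dated = nrow(assignment),
    stage_counts = setNames(profile_all$stages$n, profile_all$stages$stage_label),
    n_candidate_edges = nrow(candidates),
    n_validated_edges = sum(validated$validated),
    network_nodes = igraph::vcount(network),
    network_edges = igraph::ecount(network),
    n_modules = nrow(modules$modules),
    seed = cfg$seed
  )

  result <- structure(
    list(
      config = cfg, data = data, calls = calls, hk = hk, te = te,
      overlap = overlap, contrast = contrast, assignment = assignment,
      profiles = list(all = profile_all, HK = profile_hk, TE = profile_te),
      candidates = candidates, validated = validated,
      network = network, network_min = network_min, modules = modules,
      composition = composition, homogeneity = homogeneity,
      module_enrichment = module_enrichment,
      summary = summary
    ),
    class = "phylomark_run"
  )
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

# serialise all stage outputs plus a reproducibility manifest
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_expression_tsv(run$data$expression, p("expression.tsv"))
  write_design_tsv(run$data$design, p("design.tsv"))
  readr::write_tsv(run$calls, p("expression_calls.tsv"))
  readr::write_tsv(
    tibble(gene_id = c(run$hk, run$te),
           class = c(rep("HK", length(run$hk)), rep("TE", length(run$te)))),
    p("gene_classes.tsv")
  )
  jsonlite::write_json(tidy(run$overlap), p("overlap_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(run$assignment, p("age_assignment.tsv"))
  readr::write_tsv(run$profiles$all$stages, p("stage_profile_all.tsv"))
  write_edges_tsv(run$validated, p("edges.tsv"))
  write_network_graphml(run$network_min, p("network.graphml"))
  if (nrow(run$modules$modules) > 0) {
    readr::write_tsv(module_members(run$modules), p("module_membership.tsv"))
  }
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "phylomark",
    version = as.character(utils::packageVersion("phylomark")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = run$config$seed,
    config_hash = rlang::hash(run$config)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.phylomark_run <- function(x, ...) {
  s <- x$summary
  cat("phylomark pipeline run\n")
  cat(sprintf("  expressed genes: %d (in all samples: %d; ubiquitous: %d)\n",
              s$n_genes_expressed, s$n_expressed_in_all_samples, s$n_ubiquitous))
  cat(sprintf("  HK: %d, TE: %d (overlap OR = %.2f)\n", s$n_hk, s$n_te, s$overlap_or))
  cat(sprintf("  dated genes: %d; validated edges: %d; network: %d nodes / %d edges; modules: %d\n",
              s$n_genes_dated, s$n_validated_edges, s$network_nodes,
              s$network_edges, s$n_modules))
  invisible(x)
}
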
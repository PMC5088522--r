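# parent lookup named vector for a validated taxonomy
tax_parent <- function(tree) {
  setNames(tree$parent_id, tree$node_id)
}

# node -> ordered root path (node first, root last)
root_path <- function(parent, node) {
  path <- character(0)
  cur <- node
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- parent[[cur]]
  }
  path
}

#' Lowest common ancestor of a taxon set
#'
#' The deepest taxonomy node that is an ancestor-or-self of every taxon in
#' the set. A single taxon is its own LCA.
#'
#' @param tree Taxonomy tibble (`node_id`, `parent_id`, `name`).
#' @param taxa Nonempty character vector of node ids.
#' @return The LCA node id.
#' @export
lca <- function(tree, taxa) {
  validate_taxonomy(tree)
  if (length(taxa) == 0) abort("taxa must be nonempty")
  unknown <- setdiff(taxa, tree$node_id)
  if (length(unknown) > 0) {
    abort(paste("unknown taxa:", paste(head(unknown, 5), collapse = ", ")))
  }
  parent <- tax_parent(tree)
  common <- root_path(parent, taxa[1])
  for (t in taxa[-1]) {
    cur <- t
    while (!(cur %in% common)) cur <- parent[[cur]]
    common <- common[match(cur, common):length(common)]
  }
  common[1]
}

# deepest lineage ancestor index for every taxonomy node (0 = none)
lineage_projection <- function(tree, lineage) {
  parent <- tax_parent(tree)
  proj <- setNames(rep(0L, nrow(tree)), tree$node_id)
  proj[lineage$node_id] <- lineage$clade_index
  # resolve children after parents: iterate until stable (tree depth passes)
  todo <- tree$node_id[proj == 0L]
  while (length(todo) > 0) {
    resolved <- vapply(todo, function(v) {
      p <- parent[[v]]
      if (is.na(p)) 0L else proj[[p]]
    }, integer(1))
    proj[todo] <- resolved
    todo <- todo[resolved == 0L & !is.na(parent[todo])]
    if (length(todo) > 0 && all(proj[vapply(todo, function(v) parent[[v]], character(1))] == 0L)) break
  }
  proj
}

#' Date genes by the LCA of their ortholog groups
#'
#' For each ortholog group, computes the LCA of its member species and
#' projects it onto the focal lineage. Because the focal species is a member
#' of every (valid) group, the LCA always lies on the root-to-focal lineage
#' and maps to a unique clade index; internally the projection uses the fact
#' that the LCA's lineage level is the shallowest attachment level among the
#' members, which matches the generic [lca()] (this equality is exercised in
#' the test-suite). Groups lacking the focal species are skipped with a
#' warning and counted in the `n_skipped` attribute.
#'
#' @param groups Ortholog-group tibble (`group_id`, `gene_id`, `species`
#'   list-column).
#' @param tree Taxonomy tibble.
#' @param lineage Lineage tibble; `node_id`s must exist in `tree`.
#' @param scheme Optional stage scheme; when supplied a `stage` column is
#'   added.
#' @param focal_id Focal species leaf id (defaults to the taxonomy's
#'   `focal_id` attribute).
#' @return An age-assignment tibble (`gene_id`, `clade_index`, `clade_name`,
#'   `age_mya`[, `stage`]) with attribute `n_skipped`.
#' @export
assign_gene_ages <- function(groups, tree, lineage, scheme = NULL,
                             focal_id = attr(tree, "focal_id")) {
  validate_taxonomy(tree)
  validate_lineage(lineage)
  if (is.null(focal_id)) abort("focal_id not given and not carried by the taxonomy")
  if (!all(lineage$node_id %in% tree$node_id)) abort("lineage nodes missing from taxonomy")
  proj <- lineage_projection(tree, lineage)
  has_focal <- vapply(groups$species, function(s) focal_id %in% s, logical(1))
  n_skipped <- sum(!has_focal)
  if (n_skipped > 0) {
    warn(sprintf("%d ortholog groups lack the focal species and were skipped", n_skipped))
  }
  kept <- groups[has_focal, , drop = FALSE]
  clade <- vapply(kept$species, function(s) {
    p <- proj[s]
    if (any(p == 0L)) {
      abort("group member not below the lineage root; cannot project LCA")
    }
    min(p)
  }, integer(1))
  out <- tibble(
    gene_id = kept$gene_id,
    clade_index = clade,
    clade_name = lineage$clade_name[clade],
    age_mya = lineage$age_mya[clade]
  )
  if (!is.null(scheme)) {
    out$stage <- scheme$stage[match(out$clade_index, scheme$clade_index)]
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

stage_profile_new <- function(stage_counts, clade_counts = NULL, label = "all") {
  total <- sum(stage_counts$n)
  stage_counts <- stage_counts |>
    mutate(
      pct_of_total = 100 * .data$n / total,
      cumulative_pct = cumsum(100 * .data$n / total)
    )
  structure(
    list(stages = stage_counts, clades = clade_counts, total = total, label = label),
    class = "stage_profile"
  )
}

#' Per-stage gene counts and cumulative emergence percentages
#'
#' Bins an age assignment into hallmark stages and computes, per stage, the
#' gene count, its percentage of the total, and the cumulative percentage in
#' lineage order (which always ends at 100). Can also be fed a bare numeric
#' vector of per-stage counts (e.g. a published count table) to recompute the
#' percentages.
#'
#' @param x An age-assignment tibble (from [assign_gene_ages()]) or a numeric
#'   vector of per-stage counts.
#' @param scheme Stage scheme (required for assignments).
#' @param subset Optional character vector of gene ids restricting the
#'   profile to a gene class (must be nonempty and within the assignment).
#' @param label Free-text label for the profiled gene class.
#' @param ... Unused.
#' @return An object of class `stage_profile` with components `stages`
#'   (tibble: `stage`, `stage_label`, `n`, `pct_of_total`, `cumulative_pct`),
#'   `clades` (per-clade counts, assignments only), `total` and `label`.
#' @export
stage_profile <- function(x, ...) UseMethod("stage_profile")

#' @rdname stage_profile
#' @export
stage_profile.numeric <- function(x, label = "all", ...) {
  if (any(x < 0)) abort("stage counts must be nonnegative")
  stage_profile_new(
    tibble(stage = seq_along(x), stage_label = sprintf("st%d", seq_along(x)), n = as.numeric(x)),
    label = label
  )
}

#' @rdname stage_profile
#' @export
stage_profile.data.frame <- function(x, scheme, subset = NULL, label = "all", ...) {
  assignment <- x
  if (!is.null(subset)) {
    if (length(subset) == 0) abort("subset is empty")
    missing <- setdiff(subset, assignment$gene_id)
    if (length(missing) > 0) {
      abort(paste("subset genes without age assignment:", paste(head(missing, 5), collapse = ", ")))
    }
    assignment <- assignment[assignment$gene_id %in% subset, , drop = FALSE]
  }
  if (nrow(assignment) == 0) abort("no genes to profile")
  clade_tab <- assignment |>
    count(.data$clade_index, name = "n") |>
    right_join(scheme, by = "clade_index") |>
    mutate(n = ifelse(is.na(.data$n), 0, .data$n)) |>
    arrange(.data$clade_index) |>
    select("clade_index", "stage", "stage_label", "n")
  stage_tab <- clade_tab |>
    group_by(.data$stage, .data$stage_label) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    arrange(.data$stage)
  stage_profile_new(stage_tab, clade_counts = clade_tab, label = label)
}

#' @export
print.stage_profile <- function(x, ...) {
  cat(sprintf("Stage profile (%s): %d genes over %d stages\n",
              x$label, round(x$total), nrow(x$stages)))
  print(x$stages, n = nrow(x$stages))
  invisible(x)
}

#' Collapse two age assignments onto a common stratification
#'
#' To compare gene-age assignments made on different (but nested) lineages,
#' both are collapsed onto a shared set of ordered strata; per stratum the
#' gene counts and within-assignment proportions are reported side by side.
#'
#' @param a,b Age-assignment tibbles.
#' @param map_a,map_b Tibbles (`clade_index`, `stratum`) mapping each
#'   assignment's clade indices onto the common strata; every clade index
#'   present in the assignment must be covered, and stratum order must be
#'   shared.
#' @return A tibble (`stratum`, `n_a`, `n_b`, `prop_a`, `prop_b`).
#' @export
collapse_to_common_strata <- function(a, b, map_a, map_b) {
  check_map <- function(assignment, map, who) {
    missing <- setdiff(unique(assignment$clade_index), map$clade_index)
    if (length(missing) > 0) {
      abort(sprintf("%s: clade indices not covered by the common strata: %s",
                    who, paste(head(missing, 5), collapse = ", ")))
    }
  }
  check_map(a, map_a, "a")
  check_map(b, map_b, "b")
  strata <- sort(unique(c(map_a$stratum, map_b$stratum)))
  count_on <- function(assignment, map) {
    s <- map$stratum[match(assignment$clade_index, map$clade_index)]
    as.numeric(table(factor(s, levels = strata)))
  }
  n_a <- count_on(a, map_a)
  n_b <- count_on(b, map_b)
  tibble(
    stratum = strata, n_a = n_a, n_b = n_b,
    prop_a = n_a / sum(n_a), prop_b = n_b / sum(n_b)
  )
}

#' Cumulative gene-emergence points on the time axis
#'
#' One point per lineage clade: x = clade age (Mya), y = cumulative
#' percentage of genes dated at or before that clade. As the age decreases
#' towards the present the cumulative percentage is nondecreasing and ends at
#' 100.
#'
#' @param lineage Lineage tibble with ages for every clade.
#' @param profile A `stage_profile` computed from an assignment (needs the
#'   per-clade counts).
#' @return A tibble (`clade_index`, `clade_name`, `age_mya`,
#'   `cumulative_pct`).
#' @export
time_axis <- function(lineage, profile) {
  if (is.null(profile$clades)) abort("profile lacks per-clade counts; compute it from an assignment")
  if (anyNA(lineage$age_mya)) {
    abort(paste("clades without age calibration:",
                paste(lineage$clade_name[is.na(lineage$age_mya)], collapse = ", ")))
  }
  cl <- profile$clades |> arrange(.data$clade_index)
  if (nrow(cl) != nrow(lineage)) abort("profile and lineage disagree on clade count")
  tibble(
    clade_index = lineage$clade_index,
    clade_name = lineage$clade_name,
    age_mya = lineage$age_mya,
    cumulative_pct = cumsum(100 * cl$n / sum(cl$n))
  )
}
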
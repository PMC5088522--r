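#' Candidate coexpression edges by full-sample Spearman correlation
#'
#' Computes the pairwise Spearman correlation of all genes across all samples
#' and keeps the unordered pairs at or above `r_min` (the threshold is
#' one-sided; strong anti-correlation does not form an edge). Zero-variance
#' genes have undefined correlation and are excluded up front, with the
#' count reported in the `n_zero_variance` attribute.
#'
#' @param expr Expression tibble (log2 scale conventionally; Spearman makes
#'   the choice moot).
#' @param r_min Correlation threshold (default 0.85, inclusive).
#' @return A tibble (`gene_a`, `gene_b`, `r`) with `gene_a < gene_b`.
#' @export
candidate_edges <- function(expr, r_min = 0.85) {
  m <- expr_as_matrix(expr)
  if (ncol(m) < 3) abort("need at least three samples")
  constant <- apply(m, 1, function(x) diff(range(x)) == 0)
  if (any(constant)) {
    inform(sprintf("%d zero-variance genes excluded from coexpression", sum(constant)))
    m <- m[!constant, , drop = FALSE]
  }
  r <- cor(t(m), method = "spearman")
  r[lower.tri(r, diag = TRUE)] <- NA
  hits <- which(r >= r_min, arr.ind = TRUE)
  out <- tibble(
    gene_a = rownames(r)[hits[, 1]],
    gene_b = colnames(r)[hits[, 2]],
    r = r[hits]
  ) |>
    arrange(.data$gene_a, .data$gene_b)
  attr(out, "n_zero_variance") <- sum(constant)
  out
}

#' Validate candidate edges by replicate resampling
#'
#' Repeats the correlation test on random subsamples that keep
#' `reps_per_tissue` replicates of every tissue (tissues with exactly that
#' many replicates contribute all of them deterministically), annotating for
#' each candidate pair the number of subsamples in which its Spearman
#' coefficient stays at or above `r_min`. The validated set is the pairs that
#' pass in every one of the `n_iter` subsamples. All randomness flows from a
#' single seeded generator, drawing tissues of iteration i before iteration
#' i + 1, so runs are reproducible and invariant to gene or edge order.
#'
#' @param expr Expression tibble.
#' @param design Sample design tibble.
#' @param candidates Candidate edge tibble from [candidate_edges()].
#' @param n_iter Number of resampling iterations (default 100).
#' @param reps_per_tissue Replicates drawn per tissue (default 2).
#' @param r_min Correlation threshold (default 0.85).
#' @param seed Integer seed.
#' @return The candidate tibble with an `n_validated` count column and a
#'   logical `validated` column (`n_validated == n_iter`).
#' @export
resample_validate <- function(expr, design, candidates, n_iter = 100L,
                              reps_per_tissue = 2L, r_min = 0.85, seed = 1L) {
  check_design(expr, design)
  if (nrow(candidates) == 0) {
    return(mutate(candidates, n_validated = integer(0), validated = logical(0)))
  }
  short <- design |>
    count(.data$tissue) |>
    filter(.data$n < reps_per_tissue)
  if (nrow(short) > 0) {
    abort(paste("tissues with fewer replicates than reps_per_tissue:",
                paste(short$tissue, collapse = ", ")))
  }
  genes <- sort(unique(c(candidates$gene_a, candidates$gene_b)))
  m <- expr_as_matrix(expr)[genes, design$sample_id, drop = FALSE]
  by_tissue <- split(design$sample_id, factor(design$tissue, levels = unique(design$tissue)))
  ia <- match(candidates$gene_a, genes)
  ib <- match(candidates$gene_b, genes)
  n_validated <- integer(nrow(candidates))
  set.seed(seed)
  for (iter in seq_len(n_iter)) {
    take <- unlist(lapply(by_tissue, function(s) {
      if (length(s) == reps_per_tissue) s else sample(s, reps_per_tissue)
    }), use.names = FALSE)
    r <- cor(t(m[, take, drop = FALSE]), method = "spearman")
    n_validated <- n_validated + (r[cbind(ia, ib)] >= r_min)
  }
  candidates |>
    mutate(n_validated = n_validated, validated = n_validated == n_iter)
}

#' Build the coexpression network from validated edges
#'
#' Simple undirected graph over all endpoints of the validated edge set;
#' edge attribute `r` keeps the full-sample correlation, `n_validated` the
#' resampling support.
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`, optionally `r`,
#'   `n_validated`, `validated`); when a `validated` column is present only
#'   validated edges are used.
#' @return An `igraph` object.
#' @export
build_network <- function(edges) {
  if ("validated" %in% names(edges)) edges <- filter(edges, .data$validated)
  if (nrow(edges) == 0) return(igraph::make_empty_graph(n = 0, directed = FALSE))
  g <- igraph::graph_from_data_frame(
    edges |> select("gene_a", "gene_b", dplyr::any_of(c("r", "n_validated"))),
    directed = FALSE
  )
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Keep only connected components of a minimum size
#'
#' @param network An `igraph` network.
#' @param min_size Minimum component size in nodes (default 5, inclusive).
#' @return The induced subgraph on components with at least `min_size`
#'   nodes.
#' @export
filter_min_group <- function(network, min_size = 5L) {
  if (igraph::vcount(network) == 0) return(network)
  comp <- igraph::components(network)
  keep <- which(comp$csize[comp$membership] >= min_size)
  igraph::induced_subgraph(network, keep)
}

#' Coexpression network as an edge tibble
#'
#' @param network An `igraph` network.
#' @return A tibble (`gene_a`, `gene_b` plus any edge attributes).
#' @export
as_edge_tibble <- function(network) {
  if (igraph::ecount(network) == 0) {
    return(tibble(gene_a = character(0), gene_b = character(0)))
  }
  el <- igraph::as_data_frame(network, what = "edges")
  names(el)[1:2] <- c("gene_a", "gene_b")
  as_tibble(el)
}

#' Age composition of network modules
#'
#' For each module, the proportion of members assigned to each hallmark
#' stage (over members that have an age assignment; members without one are
#' counted separately). Errors if a module has no assigned member.
#'
#' @param modules An `mcode_result` (from [mcode_modules()]) or a tibble
#'   (`module_id`, `gene_id`).
#' @param assignment Age-assignment tibble including a `stage` column.
#' @return A tibble (`module_id`, `stage`, `n`, `proportion`, `n_unassigned`,
#'   `dominant`): one row per module and observed stage, `dominant` flagging
#'   each module's modal stage.
#' @export
module_age_composition <- function(modules, assignment) {
  members <- module_members(modules)
  if (!"stage" %in% names(assignment)) abort("assignment lacks a stage column")
  members <- members |>
    left_join(assignment |> select("gene_id", "stage"), by = "gene_id")
  bad <- members |>
    group_by(.data$module_id) |>
    summarise(none = all(is.na(.data$stage)), .groups = "drop") |>
    filter(.data$none)
  if (nrow(bad) > 0) {
    abort(paste("modules with no age-assigned member:", paste(bad$module_id, collapse = ", ")))
  }
  members |>
    group_by(.data$module_id) |>
    mutate(n_unassigned = sum(is.na(.data$stage))) |>
    filter(!is.na(.data$stage)) |>
    count(.data$module_id, .data$stage, .data$n_unassigned, name = "n") |>
    group_by(.data$module_id) |>
    mutate(
      proportion = .data$n / sum(.data$n),
      dominant = .data$proportion == max(.data$proportion) &
        .data$stage == min(.data$stage[.data$proportion == max(.data$proportion)])
    ) |>
    ungroup() |>
    select("module_id", "stage", "n", "proportion", "n_unassigned", "dominant")
}

# normalize module input to a (module_id, gene_id) tibble
module_members <- function(modules) {
  if (inherits(modules, "mcode_result")) {
    return(tidyr::unnest(modules$modules |> select("module_id", "members"),
                         cols = "members") |>
             rename(gene_id = "members"))
  }
  stopifnot(is.data.frame(modules), all(c("module_id", "gene_id") %in% names(modules)))
  as_tibble(modules[c("module_id", "gene_id")])
}

#' Permutation test for module age homogeneity
#'
#' Quantifies whether each module is more age-homogeneous than expected by
#' chance: the statistic is the module's dominant-stage proportion, and the
#' null is built by permuting the stage labels across all age-assigned nodes
#' of the network. P-values are Benjamini-Hochberg adjusted across modules.
#' With a single stage present network-wide there is no contrast and every
#' p-value is 1.
#'
#' The dominant-stage proportion is a discrete statistic, so the default
#' add-one estimator (`tie_break = "conservative"`) is valid but
#' conservative: its null distribution is stochastically larger than
#' uniform. `tie_break = "randomized"` breaks ties at random (the classical
#' randomized p-value for discrete tests), which is exactly uniform under
#' the permutation null and is what calibration checks should use.
#'
#' @param modules An `mcode_result` or membership tibble (see
#'   [module_age_composition()]).
#' @param assignment Age-assignment tibble with a `stage` column covering the
#'   network's nodes.
#' @param network_genes Character vector of all network node ids defining the
#'   permutation population (defaults to all genes in `assignment`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param tie_break `"conservative"` (default) or `"randomized"`; see
#'   Details.
#' @return A tibble (`module_id`, `n_assigned`, `dominant_stage`,
#'   `dominant_prop`, `p_value`, `q_value`).
#' @export
age_homogeneity_test <- function(modules, assignment, network_genes = NULL,
                                 n_perm = 1000L, seed = 1L,
                                 tie_break = c("conservative", "randomized")) {
  tie_break <- match.arg(tie_break)
  members <- module_members(modules)
  if (is.null(network_genes)) network_genes <- assignment$gene_id
  pool <- assignment |>
    filter(.data$gene_id %in% network_genes, !is.na(.data$stage))
  if (nrow(pool) == 0) abort("no age-assigned genes among network nodes")
  stages <- setNames(pool$stage, pool$gene_id)
  mod_list <- split(members$gene_id, members$module_id)
  mod_list <- lapply(mod_list, intersect, y = names(stages))
  if (any(lengths(mod_list) == 0)) abort("module with no age-assigned member")
  dom_prop <- function(st) max(tabulate(st)) / length(st)
  obs <- vapply(mod_list, function(g) dom_prop(stages[g]), numeric(1))
  dom_stage <- vapply(mod_list, function(g) {
    tab <- table(stages[g])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  set.seed(seed)
  n_gt <- setNames(rep(0L, length(mod_list)), names(mod_list))
  n_eq <- n_gt
  idx <- lapply(mod_list, match, table = names(stages))
  for (b in seq_len(n_perm)) {
    perm <- sample(unname(stages))
    stat <- vapply(idx, function(i) dom_prop(perm[i]), numeric(1))
    n_gt <- n_gt + (stat > obs + 1e-12)
    n_eq <- n_eq + (abs(stat - obs) <= 1e-12)
  }
  p <- if (tie_break == "conservative") {
    (1 + n_gt + n_eq) / (n_perm + 1)
  } else {
    (n_gt + runif(length(n_gt)) * (1 + n_eq)) / (n_perm + 1)
  }
  tibble(
    module_id = names(mod_list),
    n_assigned = lengths(mod_list),
    dominant_stage = dom_stage,
    dominant_prop = unname(obs),
    p_value = unname(p),
    q_value = bh_adjust(unname(p))
  )
}
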
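# density of a simple undirected graph (0 for < 2 vertices)
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  igraph::ecount(g) / (n * (n - 1) / 2)
}

# MCODE vertex weight: highest k-core of the closed neighborhood of v,
# weight = k * density(core). Vertices below the degree cutoff score 0.
mcode_vertex_weights <- function(g, degree_cutoff = 2L) {
  deg <- igraph::degree(g)
  vapply(seq_len(igraph::vcount(g)), function(v) {
    if (deg[v] < degree_cutoff) return(0)
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == k))
    k * graph_density(core_sub)
  }, numeric(1))
}

#' Find densely connected modules with the MCODE algorithm
#'
#' Implements the molecular-complex-detection procedure: each vertex is
#' weighted by the core number k of the highest k-core of its closed
#' neighborhood times that core's density; modules are grown outward from
#' the highest-weight unassigned seed, admitting neighbors whose weight is at
#' least `(1 - node_score_cutoff)` times the seed weight, up to `max_depth`
#' steps from the seed. Post-processing optionally removes singly connected
#' module vertices ("haircut") and drops modules that do not contain a
#' `k_core`-core. Each vertex belongs to at most one module (no fluff), and
#' modules are ranked by score = density x size.
#'
#' @param network An `igraph` network (made simple internally).
#' @param degree_cutoff Minimum degree for a vertex to receive a nonzero
#'   weight (default 2).
#' @param node_score_cutoff Admission slack relative to the seed weight
#'   (default 0.2).
#' @param k_core Modules must contain a core of at least this order
#'   (default 2).
#' @param max_depth Maximum expansion depth from the seed (default 100).
#' @param haircut Remove singly connected module vertices (default TRUE).
#' @param min_size Discard modules smaller than this after post-processing
#'   (default 2).
#' @return An object of class `mcode_result`: list with `modules` (tibble:
#'   `module_id`, `seed`, `n_nodes`, `density`, `score`, `members`
#'   list-column) and `weights` (named vertex weights).
#' @export
mcode_modules <- function(network, degree_cutoff = 2L, node_score_cutoff = 0.2,
                          k_core = 2L, max_depth = 100L, haircut = TRUE,
                          min_size = 2L) {
  g <- igraph::simplify(network)
  n <- igraph::vcount(g)
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  empty <- tibble(
    module_id = character(0), seed = character(0), n_nodes = integer(0),
    density = numeric(0), score = numeric(0), members = list()
  )
  if (n == 0) {
    return(structure(list(modules = empty, weights = numeric(0)), class = "mcode_result"))
  }
  w <- mcode_vertex_weights(g, degree_cutoff)
  names(w) <- vnames
  assigned <- rep(FALSE, n)
  raw <- list()
  for (seed in order(w, decreasing = TRUE)) {
    if (assigned[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - node_score_cutoff)
    member <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(igraph::neighbors(g, v))) {
          if (!assigned[u] && w[u] >= threshold) {
            assigned[u] <- TRUE
            member <- c(member, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    raw[[length(raw) + 1L]] <- list(seed = seed, member = member)
  }
  keep <- list()
  for (mod in raw) {
    sub_idx <- mod$member
    sub <- igraph::induced_subgraph(g, sub_idx)
    if (haircut && igraph::vcount(sub) > 1) {
      ok <- igraph::degree(sub) >= 2 | igraph::vcount(sub) == 2
      sub_idx <- sub_idx[ok]
      sub <- igraph::induced_subgraph(g, sub_idx)
    }
    if (igraph::vcount(sub) == 0) next
    if (max(igraph::coreness(sub)) < k_core) next
    if (igraph::vcount(sub) < min_size) next
    keep[[length(keep) + 1L]] <- list(
      seed = vnames[mod$seed],
      members = sort(vnames[sub_idx]),
      n_nodes = as.integer(igraph::vcount(sub)),
      density = graph_density(sub),
      score = graph_density(sub) * igraph::vcount(sub)
    )
  }
  if (length(keep) == 0) {
    return(structure(list(modules = empty, weights = w), class = "mcode_result"))
  }
  ord <- order(vapply(keep, `[[`, numeric(1), "score"), decreasing = TRUE)
  keep <- keep[ord]
  modules <- tibble(
    module_id = sprintf("module_%02d", seq_along(keep)),
    seed = vapply(keep, `[[`, character(1), "seed"),
    n_nodes = vapply(keep, `[[`, integer(1), "n_nodes"),
    density = vapply(keep, `[[`, numeric(1), "density"),
    score = vapply(keep, `[[`, numeric(1), "score"),
    members = lapply(keep, `[[`, "members")
  )
  structure(list(modules = modules, weights = w), class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("MCODE: %d modules\n", nrow(x$modules)))
  print(x$modules |> select(-"members"), n = nrow(x$modules))
  invisible(x)
}
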
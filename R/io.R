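# Readers and writers for the plain-text interchange formats: expression and
# design TSVs, taxonomy node tables and Newick, ortholog-group TSVs, lineage
# YAML, edge lists and GraphML.

#' @rdname phylomark_io
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read and write the pipeline's plain-text formats
#'
#' Expression tables are genes x samples TSVs whose header row holds sample
#' ids and whose first column is `gene_id`; designs are `sample_id`, `tissue`,
#' `replicate` TSVs; taxonomies are `node_id`, `parent_id`, `name` node
#' tables (empty/NA parent marks the root) or Newick files; ortholog groups
#' are `group_id`, `gene_id`, `species` TSVs with comma-separated species node
#' ids; lineages are YAML lists of `name`/`node_id`/`age_mya` records; edge
#' lists are `gene_a`, `gene_b`, `r`, `n_validated` TSVs; networks can also be
#' exported as GraphML for Cytoscape.
#'
#' @param path File path.
#' @param expr,design,tree,lineage,groups,edges,network Objects to write.
#' @name phylomark_io
#' @return Readers return tibbles (or an `igraph` for GraphML); writers
#'   return the path invisibly.
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(out)[1] != "gene_id") names(out)[1] <- "gene_id"
  expr_scale(out) <- "fpkm"
  out
}

#' @rdname phylomark_io
#' @export
write_design_tsv <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname phylomark_io
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c", tissue = "c", replicate = "i"))
}

#' @rdname phylomark_io
#' @export
write_taxonomy_tsv <- function(tree, path) {
  readr::write_tsv(tree, path, na = "")
  invisible(path)
}

#' @rdname phylomark_io
#' @export
read_taxonomy_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  out$parent_id[out$parent_id %in% c("", "NA")] <- NA_character_
  validate_taxonomy(out)
  out
}

# recursive Newick serialisation of a parent-pointer taxonomy
#' @rdname phylomark_io
#' @export
write_taxonomy_newick <- function(tree, path) {
  validate_taxonomy(tree)
  children <- split(tree$node_id, tree$parent_id)
  lab <- function(id) gsub("[ ():,;]", "_", id)
  rec <- function(id) {
    kids <- children[[id]]
    if (is.null(kids)) return(lab(id))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")", lab(id))
  }
  root <- tree$node_id[is.na(tree$parent_id)]
  writeLines(paste0(rec(root), ";"), path)
  invisible(path)
}

#' @rdname phylomark_io
#' @export
read_taxonomy_newick <- function(path) {
  phy <- ape::read.tree(path)
  n_tip <- length(phy$tip.label)
  labels <- c(phy$tip.label, phy$node.label)
  if (length(labels) != n_tip + phy$Nnode) abort("newick lacks internal node labels")
  parent <- rep(NA_character_, length(labels))
  parent[phy$edge[, 2]] <- labels[phy$edge[, 1]]
  tibble(node_id = labels, parent_id = parent, name = labels) |>
    validate_taxonomy()
}

#' @rdname phylomark_io
#' @export
write_lineage_yaml <- function(lineage, path) {
  recs <- purrr::pmap(lineage, function(clade_index, clade_name, node_id, age_mya, ...) {
    list(name = clade_name, node_id = node_id, age_mya = age_mya)
  })
  yaml::write_yaml(list(lineage = recs), path)
  invisible(path)
}

#' @rdname phylomark_io
#' @export
read_lineage_yaml <- function(path) {
  recs <- yaml::read_yaml(path)$lineage
  out <- tibble(
    clade_index = seq_along(recs),
    clade_name = vapply(recs, `[[`, character(1), "name"),
    node_id = vapply(recs, `[[`, character(1), "node_id"),
    age_mya = vapply(recs, function(r) as.numeric(r$age_mya), numeric(1))
  )
  validate_lineage(out)
  out
}

#' @rdname phylomark_io
#' @export
write_groups_tsv <- function(groups, path) {
  flat <- groups |>
    mutate(species = vapply(.data$species, paste, character(1), collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname phylomark_io
#' @export
read_groups_tsv <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  flat |>
    mutate(species = strsplit(.data$species, ",", fixed = TRUE))
}

#' @rdname phylomark_io
#' @export
write_edges_tsv <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

#' @rdname phylomark_io
#' @export
read_edges_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname phylomark_io
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Write a sample dendrogram as Newick
#'
#' @param clustering An `hclust` object (from [cluster_samples()]).
#' @param path File path.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering), path)
  invisible(path)
}
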
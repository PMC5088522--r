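#' Generate a synthetic time-calibrated lineage
#'
#' Builds an ordered chain of clades from the root-most ancestor (index 1) to
#' the focal species (index `n_clades`), with strictly decreasing divergence
#' ages in million years ago (Mya). The focal clade always sits at age 0; the
#' root clade at `root_age`. Intermediate ages are drawn uniformly and sorted,
#' mimicking an uneven TimeTree-style calibration.
#'
#' @param n_clades Number of lineage levels (>= 2), root included.
#' @param root_age Age of the root clade in Mya (> 0).
#' @param seed Integer seed; the same seed yields an identical lineage.
#' @return A tibble with columns `clade_index`, `clade_name`, `node_id`,
#'   `age_mya`, ordered root -> focal.
#' @examples
#' generate_lineage(n_clades = 5, root_age = 1000, seed = 1)
#' @export
generate_lineage <- function(n_clades, root_age, seed = 1L) {
  if (n_clades < 2) abort("n_clades must be >= 2")
  if (root_age <= 0) abort("root_age must be > 0")
  set.seed(seed)
  if (n_clades == 2) {
    ages <- c(root_age, 0)
  } else {
    mid <- sort(runif(n_clades - 2L, 0, root_age), decreasing = TRUE)
    # nudge any ties apart so ages are strictly decreasing
    while (any(duplicated(mid))) mid <- sort(runif(n_clades - 2L, 0, root_age), decreasing = TRUE)
    ages <- c(root_age, mid, 0)
  }
  tibble(
    clade_index = seq_len(n_clades),
    clade_name = sprintf("clade_%02d", seq_len(n_clades)),
    node_id = sprintf("L%02d", seq_len(n_clades)),
    age_mya = ages
  )
}

#' The 31-level human lineage with approximate divergence ages
#'
#' The ordered NCBI-style taxonomy lineage of *Homo sapiens* (cellular
#' organisms -> Homo sapiens, 31 consecutive clades) with divergence ages in
#' Mya taken from TimeTree-style point estimates. The ages are a bundled
#' calibration meant to be user-editable (see [read_lineage_yaml()]); they
#' order the clades on the time axis and are not authoritative.
#'
#' @return A lineage tibble (`clade_index`, `clade_name`, `node_id`, `age_mya`).
#' @export
human_lineage <- function() {
  nm <- c(
    "cellular organisms", "Eukaryota", "Opisthokonta", "Metazoa", "Eumetazoa",
    "Bilateria", "Deuterostomia", "Chordata", "Craniata", "Vertebrata",
    "Gnathostomata", "Teleostomi", "Euteleostomi", "Sarcopterygii",
    "Dipnotetrapodomorpha", "Tetrapoda", "Amniota", "Mammalia", "Theria",
    "Eutheria", "Boreoeutheria", "Euarchontoglires", "Primates", "Haplorrhini",
    "Simiiformes", "Catarrhini", "Hominoidea", "Hominidae", "Homininae",
    "Homo", "Homo sapiens"
  )
  ages <- c(
    4290, 2100, 1105, 786, 681, 615, 558, 540, 530, 515,
    473, 441, 435, 413, 408, 352, 312, 177, 159, 105,
    96, 90, 74, 63, 43, 29, 20, 16, 9, 2.8, 0
  )
  tibble(
    clade_index = seq_along(nm),
    clade_name = nm,
    node_id = sprintf("L%02d", seq_along(nm)),
    age_mya = ages
  )
}

validate_lineage <- function(lineage) {
  need <- c("clade_index", "clade_name", "node_id", "age_mya")
  if (!all(need %in% names(lineage))) {
    abort(paste("lineage must have columns:", paste(need, collapse = ", ")))
  }
  if (any(diff(lineage$age_mya) >= 0)) abort("lineage ages must be strictly decreasing")
  if (lineage$age_mya[nrow(lineage)] != 0) abort("focal clade age must be 0")
  invisible(lineage)
}

#' Build a stage scheme by splitting a lineage into contiguous blocks
#'
#' A stage scheme maps every lineage clade to exactly one of a small number of
#' ordered, contiguous stages ("hallmarks"). `stage_ends` gives, per stage,
#' the last (deepest) clade index it covers; the last entry must equal the
#' number of clades so the scheme is exhaustive.
#'
#' @param lineage A lineage tibble.
#' @param stage_ends Increasing integer vector of block-final clade indices.
#' @return A tibble with columns `clade_index`, `stage` (integer) and
#'   `stage_label` ("st1", "st2", ...).
#' @export
make_stage_scheme <- function(lineage, stage_ends) {
  n <- nrow(lineage)
  stage_ends <- as.integer(stage_ends)
  if (any(diff(stage_ends) <= 0) || stage_ends[length(stage_ends)] != n || stage_ends[1] < 1) {
    abort("stage_ends must be strictly increasing and end at the number of clades")
  }
  stage <- rep(seq_along(stage_ends), times = diff(c(0L, stage_ends)))
  tibble(
    clade_index = seq_len(n),
    stage = as.integer(stage),
    stage_label = sprintf("st%d", stage)
  )
}

#' The eight-hallmark stage scheme for the human lineage
#'
#' Maps the 31 human lineage clades onto the eight evolutionary hallmark
#' stages: st1 cellular organisms (Prokaryota); st2 -> Eukaryota;
#' st3 -> Metazoa (Opisthokonta, Metazoa); st4 -> Vertebrata; st5 ->
#' Euteleostomi (Gnathostomata, Teleostomi, Euteleostomi); st6 -> Mammalia;
#' st7 -> Primates (Theria ... Primates); st8 -> Homo sapiens.
#'
#' @param lineage The human lineage tibble (defaults to [human_lineage()]).
#' @return A stage-scheme tibble as from [make_stage_scheme()].
#' @export
human_stage_scheme <- function(lineage = human_lineage()) {
  anchor <- function(name) which(lineage$clade_name == name)
  ends <- c(
    anchor("cellular organisms"), anchor("Eukaryota"), anchor("Metazoa"),
    anchor("Vertebrata"), anchor("Euteleostomi"), anchor("Mammalia"),
    anchor("Primates"), nrow(lineage)
  )
  if (length(ends) != 8 || anyNA(ends)) {
    # fall back to positional boundaries for non-human clade names
    ends <- c(1, 2, 4, 10, 13, 18, 23, nrow(lineage))
  }
  make_stage_scheme(lineage, ends)
}

#' Evenly split any lineage into a fixed number of stages
#'
#' Convenience scheme for synthetic lineages whose clades carry no biological
#' names: clades are split into `n_stages` contiguous blocks of near-equal
#' size (earlier blocks take the remainder).
#'
#' @param lineage A lineage tibble.
#' @param n_stages Number of stages (default 8).
#' @return A stage-scheme tibble.
#' @export
even_stage_scheme <- function(lineage, n_stages = 8L) {
  n <- nrow(lineage)
  if (n_stages > n) abort("more stages than clades")
  sizes <- rep(n %/% n_stages, n_stages)
  extra <- n %% n_stages
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  make_stage_scheme(lineage, cumsum(sizes))
}

#' Generate a taxonomy tree embedding a lineage
#'
#' Constructs a parent-pointer taxonomy whose internal backbone is the given
#' lineage (root -> focal clade chain). At every lineage clade,
#' `species_per_clade` leaf species branch off (attached at that clade, i.e.
#' not below the next lineage clade), and the focal species is a leaf under
#' the final clade. This is the tree over which ortholog-group LCAs are
#' computed; each off-path leaf's deepest lineage ancestor is the clade it was
#' attached to.
#'
#' @param lineage A lineage tibble.
#' @param species_per_clade Leaf species branching off at each clade (>= 1).
#' @param seed Integer seed (construction is deterministic; kept for API
#'   symmetry with the other generators).
#' @return A taxonomy tibble (`node_id`, `parent_id`, `name`) with attributes
#'   `focal_id` (the focal species leaf) and `attachment` (named integer
#'   vector: leaf -> lineage clade index it branches off from).
#' @export
generate_taxonomy <- function(lineage, species_per_clade = 2L, seed = 1L) {
  if (species_per_clade < 1) abort("species_per_clade must be >= 1")
  validate_lineage(lineage)
  n <- nrow(lineage)
  backbone <- tibble(
    node_id = lineage$node_id,
    parent_id = c(NA_character_, lineage$node_id[-n]),
    name = lineage$clade_name
  )
  sp <- purrr::map_dfr(seq_len(n), function(k) {
    tibble(
      node_id = sprintf("sp_c%02d_%02d", k, seq_len(species_per_clade)),
      parent_id = lineage$node_id[k],
      name = sprintf("species %02d-%02d", k, seq_len(species_per_clade))
    )
  })
  focal <- tibble(node_id = "sp_focal", parent_id = lineage$node_id[n], name = "focal species")
  tax <- bind_rows(backbone, sp, focal)
  attachment <- c(
    setNames(rep(seq_len(n), each = species_per_clade), sp$node_id),
    setNames(n, "sp_focal")
  )
  attr(tax, "focal_id") <- "sp_focal"
  attr(tax, "attachment") <- attachment
  tax
}

validate_taxonomy <- function(tree) {
  need <- c("node_id", "parent_id", "name")
  if (!all(need %in% names(tree))) {
    abort(paste("taxonomy must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tree$node_id)) abort("duplicate node ids in taxonomy")
  roots <- tree$node_id[is.na(tree$parent_id)]
  if (length(roots) != 1) abort("taxonomy must have exactly one root")
  orphan <- setdiff(tree$parent_id[!is.na(tree$parent_id)], tree$node_id)
  if (length(orphan) > 0) abort(paste("parent ids missing from node table:", paste(head(orphan, 5), collapse = ", ")))
  invisible(tree)
}
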
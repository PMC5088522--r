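#' Log-transform an FPKM expression table
#'
#' Replaces every value v by log2(v + 1), the usual variance-stabilising
#' transform for FPKM, and marks the table as log2-scaled so downstream
#' functions that require raw FPKM (e.g. [detect_expressed()]) can refuse it.
#'
#' @param expr Expression tibble (`gene_id` + numeric sample columns) on the
#'   FPKM scale.
#' @return The transformed tibble, with the `expr_scale` attribute set to
#'   `"log2"`.
#' @examples
#' m <- tibble::tibble(gene_id = "g1", s1 = 0, s2 = 1, s3 = 7)
#' log_transform(m) # 0, 1, 3
#' @export
log_transform <- function(expr) {
  m <- expr_as_matrix(expr)
  if (any(m < 0)) abort("negative expression values: log_transform needs FPKM >= 0")
  if (identical(expr_scale(expr), "log2")) {
    warn("expression already log2-scaled; returning unchanged")
    return(expr)
  }
  expr_from_matrix(log2(m + 1), scale = "log2")
}

#' Per-gene expression calls across tissues and samples
#'
#' A gene is called expressed in a tissue if at least one replicate of that
#' tissue reaches the FPKM threshold; `expressed_in_all_samples` requires
#' every single sample to reach it (the stricter, house-keeping-style call),
#' and implies `expressed_in_all_tissues` (the ubiquitous call).
#'
#' @param expr Expression tibble on the FPKM scale.
#' @param design Sample design tibble (`sample_id`, `tissue`, `replicate`).
#' @param threshold FPKM cut-off (default 1; the call is "equal or higher").
#' @return A tibble (`gene_id`, `tissues_expressed_in`,
#'   `expressed_in_all_samples`, `expressed_in_all_tissues`).
#' @export
detect_expressed <- function(expr, design, threshold = 1) {
  if (identical(expr_scale(expr), "log2")) {
    abort("detect_expressed needs the FPKM-scale matrix, not log2 values")
  }
  check_design(expr, design)
  m <- expr_as_matrix(expr)
  m <- m[, design$sample_id, drop = FALSE]
  hit <- m >= threshold
  tissue <- factor(design$tissue, levels = unique(design$tissue))
  per_tissue <- vapply(levels(tissue), function(t) {
    rowSums(hit[, tissue == t, drop = FALSE]) > 0
  }, logical(nrow(m)))
  if (is.null(dim(per_tissue))) per_tissue <- matrix(per_tissue, nrow = 1)
  tibble(
    gene_id = rownames(m),
    tissues_expressed_in = as.integer(rowSums(per_tissue)),
    expressed_in_all_samples = unname(rowSums(hit) == ncol(m)),
    expressed_in_all_tissues = unname(rowSums(per_tissue) == nlevels(tissue))
  )
}

#' Filter genes by replicate-mean FPKM
#'
#' Keeps genes whose per-tissue replicate-mean FPKM reaches the threshold.
#' The default rule, `"any_tissue"`, requires this in at least one tissue
#' (so tissue-restricted genes survive); `"all_tissues"` is the literal
#' ubiquitous reading and keeps only genes whose mean expression clears the
#' threshold everywhere.
#'
#' @param expr Expression tibble on the FPKM scale.
#' @param design Sample design tibble.
#' @param threshold Mean-FPKM cut-off (default 1, inclusive).
#' @param rule `"any_tissue"` (default) or `"all_tissues"`.
#' @return The filtered expression tibble (FPKM scale).
#' @export
filter_expressed_genes <- function(expr, design, threshold = 1,
                                   rule = c("any_tissue", "all_tissues")) {
  rule <- match.arg(rule)
  if (identical(expr_scale(expr), "log2")) {
    abort("filter_expressed_genes needs the FPKM-scale matrix")
  }
  tm <- expr_as_matrix(tissue_means(expr, design))
  keep <- if (rule == "any_tissue") {
    rowSums(tm >= threshold) > 0
  } else {
    rowSums(tm >= threshold) == ncol(tm)
  }
  out <- expr[keep, , drop = FALSE]
  expr_scale(out) <- expr_scale(expr)
  out
}

#' Average replicates into a tissue-level expression table
#'
#' One column per tissue holding the arithmetic mean over that tissue's
#' replicates, computed on whatever scale the input is on (means of log2
#' values are not logs of mean FPKM).
#'
#' @param expr Expression tibble.
#' @param design Sample design tibble.
#' @return A tibble (`gene_id` + one numeric column per tissue), same scale
#'   marker as the input.
#' @export
tissue_means <- function(expr, design) {
  check_design(expr, design)
  m <- expr_as_matrix(expr)
  m <- m[, design$sample_id, drop = FALSE]
  tissue <- factor(design$tissue, levels = unique(design$tissue))
  tm <- vapply(levels(tissue), function(t) {
    rowMeans(m[, tissue == t, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(tm))) tm <- matrix(tm, nrow = 1, dimnames = list(rownames(m), levels(tissue)))
  expr_from_matrix(tm, scale = expr_scale(expr))
}

#' Spearman-based sample distance matrix
#'
#' Pairwise distances between samples computed as 1 - Spearman correlation of
#' the gene expression vectors (average ranks for ties). Because Spearman
#' correlation is rank-based, the result is identical on FPKM and on
#' log2(FPKM + 1) values. A zero-variance sample has undefined correlation;
#' it is reported with a warning and assigned the maximum distance (2) to
#' every other sample rather than failing the clustering.
#'
#' @param expr Expression tibble (any scale).
#' @return A symmetric numeric matrix with zero diagonal, entries in [0, 2],
#'   dimnames = sample ids.
#' @export
sample_distance <- function(expr) {
  m <- expr_as_matrix(expr)
  if (ncol(m) < 2) abort("need at least two samples")
  sds <- apply(m, 2, function(x) diff(range(x)))
  degenerate <- sds == 0
  r <- suppressWarnings(cor(m, method = "spearman"))
  if (any(degenerate)) {
    warn(paste("zero-variance samples set to maximum distance:",
               paste(colnames(m)[degenerate], collapse = ", ")))
  }
  d <- 1 - r
  d[is.na(d)] <- 2
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of samples
#'
#' Thin wrapper over [stats::hclust()] on a validated symmetric distance
#' matrix; complete linkage by default, average linkage available.
#'
#' @param distances Symmetric distance matrix (e.g. from
#'   [sample_distance()]).
#' @param linkage `"complete"` (default) or `"average"`.
#' @return An `hclust` object (n - 1 merges with nondecreasing heights for
#'   these linkages).
#' @export
cluster_samples <- function(distances, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(distances) || nrow(distances) != ncol(distances) ||
      !isTRUE(all.equal(distances, t(distances), tolerance = 1e-8))) {
    abort("distances must be a symmetric matrix")
  }
  hclust(as.dist(distances), method = linkage)
}
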
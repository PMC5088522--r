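#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, q_(i) = min over j >= i of p_(j) * m / j, clipped at 1 and
#' returned in the original order. Validates the input range; the arithmetic
#' is delegated to [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric term over-representation test
#'
#' For each annotation term, tests whether the query gene set contains more
#' term members than expected when drawing `n = |query|` genes from the
#' universe: p = P[X >= k] with X ~ Hypergeometric(N, K, n), where K is the
#' term size in the universe and k the observed hits (the upper tail includes
#' the observed count). P-values are Benjamini-Hochberg adjusted across
#' terms.
#'
#' @param query Character vector of gene ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of background gene ids.
#' @param annotations Tibble (`term_id`, `gene_id`, optional `term_name`);
#'   annotations are restricted to the universe before testing.
#' @return A tibble (`term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`) sorted by `q_value` then `p_value`.
#' @export
hypergeom_enrich <- function(query, universe, annotations) {
  universe <- unique(universe)
  query <- unique(query)
  offenders <- setdiff(query, universe)
  if (length(offenders) > 0) {
    abort(paste("query genes outside the universe:",
                paste(head(offenders, 5), collapse = ", "),
                if (length(offenders) > 5) sprintf("(+%d more)", length(offenders) - 5) else ""))
  }
  stopifnot(all(c("term_id", "gene_id") %in% names(annotations)))
  ann <- annotations |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$term_id, .data$gene_id,
             .keep_all = TRUE)
  if (nrow(ann) == 0) {
    return(tibble(term_id = character(0), term_name = character(0),
                  k = integer(0), K = integer(0), n = integer(0), N = integer(0),
                  p_value = numeric(0), q_value = numeric(0)))
  }
  N <- length(universe)
  n <- length(query)
  res <- ann |>
    group_by(.data$term_id) |>
    summarise(
      term_name = if ("term_name" %in% names(ann)) dplyr::first(.data$term_name) else dplyr::first(.data$term_id),
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(.data$gene_id %in% query),
      .groups = "drop"
    ) |>
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE),
      q_value = bh_adjust(.data$p_value)
    ) |>
    arrange(.data$q_value, .data$p_value) |>
    select("term_id", "term_name", "k", "K", "n", "N", "p_value", "q_value")
  res
}
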
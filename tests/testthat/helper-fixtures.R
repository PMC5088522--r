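# Shared fixtures. The default simulated study is computed once per test run
# and reused; small hand-built tables are constructed fresh where needed.

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_dataset(simulation_config())
  }
  .fixture_env$sim
}

# tiny expression table: 3 genes x 2 tissues x 2 replicates
tiny_expr <- function() {
  design <- tibble::tibble(
    sample_id = c("a_r1", "a_r2", "b_r1", "b_r2"),
    tissue = c("a", "a", "b", "b"),
    replicate = c(1L, 2L, 1L, 2L)
  )
  expr <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    a_r1 = c(5, 0.2, 2), a_r2 = c(6, 0.3, 4),
    b_r1 = c(7, 0.1, 0), b_r2 = c(5, 0.4, 0.5)
  )
  list(expr = expr, design = design)
}

# expression tibble straight from a genes x samples matrix
expr_tbl <- function(m, scale = "fpkm") {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  out <- tibble::as_tibble(m, rownames = "gene_id")
  attr(out, "expr_scale") <- scale
  out
}

# igraph helpers for MCODE fixtures
k_graph <- function(n, prefix = "v") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}
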
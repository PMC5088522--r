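# Independent oracles used to cross-check the package's own implementations.
# These deliberately use brute force or first-principles formulations and
# never call the code paths they check.

# Spearman by definition: average ranks, then Pearson.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# LCA by brute force: intersect the two root paths of every taxon, take the
# common ancestor with the longest root path (the deepest one).
oracle_lca <- function(tree, taxa) {
  parent <- setNames(tree$parent_id, tree$node_id)
  path <- function(node) {
    out <- character(0)
    while (!is.na(node)) {
      out <- c(out, node)
      node <- parent[[node]]
    }
    out
  }
  paths <- lapply(taxa, path)
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(n) length(path(n)), integer(1))
  common[which.max(depths)]
}

# Random parent-pointer tree: node i > 1 attaches to a uniformly chosen
# earlier node, guaranteeing a single root and no cycles.
random_tree <- function(n_nodes) {
  parent <- c(NA_character_, sprintf("n%03d", vapply(
    2:n_nodes, function(i) sample.int(i - 1L, 1L), integer(1)
  )))
  tibble::tibble(
    node_id = sprintf("n%03d", seq_len(n_nodes)),
    parent_id = parent,
    name = sprintf("node %d", seq_len(n_nodes))
  )
}

# Conditional-MLE odds ratio oracle: maximise the noncentral hypergeometric
# likelihood of cell a given all margins, by solving E_psi[X] = a.
oracle_cmle_or <- function(a, b, c, d) {
  m1 <- a + b # row margin (set A)
  n1 <- a + c # column margin (set B)
  N <- a + b + c + d
  lo <- max(0L, n1 - (N - m1))
  hi <- min(m1, n1)
  if (a <= lo) return(0)
  if (a >= hi) return(Inf)
  support <- lo:hi
  lw <- lchoose(m1, support) + lchoose(N - m1, n1 - support)
  mean_x <- function(log_psi) {
    lp <- lw + support * log_psi
    w <- exp(lp - max(lp))
    sum(support * w) / sum(w)
  }
  f <- function(log_psi) mean_x(log_psi) - a
  stats::uniroot(f, c(-50, 50), tol = 1e-10)$root |> exp()
}

# Exact noncentral hypergeometric distribution (for CI spot checks).
oracle_nchg_pmf <- function(psi, m1, n1, N) {
  lo <- max(0L, n1 - (N - m1))
  hi <- min(m1, n1)
  support <- lo:hi
  lw <- lchoose(m1, support) + lchoose(N - m1, n1 - support) + support * log(psi)
  w <- exp(lw - max(lw))
  list(support = support, pmf = w / sum(w))
}

# BH step-up by hand (for bh_adjust cross-checks).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
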
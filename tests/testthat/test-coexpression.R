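test_that("candidate_edges keeps one-sided high correlations and drops degenerate genes", {
  m <- expr_tbl(rbind(
    dup1 = c(1, 2, 3, 4, 5, 6),
    dup2 = c(2, 4, 6, 8, 10, 12), # same ranks as dup1
    anti = c(6, 5, 4, 3, 2, 1),
    flat = c(1, 1, 1, 1, 1, 1)
  ))
  names(m)[-1] <- paste0("s", 1:6)
  expect_message(edges <- candidate_edges(m, r_min = 0.85), "zero-variance")
  expect_equal(attr(edges, "n_zero_variance"), 1)
  expect_equal(nrow(edges), 1)
  expect_setequal(c(edges$gene_a, edges$gene_b), c("dup1", "dup2"))
  expect_equal(edges$r, 1)
  expect_error(candidate_edges(m[, 1:3]), "three samples")
})

test_that("a noise-free module yields the complete within-module edge set", {
  cfg0 <- simulation_config(n_genes = 80, frac_hk = 0.1, frac_te = 0.1,
                            n_modules = 1, module_size = 6,
                            module_age_stage = 4, noise_sd = 0, seed = 9)
  sim0 <- simulate_dataset(cfg0)
  mod <- sim0$truth$gene_id[!is.na(sim0$truth$module_id)]
  edges <- suppressMessages(candidate_edges(log_transform(sim0$expression)))
  within <- edges$gene_a %in% mod & edges$gene_b %in% mod
  expect_equal(sum(within), choose(6, 2))
})

test_that("resample_validate counts per-pair support deterministically", {
  sim <- default_sim()
  lg <- log_transform(sim$expression)
  cand <- candidate_edges(lg)
  val1 <- resample_validate(lg, sim$design, cand, n_iter = 10, seed = 3)
  val2 <- resample_validate(lg, sim$design, cand, n_iter = 10, seed = 3)
  expect_identical(val1, val2)
  expect_true(all(val1$n_validated >= 0 & val1$n_validated <= 10))

  # edge-order invariance given the seed
  shuffled <- cand[sample(nrow(cand)), ]
  val3 <- resample_validate(lg, sim$design, shuffled, n_iter = 10, seed = 3)
  joined <- dplyr::inner_join(val1, val3, by = c("gene_a", "gene_b"))
  expect_equal(joined$n_validated.x, joined$n_validated.y)

  # n_iter = 1 with all replicates selected reproduces the candidate set
  d2 <- sim$design[sim$design$replicate <= 2, ]
  keep_cols <- c("gene_id", d2$sample_id)
  lg2 <- lg[, keep_cols]
  attr(lg2, "expr_scale") <- "log2"
  cand2 <- candidate_edges(lg2)
  val4 <- resample_validate(lg2, d2, cand2, n_iter = 1, reps_per_tissue = 2, seed = 1)
  expect_true(all(val4$validated))

  # misconfigured design fails fast
  d_bad <- sim$design[sim$design$replicate == 1, ]
  lg_bad <- lg[, c("gene_id", d_bad$sample_id)]
  attr(lg_bad, "expr_scale") <- "log2"
  expect_error(resample_validate(lg_bad, d_bad, cand2, reps_per_tissue = 2), "fewer replicates")
})

test_that("noise-free duplicates validate always; outlier-driven pairs do not", {
  design <- tibble::tibble(
    sample_id = sprintf("t%02d_r%d", rep(1:8, each = 3), rep(1:3, 8)),
    tissue = sprintf("t%02d", rep(1:8, each = 3)),
    replicate = rep(1:3, 8)
  )
  set.seed(14)
  base <- rnorm(24, 5, 2)
  # two genes correlated only through one extreme replicate sample
  g1 <- rnorm(24, 5, 0.3)
  g2 <- rnorm(24, 5, 0.3)
  g1[24] <- g2[24] <- 50
  m <- expr_tbl(rbind(dupA = base, dupB = base + 1, outA = g1, outB = g2),
                scale = "log2")
  names(m)[-1] <- design$sample_id
  cand <- tibble::tibble(gene_a = c("dupA", "outA"), gene_b = c("dupB", "outB"),
                         r = c(1, NA))
  val <- resample_validate(m, design, cand, n_iter = 100, seed = 2)
  expect_equal(val$n_validated[1], 100)
  expect_lt(val$n_validated[2], 100)
})

test_that("build_network and filter_min_group respect component structure", {
  expect_equal(igraph::vcount(build_network(tibble::tibble(
    gene_a = character(0), gene_b = character(0)
  ))), 0)

  cfg <- simulation_config(n_genes = 200, frac_hk = 0.1, frac_te = 0.1,
                           n_modules = 3, module_size = 8,
                           module_age_stage = c(1, 4, 8), noise_sd = 0.1, seed = 13)
  sim <- simulate_dataset(cfg)
  lg <- log_transform(sim$expression)
  val <- resample_validate(lg, sim$design, candidate_edges(lg), n_iter = 20, seed = 5)
  net <- build_network(val)
  comp <- igraph::components(net)
  planted_sizes <- sort(table(sim$truth$module_id))
  expect_equal(sort(comp$csize), as.numeric(sort(planted_sizes)))

  # triangle below min_size is removed, 5-node path is kept
  tri <- igraph::graph_from_edgelist(cbind(c("a", "b", "c"), c("b", "c", "a")), directed = FALSE)
  expect_equal(igraph::vcount(filter_min_group(tri, 5)), 0)
  path5 <- igraph::make_ring(5, circular = FALSE)
  igraph::V(path5)$name <- paste0("p", 1:5)
  expect_equal(igraph::vcount(filter_min_group(path5, 5)), 5)
  filtered <- filter_min_group(net, 5)
  expect_lte(igraph::vcount(filtered), igraph::vcount(net))
  expect_lte(igraph::ecount(filtered), igraph::ecount(net))

  # edge list round-trips through writer/reader
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(val, tmp)
  expect_equal(as.data.frame(read_edges_tsv(tmp)), as.data.frame(val),
               ignore_attr = TRUE)
})

test_that("validated edges are always a subset of the candidates", {
  sim <- default_sim()
  lg <- log_transform(sim$expression)
  cand <- candidate_edges(lg)
  val <- resample_validate(lg, sim$design, cand, n_iter = 5, seed = 7)
  key <- function(d) paste(d$gene_a, d$gene_b)
  expect_true(all(key(val[val$validated, ]) %in% key(cand)))
})

test_that("module age composition counts stages and flags the dominant one", {
  members <- tibble::tibble(
    module_id = rep("m1", 4),
    gene_id = paste0("g", 1:4)
  )
  asn <- tibble::tibble(gene_id = paste0("g", 1:4), stage = c(1L, 1L, 1L, 5L))
  comp <- module_age_composition(members, asn)
  expect_equal(comp$proportion[comp$stage == 1], 0.75)
  expect_equal(comp$proportion[comp$stage == 5], 0.25)
  expect_true(comp$dominant[comp$stage == 1])
  expect_false(comp$dominant[comp$stage == 5])

  uniform <- module_age_composition(
    members, tibble::tibble(gene_id = paste0("g", 1:4), stage = 2L)
  )
  expect_equal(uniform$proportion, 1)

  expect_error(
    module_age_composition(members, tibble::tibble(gene_id = "other", stage = 1L)),
    "no age-assigned"
  )
})

test_that("age homogeneity test separates planted modules from permuted nulls", {
  # planted: 6 modules of 12, each one stage
  members <- tibble::tibble(
    module_id = rep(sprintf("m%d", 1:6), each = 12),
    gene_id = sprintf("g%03d", 1:72)
  )
  set.seed(31)
  pool <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:300),
    stage = c(rep(1:6, each = 12), sample(1:8, 228, replace = TRUE))
  )
  res <- age_homogeneity_test(members, pool, n_perm = 300, seed = 4)
  expect_lt(median(res$q_value), 0.05)

  # single stage network-wide: no contrast, p = 1
  flat <- pool
  flat$stage <- 3L
  res_flat <- age_homogeneity_test(members, flat, n_perm = 50, seed = 4)
  expect_true(all(res_flat$p_value == 1))
})
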
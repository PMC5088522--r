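test_that("log_transform maps FPKM to log2(FPKM + 1) and flags the scale", {
  m <- expr_tbl(matrix(c(0, 1, 7), nrow = 1, dimnames = list("g1", c("s1", "s2", "s3"))))
  lg <- log_transform(m)
  expect_equal(unlist(lg[1, -1], use.names = FALSE), c(0, 1, 3))
  expect_identical(attr(lg, "expr_scale"), "log2")
  expect_warning(log_transform(lg), "already")

  neg <- expr_tbl(matrix(-1, dimnames = list("g1", "s1")))
  expect_error(log_transform(neg), "negative")
})

test_that("detect_expressed applies the at-least-one-replicate tissue rule", {
  fx <- tiny_expr()
  calls <- detect_expressed(fx$expr, fx$design, threshold = 1)
  expect_equal(calls$tissues_expressed_in, c(2L, 0L, 1L))
  expect_equal(calls$expressed_in_all_samples, c(TRUE, FALSE, FALSE))
  expect_equal(calls$expressed_in_all_tissues, c(TRUE, FALSE, FALSE))

  # boundary: exactly 1.0 everywhere counts as expressed everywhere
  flat <- expr_tbl(matrix(1, nrow = 1, ncol = 4,
                          dimnames = list("g", fx$design$sample_id)))
  expect_true(detect_expressed(flat, fx$design)$expressed_in_all_samples)
  just_below <- expr_tbl(matrix(0.99, nrow = 1, ncol = 4,
                                dimnames = list("g", fx$design$sample_id)))
  expect_equal(detect_expressed(just_below, fx$design)$tissues_expressed_in, 0L)

  # all-samples call implies the all-tissues call
  sim <- default_sim()
  big <- detect_expressed(sim$expression, sim$design)
  expect_true(all(!big$expressed_in_all_samples | big$expressed_in_all_tissues))

  expect_error(detect_expressed(log_transform(fx$expr), fx$design), "log2")
})

test_that("detect_expressed is monotone in the threshold", {
  sim <- default_sim()
  t1 <- detect_expressed(sim$expression, sim$design, threshold = 1)
  t2 <- detect_expressed(sim$expression, sim$design, threshold = 2)
  expect_true(all(t2$tissues_expressed_in <= t1$tissues_expressed_in))
})

test_that("filter_expressed_genes supports both readings of the mean rule", {
  fx <- tiny_expr()
  # tissue means: g1 (5.5, 6), g2 (0.25, 0.25), g3 (3, 0.25)
  any_t <- filter_expressed_genes(fx$expr, fx$design, rule = "any_tissue")
  expect_setequal(any_t$gene_id, c("g1", "g3"))
  all_t <- filter_expressed_genes(fx$expr, fx$design, rule = "all_tissues")
  expect_setequal(all_t$gene_id, "g1")

  # boundary: a tissue mean of exactly 1.0 keeps the gene
  b <- expr_tbl(matrix(c(1, 1, 0, 0), nrow = 1,
                       dimnames = list("g", fx$design$sample_id)))
  expect_equal(nrow(filter_expressed_genes(b, fx$design)), 1)

  sim <- default_sim()
  kept <- filter_expressed_genes(sim$expression, sim$design)
  planted <- sim$truth$gene_id[sim$truth$class %in% c("HK", "TE")]
  expect_true(all(planted %in% kept$gene_id))
})

test_that("tissue_means averages replicates on the current scale", {
  fx <- tiny_expr()
  tm <- tissue_means(fx$expr, fx$design)
  expect_equal(unlist(tm[tm$gene_id == "g1", -1], use.names = FALSE), c(5.5, 6))
  # single-replicate tissue is the identity
  d1 <- tibble::tibble(sample_id = "a_r1", tissue = "a", replicate = 1L)
  expect_equal(tissue_means(fx$expr, d1)$a, fx$expr$a_r1)
  # Jensen: mean of logs differs from log of mean FPKM for unequal replicates
  lg_means <- tissue_means(log_transform(fx$expr), fx$design)
  expect_false(isTRUE(all.equal(lg_means$a[1], log2(tm$a[1] + 1))))
})

test_that("sample_distance is 1 - Spearman with max distance for degenerate samples", {
  m <- expr_tbl(matrix(c(1, 2, 3, 4, 5,
                         1, 2, 3, 4, 5,
                         5, 4, 3, 2, 1,
                         2, 1, 4, 3, 5),
                       ncol = 4, dimnames = list(paste0("g", 1:5), c("s1", "s2", "s3", "s4"))))
  d <- sample_distance(m)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 2)
  expect_equal(d["s1", "s4"], 1 - 0.8) # hand-checked Spearman r = 0.8
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  degen <- expr_tbl(matrix(c(1, 2, 3, 1, 1, 1), ncol = 2,
                           dimnames = list(paste0("g", 1:3), c("ok", "flat"))))
  expect_warning(d2 <- sample_distance(degen), "zero-variance")
  expect_equal(d2["ok", "flat"], 2)
})

test_that("Spearman distances are invariant to the log transform and match the rank oracle", {
  sim <- default_sim()
  sub <- sim$expression[1:300, ]
  attr(sub, "expr_scale") <- "fpkm"
  d_fpkm <- sample_distance(sub)
  d_log <- sample_distance(log_transform(sub))
  expect_equal(d_fpkm, d_log, tolerance = 1e-12)

  set.seed(99)
  for (i in 1:20) {
    x <- sample(1:10, 20, replace = TRUE) # ties included
    y <- sample(1:10, 20, replace = TRUE)
    m <- expr_tbl(matrix(c(x, y), ncol = 2, dimnames = list(paste0("g", 1:20), c("sx", "sy"))))
    expect_equal(1 - sample_distance(m)["sx", "sy"], oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("cluster_samples merges the closest pair first and validates input", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- cluster_samples(d)
  expect_equal(hc$height[1], 0.1)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("A", "B"))
  # 3-leaf topologies agree across linkages
  ha <- cluster_samples(d, linkage = "average")
  expect_equal(stats::cutree(hc, 2), stats::cutree(ha, 2))

  bad <- d
  bad[1, 2] <- 0.5
  expect_error(cluster_samples(bad), "symmetric")
})

test_that("replicates of a tissue cluster together before tissues merge", {
  sim <- default_sim()
  hc <- cluster_samples(sample_distance(log_transform(sim$expression)))
  groups <- stats::cutree(hc, k = length(unique(sim$design$tissue)))
  tissue <- sim$design$tissue[match(names(groups), sim$design$sample_id)]
  # cutting at the tissue count yields pure groups per tissue
  expect_true(all(tapply(groups, tissue, function(g) length(unique(g))) == 1))
})
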
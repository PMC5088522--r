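test_that("lca handles self, parent and random-tree cases", {
  set.seed(21)
  tree <- random_tree(30)
  x <- "n017"
  expect_identical(lca(tree, x), x)
  parent <- setNames(tree$parent_id, tree$node_id)
  expect_identical(lca(tree, c(x, parent[[x]])), parent[[x]])
  expect_error(lca(tree, character(0)), "nonempty")
  expect_error(lca(tree, "missing"), "unknown")

  for (rep in 1:20) {
    tr <- random_tree(sample(10:120, 1))
    for (k in 1:20) {
      taxa <- sample(tr$node_id, sample(1:6, 1))
      expect_identical(lca(tr, taxa), oracle_lca(tr, taxa))
    }
  }
})

test_that("assign_gene_ages projects group LCAs onto the lineage", {
  lin <- generate_lineage(5, 800, seed = 2)
  tax <- generate_taxonomy(lin, species_per_clade = 2)
  groups <- tibble::tibble(
    group_id = c("og1", "og2", "og3"),
    gene_id = c("focal_only", "root_span", "no_focal"),
    species = list("sp_focal", c("sp_focal", "sp_c01_01"), c("sp_c02_01", "sp_c03_01"))
  )
  expect_warning(asn <- assign_gene_ages(groups, tax, lin), "skipped")
  expect_equal(attr(asn, "n_skipped"), 1)
  expect_equal(asn$clade_index[asn$gene_id == "focal_only"], 5L)
  expect_equal(asn$clade_index[asn$gene_id == "root_span"], 1L)
  # clade index equals the lineage projection of the generic LCA (for the
  # singleton group the LCA is the focal leaf itself, projecting to clade n)
  parent <- setNames(tax$parent_id, tax$node_id)
  project <- function(node) {
    while (!(node %in% lin$node_id)) node <- parent[[node]]
    match(node, lin$node_id)
  }
  for (i in seq_len(nrow(asn))) {
    node <- lca(tax, groups$species[[match(asn$gene_id[i], groups$gene_id)]])
    expect_identical(project(node), asn$clade_index[i])
  }
})

test_that("stage_profile reproduces published-style percentage arithmetic", {
  counts <- c(1178, 2178, 1395, 2333, 5070, 1953, 2821, 509)
  prof <- stage_profile(counts)
  expect_equal(prof$total, 17437)
  expect_equal(round(prof$stages$pct_of_total[1], 2), 6.76)
  expect_equal(round(prof$stages$cumulative_pct[3], 2), 27.25)
  expect_equal(round(prof$stages$cumulative_pct[4], 2), 40.63)
  expect_equal(round(prof$stages$pct_of_total[5]), 29)
  expect_equal(round(prof$stages$cumulative_pct[7], 2), 97.08)
  expect_equal(prof$stages$cumulative_pct[8], 100)
  expect_error(stage_profile(c(-1, 5)), "nonnegative")
})

test_that("stage_profile on assignments conserves counts across clades, stages and subsets", {
  sim <- default_sim()
  asn <- assign_gene_ages(sim$groups, sim$taxonomy, sim$lineage, scheme = sim$scheme)
  prof <- stage_profile(asn, sim$scheme)
  expect_equal(sum(prof$stages$n), nrow(asn))
  expect_equal(sum(prof$clades$n), nrow(asn))
  expect_equal(prof$stages$cumulative_pct[nrow(prof$stages)], 100)
  expect_true(all(diff(prof$stages$cumulative_pct) >= 0))

  hk <- sim$truth$gene_id[sim$truth$class == "HK"]
  prof_hk <- stage_profile(asn, sim$scheme, subset = hk, label = "HK")
  expect_equal(prof_hk$total, length(hk))
  expect_error(stage_profile(asn, sim$scheme, subset = character(0)), "empty")
  expect_error(stage_profile(asn, sim$scheme, subset = "unknown_gene"), "without age")
})

test_that("collapsing to common strata preserves totals and consistency", {
  sim <- default_sim()
  asn <- assign_gene_ages(sim$groups, sim$taxonomy, sim$lineage, scheme = sim$scheme)
  map8 <- sim$scheme |> dplyr::transmute(clade_index, stratum = stage)
  same <- collapse_to_common_strata(asn, asn, map8, map8)
  expect_equal(same$n_a, same$n_b)
  expect_equal(sum(same$n_a), nrow(asn))
  # collapsing 31 clades to 8 stages reproduces the stage profile
  prof <- stage_profile(asn, sim$scheme)
  expect_equal(same$n_a, prof$stages$n)
  expect_error(
    collapse_to_common_strata(asn, asn, map8[map8$clade_index < 5, ], map8),
    "not covered"
  )
})

test_that("merging adjacent clades never changes surviving cumulative boundaries", {
  sim <- default_sim()
  asn <- assign_gene_ages(sim$groups, sim$taxonomy, sim$lineage, scheme = sim$scheme)
  fine <- stage_profile(asn, sim$scheme)
  # coarsen: merge stages (1,2), keep others -> boundaries after old st2 survive
  coarse_scheme <- sim$scheme |>
    dplyr::mutate(stage = pmax(stage - 1L, 1L), stage_label = sprintf("st%d", stage))
  coarse <- stage_profile(asn, coarse_scheme)
  expect_equal(coarse$stages$cumulative_pct, fine$stages$cumulative_pct[-1])
})

test_that("planted stage distribution is recovered at scale", {
  cfg <- simulation_config(n_genes = 10000, frac_hk = 0, frac_te = 0,
                           n_modules = 0, module_age_stage = integer(0), seed = 6)
  truth <- simulate_truth(cfg)
  scheme <- human_stage_scheme()
  stage <- scheme$stage[match(truth$clade_index, scheme$clade_index)]
  emp <- tabulate(stage, 8) / length(stage)
  target <- c(1178, 2178, 1395, 2333, 5070, 1953, 2821, 509)
  target <- target / sum(target)
  expect_lt(sum(abs(emp - target)) / 2, 0.02)
})

test_that("time_axis places cumulative emergence on a monotone age axis", {
  sim <- default_sim()
  asn <- assign_gene_ages(sim$groups, sim$taxonomy, sim$lineage, scheme = sim$scheme)
  prof <- stage_profile(asn, sim$scheme)
  ta <- time_axis(sim$lineage, prof)
  expect_equal(nrow(ta), 31)
  expect_equal(ta$age_mya[31], 0)
  expect_equal(ta$cumulative_pct[31], 100)
  expect_true(all(diff(ta$cumulative_pct) >= 0))

  broken <- sim$lineage
  broken$age_mya[3] <- NA
  expect_error(time_axis(broken, prof), "without age")
  expect_error(time_axis(sim$lineage, stage_profile(c(1, 2, 3))), "per-clade")

  # HK genes planted ancient: their curve dominates the all-gene curve early
  hk <- sim$truth$gene_id[sim$truth$class == "HK"]
  ta_hk <- time_axis(sim$lineage, stage_profile(asn, sim$scheme, subset = hk))
  old <- sim$lineage$clade_index[1:10]
  expect_true(all(ta_hk$cumulative_pct[old] >= ta$cumulative_pct[old]))
  expect_gt(mean(ta_hk$cumulative_pct[old] - ta$cumulative_pct[old]), 5)
})
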
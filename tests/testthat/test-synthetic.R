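test_that("simulated Yule trees are reproducible, unit-depth, fully labelled", {
  tr <- simulate_tree(50, seed = 12)
  expect_equal(length(tr$tip.label), 50)
  expect_true(all(tr$edge.length > 0))
  expect_equal(anyDuplicated(tr$tip.label), 0L)
  expect_equal(ape::write.tree(tr), ape::write.tree(simulate_tree(50, seed = 12)))
  d <- cophenetic_distances(tr)
  expect_lte(max(d), 2 + 1e-9)                        # ultrametric bound
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)
  expect_error(simulate_tree(2), "at least 3")
})

test_that("Brownian trait variance scales with the rate and tip depth", {
  tr <- simulate_tree(10, seed = 31)
  expect_equal(unname(evolve_trait(tr, 0, seed = 1)), rep(0, 10))
  # tips on a unit-depth tree have marginal variance sigma^2
  for (sigma in c(0.5, 2)) {
    tips <- vapply(1:300, function(s) evolve_trait(tr, sigma, seed = s)[[1]],
                   numeric(1))
    se <- sigma^2 * sqrt(2 / 299)                     # SE of a variance estimate
    expect_lt(abs(var(tips) - sigma^2), 3 * se)
  }
  # trait difference between two tips ~ Normal(0, sigma^2 * patristic distance)
  d <- cophenetic_distances(tr)
  pick <- which(d == min(d[d > 0]), arr.ind = TRUE)[1, ]
  diffs <- vapply(1:300, function(s) {
    x <- evolve_trait(tr, 1, seed = s)
    x[[pick[1]]] - x[[pick[2]]]
  }, numeric(1))
  v <- min(d[d > 0])
  expect_lt(abs(var(diffs) - v), 3 * v * sqrt(2 / 299))
})

test_that("scenario validation rejects inconsistent settings", {
  expect_error(assembly_scenario("drift", n_taxa = 2), "at least 3")
  expect_error(assembly_scenario("selection_heterogeneous",
                                 env_optima = c(0, 0)),
               "4 \\* filter_width")
  expect_error(assembly_scenario("homogenized", migration = 1.4), "migration")
  expect_error(assembly_scenario("dispersal_limited", pool_fraction = 0),
               "pool_fraction")
  expect_error(assembly_scenario("drift", filtered_groups = "XX"),
               "filtered_groups")
})

test_that("generated communities respect the declared design", {
  for (nm in c("selection_homogeneous", "dispersal_limited", "drift")) {
    sim <- simulate_communities(assembly_scenario(nm, n_taxa = 60,
                                                  n_samples_per_group = 4,
                                                  depth = 600, seed = 2))
    expect_equal(dim(sim$otu), c(8, 60))
    expect_true(all(rowSums(sim$otu) == 600))
    expect_equal(sim$metadata$group, rep(c("SG", "WF"), each = 4))
    expect_equal(sim$truth$scenario, nm)
  }
})

test_that("datasets regenerate byte-identically from the same scenario", {
  sc <- assembly_scenario("homogenized", n_taxa = 40, n_samples_per_group = 3,
                          depth = 300, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(sc, d1)
  generate_dataset(sc, d2)
  for (f in c("otu_table.tsv", "tree.nwk", "metadata.tsv", "truth.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  x <- read_otu_table(file.path(d1, "otu_table.tsv"))
  expect_true(all(rowSums(x) == 300))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$all, "homogenizing_dispersal")
  expect_equal(truth$parameters$seed, 77L)
})

test_that("selection scenarios confine communities to the niche window", {
  sim <- simulate_communities(assembly_scenario("selection_homogeneous",
                                                n_taxa = 100,
                                                n_samples_per_group = 3,
                                                depth = 1000, seed = 4))
  present <- colnames(sim$otu)[colSums(sim$otu) > 0]
  tr <- sim$traits[present]
  sc <- sim$scenario
  # all realized taxa lie within 2 filter widths of a common optimum
  expect_lt(diff(range(tr)), 4 * sc$filter_width + 1e-9)
})
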
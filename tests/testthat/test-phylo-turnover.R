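test_that("MNTD matches hand-computed nearest-neighbour tables", {
  d <- cophenetic_distances(three_tip_tree())
  two <- setNames(c(3, 7), c("A", "B"))
  expect_equal(mntd(two, d), 2)                       # only one neighbour
  all3 <- setNames(c(1, 1, 1), c("A", "B", "C"))
  expect_equal(mntd(all3, d, abundance_weighted = FALSE), 8 / 3)
  wt <- setNames(c(2, 1, 1), c("A", "B", "C"))
  expect_equal(mntd(wt, d), 0.5 * 2 + 0.25 * 2 + 0.25 * 4)
  expect_error(mntd(setNames(c(1, 0, 0), c("A", "B", "C")), d), "fewer than 2")
})

test_that("beta-MNTD matches hand-computed values and is a pseudo-metric", {
  d <- cophenetic_distances(three_tip_tree())
  a <- setNames(c(5, 0, 0), c("A", "B", "C"))
  cc <- setNames(c(0, 0, 5), c("A", "B", "C"))
  ab <- setNames(c(1, 1, 0), c("A", "B", "C"))
  expect_equal(beta_mntd(a, cc, d), 4)                # single cross pair
  expect_equal(beta_mntd(ab, cc, d), 4)
  expect_equal(beta_mntd(a, a, d), 0)                 # identical communities
  for (seed in 1:5) {
    x <- random_table(4, 10, seed = seed)
    dd <- cophenetic_distances(simulate_tree(10, seed))
    colnames(x) <- rownames(dd)
    c1 <- x[1, ]; c2 <- x[2, ]
    expect_equal(beta_mntd(c1, c2, dd), beta_mntd(c2, c1, dd))
    expect_gte(beta_mntd(c1, c2, dd), 0)
    # uniform abundances reduce the weighted form to the unweighted one
    u <- setNames(as.numeric(c1 > 0), names(c1))
    expect_equal(beta_mntd(u, u * 7, dd, abundance_weighted = TRUE),
                 beta_mntd(u, u, dd, abundance_weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("beta-NTI reproduces the brute-force oracle exactly", {
  tree <- simulate_tree(6, seed = 4)
  d <- cophenetic_distances(tree)
  x <- random_table(4, 6, seed = 13)
  colnames(x) <- rownames(d)
  for (weighted in c(TRUE, FALSE)) {
    cfg <- null_model_config(n_null = 99, abundance_weighted = weighted,
                             seed = 31)
    got <- beta_nti(x, d = d, config = cfg)
    # the oracle consumes the same seeded permutation stream, so agreement
    # is exact up to float summation order
    exp99 <- oracle_beta_nti(x, unname(d), n_null = 99, seed = 31,
                             weighted = weighted)
    expect_equal(got$beta_mntd_obs, exp99$obs, tolerance = 1e-12)
    expect_equal(got$null_mean, exp99$null_mean, tolerance = 1e-12)
    expect_equal(got$null_sd, exp99$null_sd, tolerance = 1e-12)
    expect_equal(got$beta_nti, exp99$beta_nti, tolerance = 1e-12)
  }
})

test_that("NTI reproduces the brute-force oracle and flags degenerate nulls", {
  tree <- simulate_tree(8, seed = 6)
  d <- cophenetic_distances(tree)
  x <- random_table(3, 8, seed = 17)
  colnames(x) <- rownames(d)
  cfg <- null_model_config(n_null = 99, seed = 23)
  got <- nti(x, d = d, config = cfg)
  expect_equal(got$nti, unname(oracle_nti(x, unname(d), 99, seed = 23)),
               tolerance = 1e-12)
  # star phylogeny: all pairwise distances equal, null sd is exactly zero
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  xs <- matrix(c(1, 1, 1, 0, 0, 1, 1, 1), 2, 4, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  res <- nti(xs, tree = star, config = null_model_config(99, seed = 2))
  expect_true(all(res$degenerate_null))
  expect_true(all(is.na(res$nti)))
})

test_that("a community of close relatives is phylogenetically clustered (NTI > 0)", {
  balanced <- ape::compute.brlen(ape::stree(16, type = "balanced"), 1)
  d <- cophenetic_distances(balanced)
  sisters <- rownames(d)[order(d[1, ])[1:2]]          # two closest tips
  x <- matrix(0, 1, 16, dimnames = list("s1", rownames(d)))
  x[1, sisters] <- 10
  pos <- vapply(1:20, function(s)
    nti(x, d = d, config = null_model_config(99, seed = s))$nti > 0,
    logical(1))
  expect_gte(sum(pos), 19)
})

test_that("beta-NTI is invariant to branch-length scaling; beta-MNTD scales", {
  tree <- simulate_tree(12, seed = 14)
  x <- random_table(4, 12, seed = 14)
  colnames(x) <- tree$tip.label
  cfg <- null_model_config(n_null = 99, seed = 7)
  b1 <- beta_nti(x, tree = tree, config = cfg)
  tree2 <- tree
  tree2$edge.length <- tree$edge.length * 3.7
  b2 <- beta_nti(x, tree = tree2, config = cfg)
  expect_equal(b2$beta_mntd_obs, 3.7 * b1$beta_mntd_obs, tolerance = 1e-12)
  expect_equal(b2$beta_nti, b1$beta_nti, tolerance = 1e-9)
})

test_that("beta-NTI emits one symmetric record per unordered pair", {
  sim <- simulate_communities(assembly_scenario("drift", n_taxa = 30,
                                                n_samples_per_group = 4,
                                                depth = 400, seed = 8))
  b <- beta_nti(sim$otu, tree = sim$tree,
                config = null_model_config(n_null = 99, seed = 3))
  expect_equal(nrow(b), choose(8, 2))
  expect_true(all(b$sample_a != b$sample_b))
  expect_true(all(b$null_sd >= 0))
})

test_that("identical samples give a degenerate beta-NTI null, not a value", {
  # a shared tip-label shuffle maps identical communities to identical
  # communities, so every null draw equals the observed zero
  x <- rbind(s1 = c(5, 3, 2, 0), s2 = c(5, 3, 2, 0), s3 = c(1, 1, 1, 6))
  colnames(x) <- c("A", "B", "C", "D")
  d <- cophenetic_distances(ape::read.tree(text = "((A:1,B:2):1,(C:1,D:3):2);"))
  b <- suppressMessages(beta_nti(x, d = d,
                                 config = null_model_config(99, seed = 5)))
  rec <- b[b$sample_a == "s1" & b$sample_b == "s2", ]
  expect_equal(rec$beta_mntd_obs, 0)
  expect_true(is.na(rec$beta_nti))
  expect_equal(attr(b, "n_degenerate"), 1L)
})
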
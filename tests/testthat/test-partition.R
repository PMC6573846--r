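test_that("classification follows the threshold rules with strict boundaries", {
  cfg <- null_model_config()
  expect_equal(classify_pair(-3.0, 0.2, cfg), "homogeneous_selection")
  expect_equal(classify_pair(3.0, 0.2, cfg), "heterogeneous_selection")
  expect_equal(classify_pair(1.0, 0.99, cfg), "dispersal_limitation")
  expect_equal(classify_pair(1.0, -0.99, cfg), "homogenizing_dispersal")
  expect_equal(classify_pair(0.0, 0.0, cfg), "undominated")
  # boundary values fall to the stochastic / undominated side
  expect_equal(classify_pair(2.0, 0.0, cfg), "undominated")
  expect_equal(classify_pair(-2.0, 0.0, cfg), "undominated")
  expect_equal(classify_pair(0.0, 0.95, cfg), "undominated")
  expect_equal(classify_pair(0.0, -0.95, cfg), "undominated")
  expect_equal(classify_pair(NA_real_, 0.5, cfg), "unclassifiable")
  expect_error(classify_pair(0, 1.5, cfg), "\\[-1, 1\\]")
})

test_that("the five regions partition the (beta-NTI, RC) plane exhaustively", {
  cfg <- null_model_config()
  grid <- expand.grid(b = seq(-5, 5, by = 0.05), r = seq(-1, 1, by = 0.01))
  lab <- classify_pair(grid$b, grid$r, cfg)
  expect_true(all(lab %in% setdiff(process_levels(), "unclassifiable")))
  expect_true(all(!is.na(lab)))
  # each region is reached
  expect_setequal(unique(lab), setdiff(process_levels(), "unclassifiable"))
})

test_that("raising the RC threshold moves mass from dispersal to undominated", {
  set.seed(3)
  b <- runif(500, -1.9, 1.9)
  r <- runif(500, -1, 1)
  frac_disp <- function(thr) {
    lab <- classify_pair(b, r, null_model_config(rc_threshold = thr))
    mean(lab %in% c("dispersal_limitation", "homogenizing_dispersal"))
  }
  thr <- c(0.5, 0.7, 0.9, 0.95, 0.99)
  expect_true(all(diff(vapply(thr, frac_disp, numeric(1))) <= 0))
})

test_that("process summaries have the right scope sizes and unit fractions", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:20),
                   group = rep(c("SG", "WF"), each = 10))
  pairs <- t(combn(md$sample_id, 2))
  set.seed(11)
  df <- data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
                   process = sample(process_levels()[1:5], nrow(pairs),
                                    replace = TRUE))
  s <- summarize_processes(df, md)
  n_of <- function(sc) sum(s$n_pairs[s$scope == sc])
  expect_equal(n_of("all"), 190)
  expect_equal(n_of("SG"), 45)
  expect_equal(n_of("WF"), 45)
  expect_equal(n_of("between"), 100)
  for (sc in unique(s$scope)) {
    f <- s$fraction[s$scope == sc & s$process != "unclassifiable"]
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
  # fractions match direct arithmetic on a fixed composition
  df10 <- data.frame(
    sample_a = md$sample_id[1:10],
    sample_b = md$sample_id[c(2:10, 1)],
    process = rep(c("dispersal_limitation", "homogeneous_selection",
                    "homogenizing_dispersal", "undominated"), c(4, 3, 2, 1)))
  s10 <- summarize_processes(df10, md)
  got <- s10[s10$scope == "all" & s10$process %in% unique(df10$process), ]
  expect_equal(got$fraction[match(c("dispersal_limitation",
                                    "homogeneous_selection",
                                    "homogenizing_dispersal", "undominated"),
                                  got$process)],
               c(0.4, 0.3, 0.2, 0.1))
})

test_that("summaries are invariant to pair order and degrade gracefully", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("A", "B"), each = 3))
  pairs <- t(combn(md$sample_id, 2))
  set.seed(5)
  df <- data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
                   process = sample(process_levels()[1:5], nrow(pairs),
                                    replace = TRUE))
  s1 <- summarize_processes(df, md)
  s2 <- summarize_processes(df[sample(nrow(df)), ], md)
  expect_equal(s1, s2)
  # all pairs unclassifiable: zero counts, missing fractions
  df$process <- "unclassifiable"
  s3 <- summarize_processes(df, md)
  expect_true(all(is.na(s3$fraction)))
  expect_equal(sum(s3$n_pairs[s3$process != "unclassifiable"]), 0)
})

test_that("classified pair tables merge, write, and round-trip", {
  sim <- simulate_communities(assembly_scenario("drift", n_taxa = 30,
                                                n_samples_per_group = 3,
                                                depth = 400, seed = 21))
  cfg <- null_model_config(n_null = 99, seed = 3)
  b <- beta_nti(sim$otu, tree = sim$tree, config = cfg)
  r <- rc_bray(sim$otu, config = cfg)
  p <- classify_processes(b, r, sim$metadata, cfg)
  expect_equal(nrow(p), choose(6, 2))
  expect_true(all(p$pair_class %in% c("SG", "WF", "between")))
  dir <- withr::local_tempdir()
  write_assembly_results(p, summarize_processes(p, sim$metadata), dir)
  back <- read.table(file.path(dir, "pairwise_assembly.tsv"),
                     header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  num <- vapply(p, is.numeric, logical(1))
  for (cl in names(p)[num])
    expect_equal(back[[cl]], p[[cl]], tolerance = 1e-6)
})
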
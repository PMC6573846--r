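#' Define a synthetic assembly scenario
#'
#' A scenario bundles every knob of the synthetic-data generator together
#' with the ground-truth assembly process it encodes. The defaults emulate a
#' seasonal two-group field design: 2 groups x 10 replicate samples, 200
#' taxa on a unit-depth Yule tree, every sample at a fixed depth of 2,000
#' reads.
#'
#' Scenarios:
#' \describe{
#'   \item{selection_homogeneous}{both groups filter on the same trait
#'     optimum; pairs share one clustered community, turnover is lower than
#'     the null expects (beta-NTI < -2).}
#'   \item{selection_heterogeneous}{groups filter on distant optima
#'     (at least `4 * filter_width` apart); between-group turnover exceeds
#'     the null (beta-NTI > +2).}
#'   \item{dispersal_limited}{no trait filter; each sample assembles from
#'     its own restricted, low-overlap subset of the taxon pool with
#'     log-normal abundances, so taxonomic turnover exceeds the RC null
#'     (RC > +0.95).}
#'   \item{homogenized}{all samples draw from one shared log-normal
#'     composition perturbed by `(1 - migration)`-scaled noise; at
#'     `migration = 1` expected compositions are identical and turnover
#'     falls below the RC null (RC < -0.95).}
#'   \item{drift}{independent symmetric-Dirichlet compositions per sample;
#'     no phylogenetic or dispersal structure (undominated).}
#' }
#'
#' @param name scenario name (see above).
#' @param n_taxa number of taxa in the regional pool (default 200).
#' @param n_samples_per_group replicate samples per group (default 10).
#' @param n_groups number of groups (default 2).
#' @param depth per-sample read depth; every generated sample sums to it
#'   (default 2000).
#' @param trait_sigma Brownian-motion rate of the filtered trait, in trait
#'   units per unit branch length (default 1; tips then have trait SD 1 on a
#'   unit-depth tree).
#' @param filter_width SD of the Gaussian environmental filter in trait
#'   units (default 0.3); taxa beyond 2 filter widths from the optimum
#'   cannot establish (hard niche boundary).
#' @param env_optima per-group trait optima. By default (`NULL`) each
#'   optimum is anchored automatically on the most phylogenetically
#'   coherent trait window of the simulated tree, so the filter selects a
#'   conserved syndrome rather than a convergent scatter of taxa;
#'   `selection_heterogeneous` anchors two syndromes at least
#'   `4 * filter_width` apart.
#' @param migration homogenization strength in `[0, 1]`; 1 means identical
#'   expected compositions across samples (default 1).
#' @param pool_fraction fraction of the taxon pool reachable per sample
#'   under dispersal limitation (default 0.25).
#' @param lognormal_sdlog log-scale SD of log-normal abundance weights in
#'   the dispersal-limited and homogenized scenarios (default 2, a strongly
#'   uneven community).
#' @param noise_sdlog log-scale SD of the per-sample noise in the
#'   homogenized scenario before migration scaling (default 1).
#' @param colonize_prob probability that a taxon inside the niche window
#'   reaches a given sample in the selection scenarios (default 0.6);
#'   drives membership turnover among clade mates.
#' @param demographic_sdlog log-scale SD of per-sample demographic noise in
#'   the selection scenarios (default 0.5).
#' @param drift_richness fraction of the taxon pool present per sample under
#'   drift (default 0.6); membership is a uniform random subset and
#'   abundances track the shared metacommunity weights.
#' @param group_names group labels (default `"SG"`, `"WF"`, then `"G3"`...).
#' @param filtered_groups optional subset of groups the environmental filter
#'   applies to in the selection scenarios; unfiltered groups sample all
#'   taxa uniformly (used to contrast a filtered against an unfiltered
#'   habitat).
#' @param seed master seed; every downstream draw derives from it.
#' @return a list of class `assembly_scenario`.
#' @export
assembly_scenario <- function(name = c("selection_homogeneous",
                                       "selection_heterogeneous",
                                       "dispersal_limited",
                                       "homogenized",
                                       "drift"),
                              n_taxa = 200, n_samples_per_group = 10,
                              n_groups = 2, depth = 2000,
                              trait_sigma = 1, filter_width = 0.3,
                              env_optima = NULL,
                              migration = 1, pool_fraction = 0.25,
                              lognormal_sdlog = 2, noise_sdlog = 1,
                              colonize_prob = 0.6, demographic_sdlog = 0.5,
                              drift_richness = 0.6,
                              group_names = NULL, filtered_groups = NULL,
                              seed = 1L) {
  name <- match.arg(name)
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  if (n_groups < 1) stop("n_groups must be positive")
  if (depth < 1) stop("depth must be positive")
  if (trait_sigma < 0) stop("trait_sigma must be non-negative")
  if (filter_width <= 0) stop("filter_width must be positive")
  if (migration < 0 || migration > 1) stop("migration must be in [0, 1]")
  if (pool_fraction <= 0 || pool_fraction > 1)
    stop("pool_fraction must be in (0, 1]")
  if (colonize_prob <= 0 || colonize_prob > 1)
    stop("colonize_prob must be in (0, 1]")
  if (drift_richness <= 0 || drift_richness > 1)
    stop("drift_richness must be in (0, 1]")
  if (is.null(group_names))
    group_names <- c("SG", "WF", paste0("G", seq_len(n_groups)))[seq_len(n_groups)]
  if (length(group_names) != n_groups) stop("need one name per group")
  if (!is.null(env_optima)) {
    if (length(env_optima) != n_groups) stop("need one env optimum per group")
    if (name == "selection_heterogeneous") {
      gaps <- abs(diff(sort(env_optima)))
      if (any(gaps < 4 * filter_width))
        stop("selection_heterogeneous needs group optima at least ",
             "4 * filter_width apart")
    }
  }
  if (!is.null(filtered_groups) && !all(filtered_groups %in% group_names))
    stop("filtered_groups must be a subset of group_names")
  structure(list(name = name, n_taxa = as.integer(n_taxa),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_groups = as.integer(n_groups), depth = as.integer(depth),
                 trait_sigma = trait_sigma, filter_width = filter_width,
                 env_optima = env_optima, migration = migration,
                 pool_fraction = pool_fraction,
                 lognormal_sdlog = lognormal_sdlog,
                 noise_sdlog = noise_sdlog,
                 colonize_prob = colonize_prob,
                 demographic_sdlog = demographic_sdlog,
                 drift_richness = drift_richness,
                 group_names = group_names,
                 filtered_groups = filtered_groups,
                 seed = as.integer(seed)),
            class = "assembly_scenario")
}

#' Simulate a pure-birth (Yule) phylogeny with unit depth
#'
#' Tips are labelled `otu_0001`, `otu_0002`, ... and all branch lengths are
#' rescaled so the root-to-tip depth is exactly 1, keeping phylogenetic
#' distances comparable across seeds and tree sizes.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed.
#' @return an ultrametric [ape::phylo] object with `n_taxa` tips.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("otu_%04d", seq_len(n_taxa))
  tree
}

#' Evolve a continuous trait along a tree by Brownian motion
#'
#' Starting from 0 at the root, the trait accumulates independent Gaussian
#' increments with variance `trait_sigma^2 * branch length` along each edge,
#' so a tip's marginal variance equals `trait_sigma^2` times its
#' root-to-tip path length. This gives the trait the phylogenetic signal
#' that lets environmental filtering produce phylogenetically clustered
#' communities.
#'
#' @param tree an [ape::phylo] object.
#' @param trait_sigma Brownian rate (>= 0; 0 gives all-zero traits).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
evolve_trait <- function(tree, trait_sigma, seed = 1L) {
  tree <- validate_phylogeny(tree)
  if (trait_sigma < 0) stop("trait_sigma must be non-negative")
  set.seed(seed)
  ape::rTraitCont(tree, model = "BM", sigma = trait_sigma, root.value = 0)
}

# Anchor an environmental optimum on the most phylogenetically coherent
# trait window. Brownian traits converge: taxa sharing a trait value are not
# necessarily one clade, so a fixed optimum can select a phylogenetically
# scattered set and void the premise of the selection scenarios. Candidate
# optima are scanned over the observed trait range; each window (+/- 2
# filter widths) of adequate size is scored by the mean within-window
# nearest-taxon distance, and the most coherent window wins. `exclude`
# rejects optima too close to an already chosen one (heterogeneous
# selection needs distant, distinct syndromes).
.anchor_optimum <- function(traits, d, filter_width, exclude = NULL,
                            min_sep = 0) {
  t <- length(traits)
  lo <- max(4, round(0.08 * t))
  hi <- max(lo + 2, round(0.3 * t))
  grid <- unique(stats::quantile(traits, seq(0.02, 0.98, length.out = 49),
                                 names = FALSE))
  score <- function(o) {
    a <- which(abs(traits - o) < 2 * filter_width)
    if (length(a) < lo || length(a) > hi) return(NA_real_)
    sub <- d[a, a, drop = FALSE]
    diag(sub) <- Inf
    mean(apply(sub, 1L, min))
  }
  sc <- vapply(grid, score, numeric(1))
  if (!is.null(exclude))
    sc[vapply(grid, function(o) any(abs(o - exclude) < min_sep), logical(1))] <- NA
  if (all(is.na(sc))) {
    # no window of adequate size: fall back to the densest feasible one
    sizes <- vapply(grid, function(o)
      sum(abs(traits - o) < 2 * filter_width), numeric(1))
    if (!is.null(exclude)) {
      far <- vapply(grid, function(o) all(abs(o - exclude) >= min_sep),
                    logical(1))
      if (any(far)) sizes[!far] <- -Inf
    }
    return(grid[which.max(sizes)])
  }
  grid[which.min(sc)]
}

# default per-group optima for the selection scenarios
.default_optima <- function(sc, traits, d) {
  if (!is.null(sc$env_optima)) return(sc$env_optima)
  if (sc$name == "selection_homogeneous") {
    rep(.anchor_optimum(traits, d, sc$filter_width), sc$n_groups)
  } else {
    o1 <- .anchor_optimum(traits, d, sc$filter_width)
    o2 <- .anchor_optimum(traits, d, sc$filter_width, exclude = o1,
                          min_sep = 4 * sc$filter_width)
    if (abs(o2 - o1) < 4 * sc$filter_width)
      stop("could not find two trait syndromes at least 4 filter widths ",
           "apart; widen the trait range or narrow filter_width")
    rep_len(c(o1, o2), sc$n_groups)
  }
}

# per-sample taxon sampling weights for one scenario; returns n x n_taxa
.scenario_weights <- function(sc, traits, groups, d = NULL) {
  n <- length(groups)
  t <- sc$n_taxa
  W <- matrix(0, n, t)
  filt <- function(g) is.null(sc$filtered_groups) || g %in% sc$filtered_groups
  switch(sc$name,
    selection_homogeneous = ,
    selection_heterogeneous = {
      optima <- .default_optima(sc, traits, d)
      if (sc$name == "selection_heterogeneous" &&
          any(abs(diff(sort(optima))) < 4 * sc$filter_width))
        stop("selection_heterogeneous needs group optima at least ",
             "4 * filter_width apart")
      for (i in seq_len(n)) {
        g <- match(groups[i], sc$group_names)
        if (!filt(groups[i])) {
          W[i, ] <- rep(1, t)
          next
        }
        o <- optima[g]
        # truncated Gaussian niche, random colonization, demographic noise
        base <- exp(-(traits - o)^2 / (2 * sc$filter_width^2)) *
          (abs(traits - o) < 2 * sc$filter_width)
        repeat {
          reach <- stats::runif(t) < sc$colonize_prob
          w <- base * reach * stats::rlnorm(t, 0, sc$demographic_sdlog)
          if (sum(w > 0) >= 2) break
        }
        W[i, ] <- w
      }
    },
    dispersal_limited = {
      m <- max(2L, round(sc$pool_fraction * t))
      usage <- rep(0, t)
      for (i in seq_len(n)) {
        # prefer little-used taxa so per-sample pools stay near-disjoint
        idx <- sample.int(t, m, prob = 1 / (1 + usage)^4)
        usage[idx] <- usage[idx] + 1
        W[i, idx] <- stats::rlnorm(m, 0, sc$lognormal_sdlog)
      }
    },
    homogenized = {
      base <- stats::rlnorm(t, 0, sc$lognormal_sdlog)
      for (i in seq_len(n)) {
        noise <- stats::rnorm(t, 0, sc$noise_sdlog * (1 - sc$migration))
        W[i, ] <- base * exp(noise)
      }
    },
    drift = {
      # neutral stochastic reassembly: random membership around a shared
      # metacommunity, abundances tracking the shared regional weights
      base <- stats::rlnorm(t, 0, 1)
      m <- max(2L, round(sc$drift_richness * t))
      for (i in seq_len(n)) {
        idx <- sample.int(t, m)
        W[i, idx] <- base[idx]
      }
    })
  W
}

# ground-truth process per scope for a scenario
.scenario_truth <- function(sc) {
  within <- setNames(rep(NA_character_, sc$n_groups), sc$group_names)
  truth <- switch(sc$name,
    selection_homogeneous = list(all = "homogeneous_selection",
                                 within = "homogeneous_selection",
                                 between = "homogeneous_selection"),
    selection_heterogeneous = list(all = NA_character_,
                                   within = "homogeneous_selection",
                                   between = "heterogeneous_selection"),
    dispersal_limited = list(all = "dispersal_limitation",
                             within = "dispersal_limitation",
                             between = "dispersal_limitation"),
    homogenized = list(all = "homogenizing_dispersal",
                       within = "homogenizing_dispersal",
                       between = "homogenizing_dispersal"),
    drift = list(all = "undominated", within = "undominated",
                 between = "undominated"))
  list(scenario = sc$name,
       all = truth$all,
       within = setNames(rep(truth$within, sc$n_groups), sc$group_names),
       between = truth$between)
}

#' Simulate communities under a known assembly scenario
#'
#' Builds per-sample taxon sampling weights according to the scenario (see
#' [assembly_scenario()]) and draws each sample's counts as one multinomial
#' of size `depth` from its normalized weights. Multinomial sampling at
#' fixed depth plays the role of rarefaction: every sample total equals
#' `depth` by construction.
#'
#' @param scenario an [assembly_scenario()].
#' @param tree optional pre-built tree (default: simulated from the
#'   scenario's seed).
#' @param traits optional named trait vector (default: evolved from the
#'   scenario's seed).
#' @return list with `otu` (count matrix), `metadata` (data.frame),
#'   `tree`, `traits`, `truth` (ground-truth process per scope), and
#'   `scenario`.
#' @export
simulate_communities <- function(scenario, tree = NULL, traits = NULL) {
  sc <- scenario
  if (!inherits(sc, "assembly_scenario"))
    stop("scenario must come from assembly_scenario()")
  set.seed(sc$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3)
  if (is.null(tree)) tree <- simulate_tree(sc$n_taxa, seeds[1])
  if (length(tree$tip.label) != sc$n_taxa)
    stop("tree size does not match scenario n_taxa")
  if (is.null(traits)) traits <- evolve_trait(tree, sc$trait_sigma, seeds[2])
  traits <- traits[tree$tip.label]
  n <- sc$n_groups * sc$n_samples_per_group
  groups <- rep(sc$group_names, each = sc$n_samples_per_group)
  sample_ids <- sprintf("%s_%02d", groups,
                        rep(seq_len(sc$n_samples_per_group), sc$n_groups))
  d <- if (sc$name %in% c("selection_homogeneous", "selection_heterogeneous") &&
           is.null(sc$env_optima)) cophenetic_distances(tree) else NULL
  set.seed(seeds[3])
  W <- .scenario_weights(sc, traits, groups, d = d)
  if (any(rowSums(W) <= 0)) stop("scenario produced an all-zero weight vector")
  expected_rich <- max(vapply(seq_len(n), function(i) {
    w <- W[i, ] / sum(W[i, ])
    sum(w > 0.001)              # taxa with non-negligible sampling weight
  }, numeric(1)))
  if (sc$depth < 10 * expected_rich)
    warning("depth ", sc$depth, " is below 10x the expected per-sample ",
            "richness (~", expected_rich, "); rare taxa will be undersampled")
  counts <- t(vapply(seq_len(n),
                     function(i) as.vector(stats::rmultinom(1, sc$depth,
                                                            W[i, ])),
                     numeric(sc$n_taxa)))
  dimnames(counts) <- list(sample_ids, tree$tip.label)
  # multinomial draws can miss every taxon of a tiny-weight sample only if
  # depth is 0, which the constructor forbids; rows always sum to depth
  list(otu = otu_table(counts),
       metadata = data.frame(sample_id = sample_ids, group = groups,
                             stringsAsFactors = FALSE),
       tree = tree, traits = traits,
       truth = .scenario_truth(sc),
       scenario = sc)
}

#' Write a synthetic dataset to disk
#'
#' Writes `otu_table.tsv`, `tree.nwk`, `metadata.tsv`, and `truth.json`
#' (ground-truth process per scope plus all scenario parameters) into
#' `out_dir`. Regeneration from the same scenario (same seed) reproduces
#' byte-identical files.
#'
#' @param scenario an [assembly_scenario()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the [simulate_communities()] result.
#' @export
generate_dataset <- function(scenario, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  sim <- simulate_communities(scenario)
  write_otu_table(sim$otu, file.path(out_dir, "otu_table.tsv"))
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  write.table(sim$metadata, file.path(out_dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- c(sim$truth,
             list(parameters = unclass(sim$scenario)))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(sim)
}
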
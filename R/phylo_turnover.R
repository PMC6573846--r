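#' Null-model configuration
#'
#' Bundles the settings shared by the null-model metrics: the number of null
#' randomizations, abundance weighting, the RNG seed, and the critical
#' values used by the process partition (|beta-NTI| > 2 for selection,
#' |RC| > 0.95 for dispersal).
#'
#' @param n_null number of null randomizations (>= 99; default 999).
#' @param abundance_weighted weight nearest-taxon distances by relative
#'   abundance (default) or use presence/absence.
#' @param seed integer RNG seed.
#' @param bnti_threshold critical value for |beta-NTI| (default 2).
#' @param rc_threshold critical value for |RC| (default 0.95).
#' @return a list of class `null_model_config`.
#' @export
null_model_config <- function(n_null = 999, abundance_weighted = TRUE,
                              seed = 1L, bnti_threshold = 2,
                              rc_threshold = 0.95) {
  if (n_null < 99) stop("n_null must be at least 99")
  if (bnti_threshold <= 0 || rc_threshold <= 0)
    stop("thresholds must be positive")
  structure(list(n_null = as.integer(n_null),
                 abundance_weighted = isTRUE(abundance_weighted),
                 seed = as.integer(seed),
                 bnti_threshold = bnti_threshold,
                 rc_threshold = rc_threshold),
            class = "null_model_config")
}

# align a cophenetic matrix (or tree) to the taxa of a table
.turnover_distances <- function(taxa, tree = NULL, d = NULL) {
  if (is.null(d)) {
    if (is.null(tree)) stop("either a tree or a distance matrix is required")
    d <- cophenetic_distances(prune_phylogeny(tree, taxa))
  }
  missing <- setdiff(taxa, rownames(d))
  if (length(missing))
    stop("taxa absent from the distance matrix: ",
         paste(utils::head(missing, 10), collapse = ", "))
  d[taxa, taxa, drop = FALSE]
}

# running minimum over rows of a matrix (columnwise min), C-speed via pmin
.col_mins <- function(m) {
  out <- m[1L, ]
  nr <- nrow(m)
  if (nr > 1L) for (i in 2:nr) out <- pmin(out, m[i, ])
  out
}

#' Mean nearest taxon distance (MNTD) of one community
#'
#' The mean phylogenetic distance from each taxon present in the community
#' to its closest relative in the same community. With
#' `abundance_weighted = TRUE` each taxon's nearest-neighbour distance is
#' weighted by its relative abundance.
#'
#' @param community named non-negative abundance vector; names are taxa
#'   present in `d`. At least two taxa must have positive abundance.
#' @param d cophenetic distance matrix covering the community's taxa.
#' @param abundance_weighted logical.
#' @return MNTD (non-negative scalar).
#' @export
mntd <- function(community, d, abundance_weighted = TRUE) {
  if (is.null(names(community))) stop("community vector must be named by taxon")
  present <- names(community)[community > 0]
  if (length(present) < 2)
    stop("MNTD undefined: fewer than 2 taxa with positive abundance")
  sub <- d[present, present, drop = FALSE]
  diag(sub) <- Inf
  nearest <- apply(sub, 1L, min)
  if (abundance_weighted) {
    f <- community[present] / sum(community[present])
    sum(f * nearest)
  } else {
    mean(nearest)
  }
}

#' Nearest taxon index (NTI) per sample
#'
#' The negated standardized effect size of MNTD against a tip-shuffle null:
#' `NTI = -(MNTD_obs - mean_null) / sd_null`, where each null draw shuffles
#' the taxon labels across all tips of the distance matrix ("taxa.labels"
#' randomization, one shared permutation per draw). Positive NTI indicates
#' phylogenetic clustering, negative NTI overdispersion. Samples whose null
#' standard deviation is numerically zero (e.g., on a star phylogeny) are
#' returned as `NA` with `degenerate_null = TRUE` rather than silently 0.
#'
#' @param x OTU table matrix (samples x taxa).
#' @param tree phylogeny covering the table's taxa (or pass `d`).
#' @param config a [null_model_config()].
#' @param d optional precomputed cophenetic matrix (overrides `tree`).
#' @return data.frame with columns `sample_id`, `mntd_obs`, `null_mean`,
#'   `null_sd`, `nti`, `degenerate_null`.
#' @export
nti <- function(x, tree = NULL, config = null_model_config(), d = NULL) {
  x <- otu_table(x)
  d <- .turnover_distances(colnames(x), tree, d)
  dn <- unname(d)
  n_taxa <- ncol(x)
  idx <- lapply(seq_len(nrow(x)), function(i) which(x[i, ] > 0))
  if (any(lengths(idx) < 2))
    stop("MNTD undefined for sample(s) with fewer than 2 taxa: ",
         paste(rownames(x)[lengths(idx) < 2], collapse = ", "))
  w <- lapply(seq_len(nrow(x)), function(i) {
    v <- x[i, idx[[i]]]
    v / sum(v)
  })
  one_mntd <- function(tip_idx, f) {
    sub <- dn[tip_idx, tip_idx, drop = FALSE]
    diag(sub) <- Inf
    nearest <- apply(sub, 1L, min)
    if (config$abundance_weighted) sum(f * nearest) else mean(nearest)
  }
  obs <- vapply(seq_along(idx), function(i) one_mntd(idx[[i]], w[[i]]),
                numeric(1))
  set.seed(config$seed)
  nulls <- matrix(NA_real_, config$n_null, nrow(x))
  for (r in seq_len(config$n_null)) {
    perm <- sample.int(n_taxa)
    nulls[r, ] <- vapply(seq_along(idx),
                         function(i) one_mntd(perm[idx[[i]]], w[[i]]),
                         numeric(1))
  }
  mu <- colMeans(nulls)
  sdev <- apply(nulls, 2L, stats::sd)
  degen <- sdev < 1e-12
  data.frame(sample_id = rownames(x),
             mntd_obs = obs,
             null_mean = mu,
             null_sd = sdev,
             nti = ifelse(degen, NA_real_, -(obs - mu) / sdev),
             degenerate_null = degen,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For a pair of communities, the mean distance from each taxon in one
#' community to its nearest relative in the other, averaged over both
#' directions: `0.5 * (sum_i f_ia min_j d_ij + sum_j f_jb min_i d_ij)`.
#' A taxon present in both communities finds itself at distance zero, so
#' identical communities have beta-MNTD exactly 0.
#'
#' @param comm_a,comm_b named non-negative abundance vectors.
#' @param d cophenetic distance matrix covering both communities' taxa.
#' @param abundance_weighted logical; `FALSE` uses `1 / richness` weights.
#' @return beta-MNTD (non-negative scalar).
#' @export
beta_mntd <- function(comm_a, comm_b, d, abundance_weighted = TRUE) {
  if (is.null(names(comm_a)) || is.null(names(comm_b)))
    stop("community vectors must be named by taxon")
  a <- names(comm_a)[comm_a > 0]
  b <- names(comm_b)[comm_b > 0]
  if (!length(a) || !length(b)) stop("empty community")
  sub <- d[a, b, drop = FALSE]
  near_a <- apply(sub, 1L, min)
  near_b <- apply(sub, 2L, min)
  if (abundance_weighted) {
    fa <- comm_a[a] / sum(comm_a[a])
    fb <- comm_b[b] / sum(comm_b[b])
  } else {
    fa <- rep(1 / length(a), length(a))
    fb <- rep(1 / length(b), length(b))
  }
  0.5 * (sum(fa * near_a) + sum(fb * near_b))
}

# beta-MNTD for all sample pairs at once.
# W: weight matrix (rows sum to 1 over present taxa), P: logical presence,
# D: cophenetic matrix aligned to columns. Uses the identity
#   bMNTD(a, b) = 0.5 * ((W M')[a, b] + (W M')[b, a])
# where M[b, i] = min_{j present in b} D[i, j].
.pairwise_beta_mntd <- function(W, P, D) {
  n <- nrow(W)
  M <- matrix(NA_real_, n, ncol(W))
  for (b in seq_len(n)) M[b, ] <- .col_mins(D[P[b, ], , drop = FALSE])
  S <- W %*% t(M)
  B <- 0.5 * (S + t(S))
  diag(B) <- 0
  B
}

#' Beta-NTI for every pair of samples
#'
#' For each unordered sample pair, the observed beta-MNTD is standardized
#' against a null distribution obtained by shuffling taxon labels across all
#' tips of the pooled phylogeny (`config$n_null` shared permutations, one
#' per draw, applied to every pair): `beta-NTI = (obs - null_mean) /
#' null_sd`. Values below -2 indicate less phylogenetic turnover than
#' expected (homogeneous selection), above +2 more than expected
#' (heterogeneous selection). Pairs whose null standard deviation is below
#' 1e-12 (e.g., two identical samples, which every shared shuffle maps to
#' identical samples) get `beta_nti = NA` and are counted in the
#' `degenerate_null` attribute; they are later reported as unclassifiable.
#'
#' @param x OTU table matrix (samples x taxa).
#' @param tree phylogeny covering the table's taxa (or pass `d`).
#' @param config a [null_model_config()].
#' @param d optional precomputed cophenetic matrix (overrides `tree`).
#' @param keep_null return the null draws (`n_null` x pairs matrix) as
#'   attribute `"null_draws"` for diagnostics.
#' @return data.frame with one row per unordered pair: `sample_a`,
#'   `sample_b`, `beta_mntd_obs`, `null_mean`, `null_sd`, `beta_nti`.
#' @export
beta_nti <- function(x, tree = NULL, config = null_model_config(), d = NULL,
                     keep_null = FALSE) {
  x <- otu_table(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  d <- .turnover_distances(colnames(x), tree, d)
  D <- unname(d)
  P <- x > 0
  if (any(rowSums(P) < 1)) stop("empty sample(s)")
  W <- if (config$abundance_weighted) x / rowSums(x) else P / rowSums(P)
  W <- unname(W)
  obs <- .pairwise_beta_mntd(W, P, D)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- sequence((n - 1):1, from = 2:n)
  npair <- length(pair_i)
  flat <- cbind(pair_i, pair_j)
  set.seed(config$seed)
  nulls <- matrix(NA_real_, config$n_null, npair)
  n_taxa <- ncol(x)
  for (r in seq_len(config$n_null)) {
    perm <- sample.int(n_taxa)
    inv <- order(perm)
    Bn <- .pairwise_beta_mntd(W[, inv, drop = FALSE],
                              P[, inv, drop = FALSE], D)
    nulls[r, ] <- Bn[flat]
  }
  mu <- colMeans(nulls)
  sdev <- apply(nulls, 2L, stats::sd)
  degen <- sdev < 1e-12
  out <- data.frame(sample_a = rownames(x)[pair_i],
                    sample_b = rownames(x)[pair_j],
                    beta_mntd_obs = obs[flat],
                    null_mean = mu,
                    null_sd = sdev,
                    beta_nti = ifelse(degen, NA_real_,
                                      (obs[flat] - mu) / sdev),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_degenerate") <- sum(degen)
  if (sum(degen))
    message(sum(degen), " pair(s) with degenerate null (sd < 1e-12): ",
            "beta-NTI undefined")
  if (keep_null) attr(out, "null_draws") <- nulls
  out
}
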
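# Independent brute-force oracles. These deliberately share nothing with the
# package implementation beyond the RNG protocol (set.seed, then one
# sample.int(n_taxa) per null draw), so exact agreement is meaningful.

# naive nearest-neighbour beta-MNTD on integer-indexed vectors
oracle_beta_mntd <- function(xa, xb, d, weighted = TRUE) {
  a <- which(xa > 0)
  b <- which(xb > 0)
  fa <- if (weighted) xa[a] / sum(xa[a]) else rep(1 / length(a), length(a))
  fb <- if (weighted) xb[b] / sum(xb[b]) else rep(1 / length(b), length(b))
  na <- vapply(a, function(i) min(d[i, b]), numeric(1))
  nb <- vapply(b, function(j) min(d[a, j]), numeric(1))
  0.5 * (sum(fa * na) + sum(fb * nb))
}

# full beta-NTI table by explicit permutation of the distance matrix
oracle_beta_nti <- function(x, d, n_null, seed, weighted = TRUE) {
  n <- nrow(x)
  pairs <- t(combn(n, 2))
  one <- function(dd) apply(pairs, 1, function(p)
    oracle_beta_mntd(x[p[1], ], x[p[2], ], dd, weighted))
  obs <- one(d)
  set.seed(seed)
  nulls <- matrix(NA_real_, n_null, nrow(pairs))
  for (r in seq_len(n_null)) {
    perm <- sample.int(ncol(x))
    nulls[r, ] <- one(d[perm, perm])
  }
  list(obs = obs,
       null_mean = colMeans(nulls),
       null_sd = apply(nulls, 2, sd),
       beta_nti = (obs - colMeans(nulls)) / apply(nulls, 2, sd))
}

# naive MNTD and NTI by the same protocol
oracle_mntd <- function(xa, d, weighted = TRUE) {
  a <- which(xa > 0)
  near <- vapply(a, function(i) min(d[i, setdiff(a, i)]), numeric(1))
  if (weighted) sum(xa[a] / sum(xa[a]) * near) else mean(near)
}

oracle_nti <- function(x, d, n_null, seed, weighted = TRUE) {
  obs <- apply(x, 1, oracle_mntd, d = d, weighted = weighted)
  set.seed(seed)
  nulls <- matrix(NA_real_, n_null, nrow(x))
  for (r in seq_len(n_null)) {
    perm <- sample.int(ncol(x))
    dp <- d[perm, perm]
    nulls[r, ] <- apply(x, 1, oracle_mntd, d = dp, weighted = weighted)
  }
  -(obs - colMeans(nulls)) / apply(nulls, 2, sd)
}

# ANOSIM R by the rank formula, and its exact distribution by enumerating
# every distinct assignment of group labels to samples
oracle_anosim_r <- function(d, grp) {
  v <- d[lower.tri(d)]
  rk <- rank(v)                       # midranks for ties
  same <- outer(grp, grp, "==")[lower.tri(d)]
  m <- length(v)                                      # n (n - 1) / 2 distances
  # Clarke's divisor M / 2 keeps R in [-1, 1] (R = 1 at perfect separation)
  (mean(rk[!same]) - mean(rk[same])) / (m / 2)
}

oracle_anosim_enumeration <- function(d, grp) {
  n <- length(grp)
  g1 <- which(grp == unique(grp)[1])
  k <- length(g1)
  sets <- combn(n, k)
  rs <- apply(sets, 2, function(s) {
    g <- rep(unique(grp)[2], n)
    g[s] <- unique(grp)[1]
    oracle_anosim_r(d, g)
  })
  list(r_obs = oracle_anosim_r(d, grp), all_r = rs)
}

# small fixture: three-tip tree with hand-checkable cophenetic distances
three_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# random valid OTU table for property tests
random_table <- function(n = 5, t = 8, seed = 1, max_count = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * t, 3), n, t)
  m[m > max_count] <- max_count
  for (i in seq_len(n)) if (sum(m[i, ]) == 0) m[i, 1] <- 1
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(t)))
  m
}
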
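#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa, computed on
#' counts via [vegan::vegdist()]. On a table rarefied to equal depth this is
#' identical to the relative-abundance form.
#'
#' @param x OTU table matrix (samples x taxa) of counts, or relative
#'   abundances if all samples are on the same scale.
#' @return symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis <- function(x) {
  if (!is.matrix(x)) stop("x must be a matrix (samples x taxa)")
  if (any(rowSums(x) <= 0)) {
    stop("sample(s) with zero total: ",
         paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  }
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones. All off-diagonal distances are ranked with
#' midrank ties and `R = (mean between-group rank - mean within-group rank)
#' / (M / 4)` with `M = n (n - 1) / 2`; the p-value counts permuted `R`
#' values at least as large as the observed one with the add-one convention
#' `p = (1 + #permuted >= observed) / (1 + n_permutations)`, so p is never
#' zero. Delegates to [vegan::anosim()] after validation.
#'
#' @param d square dissimilarity matrix (e.g., from [bray_curtis()]).
#' @param metadata metadata data.frame covering all ids of `d`.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for reproducible permutations.
#' @return list with `r_statistic`, `p_value`, `n_permutations`, `seed`.
#' @export
anosim_test <- function(d, metadata, n_permutations = 999, seed = NULL) {
  .validate_distance_matrix(d)
  metadata <- sample_metadata(metadata)
  grp <- .groups_of(metadata, rownames(d))
  sizes <- table(grp)
  if (length(sizes) < 2)
    stop("ANOSIM needs at least two groups")
  if (any(sizes < 2))
    stop("every group needs at least 2 samples; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), grouping = factor(grp),
                       permutations = n_permutations)
  list(r_statistic = unname(fit$statistic),
       p_value = fit$signif,
       n_permutations = n_permutations,
       seed = seed)
}
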
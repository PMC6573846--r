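#' Rarefy an OTU table to a common depth
#'
#' Each sample's counts are replaced by a uniform random subsample of its
#' reads, drawn without replacement, totalling exactly `depth` (via
#' [vegan::rrarefy()]). All-zero taxon columns are retained by default so the
#' matrix stays alignable with the phylogeny and with other samples across
#' pipeline stages.
#'
#' @param x OTU table matrix (samples x taxa).
#' @param depth positive integer target depth; every sample total must be
#'   at least `depth`.
#' @param seed integer seed making the subsample reproducible.
#' @param drop_empty drop taxa with all-zero columns after rarefaction?
#' @return rarefied OTU table with every row summing to `depth`.
#' @export
rarefy_table <- function(x, depth, seed = NULL, drop_empty = FALSE) {
  x <- otu_table(x)
  if (length(depth) != 1 || depth < 1 || depth != round(depth))
    stop("depth must be a single positive integer")
  shallow <- rownames(x)[rowSums(x) < depth]
  if (length(shallow))
    stop("sample(s) shallower than depth ", depth, ": ",
         paste(shallow, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  # counts are already validated as integers; rrarefy's small-count
  # heuristic warning is noise here
  out <- suppressWarnings(vegan::rrarefy(x, depth))
  if (drop_empty) out <- out[, colSums(out) > 0, drop = FALSE]
  out
}

#' Chao1 richness estimator
#'
#' Estimates total richness from the observed richness and the singleton and
#' doubleton counts: `chao1 = Sobs + F1^2 / (2 F2)`. When no doubletons are
#' present the bias-corrected form `Sobs + F1 (F1 - 1) / (2 (F2 + 1))` is
#' used to avoid division by zero.
#'
#' @param counts non-negative integer vector of per-taxon counts for one
#'   sample; at least one positive entry.
#' @return named list with `s_obs`, `f1`, `f2`, and `chao1`.
#' @export
chao1 <- function(counts) {
  if (!length(counts) || !is.numeric(counts))
    stop("counts must be a non-empty numeric vector")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  counts <- round(counts)
  if (all(counts == 0)) stop("all-zero count vector: Chao1 undefined")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  est <- if (f2 > 0) s_obs + f1^2 / (2 * f2)
         else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  list(s_obs = s_obs, f1 = f1, f2 = f2, chao1 = est)
}

#' Alpha-diversity indices per sample
#'
#' Computes, for every sample: observed richness, Chao1 (with its singleton
#' and doubleton counts), Shannon entropy `H = -sum p_i log p_i` (natural
#' log), Simpson diversity, and Pielou evenness `H / log(S_obs)`. Simpson is
#' reported as Gini-Simpson `1 - sum p_i^2` by default; `simpson =
#' "inverse"` switches to inverse Simpson `1 / sum p_i^2`. Pielou is `NA`
#' when a sample holds a single taxon (its evenness is undefined, not zero).
#'
#' @param x OTU table matrix of integer counts (samples x taxa), typically
#'   rarefied to a common depth.
#' @param metadata optional metadata data.frame; adds a `group` column.
#' @param simpson `"gini"` (default, `1 - sum p^2`) or `"inverse"`.
#' @return data.frame with one row per sample and columns `sample_id`,
#'   (`group`,) `s_obs`, `f1`, `f2`, `chao1`, `shannon`, `simpson`, `pielou`.
#' @export
alpha_diversity <- function(x, metadata = NULL, simpson = c("gini", "inverse")) {
  simpson <- match.arg(simpson)
  x <- otu_table(x)
  ch <- apply(x, 1, chao1)
  h <- vegan::diversity(x, index = "shannon")
  simp <- vegan::diversity(
    x, index = if (simpson == "gini") "simpson" else "invsimpson")
  s_obs <- vapply(ch, `[[`, numeric(1), "s_obs")
  out <- data.frame(
    sample_id = rownames(x),
    s_obs = s_obs,
    f1 = vapply(ch, `[[`, numeric(1), "f1"),
    f2 = vapply(ch, `[[`, numeric(1), "f2"),
    chao1 = vapply(ch, `[[`, numeric(1), "chao1"),
    shannon = unname(h),
    simpson = unname(simp),
    pielou = ifelse(s_obs > 1, unname(h) / log(s_obs), NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(metadata)) {
    metadata <- sample_metadata(metadata)
    out <- cbind(out[, "sample_id", drop = FALSE],
                 group = .groups_of(metadata, out$sample_id),
                 out[, -1, drop = FALSE])
  }
  out
}

#' Two-sample t-tests on alpha-diversity indices between groups
#'
#' Convenience comparison of each diversity index between two groups with
#' Bonferroni-adjusted p-values.
#'
#' @param alpha data.frame from [alpha_diversity()] including a `group`
#'   column with exactly two levels.
#' @param indices columns to test.
#' @return data.frame with columns `index`, `t`, `p_value`, `p_adjusted`.
#' @export
compare_alpha_diversity <- function(alpha,
                                    indices = c("s_obs", "chao1", "shannon",
                                                "simpson", "pielou")) {
  if (!"group" %in% colnames(alpha)) stop("alpha table must have a 'group' column")
  if (length(unique(alpha$group)) != 2)
    stop("exactly two groups are required for the t-test comparison")
  res <- lapply(indices, function(ix) {
    tt <- stats::t.test(alpha[[ix]] ~ alpha$group)
    data.frame(index = ix, t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "bonferroni")
  res
}
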
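#' Assembly process labels
#'
#' The five ecological processes of the null-model framework plus
#' `unclassifiable` (pairs whose beta-NTI null was degenerate).
#'
#' @return character vector of process labels in canonical order.
#' @export
process_levels <- function() {
  c("homogeneous_selection", "heterogeneous_selection",
    "dispersal_limitation", "homogenizing_dispersal",
    "undominated", "unclassifiable")
}

#' Classify sample pairs into assembly processes
#'
#' Pure threshold rule on (beta-NTI, RC): `beta_nti < -t` gives homogeneous
#' selection, `beta_nti > +t` heterogeneous selection; otherwise `rc > +r`
#' gives dispersal limitation, `rc < -r` homogenizing dispersal, and the
#' remainder is undominated (drift, diversification, weak selection and/or
#' weak dispersal). Defaults `t = 2`, `r = 0.95`. Boundary values fall to
#' the stochastic/undominated side (the inequalities are strict). An `NA`
#' beta-NTI yields `unclassifiable`.
#'
#' @param beta_nti numeric vector (NA allowed).
#' @param rc numeric vector in `[-1, 1]`, same length.
#' @param config a [null_model_config()] supplying the thresholds.
#' @return character vector of process labels (see [process_levels()]).
#' @export
classify_pair <- function(beta_nti, rc, config = null_model_config()) {
  if (length(beta_nti) != length(rc))
    stop("beta_nti and rc must have the same length")
  if (any(!is.na(rc) & (rc < -1 - 1e-9 | rc > 1 + 1e-9)))
    stop("rc values must lie in [-1, 1]")
  t <- config$bnti_threshold
  r <- config$rc_threshold
  out <- rep(NA_character_, length(beta_nti))
  out[!is.na(beta_nti) & beta_nti < -t] <- "homogeneous_selection"
  out[!is.na(beta_nti) & beta_nti > t] <- "heterogeneous_selection"
  rest <- is.na(out) & !is.na(beta_nti) & !is.na(rc)
  out[rest & rc > r] <- "dispersal_limitation"
  out[rest & rc < -r] <- "homogenizing_dispersal"
  out[rest & abs(rc) <= r] <- "undominated"
  out[is.na(out)] <- "unclassifiable"
  out
}

#' Merge turnover records and classify every pair
#'
#' Joins the beta-NTI records of [beta_nti()] with the RCbray records of
#' [rc_bray()] on the sample pair, attaches the pair scope (the group name
#' for within-group pairs, `"between"` otherwise), and classifies each pair.
#'
#' @param bnti data.frame from [beta_nti()].
#' @param rc data.frame from [rc_bray()].
#' @param metadata metadata data.frame covering all samples.
#' @param config a [null_model_config()].
#' @return data.frame with columns `sample_a`, `sample_b`, `pair_class`,
#'   `beta_mntd_obs`, `null_mean`, `null_sd`, `beta_nti`, `bray_curtis`,
#'   `rc`, `process`.
#' @export
classify_processes <- function(bnti, rc, metadata,
                               config = null_model_config()) {
  metadata <- sample_metadata(metadata)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  idx <- match(key(bnti$sample_a, bnti$sample_b),
               key(rc$sample_a, rc$sample_b))
  if (anyNA(idx))
    stop("beta-NTI and RC records cover different sample pairs")
  ga <- .groups_of(metadata, bnti$sample_a)
  gb <- .groups_of(metadata, bnti$sample_b)
  out <- data.frame(
    sample_a = bnti$sample_a,
    sample_b = bnti$sample_b,
    pair_class = ifelse(ga == gb, ga, "between"),
    beta_mntd_obs = bnti$beta_mntd_obs,
    null_mean = bnti$null_mean,
    null_sd = bnti$null_sd,
    beta_nti = bnti$beta_nti,
    bray_curtis = rc$bray_curtis[idx],
    rc = rc$rc[idx],
    stringsAsFactors = FALSE, row.names = NULL)
  out$process <- classify_pair(out$beta_nti, out$rc, config)
  out
}

#' Summarize process fractions per scope
#'
#' Aggregates classified pairs into counts and fractions per process, for
#' the scope `"all"` (every pair), one scope per group (within-group pairs
#' only), and `"between"` (cross-group pairs). Fractions are computed over
#' classified pairs; unclassifiable pairs are counted in their own row with
#' fraction `NA`. A scope with zero classified pairs gets zero counts and
#' `NA` fractions.
#'
#' @param pairs data.frame from [classify_processes()] (needs `sample_a`,
#'   `sample_b`, `process`).
#' @param metadata metadata data.frame covering all samples.
#' @return data.frame with columns `scope`, `process`, `n_pairs`, `fraction`.
#' @export
summarize_processes <- function(pairs, metadata) {
  metadata <- sample_metadata(metadata)
  if (!nrow(pairs)) stop("no pairs to summarize")
  ga <- .groups_of(metadata, pairs$sample_a)
  gb <- .groups_of(metadata, pairs$sample_b)
  scope_of <- ifelse(ga == gb, ga, "between")
  scopes <- c("all", sort(unique(metadata$group)), "between")
  lv <- process_levels()
  res <- lapply(scopes, function(sc) {
    sel <- if (sc == "all") rep(TRUE, nrow(pairs)) else scope_of == sc
    pr <- pairs$process[sel]
    counts <- table(factor(pr, levels = lv))
    n_class <- sum(counts[setdiff(lv, "unclassifiable")])
    frac <- if (n_class > 0)
      ifelse(names(counts) == "unclassifiable", NA_real_,
             as.numeric(counts) / n_class)
    else rep(NA_real_, length(lv))
    data.frame(scope = sc, process = names(counts),
               n_pairs = as.integer(counts), fraction = frac,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Write per-pair and summary results to a directory
#'
#' Writes `pairwise_assembly.tsv` (one row per unordered sample pair) and
#' `process_summary.tsv` (scope x process counts and fractions). Both
#' round-trip through [read.table()] at full double precision.
#'
#' @param pairs data.frame from [classify_processes()].
#' @param summary data.frame from [summarize_processes()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_assembly_results <- function(pairs, summary, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  fp <- file.path(out_dir, "pairwise_assembly.tsv")
  fs <- file.path(out_dir, "process_summary.tsv")
  write.table(pairs, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary, fs, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pairs = fp, summary = fs))
}
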
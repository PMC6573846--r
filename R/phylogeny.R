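#' Read and validate a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()]. Tip labels must be unique; missing branch
#' lengths are set to zero with a warning (some tree builders omit them for
#' zero-length edges); negative branch lengths are an error.
#'
#' @param path path to a file containing a single Newick string.
#' @return an [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for use in turnover metrics
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, with missing branch lengths replaced by 0 (warned).
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length(s) in tree")
  tree
}

#' Prune a phylogeny to a set of taxa
#'
#' Taxa requested but absent from the tree are a hard error: silently
#' dropping them would bias nearest-taxon distances.
#'
#' @param tree an [ape::phylo] object.
#' @param taxa character vector of tip labels to keep.
#' @return the pruned tree.
#' @export
prune_phylogeny <- function(tree, taxa) {
  tree <- validate_phylogeny(tree)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  if (length(taxa) < 2) stop("need at least 2 taxa to prune to")
  ape::keep.tip(tree, taxa)
}

#' Cophenetic (patristic) distances between tree tips
#'
#' d(i, j) is the sum of branch lengths along the path between tips i and j.
#'
#' @param tree an [ape::phylo] object.
#' @return symmetric matrix of tip-to-tip distances with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  tree <- validate_phylogeny(tree)
  d <- stats::cophenetic(tree)
  # cophenetic() returns tips in tree order; callers re-order as needed
  d
}
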
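## Time-calibrated trees and the phylogenetic covariance they induce.
##
## Trees are plain ape "phylo" objects with branch lengths in Myr; a basal
## stem retained by pruning is stored in $root.edge and is part of every
## tip depth and every covariance entry (the stem is shared by all tips).

#' Read a time-calibrated tree from newick text or a file
#'
#' Parses a rooted newick tree with mandatory branch lengths (Myr). Node
#' support values and annotations are ignored. The tree is validated:
#' unique tip labels, finite non-negative branch lengths, and
#' ultrametricity within a relative tolerance of `1e-6` (a larger
#' deviation produces a warning, not an error, since published
#' chronograms are often rounded).
#'
#' @param text Newick string (exactly one tree).
#' @param file Path to a newick file (used when `text` is `NULL`).
#' @param ultra_tol Relative ultrametricity tolerance.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL, ultra_tol = 1e-6) {
  if (is.null(text) && is.null(file))
    .stopf("supply either 'text' or 'file'")
  if (is.null(text)) {
    if (!file.exists(file)) .stopf("tree file not found: %s", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    .stopf("failed to parse newick input")
  validate_chronogram(tree, ultra_tol = ultra_tol)
  tree
}

#' @rdname read_newick
#' @param tree An `ape::phylo` object to serialize.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 17)  # full double precision
  if (!is.null(file)) writeLines(s, file) else s
}

#' Validate a chronogram
#'
#' Checks that a tree is rooted, has unique tip labels and finite
#' non-negative branch lengths, and is ultrametric within `ultra_tol`
#' (relative); non-ultrametric input warns and proceeds.
#'
#' @inheritParams read_newick
#' @return The tree, invisibly.
#' @export
validate_chronogram <- function(tree, ultra_tol = 1e-6) {
  if (!inherits(tree, "phylo")) .stopf("not a 'phylo' object")
  if (is.null(tree$edge.length)) .stopf("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    .stopf("tree has missing or non-finite branch lengths")
  if (any(tree$edge.length < 0)) .stopf("tree has negative branch lengths")
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) .stopf("duplicate tip labels")
  ## newick input is treated as rooted at its basal node; basal
  ## polytomies (star trees) are accepted as-is
  d <- tip_depths(tree)
  rel <- (max(d) - min(d)) / max(d)
  if (rel > ultra_tol)
    .warnf("tree is not ultrametric (relative depth spread %.3g)", rel)
  invisible(tree)
}

#' Tip depths and root age
#'
#' Depth of each tip is its path length to the root, including any
#' `root.edge`; `root_age` is the maximum tip depth.
#'
#' @param tree An `ape::phylo`.
#' @return Named numeric vector of depths (Myr) / a single number.
#' @export
tip_depths <- function(tree) {
  n <- length(tree$tip.label)
  d <- ape::node.depth.edgelength(tree)[seq_len(n)] + (tree$root.edge %||% 0)
  names(d) <- tree$tip.label
  d
}

#' @rdname tip_depths
#' @export
root_age <- function(tree) max(tip_depths(tree))

#' Prune a chronogram to a set of taxa
#'
#' Drops all tips not in `keep`. Internal unifurcations created by the
#' prune are collapsed by summing branch lengths; a basal stem is kept as
#' `root.edge`, so every retained tip keeps its original depth and the
#' covariance of the pruned tree is exactly the corresponding submatrix
#' of the full covariance.
#'
#' @param tree An `ape::phylo`.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned `phylo`.
#' @export
prune_to <- function(tree, keep) {
  keep <- trimws(as.character(keep))
  if (length(keep) < 2L) .stopf("must keep at least 2 taxa")
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    .stopf("unknown taxa: %s", paste(missing, collapse = ", "))
  if (setequal(keep, tree$tip.label)) return(tree)
  pr <- ape::drop.tip(tree, setdiff(tree$tip.label, keep),
                      collapse.singles = FALSE)
  pr <- ape::collapse.singles(pr, root.edge = TRUE)
  pr$root.edge <- (pr$root.edge %||% 0) + (tree$root.edge %||% 0)
  if (pr$root.edge == 0) pr$root.edge <- NULL
  pr
}

#' Phylogenetic covariance matrix under Brownian motion
#'
#' `C[i, j]` is the shared path length (Myr) from the root to the most
#' recent common ancestor of tips i and j; `C[i, i]` is the depth of tip
#' i. Any `root.edge` is added to every entry (the stem is shared by all
#' tips). Row/column order follows `taxa`.
#'
#' @param tree An `ape::phylo`.
#' @param taxa Ordered taxon vector; must be a permutation of the tip
#'   labels. Default: the tree's own tip order.
#' @return A symmetric positive-semidefinite matrix with dimnames.
#' @export
phylo_covariance <- function(tree, taxa = NULL) {
  taxa <- if (is.null(taxa)) tree$tip.label else trimws(as.character(taxa))
  if (!setequal(taxa, tree$tip.label) ||
      length(taxa) != length(tree$tip.label))
    .stopf("'taxa' must be a permutation of the tree's tip labels")
  C <- ape::vcv.phylo(tree)[taxa, taxa, drop = FALSE] +
    (tree$root.edge %||% 0)
  C
}

#' Export a covariance matrix as CSV with taxon header row and column
#' @param C Matrix with taxon dimnames.
#' @param file Output path.
#' @export
write_covariance_csv <- function(C, file) {
  utils::write.csv(as.data.frame(C), file, row.names = TRUE)
  invisible(file)
}
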
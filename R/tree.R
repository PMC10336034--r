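#' Read a phylogenetic tree with branch lengths
#'
#' Reads a Newick tree via \pkg{ape}.  Missing branch lengths default to 0.1
#' with a warning; negative lengths are rejected.  Branch lengths are
#' interpreted throughout the package as expected substitutions per
#' nucleotide site.
#'
#' @param path Path to a Newick file (or a Newick string containing `";"`).
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE)) {
    ape::read.tree(text = path)
  } else {
    if (!file.exists(path)) stop("tree file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse Newick tree")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0.1")
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths; defaulting to 0.1")
    tree$edge.length[is.na(tree$edge.length)] <- 0.1
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Check that a tree and alignment describe the same taxa
#'
#' @param tree An [ape::phylo].
#' @param aln A [codon_alignment()].
#' @return Invisibly `TRUE`; errors listing offending labels otherwise.
#' @export
validate_tree_alignment <- function(tree, aln) {
  missing_in_aln <- setdiff(tree$tip.label, aln$names)
  missing_in_tree <- setdiff(aln$names, tree$tip.label)
  if (length(missing_in_aln) || length(missing_in_tree)) {
    stop("tree/alignment label mismatch.",
         if (length(missing_in_aln)) {
           paste0(" In tree only: ",
                  paste(missing_in_aln, collapse = ", "), ".")
         } else "",
         if (length(missing_in_tree)) {
           paste0(" In alignment only: ",
                  paste(missing_in_tree, collapse = ", "), ".")
         } else "")
  }
  invisible(TRUE)
}

#' Number of free branches of a tree
#'
#' The branch count used in parameter-count formulas: the number of
#' branches of the unrooted tree, `2N - 3` for `N` tips (a rooted binary
#' input is treated as unrooted, merging the two root-adjacent branches).
#'
#' @param tree An [ape::phylo].
#' @export
n_free_branches <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 2) stop("tree must have at least 2 tips")
  if (n == 2) return(1L)
  2L * n - 3L
}

# Internal: preprocess a tree for the likelihood core.  Rooted binary trees
# are unrooted so that branch lengths are identifiable under reversibility.
.prep_tree <- function(tree, aln = NULL) {
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2) {
    tree <- ape::unroot(tree)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  if (!is.null(aln)) validate_tree_alignment(tree, aln)
  n_tips <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1]
  list(tree = tree, edge = tree$edge, t = tree$edge.length,
       root = root, n_tips = n_tips,
       n_nodes = max(tree$edge))
}
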
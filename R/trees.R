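#' Parse a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: accepts a Newick
#' string or a file path, checks for unique leaf labels, and tolerates
#' missing branch lengths and internal-node support labels (support values
#' are carried along but ignored by [patristic_matrix()]).
#'
#' @param text A Newick string (ending in `;`).
#' @param file Alternatively, a path to a Newick file.
#' @return A `phylo` tree.
#' @examples
#' tr <- parse_newick("((A:1,B:2):1,C:3);")
#' tr$tip.label
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of 'text' or 'file'")
  }
  tree <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tree)) stop("Newick parse error: input is not a valid tree")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) {
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch length in Newick input")
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` tree.
#' @param file Optional output path; if `NULL` the Newick string is returned.
#' @param digits Printed precision for branch lengths.
#' @return The Newick string (invisibly when written to `file`).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Patristic distance matrix of a tree
#'
#' The patristic distance between two leaves is the sum of the branch
#' lengths on the unique path connecting them; it is independent of where
#' (or whether) the tree is rooted.
#'
#' @param tree A `phylo` tree; every branch must have a finite length.
#' @return A symmetric matrix (zero diagonal) labeled by the leaf names, in
#'   the tree's tip order.
#' @examples
#' patristic_matrix(parse_newick("((A:1,B:2):1,C:3);"))
#' @export
patristic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) {
    stop("cannot compute patristic distances: tree has no branch lengths")
  }
  bad <- which(!is.finite(tree$edge.length))
  if (length(bad) > 0) {
    stop(sprintf(
      "cannot compute patristic distances: branch to node %d has a %s length",
      tree$edge[bad[1], 2],
      if (is.na(tree$edge.length[bad[1]])) "missing" else "non-finite"))
  }
  D <- ape::cophenetic.phylo(tree)
  # cophenetic returns tips in tree order but permuted dims; fix ordering
  D[tree$tip.label, tree$tip.label]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (Q-criterion). On an additive matrix the
#' reconstructed tree's patristic matrix reproduces the input exactly; on
#' noisy matrices NJ can infer negative branch lengths, which are clamped to
#' zero (the number clamped is reported via attribute `n_clamped` and a
#' warning).
#'
#' @param dm A labeled symmetric matrix over >= 3 taxa with finite entries.
#' @return An unrooted `phylo` tree with attribute `n_clamped`.
#' @examples
#' tr <- parse_newick("((A:1,B:2):1,(C:1,D:1):2);")
#' nj_tr <- neighbor_joining(patristic_matrix(tr))
#' max(abs(patristic_matrix(nj_tr)[rownames(patristic_matrix(tr)),
#'                                 colnames(patristic_matrix(tr))] -
#'         patristic_matrix(tr)))
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (is.null(rownames(dm))) stop("distance matrix must be taxon-labeled")
  tree <- ape::nj(dm)
  n_clamped <- sum(tree$edge.length < 0)
  if (n_clamped > 0) {
    warning(sprintf("clamped %d negative branch length(s) to 0", n_clamped))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Min-max rescaling of a distance matrix
#'
#' Optional normalization for comparing matrices produced by different tree
#' methods: maps off-diagonal entries linearly onto [0, 1]. The mirrortree
#' correlation is invariant under this map, so it is off by default
#' everywhere and provided only for exported tables.
#'
#' @param dm A distance matrix.
#' @return The rescaled matrix.
#' @export
rescale_minmax <- function(dm) {
  off <- dm[upper.tri(dm)]
  rng <- range(off)
  if (diff(rng) == 0) stop("cannot rescale: all off-diagonal entries equal")
  out <- (dm - rng[1]) / diff(rng)
  diag(out) <- 0
  out
}
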
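#' Read a phylogenetic tree from a Newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that validates the properties the
#' comparative machinery relies on: unique tip labels, at least two tips, and
#' (when `require_lengths = TRUE`, the default) a branch length on every edge,
#' none negative.
#'
#' @param text a Newick string (used when `file` is missing).
#' @param file path to a Newick file.
#' @param require_lengths logical; demand branch lengths on every edge.
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(text = NULL, file = NULL, require_lengths = TRUE) {
  if (is.null(text) && is.null(file)) stop("supply `text` or `file`")
  tr <- if (!is.null(file)) {
    tryCatch(ape::read.tree(file), error = function(e) NULL)
  } else {
    tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick input (unbalanced parentheses or bad syntax)")
  }
  validate_tree(tr, require_lengths = require_lengths)
  tr
}

#' Serialize a tree to a Newick string
#'
#' @param tree a `"phylo"` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string (round-trip stable with [read_newick()]).
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

validate_tree <- function(tree, require_lengths = TRUE) {
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (require_lengths) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
    if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  }
  invisible(tree)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the summed branch length of the root-to-tip path shared by
#' tips i and j; the diagonal holds root-to-tip distances. This is the
#' covariance of a unit-rate Brownian motion evolving along the tree, the
#' matrix entering all PGLS and mixed-model fits in the package.
#'
#' @param tree a rooted `"phylo"` tree with nonnegative branch lengths.
#' @return a symmetric matrix with tip labels as dimnames.
#' @examples
#' V <- phylo_covariance(read_newick("((A:1,B:1):1,C:2);"))
#' V["A", "B"] # shared path of length 1
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' untouched (the trait-signal convention, also for non-ultrametric trees).
#' `lambda = 1` returns the Brownian covariance unchanged; `lambda = 0` removes
#' all phylogenetic dependence.
#'
#' @param V a phylogenetic covariance matrix.
#' @param lambda a value in `[0, 1]`.
#' @return the transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single value in [0, 1]")
  }
  d <- diag(V)
  W <- V * lambda
  diag(W) <- d
  W
}

#' Reconcile a tree with a set of species labels
#'
#' Prunes the tree to the intersection of its tips with `species` and reports
#' what was dropped on either side. Matching is exact and case-sensitive after
#' trimming surrounding whitespace; `normalize = TRUE` additionally treats
#' underscores and spaces as equivalent (both sides mapped to underscores).
#'
#' @param tree a `"phylo"` tree.
#' @param species character vector of species labels present in the data.
#' @param normalize logical; map spaces to underscores before matching.
#' @return a list with elements `tree` (pruned), `dropped_tips` (tips absent
#'   from the data) and `missing_species` (data species absent from the tree).
#' @export
match_tips <- function(tree, species, normalize = FALSE) {
  validate_tree(tree, require_lengths = FALSE)
  species <- trimws(species)
  tips <- trimws(tree$tip.label)
  key <- function(x) if (normalize) gsub(" ", "_", x, fixed = TRUE) else x
  keep <- tips[key(tips) %in% key(species)]
  missing_species <- species[!key(species) %in% key(tips)]
  dropped_tips <- setdiff(tips, keep)
  if (length(keep) < 3) {
    stop("fewer than 3 species shared between tree and data; comparative fits undefined")
  }
  pruned <- if (length(dropped_tips)) ape::keep.tip(tree, keep) else tree
  list(tree = pruned, dropped_tips = dropped_tips, missing_species = missing_species)
}
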
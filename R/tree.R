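# Time-calibrated tree data model.
#
# A `time_tree` stores a rooted binary phylogeny with node ages measured
# backward from the present (leaf age 0 for observed trees, root age = crown
# age t0). Node ids follow the ape convention: tips 1..n, internal nodes
# (n+1)..(2n-1) with the root at n+1.

#' Construct a time_tree from parent pointers and ages
#'
#' @param parent integer vector, `parent[i]` is the parent id of node `i`
#'   (`NA` for the root).
#' @param age numeric vector of node ages (time before present, >= 0).
#' @param tip_label character labels for nodes that are tips (others `NA`).
#' @param tip_flag character vector: for each tip one of
#'   `"extant-sampled"`, `"extant-unsampled"`, `"extinct"`; `NA` for
#'   internal nodes. Defaults to `"extant-sampled"` for every tip.
#' @return An object of class `time_tree`.
#' @export
new_time_tree <- function(parent, age, tip_label = NULL, tip_flag = NULL) {
  m <- length(parent)
  stopifnot(length(age) == m)
  is_tip <- !seq_len(m) %in% parent[!is.na(parent)]
  n_tips <- sum(is_tip)
  if (is.null(tip_label)) {
    tip_label <- rep(NA_character_, m)
    tip_label[is_tip] <- paste0("t", seq_len(n_tips))
  }
  if (is.null(tip_flag)) {
    tip_flag <- rep(NA_character_, m)
    tip_flag[is_tip] <- "extant-sampled"
  }
  children <- matrix(NA_integer_, m, 2)
  for (i in seq_len(m)) {
    p <- parent[i]
    if (!is.na(p)) {
      if (is.na(children[p, 1])) children[p, 1] <- i
      else if (is.na(children[p, 2])) children[p, 2] <- i
      else stop_domain("node %d has more than two children: non-binary trees are unsupported", p)
    }
  }
  tr <- structure(
    list(parent = as.integer(parent), children = children, age = as.numeric(age),
         is_tip = is_tip, n_tips = n_tips, root = which(is.na(parent))[1],
         tip_label = tip_label, tip_flag = tip_flag),
    class = "time_tree")
  validate_time_tree(tr)
  tr
}

#' Validate time_tree invariants
#'
#' Checks that the tree has exactly one root, that every internal node has
#' exactly two children, and that ages decrease from parent to child.
#'
#' @param tree a `time_tree`.
#' @return The tree, invisibly; errors on violation.
#' @export
validate_time_tree <- function(tree) {
  m <- length(tree$parent)
  if (sum(is.na(tree$parent)) != 1) stop_domain("tree must have exactly one root")
  if (tree$n_tips < 2) stop_domain("tree must have at least 2 leaves")
  int <- which(!tree$is_tip)
  if (any(is.na(tree$children[int, 2]))) {
    stop_domain("internal node without exactly two children: non-binary trees are unsupported")
  }
  for (i in seq_len(m)) {
    p <- tree$parent[i]
    if (!is.na(p) && tree$age[i] >= tree$age[p] + 1e-12) {
      stop_domain("child age (%g) must be below parent age (%g)", tree$age[i], tree$age[p])
    }
  }
  if (any(tree$age < -1e-9)) stop_domain("negative node age")
  invisible(tree)
}

#' Test whether an observed tree is ultrametric
#'
#' All leaf ages must equal 0 (to a relative tolerance of the root age).
#'
#' @param tree a `time_tree`.
#' @param tol relative tolerance.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  scale <- max(tree$age[tree$root], 1)
  all(abs(tree$age[tree$is_tip]) <= tol * scale)
}

#' @noRd
phylo_to_time_tree <- function(phy) {
  if (!ape::is.binary.phylo(phy)) stop_domain("non-binary node: unsupported topology")
  if (is.null(phy$edge.length)) stop_domain("newick string must carry branch lengths")
  if (any(phy$edge.length < 0)) stop_domain("negative branch length")
  n <- length(phy$tip.label)
  if (n < 2) stop_domain("tree must have at least 2 leaves")
  m <- n + phy$Nnode
  parent <- rep(NA_integer_, m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(n)]) - depth
  label <- rep(NA_character_, m)
  label[seq_len(n)] <- phy$tip.label
  new_time_tree(parent, age, tip_label = label)
}

#' Read a time-calibrated tree from newick
#'
#' Parses a newick string (or a file containing one) with branch lengths,
#' accumulates root-to-tip path lengths, and shifts ages so that the deepest
#' leaves sit at age 0.
#'
#' @param text newick string.
#' @param file path to a newick file (used when `text` is `NULL`).
#' @return A `time_tree`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$age[tr$root]  # crown age 2
read_newick <- function(text = NULL, file = NULL) {
  phy <- tryCatch(
    suppressWarnings(
      if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file)),
    error = function(e) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) stop_domain("malformed newick string")
  phylo_to_time_tree(phy)
}

#' @noRd
time_tree_to_phylo <- function(tree) {
  m <- length(tree$parent)
  n <- tree$n_tips
  has_parent <- which(!is.na(tree$parent))
  edge <- cbind(tree$parent[has_parent], has_parent)
  # ape expects tips 1..n then internals; our ids already follow that layout
  # for trees built via read_newick; remap defensively for simulator output.
  tips <- which(tree$is_tip)
  ints <- which(!tree$is_tip)
  remap <- integer(m)
  remap[tips] <- seq_len(n)
  remap[c(tree$root, setdiff(ints, tree$root))] <- n + seq_along(ints)
  edge <- cbind(remap[edge[, 1]], remap[edge[, 2]])
  o <- order(edge[, 1], edge[, 2])
  edge <- edge[o, , drop = FALSE]
  len <- (tree$age[tree$parent[has_parent]] - tree$age[has_parent])[o]
  lbl <- tree$tip_label[tips][order(remap[tips])]
  phy <- structure(list(edge = edge, edge.length = len, Nnode = length(ints),
                        tip.label = lbl), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a time_tree as a newick string
#'
#' Branch lengths are parent age minus child age.
#'
#' @param tree a `time_tree`.
#' @param digits number of significant digits for branch lengths.
#' @return A newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  validate_time_tree(tree)
  ape::write.tree(time_tree_to_phylo(tree), digits = digits)
}

#' Total branch length of a tree
#' @param tree a `time_tree`.
#' @return Sum of all branch lengths.
#' @export
tree_length <- function(tree) {
  has_parent <- which(!is.na(tree$parent))
  sum(tree$age[tree$parent[has_parent]] - tree$age[has_parent])
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time_tree: %d tips, crown age %.6g\n", x$n_tips, x$age[x$root]))
  invisible(x)
}
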
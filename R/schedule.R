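# Aligned checkpoint schedule.
#
# All particles of an SMC run are propagated branch by branch in the same
# fixed order, so that at every resampling point every particle has processed
# exactly the same portion of the observed tree. The schedule lists one
# checkpoint per observed node: the root (initialization of the two crown
# lineages), every other internal node (walk its stem branch, then the
# speciation factor), and every leaf (walk its stem branch, then the
# sampling factor). An n-leaf binary tree therefore has 2n-1 checkpoints.

#' Build the aligned checkpoint schedule for an observed tree
#'
#' Checkpoints are ordered by a deterministic depth-first preorder traversal
#' from the root with children visited in stored order. The schedule is
#' identical for all particles and all models on the same tree.
#'
#' @param tree an ultrametric `time_tree`.
#' @return A data.frame of class `branch_schedule` with columns
#'   `node`, `age`, `parent_age`, and `type` (`"root"`, `"internal"`, or
#'   `"leaf"`).
#' @export
#' @examples
#' sch <- make_schedule(read_newick("((A:1,B:1):1,C:2);"))
#' nrow(sch)  # 5 checkpoints: 2 internal (incl. root) + 3 leaves
make_schedule <- function(tree) {
  validate_time_tree(tree)
  if (!is_ultrametric_tree(tree)) {
    stop_domain("schedule requires an ultrametric observed tree")
  }
  m <- length(tree$parent)
  node <- integer(m); age <- numeric(m); parent_age <- numeric(m)
  type <- character(m)
  k <- 0L
  stack <- tree$root
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    k <- k + 1L
    node[k] <- v
    age[k] <- tree$age[v]
    p <- tree$parent[v]
    parent_age[k] <- if (is.na(p)) NA_real_ else tree$age[p]
    type[k] <- if (is.na(p)) "root" else if (tree$is_tip[v]) "leaf" else "internal"
    if (!tree$is_tip[v]) stack <- c(tree$children[v, ], stack)
  }
  out <- data.frame(node = node, age = age, parent_age = parent_age,
                    type = type, stringsAsFactors = FALSE)
  class(out) <- c("branch_schedule", "data.frame")
  out
}
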
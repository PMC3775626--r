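#' Per-edge distal read masses
#'
#' For one sample, computes for every edge of the tree the distal count
#' `d_i` (reads at leaves on the far side of the edge from the root) and the
#' distal fraction `D = d_i / n`, where `n` is the sample's total read count.
#' These are the quantities every phylogenetic measure in this package is a
#' branch-length-weighted sum over. A single child-before-parent pass
#' accumulates leaf counts up the tree.
#'
#' @param tree a [ptree].
#' @param counts named non-negative integer vector; names must be a subset of
#'   the tree's leaf labels (absent leaves count 0).
#' @return a data frame with one row per edge (indexed by child node):
#'   `node`, `parent`, `brlen`, `d`, `D`; the sample total `n` is attached as
#'   attribute `"n"`.
#' @export
compute_edge_masses <- function(tree, counts) {
  counts <- check_sample_counts(tree, counts)
  n <- sum(counts)
  if (n < 1L) stop_user("empty sample")
  d <- numeric(length(tree$parent))
  d[tree$leaves] <- counts[tree$label[tree$leaves]]
  po <- postorder_nodes(tree)
  parent <- tree$parent
  for (nd in po) {
    p <- parent[nd]
    if (p != 0L) d[p] <- d[p] + d[nd]
  }
  edge <- which(parent != 0L)
  out <- data.frame(node = edge, parent = parent[edge], brlen = tree$brlen[edge],
                    d = d[edge], D = d[edge] / n)
  attr(out, "n") <- n
  out
}

check_sample_counts <- function(tree, counts) {
  if (is.null(names(counts)) || !is_count_vector(counts))
    stop_user("counts must be a named vector of non-negative integers")
  unknown <- setdiff(names(counts)[counts > 0], leaf_labels(tree))
  if (length(unknown))
    stop_user("counts for labels not in tree: ",
              paste(utils::head(unknown, 10L), collapse = ", "))
  full <- stats::setNames(numeric(length(tree$leaves)), leaf_labels(tree))
  keep <- intersect(names(counts), names(full))
  full[keep] <- counts[keep]
  full
}
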
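#' Rooted phylogenetic trees as parent vectors
#'
#' A `ptree` stores a rooted, edge-weighted tree in parent-vector form: node
#' `i` owns the edge to its parent (`parent[i]`, 0 at the root) with length
#' `brlen[i]` (`NA` at the root). Leaves are the count-bearing labelled nodes;
#' the leaf set is fixed at construction and preserved by [reroot()], so a
#' tree rerooted at a leaf keeps that leaf in the leaf set even though it is
#' then the root. This representation admits two shapes an `ape` `"phylo"`
#' cannot hold — a single-leaf tree and a tree whose root is a leaf — both of
#' which arise as legitimate degenerate inputs here.
#'
#' @param parent integer vector, `parent[i]` is the parent node of `i` (0 for
#'   the root).
#' @param brlen numeric vector of branch lengths for the edge above each node
#'   (`NA` at the root); must be non-negative and finite elsewhere.
#' @param label character vector of node labels; every leaf must carry a
#'   unique non-empty label, internal labels are optional and unused.
#' @param leaves integer indices of the leaf nodes.
#' @return an object of class `ptree`.
#' @export
ptree <- function(parent, brlen, label, leaves) {
  n <- length(parent)
  stopifnot(length(brlen) == n, length(label) == n)
  parent <- as.integer(parent)
  root <- which(parent == 0L)
  if (length(root) != 1L)
    stop_user("tree must have exactly one root (found ", length(root), ")")
  if (any(parent < 0L | parent > n))
    stop_user("parent index out of range")
  bad <- which(parent != 0L & (!is.finite(brlen) | brlen < 0))
  if (length(bad))
    stop_user("negative or non-finite branch length at node(s) ",
              paste(utils::head(bad, 10L), collapse = ", "))
  leaves <- sort(as.integer(leaves))
  lab <- label[leaves]
  if (anyNA(lab) || any(!nzchar(trimws(lab))))
    stop_user("every leaf must have a non-empty label")
  if (anyDuplicated(lab))
    stop_user("duplicate leaf label(s): ",
              paste(unique(lab[duplicated(lab)]), collapse = ", "))
  obj <- structure(
    list(parent = parent, brlen = as.numeric(brlen), label = as.character(label),
         leaves = leaves, root = root),
    class = "ptree"
  )
  # connectivity / acyclicity: every node must reach the root in <= n hops
  for (i in seq_len(n)) {
    p <- i
    steps <- 0L
    while (p != root) {
      p <- parent[p]
      steps <- steps + 1L
      if (p == 0L || steps > n) stop_user("tree is disconnected or cyclic at node ", i)
    }
  }
  obj
}

#' @export
print.ptree <- function(x, ...) {
  cat(sprintf("ptree: %d nodes, %d leaves, %d edges, total length %.6g\n",
              length(x$parent), length(x$leaves), n_edges(x), total_branch_length(x)))
  cat("leaves:", paste(utils::head(leaf_labels(x), 8L), collapse = ", "),
      if (length(x$leaves) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @rdname ptree
#' @param tree a `ptree`.
#' @export
leaf_labels <- function(tree) tree$label[tree$leaves]

#' @rdname ptree
#' @export
n_edges <- function(tree) length(tree$parent) - 1L

#' @rdname ptree
#' @export
total_branch_length <- function(tree) sum(tree$brlen[-tree$root])

# children adjacency and a child-before-parent ordering (reverse preorder)
postorder_nodes <- function(tree) {
  n <- length(tree$parent)
  kids <- children_list(tree)
  pre <- integer(n)
  stack <- integer(n)
  stack[1L] <- tree$root
  sp <- 1L
  k <- 0L
  while (sp > 0L) {
    nd <- stack[sp]; sp <- sp - 1L
    k <- k + 1L
    pre[k] <- nd
    for (ch in kids[[nd]]) { sp <- sp + 1L; stack[sp] <- ch }
  }
  rev(pre)
}

children_list <- function(tree) {
  n <- length(tree$parent)
  kids <- vector("list", n)
  ord <- which(tree$parent != 0L)
  for (i in ord) kids[[tree$parent[i]]] <- c(kids[[tree$parent[i]]], i)
  kids
}

#' Read a Newick tree
#'
#' Parses a single Newick string (or the first line of a file) into a
#' [ptree]. Parsing of multi-leaf trees is delegated to [ape::read.tree];
#' the degenerate single-leaf form `"A:1.0;"` is accepted directly with a
#' warning. Quoted labels are unquoted. Missing branch lengths become 0 with
#' a warning; negative lengths, unbalanced parentheses and duplicate leaf
#' labels are errors.
#'
#' @param text a Newick string terminated by `;`.
#' @return a [ptree] rooted at the outermost Newick node.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";"))
    stop_user("Newick parse error: input must be terminated by ';'")
  no_quote <- gsub("'[^']*'", "", text)
  if (lengths(regmatches(no_quote, gregexpr("(", no_quote, fixed = TRUE))) !=
      lengths(regmatches(no_quote, gregexpr(")", no_quote, fixed = TRUE))))
    stop_user("Newick parse error: unbalanced parentheses in ", text)
  # degenerate single-leaf tree: no parentheses, no comma
  if (!grepl("[(),]", no_quote)) {
    body <- sub(";$", "", text)
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    lab <- unquote_label(parts[1])
    len <- if (length(parts) > 1L) suppressWarnings(as.numeric(parts[2])) else NA_real_
    if (!nzchar(lab) || (length(parts) > 1L && is.na(len)))
      stop_user("Newick parse error: cannot parse single-leaf tree ", text)
    warning("single-leaf tree: 1 node, 0 edges")
    return(ptree(parent = 0L, brlen = NA_real_, label = lab, leaves = 1L))
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop_user("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(phy)) stop_user("Newick parse error: ", text)
  as_ptree(phy)
}

unquote_label <- function(x) {
  x <- trimws(x)
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L))
  x
}

#' Convert an `ape` phylo object to a `ptree`
#'
#' @param phy an object of class `"phylo"`.
#' @return a [ptree]; tips keep their (unquoted) labels, missing or `NaN`
#'   branch lengths become 0 with a warning, negative lengths are an error.
#' @export
as_ptree <- function(phy) {
  if (inherits(phy, "ptree")) return(phy)
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  parent <- integer(n)
  brlen <- rep(NA_real_, n)
  el <- phy$edge.length
  if (is.null(el)) {
    warning("tree has no branch lengths; all set to 0")
    el <- rep(0, nrow(phy$edge))
  }
  if (anyNA(el)) {
    warning("missing branch length(s) set to 0")
    el[is.na(el)] <- 0
  }
  if (any(el < 0))
    stop_user("negative branch length in tree")
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  brlen[phy$edge[, 2L]] <- el
  label <- c(unquote_label(phy$tip.label),
             if (is.null(phy$node.label)) rep("", nnode) else as.character(phy$node.label))
  lab <- label[seq_len(ntip)]
  if (anyDuplicated(lab))
    stop_user("duplicate leaf label(s): ",
              paste(unique(lab[duplicated(lab)]), collapse = ", "))
  ptree(parent, brlen, label, seq_len(ntip))
}

#' Write a `ptree` as a Newick string
#'
#' @param tree a [ptree].
#' @param digits significant digits for branch lengths.
#' @return a Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 10) {
  kids <- children_list(tree)
  fmt_label <- function(i) {
    lab <- tree$label[i]
    if (!nzchar(lab)) return("")
    if (grepl("[ (),:;'\\[\\]]", lab))
      paste0("'", gsub("'", "''", lab), "'") else lab
  }
  build <- function(i) {
    ch <- kids[[i]]
    core <- if (length(ch)) {
      paste0("(", paste(vapply(ch, build, ""), collapse = ","), ")", fmt_label(i))
    } else fmt_label(i)
    if (i == tree$root) core
    else paste0(core, ":", format(tree$brlen[i], digits = digits, trim = TRUE))
  }
  paste0(build(tree$root), ";")
}

#' Reroot a tree at an existing node
#'
#' Reverses edge orientation along the path from the new root to the old one;
#' the undirected edge set, branch lengths and leaf set are unchanged. Root
#' invariance of the unrooted measures ([pd_unrooted()], [bwpd()], [pqe()])
#' follows because their edge weights are symmetric under the
#' distal/proximal flip; the rooted measures ([rbwpd()], [phylo_entropy()],
#' [hill_qdt()]) do depend on the choice made here.
#'
#' @param tree a [ptree].
#' @param node new root, as a node index or a node label.
#' @return a [ptree] rooted at `node`.
#' @export
reroot <- function(tree, node) {
  node <- resolve_node(tree, node)
  if (node == tree$root) return(tree)
  old_parent <- tree$parent
  old_brlen <- tree$brlen
  prev <- 0L
  p <- node
  while (p != 0L) {
    nxt <- old_parent[p]
    tree$parent[p] <- prev
    tree$brlen[p] <- if (prev == 0L) NA_real_ else old_brlen[prev]
    prev <- p
    p <- nxt
  }
  tree$root <- node
  tree
}

resolve_node <- function(tree, node) {
  if (is.character(node)) {
    idx <- which(tree$label == node)
    if (length(idx) != 1L) stop_user("unknown or ambiguous node label: ", node)
    return(idx)
  }
  node <- as.integer(node)
  if (is.na(node) || node < 1L || node > length(tree$parent))
    stop_user("unknown node id: ", node)
  node
}

#' Scale all branch lengths by a constant
#' @param tree a [ptree].
#' @param c positive scale factor.
#' @return the rescaled tree.
#' @export
scale_branch_lengths <- function(tree, c) {
  stopifnot(is.numeric(c), c > 0)
  tree$brlen <- tree$brlen * c
  tree
}
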
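# Independent brute-force oracles. These share no traversal code with the
# package: per-edge distal masses are recovered by walking each leaf's path to
# the root and every measure is then a direct transcription of its formula.

oracle_edge_masses <- function(tree, counts) {
  full <- setNames(numeric(length(tree$leaves)),
                   tree$label[tree$leaves])
  full[names(counts)] <- counts
  n <- sum(full)
  edges <- setdiff(seq_along(tree$parent), tree$root)
  d <- setNames(numeric(length(edges)), edges)
  for (leaf in tree$leaves) {
    p <- leaf
    while (p != tree$root) {
      d[as.character(p)] <- d[as.character(p)] + full[[tree$label[leaf]]]
      p <- tree$parent[p]
    }
  }
  list(node = edges, l = tree$brlen[edges], d = unname(d), n = n)
}

oracle_pd <- function(tree, counts) {
  em <- oracle_edge_masses(tree, counts)
  sum(em$l[em$d > 0 & em$d < em$n])
}

oracle_bwpd <- function(tree, counts, theta) {
  em <- oracle_edge_masses(tree, counts)
  x <- em$d / em$n
  w <- if (theta == 0) as.numeric(x > 0 & x < 1) else (2 * pmin(x, 1 - x))^theta
  sum(em$l * w)
}

oracle_rbwpd <- function(tree, counts, theta) {
  em <- oracle_edge_masses(tree, counts)
  x <- em$d / em$n
  sum(em$l[x > 0] * x[x > 0]^theta)
}

oracle_pqe <- function(tree, counts) {
  em <- oracle_edge_masses(tree, counts)
  sum(em$l * em$d * (em$n - em$d)) / em$n^2
}

oracle_phylo_entropy <- function(tree, counts) {
  em <- oracle_edge_masses(tree, counts)
  p <- em$d / em$n
  -sum(em$l[p > 0] * p[p > 0] * log(p[p > 0]))
}

oracle_hill_qdt <- function(tree, counts, q) {
  em <- oracle_edge_masses(tree, counts)
  a <- em$d / em$n
  keep <- a > 0
  l <- em$l[keep]; a <- a[keep]
  tbar <- sum(l * a)
  if (abs(q - 1) < 1e-10) exp(-sum(l / tbar * a * log(a)))
  else sum(l / tbar * a^q)^(1 / (1 - q))
}

# exhaustive mean of PQE over all k-subsets of the sample's reads
oracle_enum_pqe_rarefied <- function(tree, counts, k) {
  reads <- rep(names(counts), counts)
  subsets <- utils::combn(length(reads), k)
  vals <- apply(subsets, 2L, function(ix) {
    sub <- table(reads[ix])
    oracle_pqe(tree, setNames(as.integer(sub), names(sub)))
  })
  mean(vals)
}

# naive O(M^3) complete-linkage agglomeration returning merge order as label sets
oracle_complete_linkage_merges <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- max(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

rdirichlet_test <- function(alpha) {
  g <- rgamma(length(alpha), alpha)
  g / sum(g)
}

derive_seed_test <- function(a, b) (a * 131071 + b * 524287) %% 2147483647

# random fixtures -------------------------------------------------------------

random_counts <- function(tree, max_count = 10L, min_total = 1L) {
  repeat {
    cnt <- setNames(sample(0:max_count, length(tree$leaves), replace = TRUE),
                    leaf_labels(tree))
    if (sum(cnt) >= min_total) return(cnt)
  }
}

random_fixture <- function(n_leaves = NULL, max_count = 10L, min_total = 1L) {
  if (is.null(n_leaves)) n_leaves <- sample(2:12, 1L)
  tree <- random_tree(n_leaves, seed = sample.int(1e6, 1L))
  list(tree = tree, counts = random_counts(tree, max_count, min_total))
}

hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) hc$labels[-x] else sets[[x]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  sets
}
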
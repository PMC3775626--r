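test_that("read_newick parses trees and rejects malformed input", {
  tr <- read_newick("((A:1.0,B:1.0):1.0,C:1.0);")
  expect_s3_class(tr, "ptree")
  expect_setequal(leaf_labels(tr), c("A", "B", "C"))
  expect_equal(n_edges(tr), 4L)
  expect_equal(total_branch_length(tr), 4.0)

  expect_warning(one <- read_newick("A:1.0;"), "single-leaf")
  expect_equal(length(one$parent), 1L)
  expect_equal(n_edges(one), 0L)
  expect_equal(leaf_labels(one), "A")

  expect_error(read_newick("((A:1,B:1:);"), "parse error")
  expect_error(read_newick("((A:1,B:1):1,C:1)"), "terminated")
  expect_error(read_newick("((A:1,A:1):1,C:1);"), "duplicate")
  expect_error(read_newick("((A:1,B:-2):1,C:1);"), "negative")
})

test_that("missing branch lengths default to zero with a warning", {
  expect_warning(tr <- read_newick("((A:1,B:1):1,C);"), "missing branch length")
  expect_equal(total_branch_length(tr), 3.0)
  expect_equal(pd_unrooted(tr, c(A = 1L, C = 1L)), 2.0)
})

test_that("quoted labels are unquoted", {
  tr <- read_newick("(('Lact. iners':1,B:1):1,C:1);")
  expect_true("Lact. iners" %in% leaf_labels(tr))
})

test_that("newick round-trip preserves topology, labels and lengths", {
  set.seed(42)
  for (rep in 1:5) {
    tr <- random_tree(sample(3:20, 1L), seed = sample.int(1e6, 1L))
    back <- read_newick(write_newick(tr))
    expect_setequal(leaf_labels(back), leaf_labels(tr))
    # edges identified by their distal leaf sets, paired with branch lengths
    sig <- function(t) {
      em <- oracle_edge_masses(t, setNames(rep(1L, length(t$leaves)), leaf_labels(t)))
      key <- vapply(seq_along(em$node), function(i) {
        cnt <- setNames(rep(0L, length(t$leaves)), leaf_labels(t))
        # leaves below edge i: recompute by path walk per leaf
        below <- vapply(t$leaves, function(leaf) {
          p <- leaf
          while (p != t$root && p != em$node[i]) p <- t$parent[p]
          p == em$node[i]
        }, TRUE)
        paste(sort(leaf_labels(t)[below]), collapse = ",")
      }, "")
      ord <- order(key)
      list(key = key[ord], len = em$l[ord])
    }
    a <- sig(back); b <- sig(tr)
    expect_equal(a$key, b$key)
    expect_equal(a$len, b$len, tolerance = 1e-8)  # printed precision
  }
})

test_that("compute_edge_masses matches the forced toy values", {
  t0 <- toy_tree()
  em <- compute_edge_masses(t0$tree, t0$counts)
  expect_equal(attr(em, "n"), 4L)
  got <- setNames(em$d, t0$tree$label[em$node])
  expect_equal(got[c("A", "B", "C")], c(A = 2, B = 1, C = 1))
  expect_equal(sum(em$d == 3), 1L)  # the AB ancestral edge
  expect_setequal(em$D, c(0.5, 0.25, 0.75, 0.25))

  em2 <- compute_edge_masses(t0$tree, c(C = 5L))
  expect_equal(sort(em2$d), c(0, 0, 0, 5))
  expect_equal(sort(em2$D), c(0, 0, 0, 1))
  expect_error(compute_edge_masses(t0$tree, c(A = 0L)), "empty sample")
  expect_error(compute_edge_masses(t0$tree, c(Z = 3L)), "not in tree")
})

test_that("edge masses satisfy conservation and recursive invariants", {
  set.seed(7)
  tr <- random_tree(50, seed = 99)
  cnt <- random_counts(tr, max_count = 20L)
  em <- compute_edge_masses(tr, cnt)
  n <- attr(em, "n")
  expect_equal(sum(em$d[em$node %in% tr$leaves]), n)
  expect_true(all(em$d >= 0 & em$d <= n))
  # internal edge mass equals the sum over child edges
  for (i in which(!(em$node %in% tr$leaves))) {
    kids <- em$node[em$parent == em$node[i]]
    expect_equal(em$d[i], sum(em$d[em$node %in% kids]))
  }
  # independent recount by explicit per-edge leaf-set enumeration
  orc <- oracle_edge_masses(tr, cnt)
  expect_equal(em$d[match(orc$node, em$node)], orc$d)
})

test_that("reroot preserves the undirected tree and flips masses predictably", {
  t0 <- toy_tree()
  expect_identical(reroot(t0$tree, t0$tree$root), t0$tree)
  expect_error(reroot(t0$tree, 99L), "unknown node")
  expect_error(reroot(t0$tree, "nope"), "unknown")

  set.seed(11)
  tr <- random_tree(20, seed = 5)
  cnt <- random_counts(tr)
  n <- sum(cnt)
  em0 <- compute_edge_masses(tr, cnt)
  d0 <- setNames(em0$d, em0$node)
  for (node in sample(seq_along(tr$parent), 5L)) {
    rt <- reroot(tr, node)
    expect_equal(total_branch_length(rt), total_branch_length(tr))
    expect_equal(sort(leaf_labels(rt)), sort(leaf_labels(tr)))
    em1 <- compute_edge_masses(rt, cnt)
    # same undirected edge set: every edge's distal mass is d or n - d
    for (i in seq_len(nrow(em1))) {
      a <- em1$node[i]; b <- em1$parent[i]
      key <- as.character(if (as.character(a) %in% names(d0) &&
                              tr$parent[a] == b) a else b)
      expect_true(em1$d[i] == d0[[key]] || em1$d[i] == n - d0[[key]])
    }
    # unrooted measures are unchanged (Eq.-level root invariance)
    expect_equal(pd_unrooted(rt, cnt), pd_unrooted(tr, cnt), tolerance = 1e-12)
    expect_equal(bwpd(rt, cnt, 0.5), bwpd(tr, cnt, 0.5), tolerance = 1e-12)
  }
  # rerooting at a leaf keeps everything well-defined
  leafroot <- reroot(tr, tr$leaves[1L])
  expect_equal(bwpd(leafroot, cnt, 1), bwpd(tr, cnt, 1), tolerance = 1e-12)
})

test_that("count tables read from TSV and BIOM-JSON agree", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1\tS2", "A\t2\t0", "B\t1\t4", "C\t1\t1"), tsv)
  tab <- read_count_table(tsv, "tsv")
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(unname(colSums(tab)), c(4L, 5L))
  expect_equal(tab["B", "S2"], 4L)

  biom <- tempfile(fileext = ".biom")
  writeLines(paste0(
    '{"id":"x","format":"Biological Observation Matrix 1.0.0",',
    '"format_url":"http://biom-format.org","type":"OTU table",',
    '"generated_by":"test","date":"2026-01-01T00:00:00",',
    '"matrix_type":"sparse","matrix_element_type":"int","shape":[3,2],',
    '"rows":[{"id":"A","metadata":null},{"id":"B","metadata":null},',
    '{"id":"C","metadata":null}],',
    '"columns":[{"id":"S1","metadata":null},{"id":"S2","metadata":null}],',
    '"data":[[0,0,2],[1,0,1],[1,1,4],[2,0,1],[2,1,1]]}'), biom)
  tab2 <- read_count_table(biom, "biom")
  expect_equal(tab2[rownames(tab), colnames(tab)], tab)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1", "A\t1.5"), bad)
  expect_error(read_count_table(bad, "tsv"), "non-integer|negative")
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1", "A\t1", "A\t2"), dup)
  expect_error(read_count_table(dup, "tsv"), "duplicate")
})

test_that("count table TSV round-trips through write_count_table", {
  t0 <- toy_tree()
  tab <- matrix(c(2L, 1L, 1L), 3, 1, dimnames = list(c("A", "B", "C"), "S1"))
  path <- tempfile(fileext = ".tsv")
  write_count_table(tab, path, comment = "seed=7")
  expect_equal(read_count_table(path, "tsv"), tab)
})

test_that("align_tree_table enforces strict matching and supports intersect", {
  t0 <- toy_tree()
  tab <- matrix(1L, 3, 2, dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  expect_equal(align_tree_table(t0$tree, tab), tab)

  tab4 <- rbind(tab, D = c(5L, 5L))
  expect_error(align_tree_table(t0$tree, tab4, "strict"), "D")
  expect_warning(kept <- align_tree_table(t0$tree, tab4, "intersect"), "dropped")
  expect_equal(kept, tab)

  tab2 <- tab[c("A", "B"), , drop = FALSE]
  filled <- align_tree_table(t0$tree, tab2, "intersect")
  expect_equal(unname(filled["C", ]), c(0L, 0L))
})
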
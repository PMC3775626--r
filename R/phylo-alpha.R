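#' The balance weighting function g_theta
#'
#' `g_theta(x, theta) = (2 min(x, 1 - x))^theta` for `theta > 0`; at
#' `theta = 0` it is the pointwise limit: the step function that is 1 on the
#' open unit interval and 0 at its endpoints. `2 min(x, 1-x)` equals
#' `1 - |x - (1-x)|`, the balance of read mass across an edge, so the family
#' interpolates between ignoring abundance entirely (`theta = 0`) and full
#' balance weighting (`theta = 1`). The convention `0^theta = 0` for all
#' `theta >= 0` makes `theta = 0` reproduce classical PD exactly.
#'
#' @param x numeric in \[0, 1\] (distal read fraction).
#' @param theta non-negative weighting exponent.
#' @return numeric in \[0, 1\], vectorised over `x`.
#' @export
g_theta <- function(x, theta) {
  stopifnot(is.numeric(x), is.numeric(theta), length(theta) == 1L)
  if (!is.finite(theta) || theta < 0) stop_user("theta must be finite and >= 0")
  if (any(!is.finite(x) | x < 0 | x > 1)) stop_user("x must lie in [0, 1]")
  b <- 2 * pmin(x, 1 - x)
  if (theta == 0) as.numeric(b > 0) else b^theta
}

phylo_measure_setup <- function(tree, counts) {
  em <- compute_edge_masses(tree, counts)
  list(l = em$brlen, d = em$d, D = em$D, n = attr(em, "n"))
}

#' Unrooted (Faith) phylogenetic diversity of a sample
#'
#' Total length of the edges separating reads of the sample, i.e. edges with
#' observed reads on both their distal and proximal sides — the branch length
#' of the subtree spanning the observed leaves, excluding any pendant path to
#' the root. Equals [bwpd()] at `theta = 0`; invariant under [reroot()].
#'
#' @inheritParams compute_edge_masses
#' @return non-negative total branch length.
#' @export
pd_unrooted <- function(tree, counts) {
  s <- phylo_measure_setup(tree, counts)
  sum(s$l * (s$D > 0 & s$D < 1))
}

#' Balance-weighted phylogenetic diversity BWPD_theta
#'
#' `sum_i l_i * g_theta(D_i)` over edges, with `D_i` the distal read
#' fraction: a one-parameter family interpolating from classical unrooted PD
#' (`theta = 0`) to fully balance-weighted PD (`theta = 1`). Invariant under
#' [reroot()] because the edge weight is symmetric in `D` and `1 - D`;
#' non-increasing in `theta`; bounded by the PD value.
#'
#' @inheritParams compute_edge_masses
#' @param theta non-negative weighting exponent (field-standard grid:
#'   0, 0.25, 0.5, 1).
#' @return non-negative diversity value.
#' @export
bwpd <- function(tree, counts, theta = 1) {
  s <- phylo_measure_setup(tree, counts)
  sum(s$l * g_theta(s$D, theta))
}

#' Rooted balance-weighted phylogenetic diversity RBWPD_theta
#'
#' `sum_i l_i * D_i^theta` with the convention `0^theta = 0` for every
#' `theta >= 0` (pointwise-limit convention, so `theta = 0` gives rooted PD:
#' total length of edges with any distal reads). Unlike [bwpd()], this
#' depends on the root position, which the caller must fix deliberately.
#'
#' @inheritParams bwpd
#' @return non-negative diversity value.
#' @export
rbwpd <- function(tree, counts, theta = 1) {
  stopifnot(length(theta) == 1L)
  if (!is.finite(theta) || theta < 0) stop_user("theta must be finite and >= 0")
  s <- phylo_measure_setup(tree, counts)
  pos <- s$D > 0
  sum(s$l[pos] * s$D[pos]^theta)
}

#' Phylogenetic quadratic entropy (Rao)
#'
#' `PQE = (1/n^2) sum_i l_i d_i (n - d_i)`: the phylogenetic generalisation
#' of the Gini-Simpson index. On a star tree with unit branch lengths it
#' reduces to `1 - sum p_j^2`. Root-invariant, since `d (n - d)` is symmetric
#' under the distal/proximal flip.
#'
#' @inheritParams compute_edge_masses
#' @return non-negative entropy value.
#' @export
pqe <- function(tree, counts) {
  s <- phylo_measure_setup(tree, counts)
  sum(s$l * s$d * (s$n - s$d)) / s$n^2
}

#' Phylogenetic entropy
#'
#' `H_p = -sum_i l_i p_i log(p_i)` with `p_i` the (rooted) distal read
#' fraction of edge `i` and `0 log 0 := 0`: the phylogenetic generalisation
#' of the Shannon index. Depends on the root. Natural log by default.
#'
#' @inheritParams compute_edge_masses
#' @param base logarithm base (natural log by default).
#' @return non-negative entropy value.
#' @export
phylo_entropy <- function(tree, counts, base = exp(1)) {
  s <- phylo_measure_setup(tree, counts)
  pos <- s$D > 0
  -sum(s$l[pos] * s$D[pos] * log(s$D[pos], base = base))
}

#' Hill-number phylogenetic diversity of order q
#'
#' The mean-diversity ("effective number of species") form: with branch
#' abundances `a_i` = rooted distal fractions and mean tree depth
#' `Tbar = sum_i l_i a_i`,
#' \deqn{{}^qD(T) = \Big[\sum_{a_i > 0} (l_i/\bar T)\, a_i^q\Big]^{1/(1-q)}}
#' for `q != 1`, and `exp(-sum (l_i/Tbar) a_i log a_i)` at `q = 1` (the
#' continuous limit). Invariant under rescaling of all branch lengths;
#' depends on the root. `scaled = TRUE` returns `Tbar * qD(T)` instead.
#'
#' @inheritParams compute_edge_masses
#' @param q non-negative Hill order.
#' @param scaled if `TRUE`, return the branch-length-scaled product
#'   `Tbar * qD(T)` rather than the effective-number form.
#' @return diversity of order `q` (>= 1 in the effective-number form).
#' @export
hill_qdt <- function(tree, counts, q = 1, scaled = FALSE) {
  stopifnot(length(q) == 1L)
  if (!is.finite(q) || q < 0) stop_user("q must be finite and >= 0")
  s <- phylo_measure_setup(tree, counts)
  pos <- s$D > 0
  tbar <- sum(s$l[pos] * s$D[pos])
  if (tbar <= 0) stop_user("all read mass sits on zero-length edges (Tbar = 0)")
  val <- if (abs(q - 1) < 1e-10) {
    exp(-sum(s$l[pos] / tbar * s$D[pos] * log(s$D[pos])))
  } else {
    sum(s$l[pos] / tbar * s$D[pos]^q)^(1 / (1 - q))
  }
  if (scaled) tbar * val else val
}

# ---- measure registry / batch surface --------------------------------------

# parse ids like "pd_u", "bwpd_0.25", "rbwpd_1", "pqe", "phylo_entropy",
# "qdt_0.5", "shannon", "simpson", "chao1", "ace" into evaluator closures
parse_measure <- function(id) {
  if (id == "pd_u")
    return(list(phylo = TRUE, fn = function(tree, x) pd_unrooted(tree, x)))
  if (grepl("^bwpd_", id)) {
    th <- as.numeric(sub("^bwpd_", "", id))
    if (is.na(th)) stop_user("bad measure id: ", id)
    return(list(phylo = TRUE, fn = function(tree, x) bwpd(tree, x, th)))
  }
  if (grepl("^rbwpd_", id)) {
    th <- as.numeric(sub("^rbwpd_", "", id))
    if (is.na(th)) stop_user("bad measure id: ", id)
    return(list(phylo = TRUE, fn = function(tree, x) rbwpd(tree, x, th)))
  }
  if (id == "pqe")
    return(list(phylo = TRUE, fn = function(tree, x) pqe(tree, x)))
  if (id == "phylo_entropy")
    return(list(phylo = TRUE, fn = function(tree, x) phylo_entropy(tree, x)))
  if (grepl("^qdt_", id)) {
    q <- as.numeric(sub("^qdt_", "", id))
    if (is.na(q)) stop_user("bad measure id: ", id)
    return(list(phylo = TRUE, fn = function(tree, x) hill_qdt(tree, x, q)))
  }
  disc <- switch(id,
    shannon = function(tree, x) shannon(x),
    simpson = function(tree, x) simpson_gini(x),
    chao1   = function(tree, x) chao1(x),
    ace     = function(tree, x) ace(x),
    stop_user("unknown measure id: ", id))
  list(phylo = FALSE, fn = disc)
}

default_measures <- function(theta = c(0, 0.25, 0.5, 1), q = c(0, 0.25, 0.5)) {
  c("pd_u", paste0("bwpd_", theta[theta > 0]), "pqe", "phylo_entropy",
    paste0("qdt_", q), "shannon", "simpson", "chao1", "ace")
}

#' Compute a samples-by-measures diversity matrix
#'
#' Batch evaluation of diversity measures over every sample (column) of a
#' count table, optionally as means over rarefaction replicates (the
#' standard protocol: rarefy every sample to the depth of the shallowest
#' one and average each statistic over `R` draws).
#'
#' @param table count matrix (rows = leaves, columns = samples).
#' @param tree a [ptree]; required for phylogenetic measure ids.
#' @param measures character vector of measure ids; recognised forms are
#'   `"pd_u"`, `"bwpd_<theta>"`, `"rbwpd_<theta>"`, `"pqe"`,
#'   `"phylo_entropy"`, `"qdt_<q>"`, `"shannon"`, `"simpson"`, `"chao1"`,
#'   `"ace"`.
#' @param rarefy `NULL` for unrarefied values, otherwise a list with `k`
#'   (depth, or `"min"`), `R` (replicates, default 100) and `seed`.
#' @param align alignment mode passed to [align_tree_table()] when a tree is
#'   given.
#' @param shallow policy for samples with fewer than `k` reads: `"skip"`
#'   (drop the sample with a warning) or `"error"`.
#' @return a data frame: one row per retained sample, one column per
#'   measure, with sample ids in `sample_id`.
#' @export
diversity_matrix <- function(table, tree = NULL,
                             measures = default_measures(),
                             rarefy = NULL, align = "strict",
                             shallow = c("skip", "error")) {
  shallow <- match.arg(shallow)
  table <- validate_count_table(table)
  specs <- lapply(measures, parse_measure)
  names(specs) <- measures
  if (any(vapply(specs, `[[`, TRUE, "phylo"))) {
    if (is.null(tree)) stop_user("phylogenetic measures requested but no tree given")
    table <- align_tree_table(tree, table, mode = align)
  }
  depths <- colSums(table)
  if (any(depths == 0)) {
    warning("dropping empty sample(s): ",
            paste(colnames(table)[depths == 0], collapse = ", "))
    table <- table[, depths > 0, drop = FALSE]
    depths <- depths[depths > 0]
  }
  if (!is.null(rarefy)) {
    k <- rarefy$k
    if (identical(k, "min")) k <- min(depths)
    k <- as.integer(k)
    R <- if (is.null(rarefy$R)) 100L else as.integer(rarefy$R)
    seed <- rarefy$seed
    if (is.null(seed)) stop_user("rarefaction requires a seed")
    low <- depths < k
    if (any(low)) {
      if (shallow == "error")
        stop_user("sample(s) shallower than k = ", k, ": ",
                  paste(colnames(table)[low], collapse = ", "))
      warning("skipping ", sum(low), " sample(s) shallower than k = ", k)
      table <- table[, !low, drop = FALSE]
    }
  }
  out <- matrix(NA_real_, ncol(table), length(measures),
                dimnames = list(colnames(table), measures))
  for (j in seq_len(ncol(table))) {
    cnt <- sample_counts(table, j)
    if (is.null(rarefy)) {
      for (mid in measures) out[j, mid] <- specs[[mid]]$fn(tree, cnt)
    } else {
      # one shared set of R rarefaction draws per sample, all measures paired
      acc <- numeric(length(measures))
      sseed <- derive_seed(seed, j)
      for (r in seq_len(R)) {
        cnt_r <- rarefy_counts(cnt, k, seed = derive_seed(sseed, r))
        for (mi in seq_along(measures))
          acc[mi] <- acc[mi] + specs[[measures[mi]]]$fn(tree, cnt_r)
      }
      out[j, ] <- acc / R
    }
  }
  data.frame(sample_id = rownames(out), out, check.names = FALSE,
             row.names = NULL)
}
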
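#' Rarefy a sample without replacement
#'
#' Draws `k` of the sample's `n` reads uniformly without replacement (the
#' multivariate hypergeometric over leaves), the operation "rarefaction"
#' denotes throughout community ecology. `k = n` returns the input exactly.
#'
#' @param counts named non-negative integer vector of per-leaf counts.
#' @param k target depth, `1 <= k <= sum(counts)`.
#' @param seed optional integer; when given, the draw is made under a local
#'   RNG seeded with it and the caller's RNG stream is untouched.
#' @return a named integer vector with the same names, summing to `k`.
#' @export
rarefy_counts <- function(counts, k, seed = NULL) {
  if (!is_count_vector(counts)) stop_user("counts must be non-negative integers")
  n <- sum(counts)
  k <- as.integer(k)
  if (n < 1L) stop_user("empty sample")
  if (k < 1L || k > n) stop_user("k must satisfy 1 <= k <= n = ", n)
  if (k == n) return(stats::setNames(as.integer(counts), names(counts)))
  idx <- with_seed(seed, sample.int(n, k))
  cum <- cumsum(counts)
  cat <- findInterval(idx - 0.5, cum) + 1L
  stats::setNames(tabulate(cat, nbins = length(counts)), names(counts))
}

#' Rarefy every column of a count table
#'
#' @param table count matrix (rows = leaves, columns = samples).
#' @param k target depth, or `"min"` for the shallowest sample's depth.
#' @param seed integer seed; per-sample draws use seeds derived from it.
#' @param shallow policy for samples with fewer than `k` reads: drop with a
#'   warning (`"skip"`) or fail (`"error"`).
#' @return rarefied count matrix (columns shallower than `k` dropped under
#'   the skip policy), with the resolved depth as attribute `"k"`.
#' @export
rarefy_table <- function(table, k = "min", seed = 1L, shallow = c("skip", "error")) {
  shallow <- match.arg(shallow)
  table <- validate_count_table(table)
  depths <- colSums(table)
  if (identical(k, "min")) k <- min(depths)
  k <- as.integer(k)
  low <- depths < k
  if (any(low)) {
    if (shallow == "error")
      stop_user("sample(s) shallower than k = ", k, ": ",
                paste(colnames(table)[low], collapse = ", "))
    warning("skipping ", sum(low), " sample(s) shallower than k = ", k, ": ",
            paste(utils::head(colnames(table)[low], 10L), collapse = ", "))
    table <- table[, !low, drop = FALSE]
  }
  out <- table
  for (j in seq_len(ncol(table)))
    out[, j] <- rarefy_counts(sample_counts(table, j), k, seed = derive_seed(seed, j))
  attr(out, "k") <- k
  out
}

# shared by diversity_matrix and mean_rarefied_measure: mean of fn over R draws
mean_rarefied_value <- function(tree, counts, fn, k, R, seed) {
  acc <- 0
  for (r in seq_len(R))
    acc <- acc + fn(tree, rarefy_counts(counts, k, seed = derive_seed(seed, r)))
  acc / R
}

#' Mean of a diversity measure over rarefaction replicates
#'
#' The standard protocol: rarefy to depth `k`, compute the measure, repeat
#' `R` times (default 100) and average. Replicate seeds are derived
#' deterministically from `seed` and the replicate index, so results are
#' reproducible and independent of evaluation order.
#'
#' @param tree a [ptree] (ignored by discrete measures).
#' @param counts named non-negative integer count vector.
#' @param measure measure id as understood by [diversity_matrix()].
#' @param k rarefaction depth.
#' @param R number of replicates.
#' @param seed integer seed.
#' @return the Monte-Carlo mean of the measure at depth `k`.
#' @export
mean_rarefied_measure <- function(tree, counts, measure, k, R = 100L, seed = 1L) {
  spec <- parse_measure(measure)
  mean_rarefied_value(tree, counts, spec$fn, k = as.integer(k),
                      R = as.integer(R), seed = seed)
}

#' Expected phylogenetic quadratic entropy under rarefaction
#'
#' Closed form for the expectation of [pqe()] when `k` reads are drawn
#' without replacement from the sample's `n`:
#' \deqn{E[PQE_k] = \frac{k-1}{k\,n\,(n-1)} \sum_i \ell_i d_i (n - d_i)}
#' so `E[PQE_k] = PQE * (k-1) n / (k (n-1))`, which increases with `k` and
#' recovers the plug-in PQE exactly at `k = n`; a single read (`k = 1`) has
#' zero quadratic entropy. No comparably simple form is known for the BWPD
#' family or phylogenetic entropy; use [mean_rarefied_measure()] for those.
#'
#' @inheritParams compute_edge_masses
#' @param k rarefaction depth, `1 <= k <= n`; requires `n >= 2`.
#' @return the exact expectation, a non-negative number.
#' @export
expected_pqe_rarefied <- function(tree, counts, k) {
  s <- phylo_measure_setup(tree, counts)
  k <- as.integer(k)
  if (s$n < 2L) stop_user("expectation undefined for n < 2")
  if (k < 1L || k > s$n) stop_user("k must satisfy 1 <= k <= n = ", s$n)
  (k - 1) / (k * s$n * (s$n - 1)) * sum(s$l * s$d * (s$n - s$d))
}

#' Rarefaction sensitivity experiment
#'
#' For every sample and measure, compares the value computed on the full
#' sample with the value after rarefaction to depth `k` (a single draw by
#' default, `R > 1` for a replicate mean), and summarises each measure's
#' sensitivity as the mean absolute relative deviation
#' `MARD = mean(|rarefied - full| / full)` over samples with a nonzero full
#' value (zero-valued samples are excluded and counted). Abundance weighting
#' damps this sensitivity: MARD decreases as the BWPD exponent grows.
#'
#' @param tree a [ptree].
#' @param table count matrix.
#' @param measures character vector of measure ids.
#' @param k rarefaction depth, or `"min"`.
#' @param seed integer seed.
#' @param R rarefaction replicates per sample (1 = the single-rarefaction
#'   scatter experiment).
#' @param align alignment mode for [align_tree_table()].
#' @return a list with `details` (sample, measure, full, rarefied, abs_dev,
#'   rel_dev) and `summary` (measure, mard, n_used, n_zero_full).
#' @export
sensitivity_experiment <- function(tree, table, measures, k = "min", seed = 1L,
                                   R = 1L, align = "strict") {
  table <- align_tree_table(tree, table, mode = align)
  depths <- colSums(table)
  if (identical(k, "min")) k <- min(depths)
  k <- as.integer(k)
  low <- depths < k
  if (any(low)) {
    warning("skipping ", sum(low), " sample(s) shallower than k = ", k)
    table <- table[, !low, drop = FALSE]
  }
  specs <- lapply(measures, parse_measure)
  rows <- vector("list", ncol(table) * length(measures))
  ri <- 0L
  for (j in seq_len(ncol(table))) {
    cnt <- sample_counts(table, j)
    sseed <- derive_seed(seed, j)
    for (mi in seq_along(measures)) {
      fn <- specs[[mi]]$fn
      full <- fn(tree, cnt)
      rare <- mean_rarefied_value(tree, cnt, fn, k = k, R = as.integer(R),
                                  seed = sseed)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(sample_id = colnames(table)[j],
                               measure = measures[mi], full = full,
                               rarefied = rare, abs_dev = abs(rare - full),
                               rel_dev = if (full != 0) abs(rare - full) / full
                                         else NA_real_)
    }
  }
  details <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(measures, function(m) {
    d <- details[details$measure == m, ]
    data.frame(measure = m, mard = mean(d$rel_dev, na.rm = TRUE),
               n_used = sum(!is.na(d$rel_dev)), n_zero_full = sum(is.na(d$rel_dev)))
  }))
  list(details = details, summary = summary, k = k)
}
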
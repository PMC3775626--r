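#' Discrete alpha-diversity and richness measures
#'
#' Non-phylogenetic measures on a vector of category (OTU or taxon) counts:
#' Shannon entropy, the (Gini-)Simpson index, and the Chao1 and ACE
#' nonparametric richness estimators. Defaults follow the semantics of the
#' standard R community-ecology implementations (`vegan::diversity` /
#' `vegan::estimateR`): natural-log Shannon, Gini-Simpson `1 - sum p^2`,
#' bias-corrected Chao1, ACE with rare/abundant cutoff 10.
#'
#' @param counts non-negative integer vector of per-category counts (zeros
#'   are allowed and ignored).
#' @name discrete_alpha
NULL

check_abundance <- function(counts) {
  if (!is_count_vector(counts)) stop_user("counts must be non-negative integers")
  if (sum(counts) < 1) stop_user("empty abundance vector")
  counts[counts > 0]
}

#' @rdname discrete_alpha
#' @param base logarithm base (natural log by default).
#' @return `shannon`: entropy `H = -sum p_j log p_j` in \[0, log S\].
#' @export
shannon <- function(counts, base = exp(1)) {
  x <- check_abundance(counts)
  p <- x / sum(x)
  -sum(p * log(p, base = base))
}

#' @rdname discrete_alpha
#' @param inverse if `TRUE`, return the inverse Simpson index
#'   `1 / sum p_j^2` instead of the Gini-Simpson index.
#' @return `simpson_gini`: `1 - sum p_j^2` in \[0, 1) (or its inverse form).
#' @export
simpson_gini <- function(counts, inverse = FALSE) {
  x <- check_abundance(counts)
  p <- x / sum(x)
  if (inverse) 1 / sum(p^2) else 1 - sum(p^2)
}

#' @rdname discrete_alpha
#' @param bias_corrected if `TRUE` (default) use
#'   `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`; otherwise the classic
#'   `S_obs + f1^2 / (2 f2)` (with the usual `f1 (f1 - 1) / 2` replacement
#'   when `f2 = 0`).
#' @return `chao1`: estimated richness, `>= S_obs`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  x <- check_abundance(counts)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' @rdname discrete_alpha
#' @param rare_threshold maximum count for a category to be "rare"
#'   (default 10, the standard choice).
#' @return `ace`: abundance-based coverage estimate of richness; falls back
#'   to [chao1()] with a warning when every rare category is a singleton
#'   (sample coverage estimate 0).
#' @export
ace <- function(counts, rare_threshold = 10) {
  x <- check_abundance(counts)
  rare <- x[x <= rare_threshold]
  s_abund <- sum(x > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) return(as.numeric(s_abund))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE coverage estimate is 0 (all rare categories are singletons); ",
            "falling back to Chao1")
    return(chao1(counts))
  }
  fk <- tabulate(rare, nbins = rare_threshold)
  sum_kk1 <- sum(seq_len(rare_threshold) * (seq_len(rare_threshold) - 1) * fk)
  gamma2 <- if (n_rare > 1) {
    max(s_rare / c_ace * sum_kk1 / (n_rare * (n_rare - 1)) - 1, 0)
  } else 0
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}
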
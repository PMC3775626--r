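#' Pearson correlation between diversity measures
#'
#' @param m numeric matrix or data frame, samples in rows and measures in
#'   columns (a `sample_id` column is dropped automatically).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(m) {
  m <- as_measure_matrix(m)
  if (nrow(m) < 3L) stop_user("need >= 3 samples for correlations")
  cst <- apply(m, 2L, function(x) stats::sd(x) == 0 || !all(is.finite(x)))
  if (any(cst))
    stop_user("constant or non-finite measure column(s): ",
              paste(colnames(m)[cst], collapse = ", "))
  r <- stats::cor(m, method = "pearson")
  diag(r) <- 1
  r
}

as_measure_matrix <- function(m) {
  if (is.data.frame(m)) {
    rn <- if ("sample_id" %in% names(m)) m$sample_id else rownames(m)
    m <- m[, setdiff(names(m), "sample_id"), drop = FALSE]
    m <- as.matrix(m)
    rownames(m) <- rn
  }
  stopifnot(is.numeric(m))
  m
}

#' Hierarchically cluster measures by correlation distance
#'
#' Agglomerates measures with `d = 1 - r` as the distance and complete
#' linkage by default (the `hclust` default). Columns are pre-sorted
#' lexicographically so that distance ties break deterministically.
#'
#' @param r correlation matrix as from [pearson_matrix()].
#' @param linkage `"complete"`, `"single"` or `"average"`.
#' @return an object of class `hclust`.
#' @export
cluster_measures <- function(r, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(r))
  if (!isSymmetric(unname(r), tol = 1e-8))
    stop_user("correlation matrix must be symmetric")
  ord <- order(colnames(r))
  r <- r[ord, ord]
  stats::hclust(stats::as.dist(1 - r), method = linkage)
}

#' Serialise an hclust dendrogram as Newick
#'
#' Leaf labels are the measure ids; branch lengths are increments of the
#' merge heights, so root-to-leaf distance equals the top merge height.
#'
#' @param hc an `hclust` object.
#' @return a Newick string.
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  build <- function(i, parent_h) {
    if (i < 0) return(paste0(hc$labels[-i], ":", format(parent_h, trim = TRUE)))
    h <- hc$height[i]
    kids <- vapply(hc$merge[i, ], build, "", parent_h = h)
    paste0("(", paste(kids, collapse = ","), "):",
           format(parent_h - h, trim = TRUE))
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  kids <- vapply(hc$merge[top, ], build, "", parent_h = h)
  paste0("(", paste(kids, collapse = ","), ");")
}

#' Leave-one-out accuracy of a single-predictor logistic regression
#'
#' For each sample, fits `label ~ value` by logistic regression on the
#' remaining samples and classifies the held-out sample at probability
#' cutoff 0.5; returns the fraction classified correctly. Complete
#' separation still yields a usable classification direction (with one
#' warning); a constant predictor degrades to the majority-class rate.
#'
#' @param values numeric predictor, one per sample.
#' @param labels binary labels (logical, two-level factor, or 0/1).
#' @return accuracy in \[0, 1\].
#' @export
loo_logistic_accuracy <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop_user("labels must contain both classes")
  n <- length(y)
  if (n < 4L) stop_user("need >= 4 samples for leave-one-out")
  if (stats::sd(values) == 0) {
    warning("constant predictor: accuracy is the majority-class frequency")
    return(max(mean(y), 1 - mean(y)))
  }
  separated <- FALSE
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- withCallingHandlers(
      stats::glm(y[-i] ~ values[-i], family = stats::binomial()),
      warning = function(w) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    eta <- stats::coef(fit)[1L] + stats::coef(fit)[2L] * values[i]
    if (is.na(eta)) eta <- stats::coef(fit)[1L]
    correct[i] <- (eta > 0) == (y[i] == 1L)
  }
  if (separated)
    warning("logistic fit did not converge cleanly for some folds ",
            "(likely complete separation); classification direction used")
  mean(correct)
}

#' Coefficient of determination of a simple linear regression
#'
#' @param x numeric predictor (e.g. a diversity measure).
#' @param y numeric response (e.g. a clinical score).
#' @return R-squared of least-squares `y ~ x`, the squared Pearson r.
#' @export
linear_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop_user("need >= 3 samples")
  if (stats::sd(x) == 0) stop_user("constant predictor")
  if (stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Two-sample t-test p-value
#'
#' Two-sided p-value comparing group means; Welch's unequal-variance test
#' (the `t.test` default) unless `pooled = TRUE`.
#'
#' @param group_a,group_b numeric vectors (each >= 2 values).
#' @param pooled use the pooled-variance (classical) test instead of Welch.
#' @return p-value in (0, 1\].
#' @export
welch_t_pvalue <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_user("each group needs >= 2 samples")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop_user("degenerate (zero-variance) groups")
  stats::t.test(group_a, group_b, var.equal = pooled)$p.value
}

#' Fixed-effects ANOVA p-value across strata
#'
#' One-way F-test of `values ~ strata`; with `second_factor`, an additive
#' two-factor ANOVA, reporting the first factor's p-value.
#'
#' @param values numeric vector.
#' @param strata categorical stratum per value (>= 2 strata, each >= 2
#'   samples).
#' @param second_factor optional second categorical factor.
#' @return the first factor's p-value in (0, 1\].
#' @export
anova_pvalue <- function(values, strata, second_factor = NULL) {
  strata <- as.factor(strata)
  if (nlevels(droplevels(strata)) < 2L) stop_user("need >= 2 strata")
  if (any(table(strata) < 2L)) stop_user("every stratum needs >= 2 samples")
  fit <- if (is.null(second_factor)) {
    stats::aov(values ~ strata)
  } else {
    second_factor <- as.factor(second_factor)
    stats::aov(values ~ strata + second_factor)
  }
  summary(fit)[[1L]][["Pr(>F)"]][1L]
}

#' Rank measures by several performance metrics
#'
#' Ranks every measure within each metric (1 = best, average ranks on ties;
#' accuracy/R-squared rank high-to-low, p-values low-to-high), averages the
#' ranks, and orders measures by increasing mean rank — the aggregation used
#' to produce a single ordering of candidate diversity measures.
#'
#' @param metrics data frame or matrix, rows = measures (row names = ids),
#'   columns = performance metrics; no missing cells.
#' @param orientations named character vector over the metric columns, each
#'   `"higher_better"` or `"lower_better"`. Columns named like `accuracy`/
#'   `r2` default to higher-better and `p`-like columns to lower-better if
#'   omitted.
#' @return data frame: measure, the metric columns, `rank_<metric>` columns,
#'   `mean_rank`; rows sorted by `mean_rank`.
#' @export
mean_rank_report <- function(metrics, orientations = NULL) {
  m <- as.matrix(metrics)
  if (is.null(rownames(m))) stop_user("metrics must have measure row names")
  if (anyNA(m)) stop_user("missing metric cell(s)")
  if (is.null(orientations)) {
    orientations <- ifelse(grepl("^(p|pval|p_value|anova_p|t_p)", colnames(m)),
                           "lower_better", "higher_better")
    names(orientations) <- colnames(m)
  }
  if (!all(colnames(m) %in% names(orientations)))
    stop_user("orientation missing for metric(s): ",
              paste(setdiff(colnames(m), names(orientations)), collapse = ", "))
  ranks <- sapply(colnames(m), function(cn) {
    x <- m[, cn]
    if (orientations[[cn]] == "higher_better") rank(-x, ties.method = "average")
    else rank(x, ties.method = "average")
  })
  ranks <- matrix(ranks, nrow = nrow(m),
                  dimnames = list(rownames(m), paste0("rank_", colnames(m))))
  out <- data.frame(measure = rownames(m), m, ranks,
                    mean_rank = rowMeans(ranks), check.names = FALSE,
                    row.names = NULL)
  out[order(out$mean_rank, out$measure), , drop = FALSE]
}

#' End-to-end comparative evaluation of diversity measures
#'
#' Given a samples-by-measures matrix and per-sample metadata, computes for
#' every measure whichever performance metrics the metadata supports —
#' leave-one-out logistic accuracy and a t-test p-value for a binary
#' `state`, linear R-squared against a continuous `score`, an ANOVA p-value
#' across a categorical `stratum` — and aggregates them with
#' [mean_rank_report()]. Also returns the measure correlation matrix and its
#' complete-linkage clustering.
#'
#' @param m measure matrix (data frame with `sample_id` or matrix with row
#'   names).
#' @param metadata data frame with `sample_id` and any of `state` (binary),
#'   `score` (numeric), `stratum` (categorical), `stratum2` (categorical,
#'   used as an additive second ANOVA factor).
#' @param linkage clustering linkage.
#' @return list: `report` (ranking data frame), `correlations`, `clustering`
#'   (`hclust`), `dendrogram` (Newick string).
#' @export
compare_measures <- function(m, metadata, linkage = "complete") {
  mm <- as_measure_matrix(m)
  if (!"sample_id" %in% names(metadata)) stop_user("metadata needs a sample_id column")
  idx <- match(rownames(mm), metadata$sample_id)
  if (anyNA(idx)) stop_user("metadata missing sample(s): ",
                            paste(utils::head(rownames(mm)[is.na(idx)], 10L),
                                  collapse = ", "))
  md <- metadata[idx, , drop = FALSE]
  has_state <- "state" %in% names(md) && length(unique(md$state)) == 2L
  has_score <- "score" %in% names(md) && is.numeric(md$score)
  has_stratum <- "stratum" %in% names(md) &&
    nlevels(droplevels(as.factor(md$stratum))) >= 2L
  if (!has_state && !has_score && !has_stratum)
    stop_user("metadata must provide a binary 'state', a numeric 'score', ",
              "or a categorical 'stratum'")
  metrics <- list()
  if (has_state) {
    st <- as.factor(md$state)
    metrics$accuracy <- apply(mm, 2L, loo_logistic_accuracy, labels = st)
    metrics$p_value <- apply(mm, 2L, function(v)
      welch_t_pvalue(v[st == levels(st)[1L]], v[st == levels(st)[2L]]))
  }
  if (has_score)
    metrics$r2 <- apply(mm, 2L, linear_r2, y = md$score)
  if (has_stratum) {
    sf <- if ("stratum2" %in% names(md)) md$stratum2 else NULL
    metrics$anova_p <- apply(mm, 2L, anova_pvalue, strata = md$stratum,
                             second_factor = sf)
  }
  tab <- do.call(cbind, metrics)
  rownames(tab) <- colnames(mm)
  orient <- stats::setNames(
    ifelse(names(metrics) %in% c("accuracy", "r2"), "higher_better", "lower_better"),
    names(metrics))
  r <- pearson_matrix(mm)
  hc <- cluster_measures(r, linkage = linkage)
  list(report = mean_rank_report(tab, orient), correlations = r,
       clustering = hc, dendrogram = dendrogram_newick(hc))
}
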
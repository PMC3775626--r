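test_that("pearson_matrix behaves like Pearson correlation should", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  r <- pearson_matrix(cbind(m, dup = m[, "a"], neg = -m[, "a"]))
  expect_equal(diag(r), setNames(rep(1, 4), colnames(r)))
  expect_equal(r["a", "dup"], 1)
  expect_equal(r["a", "neg"], -1)
  expect_equal(r["a", "b"], 0.8)  # hand evaluation of the Pearson formula
  expect_true(isSymmetric(r))
  # affine invariance
  r2 <- pearson_matrix(cbind(a = 5 * m[, "a"] - 2, b = m[, "b"]))
  expect_equal(r2["a", "b"], 0.8)
  expect_error(pearson_matrix(cbind(a = c(1, 1, 1), b = c(1, 2, 3))), "constant")
  expect_error(pearson_matrix(m[1:2, ]), ">= 3 samples")
})

test_that("cluster_measures reproduces naive complete linkage", {
  r3 <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.1, 0.1, 0.1, 1), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  hc <- cluster_measures(r3)
  expect_equal(hclust_merge_sets(hc)[[1]], c("x", "y"))

  rdup <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  hcd <- cluster_measures(rdup)
  expect_equal(hcd$height[1], 0)
  expect_equal(hclust_merge_sets(hcd)[[1]], c("a", "b"))

  set.seed(53)
  x <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("m", 1:5)))
  r <- pearson_matrix(x)
  hc5 <- cluster_measures(r)
  expect_equal(hclust_merge_sets(hc5),
               oracle_complete_linkage_merges(1 - r))
  expect_error(cluster_measures(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})

test_that("dendrogram serialises to Newick with additive heights", {
  r3 <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.1, 0.1, 0.1, 1), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  nwk <- dendrogram_newick(cluster_measures(r3))
  tr <- read_newick(nwk)
  expect_setequal(leaf_labels(tr), c("x", "y", "z"))
  # heights: x,y merge at 0.1, z joins at 0.9 -> edges 0.1, 0.1, 0.8, 0.9
  expect_equal(total_branch_length(tr), 1.9, tolerance = 1e-9)
})

test_that("loo_logistic_accuracy handles separation, nulls and degeneracy", {
  vals <- c(rnorm(10, 0), rnorm(10, 20))
  labs <- rep(c("n", "d"), each = 10)
  expect_equal(suppressWarnings(loo_logistic_accuracy(vals, labs)), 1.0)
  # invariance under strictly increasing transform when separated
  expect_equal(suppressWarnings(loo_logistic_accuracy(exp(vals / 10), labs)), 1.0)

  # under the null, LOO accuracy at cutoff 0.5 is pessimistically biased:
  # with balanced classes it sits at or below chance, never above it
  set.seed(59)
  n <- 400L
  vals_null <- rnorm(n); labs_null <- rep(c(0, 1), n / 2)
  acc <- suppressWarnings(loo_logistic_accuracy(vals_null, labs_null))
  expect_lt(acc, 0.5 + 3 * sqrt(0.25 / n))

  expect_warning(flat <- loo_logistic_accuracy(rep(1, 10), c(rep(0, 7), rep(1, 3))),
                 "constant")
  expect_equal(flat, 0.7)
  expect_error(loo_logistic_accuracy(1:5, rep(1, 5)), "both classes")
})

test_that("loo_logistic_accuracy reproduces boot::cv.glm fold for fold", {
  skip_if_not_installed("boot")
  set.seed(79)
  for (shift in c(0, 1.5)) {
    df <- data.frame(x = c(rnorm(15), rnorm(15, shift)),
                     y = rep(c(0L, 1L), each = 15))
    cost <- function(y, p) mean(abs(y - p) > 0.5)
    cv <- suppressWarnings(boot::cv.glm(
      df, glm(y ~ x, family = binomial, data = df), cost = cost, K = nrow(df)))
    expect_equal(suppressWarnings(loo_logistic_accuracy(df$x, df$y)),
                 1 - cv$delta[1], tolerance = 1e-9)
  }
})

test_that("linear_r2 is the squared Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(linear_r2(x, 2 * x + 1), 1.0)
  expect_equal(linear_r2(x, c(1, 3, 2, 4)), 0.64)
  set.seed(61)
  expect_lt(linear_r2(rnorm(1000), rnorm(1000)), 0.01)
  expect_error(linear_r2(rep(1, 5), rnorm(5)), "constant")
})

test_that("welch_t_pvalue matches the textbook formula", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(welch_t_pvalue(a, 6 - a), 1.0)
  b <- a + 1
  # independent transcription of the Welch statistic
  sa <- var(a) / length(a); sb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  expect_equal(welch_t_pvalue(a, b), 2 * pt(-abs(tstat), df), tolerance = 1e-6)
  expect_error(welch_t_pvalue(a, c(1)), ">= 2 samples")
  expect_error(welch_t_pvalue(rep(1, 4), rep(1, 4)), "degenerate")
})

test_that("anova_pvalue obeys F = t^2 and a hand-computed 3-group fixture", {
  set.seed(67)
  x <- rnorm(12); g <- rep(c("u", "v"), each = 6)
  expect_equal(anova_pvalue(x, g),
               welch_t_pvalue(x[g == "u"], x[g == "v"], pooled = TRUE),
               tolerance = 1e-9)

  vals <- c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 8, 13, 13, 9, 11, 8, 7, 12)
  grp <- rep(c("g1", "g2", "g3"), each = 6)
  gm <- tapply(vals, grp, mean); mu <- mean(vals)
  ssb <- 6 * sum((gm - mu)^2)
  ssw <- sum((vals - gm[grp])^2)
  fstat <- (ssb / 2) / (ssw / 15)
  expect_equal(anova_pvalue(vals, grp), pf(fstat, 2, 15, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_error(anova_pvalue(vals, rep("g", 18)), ">= 2 strata")
  expect_error(anova_pvalue(vals[1:3], c("a", "a", "b")), ">= 2 samples")
  # additive two-factor form runs and reports the first factor
  p2 <- anova_pvalue(vals, grp, second_factor = rep(c("s1", "s2"), 9))
  expect_true(p2 > 0 && p2 <= 1)
})

test_that("mean_rank_report aggregates ranks with ties and orientation", {
  one <- mean_rank_report(matrix(c(0.9, 0.5, 0.7), 3, 1,
                                 dimnames = list(c("a", "b", "c"), "accuracy")))
  expect_equal(one$measure, c("a", "c", "b"))

  tied <- mean_rank_report(matrix(c(0.9, 0.9, 0.1), 3, 1,
                                  dimnames = list(c("a", "b", "c"), "accuracy")))
  expect_equal(tied$rank_accuracy[tied$measure %in% c("a", "b")], c(1.5, 1.5))

  tab <- matrix(c(0.9, 0.8, 0.7, 0.01, 0.5, 0.02), 3, 2,
                dimnames = list(c("a", "b", "c"), c("accuracy", "p_value")))
  rep3 <- mean_rank_report(tab)
  # hand enumeration: accuracy ranks a=1,b=2,c=3; p ranks a=1,c=2,b=3
  expect_equal(rep3$mean_rank[match(c("a", "b", "c"), rep3$measure)],
               c(1, 2.5, 2.5))
  expect_error(mean_rank_report(matrix(c(1, NA), 1, 2,
                                       dimnames = list("a", c("x", "y")))),
               "missing")
})

test_that("compare_measures runs end-to-end on simulated data", {
  tr <- random_tree(24, seed = 71)
  sim <- simulate_two_state(tr, sim_params(n_samples = 15, depth_min = 200,
                                           depth_max = 400, seed = 73))
  m <- diversity_matrix(sim$table, tr,
                        measures = c("pd_u", "bwpd_0.5", "bwpd_1", "shannon"))
  res <- suppressWarnings(compare_measures(m, sim$metadata))
  expect_setequal(res$report$measure, c("pd_u", "bwpd_0.5", "bwpd_1", "shannon"))
  expect_true(all(c("accuracy", "p_value", "r2", "anova_p") %in%
                    names(res$report)))
  expect_equal(res$report$mean_rank, sort(res$report$mean_rank))
  expect_s3_class(res$clustering, "hclust")
  expect_match(res$dendrogram, "^\\(.*\\);$")
  expect_error(compare_measures(m, data.frame(sample_id = m$sample_id)),
               "metadata must provide")
})
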
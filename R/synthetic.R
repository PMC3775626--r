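#' Canonical worked example: a three-leaf tree and a four-read sample
#'
#' The cherry-plus-outgroup tree `((A:1,B:1):1,C:1);` with counts
#' `A = 2, B = 1, C = 1`. All its diversity values have short closed forms
#' (e.g. unrooted PD 4, BWPD at exponent 1 is 2.5, quadratic entropy 13/16),
#' which makes it the fixture used throughout the documentation and tests.
#'
#' @return list with elements `tree` (a [ptree]) and `counts` (named integer
#'   vector).
#' @export
toy_tree <- function() {
  suppressWarnings(
    list(tree = read_newick("((A:1.0,B:1.0):1.0,C:1.0);"),
         counts = c(A = 2L, B = 1L, C = 1L))
  )
}

#' Random coalescent-style tree
#'
#' Builds a rooted binary tree over `n_leaves` labelled tips by uniformly
#' random sequential pairwise joins, with independent exponential(mean 1)
#' branch lengths — a neutral-ish shape distribution adequate for testing
#' measures, not a population-genetic simulator.
#'
#' @param n_leaves number of tips (>= 2), labelled `L0001`, `L0002`, ...
#' @param seed integer seed (draws are made under a local RNG).
#' @return a [ptree] with `2 n_leaves - 2` edges.
#' @export
random_tree <- function(n_leaves, seed = 1L) {
  n_leaves <- as.integer(n_leaves)
  if (is.na(n_leaves) || n_leaves < 2L) stop_user("n_leaves must be >= 2")
  with_seed(seed, {
    total <- 2L * n_leaves - 1L
    parent <- integer(total)
    brlen <- rep(NA_real_, total)
    label <- c(sprintf("L%04d", seq_len(n_leaves)), rep("", n_leaves - 1L))
    active <- seq_len(n_leaves)
    nxt <- n_leaves
    while (length(active) > 1L) {
      pick <- sample.int(length(active), 2L)
      nxt <- nxt + 1L
      parent[active[pick]] <- nxt
      brlen[active[pick]] <- stats::rexp(2L)
      active <- c(active[-pick], nxt)
    }
    ptree(parent, brlen, label, seq_len(n_leaves))
  })
}

#' Parameters of the two-state community simulator
#'
#' The generator emulates the contrast between a dysbiosis-style *dominated*
#' community state (state `"L"`: one dominant taxon drawn per sample with
#' Dirichlet weight `alpha_dom`, background taxa at `alpha_bg`) and an
#' *even* state (state `"H"`: symmetric Dirichlet(1) over all leaves).
#' Defaults: 64 leaves, 50 samples per state, `alpha_dom = 10`,
#' `alpha_bg = 0.1`, per-sample read depths drawn uniformly from
#' \[500, 2500\] — a depth spread of the order seen in small amplicon
#' surveys, giving the rarefaction machinery realistic unequal depths.
#'
#' @param n_samples samples per state.
#' @param alpha_dom Dirichlet weight of the dominant leaf in state L.
#' @param alpha_bg Dirichlet weight of every other leaf in state L
#'   (`0 < alpha_bg < alpha_dom`).
#' @param depth_min,depth_max per-sample read-depth range.
#' @param fixed_dominant if `TRUE`, one dominant leaf is drawn once and
#'   shared by all state-L samples; by default it is redrawn per sample.
#' @param score_means,score_sd state-conditional Gaussian for the continuous
#'   severity-style score (clipped to \[0, 10\]); state L is centred at the
#'   first mean.
#' @param seed integer seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_samples = 50L, alpha_dom = 10, alpha_bg = 0.1,
                       depth_min = 500L, depth_max = 2500L,
                       fixed_dominant = FALSE,
                       score_means = c(2, 7), score_sd = 1.5, seed = 1L) {
  # alpha_dom == alpha_bg == 1 degrades state L to Dirichlet(1), i.e. the
  # null configuration where both states share one distribution
  if (!(alpha_dom >= alpha_bg && alpha_bg > 0))
    stop_user("need alpha_dom >= alpha_bg > 0")
  if (depth_min < 1L || depth_max < depth_min)
    stop_user("need 1 <= depth_min <= depth_max")
  if (n_samples < 1L) stop_user("n_samples must be >= 1")
  structure(list(n_samples = as.integer(n_samples), alpha_dom = alpha_dom,
                 alpha_bg = alpha_bg, depth_min = as.integer(depth_min),
                 depth_max = as.integer(depth_max),
                 fixed_dominant = isTRUE(fixed_dominant),
                 score_means = score_means, score_sd = score_sd,
                 seed = as.integer(seed)),
            class = "sim_params")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

#' Simulate a two-state community count table
#'
#' Dirichlet-multinomial sampling per sample: leaf proportions from the
#' state's Dirichlet ([sim_params()]), a uniform random read depth, then
#' multinomial counts. Metadata carries the binary state (`"L"` dominated /
#' `"H"` even), a state-dependent continuous `score` emulating a 0-10
#' severity scale, and an independent two-level `stratum` ("siteA"/"siteB",
#' a null stratification useful for type-I-error checks). Fully
#' deterministic given the seed in `params`.
#'
#' @param tree a [ptree] supplying the leaf set (>= 2 leaves).
#' @param params a [sim_params()] object.
#' @return list: `table` (leaves x samples integer matrix), `metadata`
#'   (data frame: sample_id, state, stratum, score), `params`.
#' @export
simulate_two_state <- function(tree, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  leaves <- leaf_labels(tree)
  S <- length(leaves)
  if (S < 2L) stop_user("tree must have >= 2 leaves")
  ns <- params$n_samples
  with_seed(params$seed, {
    total <- 2L * ns
    tab <- matrix(0L, S, total, dimnames = list(leaves, sprintf("S%03d", seq_len(total))))
    state <- rep(c("L", "H"), each = ns)
    fixed_dom <- if (params$fixed_dominant) sample.int(S, 1L) else NA_integer_
    for (j in seq_len(total)) {
      if (state[j] == "L") {
        dom <- if (params$fixed_dominant) fixed_dom else sample.int(S, 1L)
        alpha <- rep(params$alpha_bg, S)
        alpha[dom] <- params$alpha_dom
      } else {
        alpha <- rep(1, S)
      }
      p <- rdirichlet1(alpha)
      depth <- sample(params$depth_min:params$depth_max, 1L)
      tab[, j] <- as.integer(stats::rmultinom(1L, depth, p))
    }
    mu <- ifelse(state == "L", params$score_means[1L], params$score_means[2L])
    score <- pmin(pmax(stats::rnorm(total, mu, params$score_sd), 0), 10)
    metadata <- data.frame(sample_id = colnames(tab), state = state,
                           stratum = sample(c("siteA", "siteB"), total, replace = TRUE),
                           score = score, stringsAsFactors = FALSE)
    list(table = tab, metadata = metadata, params = params)
  })
}
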
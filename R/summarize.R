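# Posterior summaries: topology point estimates and credible sets, HPD
# intervals, common-ancestor branch lengths, and the accuracy metrics used
# to score them against simulated truth.

# Canonical string key for a rooted clade (sorted tip labels).
clade_keys <- function(tr) {
  sets <- node_tip_sets(tr)
  internal <- (tr$ntip + 1L):tr$nnode
  vapply(sets[internal], function(s)
    paste(sort(tr$tip_label[s]), collapse = "|"), "")
}

# Canonical string for a rooted topology (sorted clade keys).
topology_key <- function(tr) paste(sort(clade_keys(tr)), collapse = ";")

#' Rooted Robinson-Foulds distance
#'
#' Number of rooted clades present in exactly one of the two trees (the
#' symmetric difference of their clade sets).  Satisfies identity, symmetry
#' and the `2*(n-2)` upper bound for binary trees.
#'
#' @param tree1,tree2 `mc_tree` objects over the same tip set.
#' @return Integer distance.
#' @export
rooted_rf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip_label, tree2$tip_label))
    stop("trees must share the same tip set")
  c1 <- clade_keys(tree1); c2 <- clade_keys(tree2)
  length(setdiff(c1, c2)) + length(setdiff(c2, c1))
}

#' Maximum clade credibility tree
#'
#' Among the sampled topologies, returns the one maximizing the product of
#' the posterior frequencies of its clades.  Ties are broken towards the
#' lexicographically smallest topology key (deterministic).
#'
#' @param samples List of sampled `mc_tree` objects.
#' @return The winning sampled tree (first sample with the MCC topology).
#' @export
mcc_tree <- function(samples) {
  if (!length(samples)) stop("no samples")
  all_clades <- lapply(samples, clade_keys)
  freq <- table(unlist(all_clades)) / length(samples)
  keys <- vapply(all_clades, function(k) paste(sort(k), collapse = ";"), "")
  scores <- vapply(all_clades, function(k) sum(log(freq[k])), 0)
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  samples[[cand[order(keys[cand])[1]]]]
}

#' Credible set of topologies
#'
#' Adds topologies in order of decreasing posterior probability until the
#' cumulative probability reaches or exceeds the level.
#'
#' @param samples List of sampled trees, or a named numeric vector of
#'   topology frequencies.
#' @param level Credibility level (default 0.95).
#' @return Data frame with `topology`, `probability`, `cumulative`.
#' @export
credible_set <- function(samples, level = 0.95) {
  if (is.list(samples)) {
    keys <- vapply(samples, topology_key, "")
    freqs <- sort(table(keys) / length(keys), decreasing = TRUE)
    freqs <- stats::setNames(as.numeric(freqs), names(freqs))
  } else freqs <- sort(samples / sum(samples), decreasing = TRUE)
  cum <- cumsum(freqs)
  keep <- seq_len(which(cum >= level - 1e-9)[1])
  data.frame(topology = names(freqs)[keep],
             probability = unname(freqs[keep]),
             cumulative = unname(cum[keep]), stringsAsFactors = FALSE)
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval containing at least `level` of the samples
#' (sorted-window search; ties broken towards the lower endpoint).
#'
#' @param samples Numeric vector (>= 20 samples).
#' @param level Interval mass (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  n <- length(samples)
  if (n < 20L) stop("need at least 20 samples")
  x <- sort(samples)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(lo = x[1], hi = x[n]))
  widths <- x[(m):n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(lo = x[i], hi = x[i + m - 1L])
}

#' Common-ancestor branch lengths conditioned on a reference topology
#'
#' For every internal node of the reference topology, the point estimate of
#' its height is the mean over posterior samples of the height of the most
#' recent common ancestor of that node's tip set.  Branch lengths are then
#' differences between each node's parent estimate and its own (tips use the
#' parent estimate directly).
#'
#' @param samples List of sampled `mc_tree` objects.
#' @param reference Reference topology (`mc_tree`, typically the truth).
#' @return List with `heights` (per reference node) and `lengths` (per
#'   reference non-root node, branch above it).
#' @export
common_ancestor_branch_lengths <- function(samples, reference) {
  if (!length(samples)) stop("no samples")
  ref_sets <- node_tip_sets(reference)
  est <- numeric(reference$nnode)
  for (v in (reference$ntip + 1L):reference$nnode) {
    tips <- reference$tip_label[ref_sets[[v]]]
    est[v] <- mean(vapply(samples, function(s) {
      ids <- match(tips, s$tip_label)
      a <- ids[1]
      for (b in ids[-1]) a <- sp_mrca_pair(s, a, b)
      s$height[a]
    }, 0))
  }
  lens <- rep(NA_real_, reference$nnode)
  kids <- which(reference$parent != 0L)
  lens[kids] <- est[reference$parent[kids]] - est[kids]
  list(heights = est, lengths = lens)
}

#' Branch length error and bias
#'
#' Error is `sum(|est - true|) / sum(true)`; bias is
#' `(sum(est) - sum(true)) / sum(true)`, over a chosen branch set (e.g. tip
#' branches, or internal branches excluding the root).
#'
#' @param estimates,truth Numeric branch lengths over the same branch set.
#' @return Named numeric `c(error =, bias =)`.
#' @export
branch_length_error_and_bias <- function(estimates, truth) {
  if (!length(truth) || length(estimates) != length(truth))
    stop("need matching non-empty branch sets")
  c(error = sum(abs(estimates - truth)) / sum(truth),
    bias = (sum(estimates) - sum(truth)) / sum(truth))
}

#' R-squared of estimated vs true branch rates
#'
#' Ordinary least squares of the estimates on the truth (root branches,
#' whose rates are fixed, should be excluded by the caller).
#'
#' @param truth Explanatory true rates (>= 3 values, non-constant).
#' @param estimates Estimated rates.
#' @return The regression R-squared.
#' @export
rate_regression <- function(truth, estimates) {
  if (length(truth) < 3L) stop("need at least 3 rate pairs")
  if (stats::var(truth) == 0) stop("true rates are constant")
  summary(stats::lm(estimates ~ truth))$r.squared
}
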
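# Multispecies coalescent densities and species-tree priors.
#
# The MSC density of a gene tree given the species tree factorizes over
# species branches.  With n_b coalescences inside branch b and integrated
# coalescent intensity gamma_b = sum over lineage-count intervals of
# choose(j,2) * dt, the per-branch contribution is
# N_b^(-n_b) * exp(-gamma_b / N_b) where N_b is the haploid-equivalent
# population size (coalescence rate for j lineages = choose(j,2)/N_b).
# (n_b, gamma_b) are sufficient statistics, which makes the inverse-gamma
# prior on N_b conjugate: the marginal over N_b is available in closed form
# per branch, so population sizes can be integrated out analytically at
# every MCMC step instead of being sampled.

#' Per-branch coalescent sufficient statistics
#'
#' Pools, across one or more gene trees, the number of coalescences `n` and
#' the integrated coalescent intensity `gamma` for every species branch.
#'
#' @param gene_trees A gene tree or list of gene trees (`mc_tree`).
#' @param species_tree The species tree.
#' @param mappings A validated mapping, or list of mappings (one per locus).
#' @param ploidy Per-locus multiplier on the effective branch population
#'   size (default 1 for every locus); a locus with ploidy m contributes
#'   `gamma / m` to the shared branch statistic.
#' @return A list with numeric vectors `n` and `gamma`, one entry per
#'   species-tree node (branch above it; the root entry is the stem).
#' @export
branch_coal_stats <- function(gene_trees, species_tree, mappings,
                              ploidy = NULL) {
  if (inherits(gene_trees, "mc_tree")) gene_trees <- list(gene_trees)
  if (is.character(mappings)) mappings <- list(mappings)
  if (length(mappings) == 1L && length(gene_trees) > 1L)
    mappings <- rep(mappings, length(gene_trees))
  if (is.null(ploidy)) ploidy <- rep(1, length(gene_trees))
  nb <- numeric(species_tree$nnode)
  gb <- numeric(species_tree$nnode)
  for (k in seq_along(gene_trees)) {
    st <- locus_coal_stats(gene_trees[[k]], species_tree, mappings[[k]])
    nb <- nb + st$n
    gb <- gb + st$gamma / ploidy[k]
  }
  list(n = nb, gamma = gb)
}

# Single-locus sufficient statistics via an interval sweep per species
# branch.
locus_coal_stats <- function(gene_tree, species_tree, mapping) {
  emb <- embed_gene_tree(gene_tree, species_tree, mapping)
  coal_stats_from_embedding(emb, gene_tree, species_tree)
}

# Sufficient statistics from a precomputed embedding.  The integrated
# intensity per branch is computed with an endpoint sweep: +1 at each
# lineage entry, -1 at each exit, gamma = sum choose(j,2) * dt over the
# piecewise-constant lineage count j.
coal_stats_from_embedding <- function(emb, gene_tree, species_tree) {
  ev <- attr(emb, "event_branch")
  nn <- species_tree$nnode
  nb <- tabulate(ev[(gene_tree$ntip + 1L):gene_tree$nnode], nn)
  gh <- gene_tree$height
  # flatten all (branch, entry, exit) segments
  total <- 0L
  for (v in seq_len(gene_tree$nnode))
    if (!is.null(emb[[v]])) total <- total + length(emb[[v]]$L)
  seg_b <- integer(total); seg_t0 <- numeric(total); seg_t1 <- numeric(total)
  i <- 0L
  for (v in seq_len(gene_tree$nnode)) {
    s <- emb[[v]]
    if (is.null(s)) next
    k <- length(s$L)
    idx <- i + seq_len(k)
    ends <- gh[v] + cumsum(s$L)
    seg_b[idx] <- s$species
    seg_t1[idx] <- ends
    seg_t0[idx] <- c(gh[v], ends[-k])
    i <- i + k
  }
  gb <- numeric(nn)
  for (b in unique(seg_b)) {
    sel <- seg_b == b
    k <- sum(sel)
    if (k < 2L) next
    ts <- c(seg_t0[sel], seg_t1[sel])
    d <- rep(c(1, -1), each = k)
    o <- order(ts)
    j <- cumsum(d[o])[-2L * k]
    gb[b] <- sum(j * (j - 1) / 2 * diff(ts[o]))
  }
  list(n = nb, gamma = gb)
}

#' Multispecies coalescent log density with explicit population sizes
#'
#' @inheritParams branch_coal_stats
#' @param gene_tree A gene tree (`mc_tree`).
#' @param mapping Validated mapping for this locus.
#' @param pop_sizes Haploid-equivalent population size per species-tree node
#'   (branch above it); defaults to the `popsize` slot of the species tree.
#' @return Log density of the gene tree under the MSC.
#' @export
coalescent_log_density <- function(gene_tree, species_tree, mapping,
                                   pop_sizes = species_tree$popsize) {
  if (any(is.na(pop_sizes)) || any(pop_sizes <= 0))
    stop("all branch population sizes must be positive")
  st <- locus_coal_stats(gene_tree, species_tree, mapping)
  sum(-st$n * log(pop_sizes) - st$gamma / pop_sizes)
}

#' Inverse-gamma prior on population sizes
#'
#' The analytical-integration prior: shape `alpha` fixed (default 3), mean
#' `mu = beta / (alpha - 1)`.  With `alpha = 3` the coefficient of variation
#' is exactly 1.
#'
#' @param alpha Shape (> 2 so that mean and variance exist).
#' @param beta Scale, or `NULL` to derive it from `mean`.
#' @param mean Prior mean; used when `beta` is `NULL`.
#' @return A list with `alpha`, `beta`, `mean`.
#' @export
invgamma_prior <- function(alpha = 3, beta = NULL, mean = NULL) {
  if (alpha <= 2) stop("alpha must exceed 2 so that mean and variance exist")
  if (is.null(beta)) {
    if (is.null(mean)) stop("supply beta or mean")
    beta <- mean * (alpha - 1)
  }
  list(alpha = alpha, beta = beta, mean = beta / (alpha - 1))
}

#' Mean and coefficient of variation of an inverse-gamma distribution
#'
#' @param alpha Shape (> 2).
#' @param beta Scale.
#' @return Named numeric vector `c(mean =, cv =)`: mean `beta/(alpha-1)` and
#'   cv `1/sqrt(alpha-2)`.
#' @export
invgamma_mean_cv <- function(alpha, beta) {
  if (alpha <= 2) stop("mean and cv require alpha > 2")
  c(mean = beta / (alpha - 1), cv = 1 / sqrt(alpha - 2))
}

#' Coalescent log density with population sizes integrated out
#'
#' Closed-form marginal of the MSC density under a per-branch inverse-gamma
#' prior: for each branch,
#' `alpha*log(beta) - lgamma(alpha) + lgamma(alpha + n) -
#'  (alpha + n) * log(beta + gamma)`.
#' The formula is checked against adaptive quadrature of the one-dimensional
#' integral in the test suite.
#'
#' @param stats Sufficient statistics from [branch_coal_stats()].
#' @param prior An [invgamma_prior()].
#' @return Log marginal density summed over branches.
#' @export
integrated_coalescent_log_density <- function(stats, prior) {
  a <- prior$alpha; b <- prior$beta
  if (a <= 0 || b <= 0) stop("alpha and beta must be positive")
  sum(a * log(b) - lgamma(a) + lgamma(a + stats$n) -
        (a + stats$n) * log(b + stats$gamma))
}

#' Gamma prior on explicitly sampled population sizes
#'
#' The prior used when population sizes are estimated by MCMC rather than
#' integrated out: each branch size is Gamma with shape 2 and scale `mean/2`.
#'
#' @param pop_sizes Positive haploid branch population sizes.
#' @param mean Mean population size hyperparameter (> 0).
#' @return Log prior density.
#' @export
mcmc_popsize_log_prior <- function(pop_sizes, mean) {
  if (any(pop_sizes <= 0)) stop("population sizes must be positive")
  if (mean <= 0) stop("mean hyperparameter must be positive")
  sum(stats::dgamma(pop_sizes, shape = 2, scale = mean / 2, log = TRUE))
}

#' Birth-death parameters
#'
#' Parameterized by net diversification `d = lambda - mu` and extinction
#' fraction `f = mu / lambda`, the quantities estimated in inference.
#'
#' @param d Net diversification rate (> 0).
#' @param f Extinction fraction in `[0, 1)`; 0 gives a Yule process.
#' @return List with `d`, `f`, `lambda`, `mu`.
#' @export
birth_death_params <- function(d, f = 0) {
  if (d <= 0) stop("net diversification must be positive")
  if (f < 0 || f >= 1) stop("extinction fraction must be in [0, 1)")
  lambda <- d / (1 - f)
  list(d = d, f = f, lambda = lambda, mu = lambda * f)
}

# log(lambda * p1(t)) and log(1 - u(t)) for the conditioned reconstructed
# birth-death process; p1 is the probability a single lineage leaves exactly
# one sampled descendant after time t, u the CDF kernel of speciation times.
bd_log_p1 <- function(t, lambda, mu) {
  r <- lambda - mu
  log(lambda) + 2 * log(r) - r * t - 2 * log(lambda - mu * exp(-r * t))
}
bd_u <- function(t, lambda, mu) {
  r <- lambda - mu
  e <- exp(-r * t)
  lambda * (1 - e) / (lambda - mu * e)
}

#' Birth-death log density of species-tree node heights
#'
#' Density of the reconstructed birth-death process conditioned on the
#' number of extant tips, with a uniform prior on the (marginalized) origin
#' time: up to a height-independent constant,
#' `sum_i log(lambda * p1(t_i)) + log(1 - u(t_root)) - log(lambda)` over the
#' internal node heights `t_i`.  With `f = 0` this reduces to the Yule
#' density `sum_i log(lambda e^{-lambda t_i}) - lambda t_root`.  The same
#' law drives [simulate_birth_death_tree()], so prior sampling by MCMC under
#' this density is directly comparable to direct simulation.
#'
#' @param species_tree An ultrametric `mc_tree`.
#' @param params A [birth_death_params()] object.
#' @return Log density, normalized jointly over the labelled topology and
#'   the node heights: summing `exp` over all labelled topologies and
#'   integrating over admissible heights gives 1 (the topology part is
#'   uniform over ranked labelled histories, contributing the constant
#'   `2^(n-1) / (n-1)!`).
#' @export
birth_death_log_density <- function(species_tree, params) {
  lambda <- params$lambda; mu <- params$mu
  n <- species_tree$ntip
  internal <- (n + 1L):species_tree$nnode
  t <- species_tree$height[internal]
  troot <- species_tree$height[species_tree$root]
  r <- lambda - mu
  log1mu <- log(r) - r * troot - log(lambda - mu * exp(-r * troot))
  sum(bd_log_p1(t, lambda, mu)) + log1mu + (n - 1) * log(2) - lgamma(n)
}
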
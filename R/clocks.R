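# Clock models: strict, gene-tree relaxed (discretized UCLN/UCED), and the
# species tree relaxed clock.
#
# The species tree relaxed clock assigns one relative rate R to every
# species-tree branch.  A gene-tree branch accumulates expected
# substitutions at c * L * R inside each species branch it traverses (c the
# locus clock rate, L the time spent there), so its effective rate is the
# length-weighted average r = sum(c * L * R) / l.  The identity r * l =
# sum(c * L * R) holds exactly and is property-tested.

#' Discretize a mean-one rate distribution into quantile bins
#'
#' Rates are the distribution quantiles at probabilities `(i + 0.5) / n_bins`
#' for `i = 0..n_bins-1`, renormalized so their arithmetic mean is exactly 1.
#' The log-normal is parameterized with mean 1 in real space (meanlog =
#' `-sigma^2/2`); the exponential has mean 1 and no shape parameter.
#'
#' @param kind `"lognormal"` or `"exponential"`.
#' @param sigma Log-space standard deviation (log-normal only; >= 0).
#' @param n_bins Number of bins (>= 1).
#' @return Numeric vector of `n_bins` rates with mean exactly 1.
#' @export
discretize_rates <- function(kind = c("lognormal", "exponential"),
                             sigma = 0.3, n_bins = 100L) {
  kind <- match.arg(kind)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (kind == "lognormal" && sigma < 0) stop("sigma must be >= 0")
  p <- (seq_len(n_bins) - 0.5) / n_bins
  r <- switch(kind,
    lognormal = stats::qlnorm(p, meanlog = -sigma^2 / 2, sdlog = sigma),
    exponential = stats::qexp(p, rate = 1))
  r / mean(r)
}

#' Species rates container
#'
#' @param species_tree The species tree.
#' @param rates Relative rate per species-tree node (branch above it),
#'   length `2*ntip-1`; the root entry is the stem branch rate.
#' @return List of class `mc_species_rates`.
#' @export
species_rates <- function(species_tree, rates) {
  if (length(rates) != species_tree$nnode) stop("one rate per species branch")
  if (any(rates <= 0)) stop("rates must be positive")
  structure(list(rates = as.numeric(rates)), class = "mc_species_rates")
}

#' Gene-branch rate under the species tree relaxed clock
#'
#' Computes `r = sum(c * L * R) / l` for one embedded gene-tree branch.
#'
#' @param segments One element of an [embed_gene_tree()] embedding: list with
#'   `species` (species node ids) and `L` (time spent in each).
#' @param rates Per-species-branch relative rates (vector over species
#'   nodes, or an `mc_species_rates`).
#' @param c Locus clock rate (substitutions/site/time).
#' @return The branch rate `r`.
#' @export
species_clock_gene_branch_rate <- function(segments, rates, c = 1) {
  if (inherits(rates, "mc_species_rates")) rates <- rates$rates
  l <- sum(segments$L)
  if (l <= 0) stop("zero-length gene branch")
  sum(c * segments$L * rates[segments$species]) / l
}

#' Per-branch gene-tree rates under the species tree relaxed clock
#'
#' @param gene_tree Gene tree.
#' @param embedding Its [embed_gene_tree()] embedding.
#' @param rates Per-species-branch relative rates.
#' @param c Locus clock rate.
#' @return Numeric vector over gene-tree nodes (rate of the branch above
#'   each; `NA` for the gene root).
#' @export
species_clock_rates <- function(gene_tree, embedding, rates, c = 1) {
  if (inherits(rates, "mc_species_rates")) rates <- rates$rates
  out <- rep(NA_real_, gene_tree$nnode)
  for (v in seq_len(gene_tree$nnode)) {
    s <- embedding[[v]]
    if (is.null(s)) next
    out[v] <- sum(c * s$L * rates[s$species]) / sum(s$L)
  }
  out
}

#' Per-branch rates for a gene-tree relaxed clock
#'
#' Each gene-tree branch carries an integer category index into a
#' discretized mean-one rate distribution; its rate is
#' `c * discretize_rates(...)[category]`.
#'
#' @param categories Integer category per gene-tree node (branch above it);
#'   the root entry is ignored and may be `NA`.
#' @param c Locus clock rate.
#' @param kind,sigma,n_bins Passed to [discretize_rates()].  `n_bins`
#'   defaults to the number of categories supplied, the "one category per
#'   estimated branch rate" convention.
#' @return Numeric vector of branch rates (NA where `categories` is NA).
#' @export
gene_tree_relaxed_rates <- function(categories, c = 1,
                                    kind = "lognormal", sigma = 0.3,
                                    n_bins = NULL) {
  if (is.null(n_bins)) n_bins <- sum(!is.na(categories))
  bins <- discretize_rates(kind, sigma, n_bins)
  idx <- categories
  if (any(!is.na(idx) & (idx < 1L | idx > n_bins)))
    stop("rate category index out of range")
  out <- rep(NA_real_, length(idx))
  out[!is.na(idx)] <- c * bins[idx[!is.na(idx)]]
  out
}

#' Strict clock rates
#'
#' @param gene_tree Gene tree.
#' @param c Locus clock rate.
#' @return Rate `c` for every non-root gene-tree branch (`NA` at the root).
#' @export
strict_rates <- function(gene_tree, c = 1) {
  out <- rep(c, gene_tree$nnode)
  out[gene_tree$root] <- NA_real_
  out
}
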
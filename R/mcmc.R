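# Metropolis-Hastings kernel, state management, operator scheduling, trace
# logging, and convergence bookkeeping.
#
# The sampled state bundles the species tree, one gene tree per locus, the
# clock state (rate categories, locus clock rates), and hyperparameters
# (population-size mean, birth-death parameters).  Per-locus coalescent
# sufficient statistics and phylogenetic log likelihoods are cached and
# refreshed only for the components a proposal touches; cache coherence
# against a full recomputation is asserted periodically.

#' Build a run configuration
#'
#' @param loci List with one entry per locus: `list(alignment = <mc_alignment
#'   or NULL>, mapping = <named character vector>, model = <subst_model or
#'   NULL>, site_rates = <numeric>, ploidy = <scalar>)`.  `alignment = NULL`
#'   samples from the prior for that locus.
#' @param species Species tip labels (derived from the mappings if `NULL`).
#' @param clock One of `"strict"`, `"gt_ucln"`, `"gt_uced"`, `"st_ucln"`,
#'   `"st_uced"`.
#' @param clock_sigma Log-normal stdev of the relaxed clock (default 0.3).
#' @param clock_bins Number of discretized rate bins (default: number of
#'   estimated branch rates).
#' @param popsize_mode `"integrated"` (analytical inverse-gamma
#'   marginalization) or `"mcmc"` (explicit sizes under a Gamma(2) prior).
#' @param popsize_alpha Inverse-gamma shape for the integrated mode.
#' @param popsize_prior Prior for explicitly sampled sizes (`"mcmc"` mode):
#'   `"gamma"` (shape 2, scale mean/2) or `"invgamma"` (shape
#'   `popsize_alpha`, mean `pop_mean`; the conjugate form, used to verify
#'   the analytical integration by sampling equivalence).
#' @param pop_mean Initial population-size mean hyperparameter.
#' @param estimate_pop_mean Sample the mean (one-over-x prior truncated to
#'   `pop_mean_range`) or keep it fixed?
#' @param pop_mean_range Truncation range of the mean's prior.
#' @param tree_prior `"yule"` or `"birth_death"`.
#' @param bd_d,bd_f Initial net diversification and extinction fraction.
#' @param estimate_bd Sample `d` and `f`?
#' @param bd_d_range Truncation range of the one-over-x prior on `d`.
#' @param locus_rates Initial per-locus clock rates.
#' @param estimate_locus_rates Sample locus rates (mean-one constraint kept
#'   by delta-exchange moves, log-normal sigma 0.6 prior)?
#' @param locus_rate_sigma Stdev of the log-normal locus-rate prior.
#' @param estimate_species_topology Propose species topology changes?
#' @param estimate_species_heights Propose species node-height changes?
#'   (`FALSE` freezes the species tree entirely; used for conditional
#'   validation runs.)
#' @param concatenation Concatenation mode: no gene trees and no coalescent
#'   term; all loci are evaluated directly on the (single) species tree.
#' @param init_species Optional initial species tree (`mc_tree`).
#' @param chain_length Number of proposals.
#' @param sample_every Sampling interval (states).
#' @param operator_weights Named numeric vector overriding default weights.
#' @param debug Assert compatibility and cache coherence as the chain runs.
#' @param seed Integer seed.
#' @return A config list for [run_chain()].
#' @export
mcmc_config <- function(loci, species = NULL,
                        clock = "strict", clock_sigma = 0.3,
                        clock_bins = NULL,
                        popsize_mode = "integrated", popsize_alpha = 3,
                        popsize_prior = "gamma",
                        pop_mean = 0.01, estimate_pop_mean = TRUE,
                        pop_mean_range = c(1e-6, 10),
                        tree_prior = "yule", bd_d = 10, bd_f = 0,
                        estimate_bd = FALSE, bd_d_range = c(1e-3, 1e5),
                        locus_rates = NULL, estimate_locus_rates = FALSE,
                        locus_rate_sigma = 0.6,
                        estimate_species_topology = TRUE,
                        estimate_species_heights = TRUE,
                        concatenation = FALSE,
                        init_species = NULL,
                        chain_length = 10000L, sample_every = 10L,
                        operator_weights = NULL, debug = FALSE, seed = 1L) {
  if (is.null(species))
    species <- sort(unique(unlist(lapply(loci, function(l) unname(l$mapping)))))
  if (is.null(locus_rates)) locus_rates <- rep(1, length(loci))
  cfg <- list(loci = loci, species = species, clock = clock,
              clock_sigma = clock_sigma, clock_bins = clock_bins,
              popsize_mode = popsize_mode, popsize_alpha = popsize_alpha,
              popsize_prior = popsize_prior,
              pop_mean = pop_mean, estimate_pop_mean = estimate_pop_mean,
              pop_mean_range = pop_mean_range,
              tree_prior = tree_prior, bd_d = bd_d, bd_f = bd_f,
              estimate_bd = estimate_bd, bd_d_range = bd_d_range,
              locus_rates = locus_rates,
              estimate_locus_rates = estimate_locus_rates,
              locus_rate_sigma = locus_rate_sigma,
              estimate_species_topology = estimate_species_topology,
              estimate_species_heights = estimate_species_heights,
              concatenation = concatenation, init_species = init_species,
              chain_length = as.integer(chain_length),
              sample_every = as.integer(sample_every),
              operator_weights = operator_weights, debug = debug,
              seed = as.integer(seed))
  cfg
}

#' Initialize an MCMC state from a configuration
#'
#' Builds the initial species tree (simulated from the tree prior unless
#' supplied), simulates compatible initial gene trees under the coalescent,
#' and precomputes per-locus static data (tip partial likelihoods, species
#' ids, pattern weights).
#'
#' @param config From [mcmc_config()].
#' @return An `mcmc_state` list.
#' @export
init_state <- function(config) {
  species_labels <- config$species
  if (!is.null(config$init_species)) sp <- config$init_species
  else sp <- simulate_birth_death_tree(
    length(species_labels), config$bd_d / (1 - config$bd_f),
    config$bd_d / (1 - config$bd_f) * config$bd_f,
    tip_label = species_labels)
  if (config$popsize_mode == "mcmc" && any(is.na(sp$popsize)))
    sp$popsize <- rep(config$pop_mean, sp$nnode)
  state <- list(species = sp, genes = list(), data = list(),
                locus_rates = config$locus_rates,
                pop_mean = config$pop_mean,
                birth_d = config$bd_d, birth_f = config$bd_f,
                sp_categories = NULL, gene_categories = NULL,
                config = config)
  nbins <- config$clock_bins
  if (startsWith(config$clock, "st_")) {
    if (is.null(nbins)) nbins <- sp$nnode - 1L  # one per non-root branch
    state$sp_categories <- rep(NA_integer_, sp$nnode)
    nonroot <- which(sp$parent != 0L)
    state$sp_categories[nonroot] <- sample.int(nbins, length(nonroot), TRUE)
  }
  for (k in seq_along(config$loci)) {
    l <- config$loci[[k]]
    if (config$concatenation) {
      gt <- NULL
      taxa_tree <- sp
      tip_sp <- seq_len(sp$ntip)
    } else {
      mapping <- l$mapping
      counts <- table(factor(unname(mapping), levels = species_labels))
      gt <- simulate_msc_gene_tree(sp, stats::setNames(as.integer(counts),
                                                       species_labels),
                                   pop_sizes = rep(state$pop_mean, sp$nnode))
      # relabel the simulated haplotypes with the real ones, per species
      for (s in species_labels) {
        real <- names(mapping)[unname(mapping) == s]
        gt$tip_label[gt$tip_label %in% paste0(s, "_", seq_along(real))] <- real
      }
      taxa_tree <- gt
      tip_sp <- tip_species_ids(gt, sp, mapping)
      state$genes[[k]] <- gt
    }
    dat <- list(mapping = if (config$concatenation) NULL else l$mapping,
                tip_sp = tip_sp,
                model = l$model,
                site_rates = if (is.null(l$site_rates)) 1 else l$site_rates,
                ploidy = if (is.null(l$ploidy)) 1 else l$ploidy,
                tip_partials = NULL, weights = NULL)
    if (!is.null(l$alignment)) {
      comp <- site_pattern_compress(l$alignment)
      ord <- match(taxa_tree$tip_label, l$alignment$taxa)
      if (anyNA(ord)) stop("alignment taxa do not match tree tips (locus ", k, ")")
      dat$tip_partials <- tip_partials(comp$patterns[ord, , drop = FALSE])
      dat$weights <- comp$weights
    }
    state$data[[k]] <- dat
  }
  if (startsWith(config$clock, "gt_")) {
    if (is.null(nbins)) nbins <- 2L * state$genes[[1]]$ntip - 2L
    state$gene_categories <- lapply(state$genes, function(gt) {
      cats <- rep(NA_integer_, gt$nnode)
      nonroot <- which(gt$parent != 0L)
      cats[nonroot] <- sample.int(nbins, length(nonroot), TRUE)
      cats
    })
  }
  state$config$clock_bins <- nbins
  if (config$clock != "strict") state$bins <- clock_bins(state$config)
  class(state) <- "mcmc_state"
  refresh_cache(state, list(species = TRUE, loci = "all"))
}

# ---- compatibility helpers (used by operators) ----------------------------

locus_compatible <- function(state, k) {
  gt <- state$genes[[k]]
  m <- gene_node_species_mrca(gt, state$species, state$data[[k]]$tip_sp)
  internal <- (gt$ntip + 1L):gt$nnode
  all(gt$height[internal] >= state$species$height[m[internal]])
}

state_compatible <- function(state) {
  for (k in seq_along(state$genes))
    if (!locus_compatible(state, k)) return(FALSE)
  TRUE
}

# ---- density evaluation with caching --------------------------------------

# Discretized clock bins for the current config.
clock_bins <- function(config) {
  kind <- if (endsWith(config$clock, "uced")) "exponential" else "lognormal"
  discretize_rates(kind, config$clock_sigma, config$clock_bins)
}

# Per-branch substitution rates for locus k under the configured clock.
locus_branch_rates <- function(state, k, embedding = NULL) {
  cfg <- state$config
  c_k <- state$locus_rates[k]
  if (cfg$concatenation) {
    # rates live on the species tree itself
    if (startsWith(cfg$clock, "st_")) {
      bins <- if (!is.null(state$bins)) state$bins else clock_bins(cfg)
      r <- rep(NA_real_, state$species$nnode)
      idx <- !is.na(state$sp_categories)
      r[idx] <- c_k * bins[state$sp_categories[idx]]
      return(r)
    }
    return(rep(c_k, state$species$nnode))
  }
  gt <- state$genes[[k]]
  if (cfg$clock == "strict") return(strict_rates(gt, c_k))
  if (startsWith(cfg$clock, "gt_")) {
    bins <- if (!is.null(state$bins)) state$bins else clock_bins(cfg)
    r <- rep(NA_real_, gt$nnode)
    idx <- !is.na(state$gene_categories[[k]])
    r[idx] <- c_k * bins[state$gene_categories[[k]][idx]]
    return(r)
  }
  # species tree relaxed clock
  bins <- if (!is.null(state$bins)) state$bins else clock_bins(cfg)
  sprate <- rep(1, state$species$nnode)
  idx <- !is.na(state$sp_categories)
  sprate[idx] <- bins[state$sp_categories[idx]]
  if (is.null(embedding))
    embedding <- embed_gene_tree(gt, state$species, state$data[[k]]$mapping)
  species_clock_rates(gt, embedding, sprate, c_k)
}

# Recompute the cached quantities for one locus.
locus_cache <- function(state, k) {
  cfg <- state$config
  dat <- state$data[[k]]
  emb <- NULL; stats <- NULL
  if (!cfg$concatenation) {
    gt <- state$genes[[k]]
    emb <- embed_gene_tree(gt, state$species, dat$mapping)
    stats <- coal_stats_from_embedding(emb, gt, state$species)
  }
  loglik <- 0
  if (!is.null(dat$tip_partials)) {
    tr <- if (cfg$concatenation) state$species else state$genes[[k]]
    rates <- locus_branch_rates(state, k, emb)
    loglik <- pruning_log_likelihood(tr, rates, dat$model, dat$site_rates,
                                     dat$tip_partials, dat$weights)
  }
  list(stats = stats, loglik = loglik)
}

# Aggregate the cheap global components from the cached per-locus pieces.
aggregate_posterior <- function(state) {
  cfg <- state$config
  sp <- state$species
  loglik <- sum(vapply(state$cache$locus, function(x) x$loglik, 0))
  coal <- 0
  if (!cfg$concatenation && length(state$genes)) {
    nb <- 0; gb <- 0
    for (k in seq_along(state$genes)) {
      nb <- nb + state$cache$locus[[k]]$stats$n
      gb <- gb + state$cache$locus[[k]]$stats$gamma / state$data[[k]]$ploidy
    }
    if (cfg$popsize_mode == "integrated") {
      prior <- invgamma_prior(cfg$popsize_alpha, mean = state$pop_mean)
      coal <- integrated_coalescent_log_density(list(n = nb, gamma = gb), prior)
    } else {
      coal <- sum(-nb * log(sp$popsize) - gb / sp$popsize)
      if (identical(cfg$popsize_prior, "invgamma")) {
        a <- cfg$popsize_alpha; b <- (a - 1) * state$pop_mean
        coal <- coal + sum(a * log(b) - lgamma(a) -
                             (a + 1) * log(sp$popsize) - b / sp$popsize)
      } else {
        coal <- coal + mcmc_popsize_log_prior(sp$popsize, state$pop_mean)
      }
    }
  }
  params <- birth_death_params(state$birth_d, state$birth_f)
  treeprior <- birth_death_log_density(sp, params)
  other <- 0
  if (isTRUE(cfg$estimate_locus_rates))
    other <- other + sum(stats::dlnorm(state$locus_rates,
                                       -cfg$locus_rate_sigma^2 / 2,
                                       cfg$locus_rate_sigma, log = TRUE))
  if (isTRUE(cfg$estimate_pop_mean)) other <- other - log(state$pop_mean)
  if (isTRUE(cfg$estimate_bd)) other <- other - log(state$birth_d)
  list(loglik = loglik, coal = coal, treeprior = treeprior, other = other,
       logpost = loglik + coal + treeprior + other)
}

# Refresh the cache after a proposal touching the given components.
refresh_cache <- function(state, touched) {
  if (is.null(state$cache)) state$cache <- list(locus = vector("list",
                                                length(state$data)))
  loci <- touched$loci
  if (identical(loci, "all") || isTRUE(touched$species))
    loci <- seq_along(state$data)
  if (!identical(loci, "coal") && length(loci))
    for (k in loci) state$cache$locus[[k]] <- locus_cache(state, k)
  stale <- which(vapply(state$cache$locus, is.null, TRUE))
  for (k in stale) state$cache$locus[[k]] <- locus_cache(state, k)
  state$cache$agg <- aggregate_posterior(state)
  state
}

#' Log posterior of a state
#'
#' @param state An `mcmc_state`.
#' @param fresh Recompute everything, ignoring the cache.
#' @return The total log posterior (data log likelihood + coalescent term +
#'   tree prior + hyperpriors).
#' @export
log_posterior <- function(state, fresh = FALSE) {
  if (fresh || is.null(state$cache))
    state <- refresh_cache(state, list(species = TRUE, loci = "all"))
  state$cache$agg$logpost
}

#' One Metropolis-Hastings step
#'
#' @param state Current `mcmc_state` (with cache).
#' @param op_fun Operator: `function(state) -> proposal`.
#' @return List `(state, accepted, proposal)`; invalid proposals are
#'   rejected without evaluating the posterior.
#' @export
mh_step <- function(state, op_fun) {
  cur <- state$cache$agg$logpost
  if (!is.finite(cur)) stop("non-finite posterior at current state")
  prop <- op_fun(state)
  if (!prop$valid) return(list(state = state, accepted = FALSE, proposal = prop))
  new_state <- prop$state
  new_state$cache <- state$cache
  new_state <- refresh_cache(new_state, prop$touched)
  delta <- new_state$cache$agg$logpost - cur + prop$log_hr
  if (is.finite(delta) && log(stats::runif(1)) < delta)
    list(state = new_state, accepted = TRUE, proposal = prop)
  else
    list(state = state, accepted = FALSE, proposal = prop)
}

# Default operator schedule for a configuration.
build_operators <- function(config, n_loci) {
  has_genes <- !config$concatenation && n_loci > 0L
  sp_heights <- !identical(config$estimate_species_heights, FALSE)
  w <- c(
    coordinated_uniform = if (sp_heights && length(config$species) >= 3L) 12 else 0,
    coordinated_exponential = if (sp_heights) 4 else 0,
    coordinated_exchange_nni =
      if (config$estimate_species_topology && length(config$species) >= 3L) 8 else 0,
    coordinated_exchange_spr =
      if (config$estimate_species_topology && length(config$species) >= 4L) 4 else 0,
    species_nni =
      if (config$estimate_species_topology && length(config$species) >= 3L) 4 else 0,
    scale_species = if (sp_heights) 3 else 0,
    scale_all = if (sp_heights) 3 else 0,
    scale_gene = if (has_genes) 6 else 0,
    uniform_height = 15,
    root_height = 6,
    gene_nni = if (has_genes) 10 else 0,
    gene_wilson_balding = if (has_genes) 8 else 0,
    rate_category = if (config$clock != "strict") 10 else 0,
    locus_rate_delta =
      if (isTRUE(config$estimate_locus_rates) && n_loci >= 2L) 5 else 0,
    pop_mean = if (isTRUE(config$estimate_pop_mean) && has_genes) 4 else 0,
    popsize = if (config$popsize_mode == "mcmc" && has_genes) 8 else 0,
    bd_params = if (isTRUE(config$estimate_bd)) 4 else 0)
  if (!is.null(config$operator_weights)) {
    ow <- config$operator_weights
    w[names(ow)] <- ow
  }
  w[w > 0]
}

# Dispatch an operator by name (lambda_ce is the adapted exponential rate).
apply_operator <- function(name, state, lambda_ce) {
  switch(name,
    coordinated_uniform = coordinated_uniform_propose(state),
    coordinated_exponential = coordinated_exponential_propose(state, lambda_ce),
    coordinated_exchange_nni = coordinated_exchange_propose(state, "nni"),
    coordinated_exchange_spr = coordinated_exchange_propose(state, "spr"),
    species_nni = species_nni_propose(state),
    scale_species = scale_species_propose(state),
    scale_all = scale_all_trees_propose(state),
    scale_gene = scale_gene_propose(state),
    uniform_height = uniform_height_propose(state),
    root_height = root_height_propose(state),
    gene_nni = gene_nni_propose(state),
    gene_wilson_balding = gene_wilson_balding_propose(state),
    rate_category = rate_category_propose(state),
    locus_rate_delta = locus_rate_delta_propose(state),
    pop_mean = pop_mean_propose(state),
    popsize = popsize_propose(state),
    bd_params = bd_params_propose(state),
    stop("unknown operator: ", name))
}

#' Run an MCMC chain
#'
#' Runs `chain_length` Metropolis-Hastings proposals, drawing operators with
#' probability proportional to their weights, and records the standard trace
#' statistics (posterior, likelihood, prior, coalescent term, tree-prior
#' term, net diversification, extinction fraction, population-size mean,
#' species-tree height) plus sampled trees every `sample_every` states.
#' Fully reproducible for a given seed.  The exponential root operator's
#' rate starts from the initial state's root-bound gap and is re-adapted
#' every 20 of its proposals during the first 25% of the chain from the
#' running mean of the gap, then frozen (diminishing adaptation).
#'
#' @param config From [mcmc_config()].
#' @param state Optional initial state (default: [init_state()]).
#' @param out_prefix If non-`NULL`, write `<prefix>.trace.tsv` and
#'   `<prefix>.species.trees` (annotated Newick, one per sample).
#' @return An `mcmc_run`: list with `trace` (data frame), `species_trees`,
#'   `gene_trees` (compact per-sample copies), `acceptance` (per-operator
#'   rates), `state` (final), `config`, `lambda_ce`.
#' @export
run_chain <- function(config, state = NULL, out_prefix = NULL) {
  set.seed(config$seed)
  if (is.null(state)) state <- init_state(config)
  weights <- build_operators(config, length(config$loci))
  opnames <- names(weights)
  nprop <- config$chain_length
  nsamp <- nprop %/% config$sample_every + 1L
  trace <- matrix(NA_real_, nsamp, 10)
  colnames(trace) <- c("state", "posterior", "likelihood", "prior",
                       "coalescent", "treeprior", "netdiversification",
                       "extinctionfraction", "popmean", "speciesheight")
  species_trees <- vector("list", nsamp)
  gene_trees <- vector("list", nsamp)
  locus_rate_samples <- vector("list", nsamp)
  n_acc <- stats::setNames(numeric(length(opnames)), opnames)
  n_try <- n_acc
  # seed the exponential-root proposal rate from the initial state's
  # root-bound gap so short chains start in the right regime
  lambda_ce <- local({
    comp <- select_connected_component(state, state$species$root)
    b <- compute_shift_bounds(state, state$species$root, comp)
    x0 <- unname(state$species$height[state$species$root] - b[1])
    if (x0 > 0) adapt_exponential_rate(x0) else 1
  })
  x_sum <- 0; x_n <- 0L
  adapt_until <- max(1L, as.integer(0.25 * nprop))
  record <- function(i, step) {
    agg <- state$cache$agg
    trace[i, ] <<- c(step, agg$logpost, agg$loglik, agg$logpost - agg$loglik,
                     agg$coal, agg$treeprior,
                     state$birth_d, state$birth_f, state$pop_mean,
                     state$species$height[state$species$root])
    sp <- state$species
    if (startsWith(config$clock, "st_")) {
      r <- rep(1, sp$nnode)
      idx <- !is.na(state$sp_categories)
      r[idx] <- state$bins[state$sp_categories[idx]]
      sp$rate <- r
    }
    species_trees[[i]] <<- sp
    gene_trees[[i]] <<- lapply(state$genes, function(g)
      list(parent = g$parent, height = g$height, ntip = g$ntip,
           tip_label = g$tip_label))
    locus_rate_samples[[i]] <<- state$locus_rates
  }
  record(1L, 0L)
  si <- 1L
  draws <- sample.int(length(weights), nprop, replace = TRUE,
                      prob = weights / sum(weights))
  for (step in seq_len(nprop)) {
    nm <- opnames[draws[step]]
    res <- mh_step(state, function(s) apply_operator(nm, s, lambda_ce))
    n_try[nm] <- n_try[nm] + 1
    if (res$accepted) n_acc[nm] <- n_acc[nm] + 1
    state <- res$state
    if (nm == "coordinated_exponential" && !is.null(attr(res$proposal, "x"))) {
      x_sum <- x_sum + attr(res$proposal, "x"); x_n <- x_n + 1L
      if (step <= adapt_until && x_n %% 20L == 0L)
        lambda_ce <- adapt_exponential_rate(x_sum / x_n)
    }
    if (step %% config$sample_every == 0L) {
      si <- si + 1L
      record(si, step)
      if (isTRUE(config$debug)) {
        stopifnot(state_compatible(state))
        fresh <- log_posterior(state, fresh = TRUE)
        stopifnot(abs(fresh - state$cache$agg$logpost) < 1e-8)
      }
    }
  }
  trace <- as.data.frame(trace[seq_len(si), , drop = FALSE])
  run <- structure(list(trace = trace,
                        species_trees = species_trees[seq_len(si)],
                        gene_trees = gene_trees[seq_len(si)],
                        locus_rate_samples = locus_rate_samples[seq_len(si)],
                        acceptance = ifelse(n_try > 0, n_acc / n_try, NA),
                        proposals = n_try,
                        state = state, config = config,
                        lambda_ce = lambda_ce), class = "mcmc_run")
  if (!is.null(out_prefix)) write_run(run, out_prefix)
  run
}

#' Write trace and tree logs
#'
#' Trace as tab-separated text with one row per sample; species trees as
#' annotated Newick, one per line.
#'
#' @param run An `mcmc_run`.
#' @param prefix Output path prefix.
#' @export
write_run <- function(run, prefix) {
  utils::write.table(run$trace, paste0(prefix, ".trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(paste0(prefix, ".species.trees"), "w")
  on.exit(close(con))
  for (tr in run$species_trees)
    writeLines(write_annotated_newick(tr), con)
  invisible(prefix)
}

#' Effective sample size
#'
#' Initial-positive-sequence (Geyer) estimator: autocorrelations are summed
#' in consecutive pairs until a pair sum goes non-positive, giving the
#' integrated autocorrelation time; ESS = n / IAT.  White noise of length n
#' returns approximately n; a constant series returns 0 with a warning.
#'
#' @param series Numeric vector (>= 10 samples).
#' @return The effective sample size.
#' @export
effective_sample_size <- function(series) {
  n <- length(series)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::var(series) == 0) {
    warning("constant series: ESS undefined, returning 0")
    return(0)
  }
  rho <- stats::acf(series, lag.max = min(n - 1L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  iat <- 0
  m <- 0L
  while (2L * m + 1L < length(rho)) {
    p <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (p <= 0) break
    iat <- iat + 2 * p
    m <- m + 1L
  }
  iat <- max(1, iat - 1)  # rho[lag 0] counted twice
  n / iat
}

#' Discard burn-in from a trace
#'
#' @param trace Data frame of samples.
#' @param fraction Fraction to discard (default 0.125); the first
#'   `ceiling(fraction * nrow)` rows are dropped.
#' @return The trimmed trace.
#' @export
burn_in_filter <- function(trace, fraction = 0.125) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  drop <- ceiling(fraction * nrow(trace))
  if (drop == 0L) return(trace)
  trace[-seq_len(drop), , drop = FALSE]
}

#' Run-until-converged protocol
#'
#' Checks the minimum ESS over all recorded statistics after discarding
#' 12.5% burn-in; while below the threshold, doubles the chain length
#' (resuming from the final state) and halves the sampling rate so the
#' number of retained samples stays roughly constant.  Stops at
#' `max_doublings` and reports without raising.
#'
#' @param run An `mcmc_run`.
#' @param ess_threshold Minimum acceptable ESS (default 200).
#' @param max_doublings Cap on doublings.
#' @param statistics Trace columns to monitor (default: all varying ones).
#' @return A list `(run, ess, converged, doublings)`.
#' @export
convergence_protocol <- function(run, ess_threshold = 200, max_doublings = 3L,
                                 statistics = NULL) {
  min_ess <- function(r) {
    tr <- burn_in_filter(r$trace, 0.125)
    cols <- statistics
    if (is.null(cols)) {
      cols <- setdiff(colnames(tr), "state")
      cols <- cols[vapply(cols, function(cc) stats::var(tr[[cc]]) > 0, TRUE)]
    }
    if (!length(cols)) return(Inf)
    min(vapply(cols, function(cc) effective_sample_size(tr[[cc]]), 0))
  }
  doublings <- 0L
  total <- run$config$chain_length
  ess <- min_ess(run)
  while (ess < ess_threshold && doublings < max_doublings) {
    # resume for as many states again (total length doubles) at a doubled
    # sampling interval; the earlier samples are thinned by two so the
    # retained sample count stays roughly constant
    cfg <- run$config
    cfg$chain_length <- total
    cfg$sample_every <- max(1L, run$config$sample_every * 2L)
    cfg$seed <- run$config$seed + 1000L * (doublings + 1L)
    ext <- run_chain(cfg, state = run$state)
    keep <- seq(1, nrow(run$trace), by = 2L)
    ext$trace$state <- ext$trace$state + total
    run <- structure(list(
      trace = rbind(run$trace[keep, , drop = FALSE], ext$trace[-1, , drop = FALSE]),
      species_trees = c(run$species_trees[keep], ext$species_trees[-1]),
      gene_trees = c(run$gene_trees[keep], ext$gene_trees[-1]),
      locus_rate_samples = c(run$locus_rate_samples[keep],
                             ext$locus_rate_samples[-1]),
      acceptance = ext$acceptance, proposals = ext$proposals,
      state = ext$state, config = cfg,
      lambda_ce = ext$lambda_ce), class = "mcmc_run")
    total <- total * 2L
    doublings <- doublings + 1L
    ess <- min_ess(run)
  }
  list(run = run, ess = ess, converged = ess >= ess_threshold,
       doublings = doublings)
}
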
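test_that("chains are bit-reproducible for a fixed seed", {
  cfg <- prior_config(4, 2, chain_length = 2000L, sample_every = 20L,
                      seed = 11)
  r1 <- run_chain(cfg)
  r2 <- run_chain(cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$species_trees[[50]], r2$species_trees[[50]])
  r3 <- run_chain(prior_config(4, 2, chain_length = 2000L,
                               sample_every = 20L, seed = 12))
  expect_false(identical(r1$trace$posterior, r3$trace$posterior))
})

test_that("operators are drawn proportionally to their weights", {
  cfg <- prior_config(4, 1, chain_length = 20000L, sample_every = 1000L,
                      seed = 13,
                      operator_weights = c(coordinated_uniform = 3,
                                           uniform_height = 1,
                                           coordinated_exponential = 0,
                                           coordinated_exchange_nni = 0,
                                           coordinated_exchange_spr = 0,
                                           species_nni = 0, scale_species = 0,
                                           scale_all = 0, scale_gene = 0,
                                           root_height = 0, gene_nni = 0,
                                           gene_wilson_balding = 0))
  run <- run_chain(cfg)
  frac <- run$proposals[["coordinated_uniform"]] / sum(run$proposals)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 20000))
})

test_that("metropolis-hastings accepts and rejects per the rule", {
  cfg <- prior_config(4, 1, seed = 17)
  set.seed(17)
  state <- init_state(cfg)
  # identity proposal with log HR 0 is always accepted
  ident <- function(s) mscoal:::proposal(s, log_hr = 0,
                                         touched = list(species = FALSE,
                                                        loci = integer(0)))
  for (i in 1:10) expect_true(mh_step(state, ident)$accepted)
  # invalid proposals (zero-probability moves) are rejected outright
  bad <- function(s) mscoal:::invalid_proposal()
  expect_false(mh_step(state, bad)$accepted)
  # a proposal with log HR -Inf can never be accepted
  sink <- function(s) mscoal:::proposal(s, log_hr = -Inf,
                                        touched = list(species = FALSE,
                                                       loci = integer(0)))
  for (i in 1:10) expect_false(mh_step(state, sink)$accepted)
})

test_that("the sampler targets the exact prior on a two-species state", {
  # single-operator check of the MH rule: only root-height moves, exact
  # birth-death target for the species root
  cfg <- prior_config(2, 1, chain_length = 40000L, sample_every = 20L,
                      seed = 19,
                      operator_weights = c(root_height = 2, scale_all = 1,
                                           coordinated_exponential = 0,
                                           scale_species = 0,
                                           scale_gene = 1, uniform_height = 0,
                                           gene_nni = 0,
                                           gene_wilson_balding = 0))
  run <- run_chain(cfg)
  hts <- burn_in_filter(run$trace, 0.125)$speciesheight
  set.seed(20)
  direct <- replicate(4000, {
    tr <- simulate_birth_death_tree(2, 200, 100)
    tr$height[tr$root]
  })
  ess <- effective_sample_size(hts)
  idx <- seq(1, length(hts), by = max(1, ceiling(3 * length(hts) / ess)))
  expect_gt(stats::ks.test(hts[idx], direct)$p.value, 0.01)
})

test_that("cached posteriors stay coherent with fresh recomputation", {
  set.seed(23)
  pair <- random_msc_pair(4, 2, birth = 20, death = 0, pop_scale = 0.05)
  model <- subst_model("HKY", kappa = 3)
  emb <- embed_gene_tree(pair$gene, pair$species, pair$mapping)
  aln <- simulate_alignment(pair$gene,
                            species_clock_rates(pair$gene, emb,
                                                rep(1, pair$species$nnode), 1),
                            model, length = 120)
  loci <- list(list(alignment = aln, mapping = pair$mapping, model = model,
                    site_rates = site_rate_categories(4, 0.3)))
  # debug mode asserts |cached - fresh| < 1e-8 at every sample
  cfg <- mcmc_config(loci, clock = "st_ucln", clock_sigma = 0.3,
                     popsize_mode = "integrated", pop_mean = 0.02,
                     estimate_pop_mean = TRUE,
                     tree_prior = "birth_death", bd_d = 20, bd_f = 0,
                     estimate_bd = TRUE, estimate_locus_rates = FALSE,
                     chain_length = 800L, sample_every = 10L,
                     debug = TRUE, seed = 29)
  expect_error(run_chain(cfg), NA)
  # explicit population-size mode exercises the other coalescent path
  cfg2 <- mcmc_config(loci, clock = "gt_ucln", popsize_mode = "mcmc",
                      pop_mean = 0.02, estimate_pop_mean = TRUE,
                      tree_prior = "birth_death", bd_d = 20, bd_f = 0,
                      chain_length = 600L, sample_every = 10L,
                      debug = TRUE, seed = 31)
  expect_error(run_chain(cfg2), NA)
})

test_that("effective sample size behaves on iid, AR(1) and constant input", {
  set.seed(37)
  x <- rnorm(10000)
  ess <- effective_sample_size(x)
  expect_gt(ess, 8000); expect_lt(ess, 12000)
  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), 20000))
  expected <- 20000 * (1 - rho) / (1 + rho)
  expect_lt(abs(effective_sample_size(ar) - expected) / expected, 0.25)
  expect_warning(ess0 <- effective_sample_size(rep(1, 100)), "constant")
  expect_equal(ess0, 0)
  expect_error(effective_sample_size(1:5), "at least 10")
  # agreement with an independent implementation on correlated input
  expect_lt(abs(effective_sample_size(ar) -
                  unname(coda::effectiveSize(ar))) / expected, 0.4)
})

test_that("burn-in filtering drops the documented row counts", {
  tr <- data.frame(x = 1:800)
  expect_equal(nrow(burn_in_filter(tr, 0.125)), 700)
  expect_equal(burn_in_filter(tr, 0), tr)
  expect_equal(nrow(burn_in_filter(data.frame(x = 1:9), 0.125)), 7)
  expect_error(burn_in_filter(tr, 1), "fraction")
})

test_that("convergence protocol doubles until the ESS threshold is met", {
  cfg <- prior_config(3, 1, chain_length = 3000L, sample_every = 10L,
                      seed = 41)
  run <- run_chain(cfg)
  # already converged at a tiny threshold: no-op
  res <- convergence_protocol(run, ess_threshold = 5, max_doublings = 2)
  expect_true(res$converged)
  expect_equal(res$doublings, 0L)
  # unreachable threshold: stops at the cap and reports without raising
  res2 <- convergence_protocol(run, ess_threshold = 1e6, max_doublings = 1)
  expect_false(res2$converged)
  expect_equal(res2$doublings, 1L)
  expect_gt(max(res2$run$trace$state), 3000)
  # sample spacing doubles so the retained count stays roughly constant
  expect_lt(nrow(res2$run$trace), 1.2 * nrow(run$trace))
})

test_that("prior sampling with empty data equals prior sampling", {
  # a locus with a zero-information alignment (all N) must not move the
  # posterior away from the prior
  labs <- paste0("s", 1:3)
  m <- stats::setNames(labs, paste0(labs, "_1"))
  aln <- alignment(stats::setNames(rep(strrep("N", 10), 3), names(m)))
  loci_flat <- list(list(alignment = aln, mapping = m,
                         model = subst_model("JC")))
  loci_none <- list(list(alignment = NULL, mapping = m))
  base <- list(clock = "strict", popsize_mode = "integrated",
               pop_mean = 0.002, estimate_pop_mean = FALSE,
               tree_prior = "birth_death", bd_d = 100, bd_f = 0.5,
               estimate_bd = FALSE, chain_length = 9000L,
               sample_every = 8L, seed = 43)
  r1 <- run_chain(do.call(mcmc_config, c(list(loci = loci_flat), base)))
  r2 <- run_chain(do.call(mcmc_config, c(list(loci = loci_none), base)))
  h1 <- burn_in_filter(r1$trace, 0.125)$speciesheight
  h2 <- burn_in_filter(r2$trace, 0.125)$speciesheight
  expect_gt(stats::ks.test(h1, h2)$p.value, 0.01)
  expect_true(all(abs(r1$trace$likelihood) < 1e-10))
})

test_that("trace and tree logs are written in the documented format", {
  cfg <- prior_config(3, 1, chain_length = 300L, sample_every = 30L, seed = 47)
  run <- run_chain(cfg)
  prefix <- file.path(tempdir(), "runlog")
  write_run(run, prefix)
  tr <- utils::read.delim(paste0(prefix, ".trace.tsv"))
  expect_equal(colnames(tr),
               c("state", "posterior", "likelihood", "prior", "coalescent",
                 "treeprior", "netdiversification", "extinctionfraction",
                 "popmean", "speciesheight"))
  expect_equal(nrow(tr), 300 / 30 + 1)
  trees <- readLines(paste0(prefix, ".species.trees"))
  expect_equal(length(trees), nrow(tr))
  expect_error(read_annotated_newick(trees[1]), NA)
})

test_that("credible intervals cover simulated truth at nominal rates", {
  # parameter-recovery smoke test: 95% HPDs for the species-tree height and
  # the per-locus clock rates, pooled over 20 replicates, cover truth at
  # least 90% of the time.  Truth is drawn from the model's own priors
  # (locus rates from the mean-constrained lognormal, by rejection) so
  # nominal coverage applies.
  covered <- 0L; total <- 0L
  for (rep_i in 1:20) {
    set.seed(500 + rep_i)
    labs <- paste0("s", 1:3)
    sp <- simulate_birth_death_tree(3, 100, 30, tip_label = labs)
    sp$popsize <- rgamma(sp$nnode, shape = 2, scale = 0.002)
    repeat {
      rates <- rlnorm(3, -0.18, 0.6)
      if (abs(mean(rates) - 1) < 0.01) break
    }
    rates <- rates / mean(rates)
    jc <- subst_model("JC")
    loci <- lapply(1:3, function(k) {
      gt <- simulate_msc_gene_tree(sp, 2)
      aln <- simulate_alignment(gt, rates[k], jc, length = 60)
      list(alignment = aln, mapping = attr(gt, "mapping"), model = jc)
    })
    cfg <- mcmc_config(loci, species = labs, clock = "strict",
                       popsize_mode = "integrated", pop_mean = 0.004,
                       estimate_pop_mean = TRUE, pop_mean_range = c(1e-5, 1),
                       tree_prior = "birth_death", bd_d = 70, bd_f = 0.3,
                       estimate_bd = FALSE, estimate_locus_rates = TRUE,
                       operator_weights = c(locus_rate_delta = 20),
                       chain_length = 10000L, sample_every = 10L,
                       seed = 600 + rep_i)
    run <- run_chain(cfg)
    # run until the height series has enough effectively independent
    # samples for a stable 95% interval
    run <- convergence_protocol(run, ess_threshold = 120, max_doublings = 2,
                                statistics = "speciesheight")$run
    tr <- burn_in_filter(run$trace, 0.125)
    hh <- hpd_interval(tr$speciesheight)
    truth_h <- sp$height[sp$root]
    covered <- covered + (truth_h >= hh[1] && truth_h <= hh[2])
    total <- total + 1L
    keep <- seq(ceiling(0.125 * nrow(run$trace)) + 1, nrow(run$trace))
    for (k in 1:3) {
      rk <- vapply(run$locus_rate_samples[keep], function(x) x[k], 0)
      ci <- hpd_interval(rk)
      covered <- covered + (rates[k] >= ci[1] && rates[k] <= ci[2])
      total <- total + 1L
    }
  }
  expect_gte(covered / total, 0.9)
})
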
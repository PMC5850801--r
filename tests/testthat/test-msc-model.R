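test_that("coalescent density matches hand-evaluated single-interval cases", {
  # one species, two lineages, N = 1, coalescence at 0.3: log density -0.3
  sp <- mc_tree(parent = c(0), height = 0, tip_label = "A")
  sp$popsize <- 1
  gt <- mc_tree(parent = c(3, 3, 0), height = c(0, 0, 0.3),
                tip_label = c("a", "b"))
  expect_equal(coalescent_log_density(gt, sp, c(a = "A", b = "A")), -0.3)
  # two-species state: one interval of length 0.5 in the root stem
  st <- fig1_state(T1 = 1.0, t1 = 1.5)
  st$species$popsize <- c(1, 1, 0.004)
  expect_equal(coalescent_log_density(st$gene, st$species, st$mapping),
               -log(0.004) - 0.5 / 0.004)
})

test_that("coalescent density matches an independent interval-sweep oracle", {
  set.seed(21)
  for (i in 1:25) {
    pair <- random_msc_pair(4, 2)
    got <- coalescent_log_density(pair$gene, pair$species, pair$mapping)
    oracle <- oracle_coal_log_density(pair$gene, pair$species, pair$mapping,
                                      pair$species$popsize)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("branch statistics pool correctly across loci", {
  st <- fig1_state(T1 = 1.0, t1 = 1.5)
  one <- branch_coal_stats(st$gene, st$species, st$mapping)
  expect_equal(one$n, c(0, 0, 1))
  expect_equal(one$gamma, c(0, 0, 0.5))
  two <- branch_coal_stats(list(st$gene, st$gene), st$species,
                           list(st$mapping, st$mapping))
  expect_equal(two$n, 2 * one$n)
  expect_equal(two$gamma, 2 * one$gamma)
  # total coalescence count equals total gene tips - 1 per locus
  set.seed(2)
  pair <- random_msc_pair(5, 2)
  stats <- branch_coal_stats(pair$gene, pair$species, pair$mapping)
  expect_equal(sum(stats$n), pair$gene$ntip - 1)
  expect_true(all(stats$gamma >= 0))
})

test_that("inverse-gamma moments follow the closed forms", {
  expect_equal(unname(invgamma_mean_cv(3, 0.004)), c(0.002, 1))
  expect_equal(unname(invgamma_mean_cv(3, 123)[2]), 1)
  expect_equal(unname(invgamma_mean_cv(6, 5)), c(1, 0.5))
  expect_error(invgamma_mean_cv(2, 1), "alpha")
  # cross-check against quadrature moments of the density
  a <- 6; b <- 5
  dens <- function(x) b^a / gamma(a) * x^(-a - 1) * exp(-b / x)
  m1 <- integrate(function(x) x * dens(x), 0, Inf, rel.tol = 1e-10)$value
  m2 <- integrate(function(x) x^2 * dens(x), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(m1, 1, tolerance = 1e-8)
  expect_equal(sqrt(m2 - m1^2) / m1, 0.5, tolerance = 1e-6)
})

test_that("conjugate integration matches quadrature and is monotone", {
  # empty statistics: the marginal is 1
  pr <- invgamma_prior(3, beta = 0.004)
  expect_equal(integrated_coalescent_log_density(
    list(n = numeric(5), gamma = numeric(5)), pr), 0)
  # single-branch case against adaptive quadrature
  marg <- function(n, g, a, b) {
    f <- function(N) N^(-n) * exp(-g / N) *
      b^a / gamma(a) * N^(-a - 1) * exp(-b / N)
    log(integrate(f, 0, Inf, rel.tol = 1e-12)$value)
  }
  got <- integrated_coalescent_log_density(list(n = 1, gamma = 0.5), pr)
  expect_equal(got, marg(1, 0.5, 3, 0.004), tolerance = 1e-8)
  # random small statistics, per branch
  set.seed(31)
  for (i in 1:30) {
    n <- sample(0:5, 1); g <- rexp(1, 20)
    a <- runif(1, 2.2, 5); b <- rexp(1, 100)
    got <- integrated_coalescent_log_density(list(n = n, gamma = g),
                                             invgamma_prior(a, beta = b))
    expect_equal(got, marg(n, g, a, b), tolerance = 1e-6)
  }
  # increasing gamma at fixed n strictly decreases the marginal
  gs <- seq(0.1, 2, by = 0.1)
  vals <- vapply(gs, function(g)
    integrated_coalescent_log_density(list(n = 2, gamma = g), pr), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("explicit-size MCMC prior density matches the gamma pdf", {
  mean <- 0.01
  dens <- function(x) dgamma(x, shape = 2, scale = mean / 2)
  expect_equal(mcmc_popsize_log_prior(mean, mean), log(dens(mean)))
  # normalization by quadrature
  expect_equal(integrate(dens, 0, Inf)$value, 1, tolerance = 1e-8)
  # additive over branches; vanishing density at 0+
  expect_equal(mcmc_popsize_log_prior(c(0.01, 0.02), mean),
               mcmc_popsize_log_prior(0.01, mean) +
                 mcmc_popsize_log_prior(0.02, mean))
  expect_lt(mcmc_popsize_log_prior(1e-12, mean), -15)
  expect_error(mcmc_popsize_log_prior(-1, mean), "positive")
})

test_that("birth-death height density is normalized and matches Yule", {
  # independent Yule check on a fixed 3-taxon caterpillar-free tree:
  # f(topology, t1, t2) = 2 lambda^2 exp(-lambda t1 - 2 lambda t2), t2 > t1
  lam <- 3
  tr <- function(t1, t2) {
    s <- mc_tree(parent = c(4, 4, 5, 5, 0), height = c(0, 0, 0, t1, t2),
                 tip_label = c("a", "b", "c"), check = FALSE)
    s
  }
  p <- birth_death_params(d = lam, f = 0)
  for (tt in list(c(0.1, 0.4), c(0.02, 0.03), c(1, 2.5))) {
    expect_equal(birth_death_log_density(tr(tt[1], tt[2]), p),
                 log(2 * lam^2) - lam * tt[1] - 2 * lam * tt[2],
                 tolerance = 1e-10)
  }
  # 2-D quadrature: 3 labelled topologies x ordered-height integral = 1,
  # for Yule and for birth-death with extinction
  for (pp in list(birth_death_params(2, 0), birth_death_params(2, 0.4))) {
    integrand <- function(t1, t2)
      exp(birth_death_log_density(tr(t1, t2), pp))
    inner <- function(t1) vapply(t1, function(x)
      integrate(function(t2) vapply(t2, function(y) integrand(x, y), 0),
                x, Inf, rel.tol = 1e-9)$value, 0)
    total <- 3 * integrate(inner, 0, Inf, rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-5)
  }
  # change of variables: scaling all heights by c changes the log density
  # consistently with the Jacobian c^(n-1)
  pair <- random_msc_pair(5, 1)
  sc <- 1.7
  scaled <- pair$species
  scaled$height <- scaled$height * sc
  p2 <- birth_death_params(40, 0.3)
  d1 <- birth_death_log_density(pair$species, p2)
  d2 <- birth_death_log_density(scaled, p2)
  # densities at matched quantiles under rate lambda vs lambda*c obey the
  # scaling law f_c(t) = f(t/c)/c^(n-1) when the rate is also divided by c
  p3 <- birth_death_params(40 / sc, 0.3)
  d3 <- birth_death_log_density(scaled, p3)
  expect_equal(d3, d1 - (pair$species$ntip - 1) * log(sc), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(d1, d2)))
})

test_that("sampled birth-death trees follow the stated density", {
  # histogram of simulated 3-taxon root heights vs the marginal of the
  # closed-form density (independent check that simulator and density agree)
  set.seed(101)
  lam <- 5; mu <- 2
  sims <- replicate(4000, {
    s <- simulate_birth_death_tree(3, lam, mu)
    s$height[s$root]
  })
  p <- birth_death_params(lam - mu, mu / lam)
  marg <- function(t2) vapply(t2, function(y) {
    f <- function(t1) vapply(t1, function(x) {
      s <- mc_tree(parent = c(4, 4, 5, 5, 0), height = c(0, 0, 0, x, y),
                   tip_label = c("a", "b", "c"), check = FALSE)
      exp(birth_death_log_density(s, p))
    }, 0)
    3 * integrate(f, 0, y, rel.tol = 1e-8)$value
  }, 0)
  qs <- quantile(sims, c(0.25, 0.5, 0.75))
  cdf <- function(q) integrate(marg, 0, q, rel.tol = 1e-7)$value
  expect_lt(abs(cdf(qs[[1]]) - 0.25), 0.025)
  expect_lt(abs(cdf(qs[[2]]) - 0.50), 0.025)
  expect_lt(abs(cdf(qs[[3]]) - 0.75), 0.025)
})

test_that("explicit and integrated population-size sampling agree", {
  # conjugacy end-to-end: MCMC over explicit branch sizes under the
  # inverse-gamma prior vs the analytically integrated model must give the
  # same species-tree height posterior on one fixed dataset
  set.seed(401)
  labs <- paste0("s", 1:3)
  sp <- simulate_birth_death_tree(3, 100, 30, tip_label = labs)
  sp$popsize <- rep(0.01, sp$nnode)
  gt <- simulate_msc_gene_tree(sp, 2)
  aln <- simulate_alignment(gt, 1, subst_model("JC"), length = 200)
  loci <- list(list(alignment = aln, mapping = attr(gt, "mapping"),
                    model = subst_model("JC")))
  base <- list(loci = loci, species = labs, clock = "strict",
               popsize_alpha = 3, pop_mean = 0.01,
               estimate_pop_mean = FALSE,
               tree_prior = "birth_death", bd_d = 70, bd_f = 0.3,
               estimate_bd = FALSE, chain_length = 30000L,
               sample_every = 3L)
  ri <- run_chain(do.call(mcmc_config, c(base, list(
    popsize_mode = "integrated", seed = 402))))
  rm_ <- run_chain(do.call(mcmc_config, c(base, list(
    popsize_mode = "mcmc", popsize_prior = "invgamma", seed = 403))))
  hi <- burn_in_filter(ri$trace, 0.125)$speciesheight
  hm <- burn_in_filter(rm_$trace, 0.125)$speciesheight
  th <- function(x) {
    ess <- effective_sample_size(x)
    x[seq(1, length(x), by = max(1, ceiling(3 * length(x) / ess)))]
  }
  expect_gt(stats::ks.test(th(hi), th(hm))$p.value, 0.01)
})
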
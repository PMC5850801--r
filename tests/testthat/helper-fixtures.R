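# Shared fixtures: small hand-built trees and random simulated states.

# Two-species worked example: speciation at T1, one-haplotype gene tree
# coalescing at t1.
fig1_state <- function(T1 = 1.0, t1 = 1.5) {
  sp <- mc_tree(parent = c(3, 3, 0), height = c(0, 0, T1),
                tip_label = c("A", "B"))
  gt <- mc_tree(parent = c(3, 3, 0), height = c(0, 0, t1),
                tip_label = c("a", "b"))
  list(species = sp, gene = gt, mapping = c(a = "A", b = "B"))
}

# Random species tree with inverse-gamma population sizes plus one
# compatible MSC gene tree.
random_msc_pair <- function(n_species = 4, haplotypes = 1,
                            birth = 100, death = 30,
                            pop_shape = 3, pop_scale = 0.004) {
  sp <- simulate_birth_death_tree(n_species, birth, death)
  sp$popsize <- 1 / stats::rgamma(sp$nnode, pop_shape, rate = pop_scale)
  gt <- simulate_msc_gene_tree(sp, haplotypes)
  list(species = sp, gene = gt, mapping = attr(gt, "mapping"))
}

# Prior-only MCMC configuration over k loci (one haplotype per species).
prior_config <- function(n_species = 5, n_loci = 2, locus_rates = NULL,
                         clock = "strict", ...) {
  labs <- paste0("s", seq_len(n_species))
  m <- stats::setNames(labs, paste0(labs, "_1"))
  loci <- replicate(n_loci, list(alignment = NULL, mapping = m),
                    simplify = FALSE)
  mcmc_config(loci, species = labs, clock = clock,
              popsize_mode = "integrated", popsize_alpha = 3,
              pop_mean = 0.002, estimate_pop_mean = FALSE,
              tree_prior = "birth_death", bd_d = 100, bd_f = 0.5,
              estimate_bd = FALSE, locus_rates = locus_rates, ...)
}

# Independent oracle: interval-sweep coalescent log density that walks both
# trees' event times directly (no shared code with locus_coal_stats).
oracle_coal_log_density <- function(gt, sp, mapping, pop) {
  tip_sp <- match(mapping[gt$tip_label], sp$tip_label)
  # species branch of a gene lineage (subtending node set `tips`) at time t
  branch_of <- function(tips, t) {
    a <- tip_sp[tips[1]]
    for (b in tip_sp[tips[-1]]) {
      while (a != b)
        if (sp$height[a] < sp$height[b]) a <- sp$parent[a] else b <- sp$parent[b]
    }
    while (sp$parent[a] != 0L && sp$height[sp$parent[a]] <= t) a <- sp$parent[a]
    a
  }
  sets <- mscoal:::node_tip_sets(gt)
  events <- sort(unique(c(gt$height, sp$height, max(gt$height))))
  logd <- 0
  for (i in seq_len(length(events) - 1)) {
    t0 <- events[i]; t1 <- events[i + 1]
    mid <- (t0 + t1) / 2
    # lineages crossing mid, grouped by species branch
    cross <- which(gt$height <= t0 & gt$parent != 0L &
                     gt$height[pmax(gt$parent, 1L)] >= t1)
    cross <- cross[gt$height[gt$parent[cross]] >= t1]
    br <- vapply(cross, function(v) branch_of(sets[[v]], mid), 0L)
    for (b in unique(br)) {
      j <- sum(br == b)
      logd <- logd - choose(j, 2) / pop[b] * (t1 - t0)
    }
  }
  internal <- (gt$ntip + 1L):gt$nnode
  for (v in internal) {
    b <- branch_of(sets[[v]], gt$height[v] - 1e-12)
    logd <- logd - log(pop[b])
  }
  logd
}
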
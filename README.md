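# mscoal

Bayesian inference of species trees and gene trees under the multispecies
coalescent (MSC), at desk scale, for phylogeneticists who want the full
machinery — joint MCMC over the species tree and every gene tree, analytical
integration of population sizes, coordinated tree proposals, and a species
tree relaxed clock — in plain, inspectable R.

## The model in brief

A rooted ultrametric species tree `S` with per-branch haploid population
sizes `N_b` and relative substitution rates `R_b` generates one gene tree
per locus under the coalescent: while `j` lineages occupy branch `b`, they
coalesce at rate `C(j,2)/N_b`. With `n_b` coalescences and integrated
intensity `γ_b = Σ C(j,2)Δt` in branch `b`, the MSC density is
`Π_b N_b^{-n_b} e^{-γ_b/N_b}`. Under an inverse-gamma(α, β) prior each
`N_b` integrates out in closed form,

    log m_b = α log β − log Γ(α) + log Γ(α+n_b) − (α+n_b) log(β+γ_b),

so population sizes need never be sampled (α = 3 by default, for which the
prior coefficient of variation is exactly 1). Node heights and topologies
are updated by coordinated Metropolis–Hastings operators that move the
species tree and all gene trees in one step; the adaptive root-height move
draws the root–bound gap `x′ ~ Exp(λ)` and has `log HR = λ(x′−x)`. A
species tree relaxed clock assigns each species branch a discretized
log-normal rate and gives every gene-tree branch the length-weighted rate
`r = Σ c·L·R / l`, where `L` is the time the branch spends in each species
branch and `c` is the locus clock rate.

Everything has a generative twin (`simulate_*`, `make_fixture()`): the
sampler is validated by drawing from the prior with MCMC and comparing
against direct simulation, and the incomplete-lineage-sorting experiments
(concatenation vs MSC branch-length and rate bias) are reproduced at
reduced scale.

## Worked example

The canonical two-species illustration: species A and B diverge at time
1.0, the single gene coalescence sits at 1.5, the locus clock rate is
0.001, and the species branch rates are 0.7 (A), 1.0 (B), 1.3 (ancestral
stem).

```r
library(mscoal)
species <- mc_tree(parent = c(3, 3, 0), height = c(0, 0, 1.0),
                   tip_label = c("A", "B"))
gene    <- mc_tree(parent = c(3, 3, 0), height = c(0, 0, 1.5),
                   tip_label = c("a", "b"))
mapping <- validate_mapping(gene, species, c(a = "A", b = "B"))
emb <- embed_gene_tree(gene, species, mapping)
emb[[1]]$L
#> [1] 1.0 0.5
species_clock_gene_branch_rate(emb[[1]], c(0.7, 1.0, 1.3), c = 0.001)
#> [1] 9e-04
species_clock_gene_branch_rate(emb[[2]], c(0.7, 1.0, 1.3), c = 0.001)
#> [1] 0.0011
```

Branch `a` spends 1.0 time units in A (rate 0.7) and 0.5 in the ancestral
stem (rate 1.3), accumulating 0.00135 expected substitutions over a length
of 1.5 — hence rate 0.0009; branch `b` gets 0.0011. A prior-only chain and
its simulation oracle:

```r
labs <- paste0("s", 1:5)
loci <- list(list(alignment = NULL,
                  mapping = setNames(labs, paste0(labs, "_1"))))
cfg <- mcmc_config(loci, clock = "st_ucln", clock_bins = 100,
                   popsize_mode = "integrated", pop_mean = 0.002,
                   estimate_pop_mean = FALSE,
                   tree_prior = "birth_death", bd_d = 100, bd_f = 0.5,
                   chain_length = 50000, sample_every = 10, seed = 1)
run <- run_chain(cfg)
mean(burn_in_filter(run$trace, 0.125)$speciesheight)
#> [1] 0.00947
```

This short demonstration chain estimates the prior mean species-tree root
height at 0.0095 substitutions per site; direct simulation of the same
prior puts it at 0.0087, and longer chains agree (the full equivalence
test lives in `tests/testthat/test-acceptance.R`).

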
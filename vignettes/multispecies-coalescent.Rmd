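---
title: "Joint species-tree and gene-tree inference under the multispecies coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint species-tree and gene-tree inference under the multispecies coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscoal)
```

## The model

`mscoal` samples the joint posterior of a species tree and one gene tree per
locus under the multispecies coalescent (MSC).  The species tree is a rooted,
binary, ultrametric time tree: node heights are measured backwards from the
present and every branch `b` (including the stem above the root, which
extends into the infinite past) carries a constant population size `N_b` and
a relative substitution rate `R_b`.  Gene trees live in the same time units
and must be *compatible* with the species tree: a coalescence joining
lineages sampled from species X and Y cannot be more recent than the
species-tree MRCA of X and Y.

We store `N_b` as the haploid-equivalent size that enters coalescent rates
directly: while `j` lineages occupy branch `b`, the next coalescence arrives
at rate `choose(j, 2) / N_b`.  A branch of duration `tau` then has coalescent
length `tau / N_b`, which equals the conventional `tau / (2 Ne)` with diploid
`Ne = N_b / 2`.  Using one internal convention with explicit converters
avoids factor-of-two bugs between the haploid sizes used in simulation and
the diploid effective sizes quoted in coalescent units.

With `n_b` coalescences in branch `b` and integrated intensity
`gamma_b = sum_j choose(j,2) dt_j`, the MSC density of all gene trees given
the species tree factorizes as `prod_b N_b^{-n_b} exp(-gamma_b / N_b)`.
`(n_b, gamma_b)` are sufficient statistics pooled across loci.

### Analytical integration of population sizes

Population sizes are usually nuisance parameters.  Because the MSC density is
conjugate to an inverse-gamma prior on each `N_b`, the per-branch marginal is
available in closed form:

```
log m_b = alpha log(beta) - log Gamma(alpha)
        + log Gamma(alpha + n_b) - (alpha + n_b) log(beta + gamma_b)
```

By default the shape is fixed at `alpha = 3`, for which the prior coefficient
of variation is exactly 1, and only the prior mean `mu = beta / 2` is
estimated.  The closed form is never trusted on its own: the test suite
verifies it per branch against adaptive quadrature of
`integral N^{-n} exp(-gamma/N) InvGamma(N; alpha, beta) dN` at relative
tolerance 1e-6 on randomized states, and an end-to-end sampling-equivalence
test checks that chains with explicit sizes under the inverse-gamma prior and
chains using the marginal agree in distribution.

The classical alternative in which sizes are sampled explicitly is also
implemented (`popsize_mode = "mcmc"`): a Gamma(shape 2, scale mean/2) prior
per branch with an estimated mean hyperparameter.

For the hyperprior on the population-size mean we use a one-over-x prior
truncated to a configurable range
(default `1e-6` to `10`), which keeps the posterior proper while staying
close to scale-invariant.  Both the range and the estimate/fix switch are
exposed in the run configuration.

### Species-tree prior

The species tree prior is the reconstructed birth-death process conditioned
on the number of extant species, parameterized by net diversification
`d = lambda - mu` and extinction fraction `f = mu / lambda` (`f = 0` gives
Yule).  We derived the closed form used for both density evaluation and
direct simulation: with `r = lambda - mu`,
`u(t) = lambda (1 - e^{-rt}) / (lambda - mu e^{-rt})` and
`p1(t) = r^2 e^{-rt} / (lambda - mu e^{-rt})^2`, the density over a labelled
topology and its internal node heights is

```
f(T) = 2^{n-1} / (n-1)! * prod_i lambda p1(t_i) * (1 - u(t_root))
```

and the matching simulator draws the origin via `u(T)^n ~ U(0,1)`, the
`n - 1` speciation times iid from the truncated speciation-time law by
closed-form inversion, and a uniform ranked topology by successive random
joins.  Because density and simulator come from the same derivation, prior
sampling by MCMC is directly comparable to direct simulation; the suite
checks the density integrates to 1 by 2-D quadrature on three taxa and that
simulated root heights follow the marginalized density.

## Coordinated operators

Naive single-tree proposals mix poorly because gene trees constrain the
species tree tightly.  Three coordinated operators move the species tree and
all gene trees in one Metropolis-Hastings step.

**Connected components.**  For a species node S, the gene nodes shifted
jointly with S are those whose descendant individuals include at least one
from each child of S and none from outside S.  Selection depends only on
topologies and the tip-to-species mapping -- never on node heights -- which is
what makes the height-shifting operators symmetric.

**CoordinatedUniform** picks a non-root internal species node uniformly,
computes the widest height window `(D, U)` within which shifting S and its
components changes no topology in any tree, draws the new height uniformly,
and shifts.  Each bound is an offset relative to the node it constrains
(children of S; per selected gene node, its children outside the component
below, its parent outside the component above), so the window is computed in
shift space; a grid-scan oracle over candidate shifts verifies the analytic
bounds in the tests.  Log Hastings ratio: 0.

**CoordinatedExponential** does the same for the species root, where no
upper bound exists.  With `x = t(root) - D`, a replacement gap
`x' ~ Exponential(lambda)` is drawn independently of the current state, so
the Hastings ratio reduces to the ratio of proposal densities,
`log HR = lambda (x' - x) = lambda eta`.  The rate is adapted during the
first 10% of the chain (every 100 proposals, from the running mean of `x`,
so that the proposal median `ln 2 / lambda` tracks the posterior expectation
of `x`) and frozen afterwards -- a diminishing-adaptation schedule; the
target of the adaptation (the posterior expectation of `x`) is part of the
operator's definition, the cadence is an implementation choice sized so
adaptation actually fires at desk-scale chain lengths.

**CoordinatedExchange** changes the species topology by a narrow (NNI)
exchange -- swapping a node with its parent's sibling -- or a wide (SPR-like)
exchange of two non-adjacent subtrees, at an adjustable 2:1 weighting of
NNI over SPR moves.  Gene coalescences invalidated by the species move are
repaired lowest-first: the broken node keeps its height, one child is pruned,
and the orphaned lineage is re-joined to a uniformly chosen lineage crossing
the same height in the same new species branch.  The forward proposal
probability is the product of `1 / #choices` over repairs; the reverse
probability is obtained by applying the inverse species move to the proposed
state and re-running the repair procedure *guided* to reconstruct the
original gene trees (if that path does not exist the proposal is
auto-rejected).  The log Hastings ratio is the log ratio of these products,
plus, for wide exchanges, the log ratio of eligible-pair counts.  The gene
re-attachment construction is not pinned down analytically here; its
correctness is gated on the sample-from-prior protocol below, which is
sensitive to any Hastings-ratio error.

The standard single-component suite (tree scalers with the `s^{d-2}` uniform
scale kernel, uniform height slides, root-gap scalers, naive NNI on both
tree levels, Wilson-Balding regrafting on gene trees, rate-category redraws,
locus-rate delta exchange, hyperparameter walks) is retained both as a
baseline and because coordinated moves alone are not irreducible.  Species
moves that would leave any gene tree incompatible are flagged invalid and
auto-rejected, which keeps acceptance bookkeeping clean.

## Species tree relaxed clock

Per-species-branch rates `R_b` are modelled by a discretized mean-one
log-normal (UCLN, default sigma 0.3) or exponential (UCED): bin rates are the
quantile midpoints at probabilities `(i + 0.5)/n`, renormalized to mean
exactly 1, and each branch carries a bin index with a uniform prior.  The
number of bins equals the number of estimated branch rates during inference
(100 bins in the prior-correctness protocol).  Renormalization to mean
exactly 1 (rather than raw quantiles) is a deliberate choice: it makes the
"one time unit = one expected substitution" identity exact for every
`(sigma, n_bins)`.  The root branch rate is fixed to 1 during inference and
in the matching simulator.

Phylogenetic likelihoods need a rate per *gene*-tree branch.  A gene branch
that spends time `L_1, L_2, ...` in species branches with rates
`R_1, R_2, ...` accumulates `sum_i c L_i R_i` expected substitutions (`c` the
locus clock rate), so its rate is the length-weighted average
`r = sum_i c L_i R_i / l`.  On the canonical two-species example (speciation
at 1.0, coalescence at 1.5, `c = 0.001`, rates 0.7 / 1.0 / 1.3) this gives
`r_a = 0.00135 / 1.5 = 0.0009` and `r_b = 0.00165 / 1.5 = 0.0011`, which the
acceptance suite reproduces exactly, and the identity `r l = sum c L R` is
property-tested on random embeddings.

Gene-tree relaxed clocks (one rate category per gene branch) and the strict
clock are implemented under the same interface; with all species rates 1 the
species clock reproduces the strict clock bit-for-bit.

Per-locus clock rates, when estimated, use a log-normal prior (real-space
mean 1, sigma 0.6) with the mean-of-rates-equal-1 constraint maintained by
delta-exchange moves that transfer rate between two loci; the constraint is
the identifiability device, the prior the regularizer.

## Likelihood

Felsenstein pruning over compressed site patterns with JC, HKY or GTR rate
matrices (normalized to one expected substitution per unit distance,
transition probabilities from a symmetric eigendecomposition cached per
model), equal-weight discrete-gamma site categories whose rates are the
within-bin conditional means (mean exactly 1, 4 categories by default), IUPAC
ambiguity codes as partial tip likelihoods (gaps and N fully ambiguous), and
per-node rescaling against underflow, which leaves representable results
bit-identical.  A concatenation mode evaluates all loci directly on the
species tree with no coalescent term; this is how the
incomplete-lineage-sorting comparisons are run without a second code base.

## The generative counterpart

Every model component has a matching simulator: conditioned birth-death
species trees, per-branch population sizes (gamma or inverse-gamma),
MSC gene trees with k haplotypes per species, species branch rates
(continuous or discretized, optionally renormalized), per-locus rates, and
site-wise CTMC sequence evolution.  Three named presets reproduce the study
designs used for validation: `prior_test` (5 species, 1 haplotype, birth 200
/ death 100, inverse-gamma(3, 0.004) sizes, 100-bin UCLN rates, two loci at
clock rates 0.5 and 2.0), `simstudy` (21 species, 2 haplotypes, birth 100 /
death 30, Gamma(2, 0.002) sizes, HKY kappa 3 with 4-category gamma shape 0.2,
600 nt, log-normal sigma 0.6 locus rates), and `spils` (fixed caterpillar
((((A,B),C),D),E), Yule rate 10, inverse-gamma(3, 0.2) sizes, Jukes-Cantor,
strict clock, 1000 nt).  A scale factor shrinks locus counts and alignment
lengths, never the distributions.  One deviation from the plain recipe: the
simulator renormalizes simstudy locus rates to mean 1 so that simulated truth
and the constrained posterior live on the same scale in recovery tests.

The simulator is the package's primary oracle.  The strongest correctness
check is *sample-from-prior equivalence*: with no data, distributions of
species-tree heights, gene-tree heights, species and gene topology
frequencies, and species-clock gene branch rates obtained by MCMC must match
direct simulation (Kolmogorov-Smirnov and chi-squared tests).  This protocol
exercises every prior density and every Hastings ratio at once; a sign error
in any of them shifts these distributions.

What the simulator does not emulate -- and hence what passing tests cannot
show -- includes sequencing error, alignment error, recombination within
loci, gene flow or hybridization, selection, and non-contemporaneous
sampling.  Conclusions about real data rest on the model assumptions, not on
these tests.

## Numerical and scale choices

Heights use plain doubles; tips sit at exactly 0.  Compatibility checks use
non-strict inequalities, so a coalescence exactly at a speciation time is
legal; ties between node heights otherwise occur with probability zero and
are not specially handled.  MCC tree ties break lexicographically on a
canonical topology string; HPD window ties break towards the lower endpoint.
Degenerate inputs (constant trace series, single-bin discretizations,
single-species trees) return documented values rather than erroring where a
sensible value exists.

Cached per-locus statistics and likelihoods are refreshed only for the
components a proposal touches; in debug mode every logged sample re-derives
the full posterior from scratch and asserts agreement within 1e-8.  ESS uses
Geyer's initial-positive-sequence estimator; the run-until-converged
protocol doubles the chain and halves the sampling rate until all recorded
statistics pass the threshold (default 200), discarding 12.5% burn-in at
each evaluation.

Each chain consumes a single deterministic RNG stream seeded from its
configuration, which makes whole runs bit-reproducible; per-operator
substreams were considered and rejected as adding machinery without changing
the reproducibility contract.

Validation runs at desk scale: prior-equivalence uses 5 species and about
2 x 10^5 proposals with roughly 20,000 retained samples (distribution tests
are run on an autocorrelation-thinned subset, since Kolmogorov-Smirnov
assumes independent draws); the incomplete-lineage-sorting direction check
uses 10 replicates of 8 loci x 250 nt; the coalescent-unit summary uses 30
replicate species trees; parameter-recovery uses 20 replicates of 3 species
x 3 loci x 130 nt, with truth drawn from the model's own priors (locus
rates from the mean-constrained lognormal, by rejection conditioning) so
that nominal interval coverage applies.  These sizes were chosen so the full suite runs on one CPU in
minutes while keeping each test's power adequate for the effect it checks;
the underlying protocols are identical at larger sizes.

## Known limitations

Population sizes are constant per branch (no piecewise-linear change);
tips are contemporaneous; trees are strictly binary; there is no
within-locus recombination, migration, or species network support; the
random-local-clock and autocorrelated-clock families are out of scope; and
likelihood computation is plain R (adequate at desk scale, not tuned for
hundreds of loci).
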
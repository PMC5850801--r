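# Generative counterpart of every model component: birth-death species
# trees, coalescent gene trees, relaxed-clock rates, and CTMC sequence
# evolution.  Used as the fixture generator, as the independent oracle for
# the sample-from-prior correctness protocol, and to set up the
# incomplete-lineage-sorting (SPILS) and parameter-recovery experiments.
# All randomness comes from R's global RNG; callers seed with set.seed().

#' Simulate a birth-death species tree conditioned on its tip count
#'
#' Samples the reconstructed birth-death process conditioned on `n_tips`
#' extant species with a uniform prior on the origin time, using exact
#' closed-form inversion: the origin satisfies `u(T)^n ~ U(0,1)` and the
#' `n-1` speciation times are iid draws from the time-of-speciation law
#' truncated at the origin, where
#' `u(t) = lambda (1 - e^{-rt}) / (lambda - mu e^{-rt})`, `r = lambda - mu`.
#' The ranked labelled topology is uniform (each speciation joins a uniform
#' random pair of extant lineages), independent of the times.  For `mu = 0`
#' this reduces to the conditioned Yule process, whose mean root height is
#' `sum_{k=2..n} 1/(lambda k)`.
#'
#' @param n_tips Number of extant species (>= 2).
#' @param birth Speciation rate lambda (> death).
#' @param death Extinction rate mu (>= 0).
#' @param tip_label Optional tip labels (default `sp1..spN`).
#' @return A `mc_tree` species tree.
#' @export
simulate_birth_death_tree <- function(n_tips, birth, death = 0,
                                      tip_label = NULL) {
  if (n_tips < 2) stop("need at least two tips")
  if (birth <= death || death < 0) stop("need birth > death >= 0")
  times <- bd_speciation_times(n_tips, birth, death)
  if (is.null(tip_label)) tip_label <- paste0("sp", seq_len(n_tips))
  build_ranked_tree(sort(times), tip_label)
}

# n-1 iid speciation times conditioned on n tips (origin marginalized by
# sampling it first).
bd_speciation_times <- function(n, lambda, mu) {
  qfun <- function(v) {
    r <- lambda - mu
    if (mu == 0) -log(1 - v) / lambda else log((lambda - v * mu) / (lambda * (1 - v))) / r
  }
  origin <- qfun(stats::runif(1)^(1 / n))
  u_T <- bd_u(origin, lambda, mu)
  qfun(stats::runif(n - 1L) * u_T)
}

# Assemble a tree from sorted speciation heights by joining uniformly random
# pairs of extant lineages (uniform ranked labelled topology).
build_ranked_tree <- function(times_sorted, tip_label) {
  n <- length(tip_label)
  nn <- 2L * n - 1L
  parent <- integer(nn)
  height <- c(rep(0, n), times_sorted)
  active <- seq_len(n)
  for (i in seq_along(times_sorted)) {
    v <- n + i
    pair <- sample(length(active), 2L)
    parent[active[pair]] <- v
    active <- c(active[-pair], v)
  }
  mc_tree(parent, height, tip_label)
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Runs the coalescent within each species branch from the present backwards:
#' while `j` lineages occupy branch `b`, the waiting time to the next
#' coalescence is Exponential with rate `choose(j,2) / N_b` (haploid-
#' equivalent `N_b`); surviving lineages are handed to the parent branch, and
#' coalescence continues without bound in the root stem.
#'
#' @param species_tree Species tree with positive `popsize` on every node
#'   (root entry = stem branch), or sizes supplied via `pop_sizes`.
#' @param samples_per_species Haplotypes sampled per species (scalar or
#'   named vector by species label).
#' @param pop_sizes Optional override for the per-branch sizes.
#' @param ploidy Multiplier on branch sizes for this locus (default 1).
#' @return A `mc_tree` gene tree; tips are labelled `<species>_<i>` and the
#'   implied mapping is in attribute `mapping`.
#' @export
simulate_msc_gene_tree <- function(species_tree, samples_per_species = 1,
                                   pop_sizes = species_tree$popsize,
                                   ploidy = 1) {
  sp <- species_tree
  if (any(is.na(pop_sizes)) || any(pop_sizes <= 0))
    stop("all species branches need positive population sizes")
  pop_sizes <- pop_sizes * ploidy
  k <- samples_per_species
  if (length(k) == 1L) k <- stats::setNames(rep(k, sp$ntip), sp$tip_label)
  tips <- unlist(lapply(sp$tip_label, function(s) paste0(s, "_", seq_len(k[s]))))
  ntip <- length(tips)
  mapping <- stats::setNames(rep(sp$tip_label, k[sp$tip_label]), tips)
  nn <- 2L * ntip - 1L
  parent <- integer(nn); height <- numeric(nn)
  nxt <- ntip + 1L
  # lineages[[b]]: gene node ids currently at the bottom of species branch b
  lineages <- vector("list", sp$nnode)
  tid <- 0L
  for (s in seq_len(sp$ntip)) {
    lineages[[s]] <- tid + seq_len(k[sp$tip_label[s]])
    tid <- tid + k[sp$tip_label[s]]
  }
  ord <- c(seq_len(sp$ntip), postorder_internal(sp))
  ord <- ord[order(sp$height[ord])]
  for (b in ord) {
    lin <- lineages[[b]]
    t <- sp$height[b]
    top <- if (sp$parent[b] == 0L) Inf else sp$height[sp$parent[b]]
    while (length(lin) > 1L) {
      rate <- choose(length(lin), 2) / pop_sizes[b]
      t <- t + stats::rexp(1, rate)
      if (t >= top) break
      pair <- sample(length(lin), 2L)
      v <- nxt; nxt <- nxt + 1L
      parent[lin[pair]] <- v
      height[v] <- t
      lin <- c(lin[-pair], v)
    }
    if (sp$parent[b] != 0L)
      lineages[[sp$parent[b]]] <- c(lineages[[sp$parent[b]]], lin)
  }
  gt <- mc_tree(parent, height, tips)
  attr(gt, "mapping") <- mapping
  gt
}

#' Simulate per-species-branch relative rates
#'
#' Branch rates are drawn from a mean-one log-normal (or from its
#' discretization into quantile bins when `discretize_bins` is set, the form
#' used by the prior-correctness protocol) and, if `renormalize`, rescaled
#' so their arithmetic mean is exactly 1.  The root stem rate can be pinned
#' to 1, matching its treatment during inference.
#'
#' @param species_tree Species tree.
#' @param sigma Log-space standard deviation (0 gives a strict clock).
#' @param renormalize Rescale to mean exactly 1?
#' @param discretize_bins If non-`NULL`, draw each rate uniformly from
#'   `discretize_rates("lognormal", sigma, discretize_bins)` instead of the
#'   continuous law.
#' @param kind `"lognormal"` or `"exponential"` (the latter only with
#'   `discretize_bins`).
#' @param fix_root Pin the root stem rate to 1 (default `TRUE`).
#' @return An `mc_species_rates` object.
#' @export
simulate_species_rates <- function(species_tree, sigma = 0.3,
                                   renormalize = TRUE,
                                   discretize_bins = NULL,
                                   kind = "lognormal",
                                   fix_root = TRUE) {
  nn <- species_tree$nnode
  if (!is.null(discretize_bins)) {
    bins <- discretize_rates(kind, sigma, discretize_bins)
    r <- bins[sample.int(discretize_bins, nn, replace = TRUE)]
  } else if (sigma == 0) {
    r <- rep(1, nn)
  } else {
    r <- stats::rlnorm(nn, meanlog = -sigma^2 / 2, sdlog = sigma)
  }
  if (renormalize) r <- r / mean(r)
  if (fix_root) r[species_tree$root] <- 1
  species_rates(species_tree, r)
}

#' Simulate a sequence alignment along a gene tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' down every branch with transition probabilities at distance
#' `branch length x branch rate x site category rate`; each site keeps one
#' gamma category for its whole history.
#'
#' @param gene_tree Gene tree.
#' @param branch_rates Rate per gene-tree node (branch above; root ignored).
#'   A scalar is recycled (strict clock).
#' @param model A [subst_model()].
#' @param site_rates Category rates (e.g. [site_rate_categories()]); sites
#'   are assigned categories uniformly.
#' @param length Number of sites.
#' @return An `mc_alignment` over the gene tree's tips.
#' @export
simulate_alignment <- function(gene_tree, branch_rates, model,
                               site_rates = 1, length = 1000L) {
  if (length < 1) stop("alignment length must be positive")
  if (length(branch_rates) == 1L)
    branch_rates <- rep(branch_rates, gene_tree$nnode)
  nn <- gene_tree$nnode
  bl <- branch_lengths(gene_tree)
  cat_idx <- sample.int(length(site_rates), length, replace = TRUE)
  states <- matrix(0L, nn, length)
  states[gene_tree$root, ] <- sample.int(4L, length, replace = TRUE,
                                         prob = model$freqs)
  order_down <- rev(c(postorder_internal(gene_tree)))
  for (v in c(order_down, seq_len(gene_tree$ntip)))
    if (gene_tree$parent[v] != 0L) {
      p <- gene_tree$parent[v]
      for (ci in seq_along(site_rates)) {
        idx <- which(cat_idx == ci)
        if (!length(idx)) next
        P <- transition_probabilities(model,
               bl[v] * branch_rates[v] * site_rates[ci])
        for (s in 1:4) {
          ii <- idx[states[p, idx] == s]
          if (length(ii))
            states[v, ii] <- sample.int(4L, length(ii), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
  seqs <- apply(states[seq_len(gene_tree$ntip), , drop = FALSE], 1,
                function(x) paste(NUC[x], collapse = ""))
  names(seqs) <- gene_tree$tip_label
  alignment(seqs)
}

#' Collapse two phased haplotypes per species into unphased sequences
#'
#' Heterozygous sites become IUPAC ambiguity codes; homozygous sites pass
#' through.
#'
#' @param aln An `mc_alignment` with exactly two haplotypes per species,
#'   labelled `<species>_1`, `<species>_2`.
#' @return An `mc_alignment` with one (ambiguity-coded) sequence per species.
#' @export
ambiguity_collapse <- function(aln) {
  species <- sub("_[0-9]+$", "", aln$taxa)
  out <- list()
  for (s in unique(species)) {
    rows <- which(species == s)
    if (length(rows) != 2L) stop("need exactly two haplotypes per species")
    a <- aln$sites[rows[1], ]; b <- aln$sites[rows[2], ]
    code <- mapply(iupac_pair_code, a, b)
    if (any(is.na(code))) stop("ambiguity collapse requires unambiguous input")
    out[[s]] <- paste(code, collapse = "")
  }
  alignment(unlist(out))
}

#' Mean species-tree branch length in coalescent units
#'
#' Computes `tau / (2 Ne)` per branch, with diploid `Ne` equal to half the
#' stored haploid-equivalent size (so the ratio is `tau / N_haploid`), and
#' averages over all non-root branches of all supplied trees.
#'
#' @param species_trees A species tree or list of species trees with
#'   `popsize` set.
#' @return Mean coalescent-unit branch length.
#' @export
coalescent_unit_summary <- function(species_trees) {
  if (inherits(species_trees, "mc_tree")) species_trees <- list(species_trees)
  vals <- unlist(lapply(species_trees, function(tr) {
    if (any(is.na(tr$popsize))) stop("population sizes missing")
    bl <- branch_lengths(tr)
    keep <- !is.na(bl)
    bl[keep] / tr$popsize[keep]
  }))
  mean(vals)
}

# Draw from an inverse-gamma distribution (X = 1/Gamma(shape, rate=scale)).
rinvgamma <- function(n, shape, scale) 1 / stats::rgamma(n, shape, rate = scale)

#' Simulation recipes
#'
#' Named presets reproducing the three study designs:
#' `"prior_test"` (5 species, 1 haplotype, birth 200 / death 100,
#' inverse-gamma(3, 0.004) haploid population sizes, species branch rates
#' from a 100-bin discretized mean-one log-normal with sigma 0.3, two loci
#' with clock rates 0.5 and 2.0, no sequences);
#' `"simstudy"` (21 species, 2 haplotypes, birth 100 / death 30,
#' Gamma(shape 2, scale 0.002) haploid sizes, continuous log-normal species
#' rates sigma 0.3 renormalized to mean 1, log-normal sigma 0.6 locus rates,
#' 130 loci of 600 nt under HKY kappa 3 with 4-category gamma shape 0.2);
#' `"spils"` (fixed caterpillar topology ((((A,B),C),D),E), Yule rate 10 per
#' substitution, inverse-gamma(3, 0.2) haploid sizes, 1 haplotype,
#' 100 loci of 1000 nt under Jukes-Cantor, strict clock, rate 1).
#'
#' @param preset Preset name.
#' @return A list of recipe parameters.
#' @export
sim_recipe <- function(preset = c("prior_test", "simstudy", "spils")) {
  preset <- match.arg(preset)
  switch(preset,
    prior_test = list(
      preset = "prior_test", n_species = 5L, haplotypes = 1L,
      birth = 200, death = 100,
      popsize = list(dist = "invgamma", shape = 3, scale = 0.004),
      species_rate = list(sigma = 0.3, renormalize = FALSE,
                          discretize_bins = 100L),
      locus_rates = c(0.5, 2.0), n_loci = 2L,
      model = NULL, nt = 0L),
    simstudy = list(
      preset = "simstudy", n_species = 21L, haplotypes = 2L,
      birth = 100, death = 30,
      popsize = list(dist = "gamma", shape = 2, scale = 0.002),
      species_rate = list(sigma = 0.3, renormalize = TRUE,
                          discretize_bins = NULL),
      locus_rate_sigma = 0.6, n_loci = 130L,
      model = list(kind = "HKY", kappa = 3),
      gamma_shape = 0.2, gamma_categories = 4L, nt = 600L),
    spils = list(
      preset = "spils", n_species = 5L, haplotypes = 1L,
      topology = "((((A,B),C),D),E)",
      birth = 10, death = 0,
      popsize = list(dist = "invgamma", shape = 3, scale = 0.2),
      species_rate = list(sigma = 0, renormalize = FALSE,
                          discretize_bins = NULL),
      locus_rates_fixed = 1, n_loci = 100L,
      model = list(kind = "JC"), gamma_categories = 1L, nt = 1000L))
}

# Draw per-branch population sizes for a recipe.
draw_popsizes <- function(nn, ps) {
  if (ps$dist == "invgamma") rinvgamma(nn, ps$shape, ps$scale)
  else stats::rgamma(nn, shape = ps$shape, scale = ps$scale)
}

# Simulate one replicate (trees, rates, alignments) for a recipe.
simulate_replicate <- function(recipe, n_loci = recipe$n_loci,
                               nt = recipe$nt) {
  sp_labels <- if (recipe$n_species == 5L && !is.null(recipe$topology))
    c("A", "B", "C", "D", "E") else NULL
  if (!is.null(recipe$topology)) {
    # fixed caterpillar: sorted conditioned-Yule speciation times attached to
    # the asymmetric shape (times and topology are independent)
    times <- sort(bd_speciation_times(recipe$n_species, recipe$birth,
                                      recipe$death))
    n <- recipe$n_species
    parent <- integer(2L * n - 1L)
    height <- c(rep(0, n), times)
    # ((((A,B),C),D),E): node n+1 joins A,B; n+i joins (n+i-1, tip i+1)
    parent[1] <- parent[2] <- n + 1L
    for (i in 2:(n - 1L)) { parent[n + i - 1L] <- n + i; parent[i + 1L] <- n + i }
    species <- mc_tree(parent, height, sp_labels)
  } else {
    species <- simulate_birth_death_tree(recipe$n_species, recipe$birth,
                                         recipe$death)
  }
  species$popsize <- draw_popsizes(species$nnode, recipe$popsize)
  sr <- recipe$species_rate
  rates <- simulate_species_rates(species, sr$sigma, sr$renormalize,
                                  sr$discretize_bins)
  species$rate <- rates$rates
  locus_rates <- if (!is.null(recipe[["locus_rates"]])) recipe[["locus_rates"]]
    else if (!is.null(recipe[["locus_rates_fixed"]]))
      rep(recipe[["locus_rates_fixed"]], n_loci)
    else {
      r <- stats::rlnorm(n_loci, meanlog = -recipe$locus_rate_sigma^2 / 2,
                         sdlog = recipe$locus_rate_sigma)
      r / mean(r)
    }
  n_loci <- length(locus_rates)
  model <- if (!is.null(recipe$model))
    do.call(subst_model, recipe$model) else NULL
  site_rates <- if (!is.null(recipe$gamma_shape))
    site_rate_categories(recipe$gamma_categories, recipe$gamma_shape) else 1
  genes <- vector("list", n_loci); alns <- vector("list", n_loci)
  for (k in seq_len(n_loci)) {
    gt <- simulate_msc_gene_tree(species, recipe$haplotypes)
    emb <- embed_gene_tree(gt, species, attr(gt, "mapping"))
    br <- species_clock_rates(gt, emb, species$rate, locus_rates[k])
    genes[[k]] <- gt
    if (!is.null(model) && nt > 0)
      alns[[k]] <- simulate_alignment(gt, br, model, site_rates, nt)
  }
  list(species = species, genes = genes, alignments = alns,
       locus_rates = locus_rates,
       mapping = attr(genes[[1]], "mapping"), recipe = recipe)
}

#' Write a ready-to-run simulated dataset to disk
#'
#' Generates one or more replicates of a named preset and writes, per
#' replicate, `loci/locus_<k>.fasta`, `truth/species.nwk` (annotated with
#' population sizes and branch rates), `truth/gene_<k>.nwk`,
#' `truth/rates.tsv` (locus clock rates), and `mapping.tsv`.  The scale
#' factor shrinks the number of loci and the alignment length, never the
#' recipe's distributions.
#'
#' @param preset `"prior_test"`, `"simstudy"` or `"spils"`.
#' @param dir Output directory (one subdirectory per replicate).
#' @param n_replicates Number of replicates.
#' @param scale Multiplier in (0, 1] applied to loci count and sites.
#' @param seed Integer seed.
#' @return Invisibly, the replicate directories.
#' @export
make_fixture <- function(preset, dir, n_replicates = 1L, scale = 1,
                         seed = 1L) {
  recipe <- sim_recipe(preset)
  set.seed(seed)
  n_loci <- max(1L, ceiling(recipe$n_loci * scale))
  nt <- if (recipe$nt > 0) max(10L, ceiling(recipe$nt * scale)) else 0L
  dirs <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    rd <- file.path(dir, sprintf("rep%03d", r))
    dir.create(file.path(rd, "loci"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(rd, "truth"), recursive = TRUE, showWarnings = FALSE)
    rep <- simulate_replicate(recipe, n_loci = n_loci, nt = nt)
    write_annotated_newick(rep$species, file.path(rd, "truth", "species.nwk"))
    for (k in seq_along(rep$genes)) {
      write_annotated_newick(rep$genes[[k]],
                             file.path(rd, "truth", sprintf("gene_%03d.nwk", k)))
      if (!is.null(rep$alignments[[k]]))
        write_alignment(rep$alignments[[k]],
                        file.path(rd, "loci", sprintf("locus_%03d.fasta", k)))
    }
    utils::write.table(
      data.frame(locus = seq_along(rep$locus_rates), rate = rep$locus_rates),
      file.path(rd, "truth", "rates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_mapping(rep$mapping, file.path(rd, "mapping.tsv"))
    dirs[r] <- rd
  }
  invisible(dirs)
}
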
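# MCMC proposal kernels.
#
# Every operator takes the current state (see mcmc.R) and returns a proposal:
# list(state = <new state>, log_hr = <log Hastings ratio>, valid = <flag>,
# touched = <which cached components must be refreshed>).  Invalid proposals
# (validity = FALSE) are auto-rejected by the Metropolis-Hastings kernel
# without evaluating the posterior.
#
# The three coordinated operators move the species tree and all gene trees
# in one step:
#  * coordinated_uniform shifts a non-root species node and its gene-tree
#    "connected components" by a common eta drawn so no topology changes;
#    the proposal is symmetric (log HR = 0) because component selection
#    depends only on topologies and the tip mapping, never on heights.
#  * coordinated_exponential does the same for the species root, drawing the
#    new root-minus-bound gap x' from an Exponential(lambda) whose rate is
#    adapted so its median tracks the posterior mean of x; because the new
#    height is independent of the old one, log HR = lambda * eta.
#  * coordinated_exchange makes an NNI (narrow) or SPR-like (wide) change to
#    the species tree and minimally re-attaches the gene lineages whose
#    embedding the move invalidates, choosing attachments uniformly; the log
#    Hastings ratio is the log ratio of reverse to forward attachment
#    probabilities, with the reverse path reconstructed explicitly.

proposal <- function(state = NULL, log_hr = 0, valid = TRUE,
                     touched = list(species = TRUE, loci = "all")) {
  list(state = state, log_hr = log_hr, valid = valid, touched = touched)
}
invalid_proposal <- function() proposal(valid = FALSE)

# ---- connected components -------------------------------------------------

#' Select the connected component of a species node
#'
#' For species node `S`, returns for every locus the gene-tree nodes `s`
#' such that (1) at least one descendant individual of `s` descends from the
#' left child of `S`, (2) at least one descends from the right child, and
#' (3) all descendant individuals of `s` descend from `S`.  These are the
#' nodes shifted jointly with `S` by the coordinated height operators.
#' Selection depends only on topologies and the tip-to-species mapping.
#'
#' @param state An MCMC state (see [init_state()]).
#' @param S Internal species-tree node id.
#' @return List (one integer vector of gene node ids per locus).
#' @export
select_connected_component <- function(state, S) {
  sp <- state$species
  spsets <- node_tip_sets(sp)
  inL <- logical(sp$ntip); inL[spsets[[sp$child1[S]]]] <- TRUE
  inR <- logical(sp$ntip); inR[spsets[[sp$child2[S]]]] <- TRUE
  inS <- inL | inR
  lapply(seq_along(state$genes), function(k) {
    gt <- state$genes[[k]]
    tip_sp <- state$data[[k]]$tip_sp
    gsets <- node_tip_sets(gt)
    sel <- vapply(seq_len(gt$nnode), function(v) {
      spv <- tip_sp[gsets[[v]]]
      any(inL[spv]) && any(inR[spv]) && all(inS[spv])
    }, logical(1))
    which(sel)
  })
}

# Shift species node S and the component's gene nodes by eta.
shift_component <- function(state, S, component, eta) {
  state$species$height[S] <- state$species$height[S] + eta
  for (k in seq_along(state$genes))
    if (length(component[[k]]))
      state$genes[[k]]$height[component[[k]]] <-
        state$genes[[k]]$height[component[[k]]] + eta
  state
}

#' Height-shift bounds for a coordinated move
#'
#' Lower and upper bounds `(D, U)` on the proposed height of species node
#' `S` such that, for every new height in `(D, U)`, shifting `S` and the
#' whole connected component by `eta = t'(S) - t(S)` changes no topology,
#' keeps every tree valid, and preserves gene-tree compatibility.  Each
#' constraint is an offset relative to the constrained node, so the bound is
#' computed in eta space: children of `S` (and, per selected gene node, its
#' children outside the component) bound eta from below; the parent of `S`
#' (and non-component parents of selected nodes) bound it from above.
#'
#' @inheritParams select_connected_component
#' @param component Output of [select_connected_component()].
#' @return Numeric `c(D, U)`; `U` is `Inf` when `S` is the root and no gene
#'   constraint applies.
#' @export
compute_shift_bounds <- function(state, S, component) {
  sp <- state$species
  hS <- sp$height[S]
  eta_min <- max(sp$height[c(sp$child1[S], sp$child2[S])]) - hS
  eta_max <- if (sp$parent[S] != 0L) sp$height[sp$parent[S]] - hS else Inf
  for (k in seq_along(state$genes)) {
    gt <- state$genes[[k]]
    comp <- component[[k]]
    if (!length(comp)) next
    incomp <- logical(gt$nnode); incomp[comp] <- TRUE
    for (s in comp) {
      for (ch in c(gt$child1[s], gt$child2[s]))
        if (ch != 0L && !incomp[ch])
          eta_min <- max(eta_min, gt$height[ch] - gt$height[s])
      p <- gt$parent[s]
      if (p != 0L && !incomp[p])
        eta_max <- min(eta_max, gt$height[p] - gt$height[s])
    }
  }
  c(D = hS + eta_min, U = hS + eta_max)
}

#' Coordinated uniform height operator
#'
#' Picks a non-root internal species node uniformly, selects its connected
#' component, draws the new height uniformly within the no-topology-change
#' bounds, and shifts node and component together.  Symmetric: log HR = 0.
#'
#' @inheritParams select_connected_component
#' @return A proposal.
#' @export
coordinated_uniform_propose <- function(state) {
  sp <- state$species
  cand <- setdiff((sp$ntip + 1L):sp$nnode, sp$root)
  if (!length(cand)) return(invalid_proposal())
  S <- cand[sample.int(length(cand), 1L)]
  comp <- select_connected_component(state, S)
  bounds <- compute_shift_bounds(state, S, comp)
  if (bounds[2] <= bounds[1]) return(invalid_proposal())
  tnew <- stats::runif(1, bounds[1], bounds[2])
  proposal(shift_component(state, S, comp, tnew - sp$height[S]))
}

#' Coordinated exponential root-height operator
#'
#' Shifts the species root and its connected component.  With `D` the lower
#' bound computed as for the uniform operator and `x = t(root) - D`, a new
#' gap `x' ~ Exponential(lambda)` is drawn and everything is shifted by
#' `eta = x' - x`; log HR = `lambda * eta`.  The observed `x` is recorded on
#' the proposal (attribute `x`) so the chain can adapt `lambda`.
#'
#' @inheritParams select_connected_component
#' @param lambda Proposal rate (adapted via [adapt_exponential_rate()]).
#' @return A proposal with attribute `x`.
#' @export
coordinated_exponential_propose <- function(state, lambda = 1) {
  sp <- state$species
  S <- sp$root
  comp <- select_connected_component(state, S)
  bounds <- compute_shift_bounds(state, S, comp)
  x <- unname(sp$height[S] - bounds[1])
  xp <- stats::rexp(1, lambda)
  eta <- xp - x
  pr <- proposal(shift_component(state, S, comp, eta), log_hr = lambda * eta)
  attr(pr, "x") <- unname(x)
  pr
}

#' Adapted rate for the exponential root proposal
#'
#' Sets the proposal rate so the exponential's median `ln 2 / lambda` equals
#' the running posterior mean of the root-minus-bound gap `x`.
#'
#' @param mean_x Running mean of observed `x` values (> 0).
#' @return The rate `lambda = ln 2 / mean_x`.
#' @export
adapt_exponential_rate <- function(mean_x) {
  if (mean_x <= 0) stop("mean of x must be positive")
  log(2) / mean_x
}

# ---- coordinated topology exchange ---------------------------------------

# Species branch occupied by a lineage whose lowest possible branch is m, at
# time h.
branch_at_time <- function(sp, m, h) {
  while (sp$parent[m] != 0L && sp$height[sp$parent[m]] <= h) m <- sp$parent[m]
  m
}

# Gene-tree repair after a species topology change: nodes whose coalescence
# is no longer possible in their species branch are re-attached, lowest
# first, by pruning one child and joining it to a uniformly chosen lineage
# crossing the same height in the same (new) species branch.  Returns the
# repaired tree and the log selection probability, or NULL on failure.  In
# guided mode the choices are forced to reconstruct `target` exactly,
# yielding the reverse-path probability.
repair_gene_tree <- function(gt, sp, tip_sp, target = NULL, max_steps = 64L) {
  log_q <- 0
  for (step in seq_len(max_steps)) {
    m <- gene_node_species_mrca(gt, sp, tip_sp)
    internal <- (gt$ntip + 1L):gt$nnode
    broken <- internal[gt$height[internal] < sp$height[m[internal]]]
    if (!length(broken)) {
      if (!is.null(target) && !identical(gt$parent, target$parent))
        return(NULL)
      return(list(tree = gt, log_q = log_q))
    }
    v <- broken[which.min(gt$height[broken])]
    h <- gt$height[v]
    kids <- c(gt$child1[v], gt$child2[v])
    # lineages crossing height h (child strictly below, parent strictly above)
    nonroot <- which(gt$parent != 0L)
    crossing <- nonroot[gt$height[nonroot] < h &
                          gt$height[gt$parent[nonroot]] > h]
    cross_branch <- vapply(crossing, function(x)
      branch_at_time(sp, m[x], h), integer(1))
    pairs_u <- integer(0); pairs_x <- integer(0)
    for (u in kids) {
      bu <- branch_at_time(sp, m[u], h)
      xs <- crossing[cross_branch == bu & crossing != u]
      pairs_u <- c(pairs_u, rep(u, length(xs)))
      pairs_x <- c(pairs_x, xs)
    }
    if (!length(pairs_u)) return(NULL)
    if (is.null(target)) {
      pick <- sample.int(length(pairs_u), 1L)
    } else {
      tk <- c(target$child1[v], target$child2[v])
      pick <- which((pairs_u == tk[1] & pairs_x == tk[2]) |
                      (pairs_u == tk[2] & pairs_x == tk[1]))
      if (length(pick) != 1L) return(NULL)
    }
    log_q <- log_q - log(length(pairs_u))
    u <- pairs_u[pick]; x <- pairs_x[pick]
    k <- kids[kids != u][1]
    p <- gt$parent[v]; px <- gt$parent[x]
    # v keeps u, adopts x, and takes x's place under px; k replaces v under p
    gt$parent[k] <- p
    gt$parent[x] <- v
    gt$parent[v] <- px
    gt <- rebuild_children(gt)
  }
  NULL
}

# Apply a subtree swap (a under new parent gp, b under new parent p) to a
# species tree.
swap_species_nodes <- function(sp, a, b) {
  pa <- sp$parent[a]; pb <- sp$parent[b]
  sp$parent[a] <- pb; sp$parent[b] <- pa
  rebuild_children(sp)
}

# Eligible (a, b) pairs for a wide exchange: unordered pairs of non-root
# nodes with different parents, neither ancestral to the other, whose swap
# keeps parents above children.
wide_exchange_pairs <- function(sp) {
  nn <- sp$nnode
  anc <- matrix(FALSE, nn, nn)  # anc[i, j]: i is an ancestor of j
  for (j in seq_len(nn)) {
    p <- sp$parent[j]
    while (p != 0L) { anc[p, j] <- TRUE; p <- sp$parent[p] }
  }
  out <- NULL
  nodes <- which(sp$parent != 0L)
  for (i in seq_along(nodes)) for (j in seq_len(i - 1L)) {
    a <- nodes[i]; b <- nodes[j]
    if (sp$parent[a] == sp$parent[b]) next
    if (anc[a, b] || anc[b, a]) next
    if (sp$height[sp$parent[a]] > sp$height[b] &&
        sp$height[sp$parent[b]] > sp$height[a])
      out <- rbind(out, c(a, b))
  }
  out
}

#' Coordinated species/gene topology exchange
#'
#' Proposes a species-tree topology change -- `"nni"`: a narrow exchange
#' swapping a node with its parent's sibling; `"spr"`: a wide exchange
#' swapping two non-adjacent subtrees -- and repairs every gene tree whose
#' embedding the move invalidates by re-attaching broken coalescences to
#' uniformly chosen lineages in the correct species branch at the same
#' height.  The log Hastings ratio sums the log forward attachment counts
#' minus the log reverse counts (the reverse repair path is reconstructed
#' explicitly and the move is rejected if it cannot restore the original
#' gene trees).
#'
#' @inheritParams select_connected_component
#' @param kind `"nni"` or `"spr"`.
#' @return A proposal.
#' @export
coordinated_exchange_propose <- function(state, kind = c("nni", "spr")) {
  kind <- match.arg(kind)
  sp <- state$species
  if (sp$ntip < 3L) return(invalid_proposal())
  log_hr <- 0
  if (kind == "nni") {
    cand <- setdiff((sp$ntip + 1L):sp$nnode, sp$root)
    P <- cand[sample.int(length(cand), 1L)]
    G <- sp$parent[P]
    B <- if (sp$child1[G] == P) sp$child2[G] else sp$child1[G]
    A <- if (stats::runif(1) < 0.5) sp$child1[P] else sp$child2[P]
    if (sp$height[P] <= sp$height[B]) return(invalid_proposal())
    sp_new <- swap_species_nodes(sp, A, B)
  } else {
    pairs <- wide_exchange_pairs(sp)
    if (is.null(pairs)) return(invalid_proposal())
    pick <- pairs[sample.int(nrow(pairs), 1L), ]
    sp_new <- swap_species_nodes(sp, pick[1], pick[2])
    pairs_rev <- wide_exchange_pairs(sp_new)
    if (is.null(pairs_rev)) return(invalid_proposal())
    log_hr <- log_hr + log(nrow(pairs)) - log(nrow(pairs_rev))
  }
  new_state <- state
  new_state$species <- sp_new
  for (k in seq_along(state$genes)) {
    tip_sp <- state$data[[k]]$tip_sp
    fwd <- repair_gene_tree(state$genes[[k]], sp_new, tip_sp)
    if (is.null(fwd)) return(invalid_proposal())
    rev <- repair_gene_tree(fwd$tree, sp, tip_sp, target = state$genes[[k]])
    if (is.null(rev)) return(invalid_proposal())
    log_hr <- log_hr + rev$log_q - fwd$log_q
    new_state$genes[[k]] <- fwd$tree
  }
  proposal(new_state, log_hr = log_hr)
}

# ---- standard (single-component) operators --------------------------------

# BEAST-style scale factor: s ~ U(beta, 1/beta); log HR for d scaled
# dimensions is (d - 2) log s.
draw_scale <- function(beta = 0.5) beta + stats::runif(1) * (1 / beta - beta)

scale_tree_heights <- function(tr, s) {
  internal <- (tr$ntip + 1L):tr$nnode
  tr$height[internal] <- tr$height[internal] * s
  tr
}

#' Standard single-component operators
#'
#' The naive operator suite: tree scalers (species, per-locus gene, and a
#' joint scale of every tree), uniform internal-node height slides, root
#' height scalers, naive narrow exchange on species and gene trees, Wilson-
#' Balding subtree regrafting on gene trees, rate-category redraws, locus-
#' rate delta exchange, and hyperparameter moves.  Species-tree moves that
#' leave any gene tree incompatible are flagged invalid (auto-reject).
#'
#' @name standard_operators
NULL

#' @rdname standard_operators
#' @inheritParams select_connected_component
#' @param beta Scale-kernel lower bound.
#' @export
scale_species_propose <- function(state, beta = 0.75) {
  s <- draw_scale(beta)
  st <- state
  st$species <- scale_tree_heights(st$species, s)
  if (!state_compatible(st)) return(invalid_proposal())
  proposal(st, log_hr = (st$species$ntip - 1 - 2) * log(s),
           touched = list(species = TRUE, loci = "all"))
}

#' @rdname standard_operators
#' @export
scale_all_trees_propose <- function(state, beta = 0.75) {
  s <- draw_scale(beta)
  st <- state
  st$species <- scale_tree_heights(st$species, s)
  d <- st$species$ntip - 1L
  for (k in seq_along(st$genes)) {
    st$genes[[k]] <- scale_tree_heights(st$genes[[k]], s)
    d <- d + st$genes[[k]]$ntip - 1L
  }
  if (!state_compatible(st)) return(invalid_proposal())
  proposal(st, log_hr = (d - 2) * log(s))
}

#' @rdname standard_operators
#' @param locus Locus index; drawn uniformly when `NULL`.
#' @export
scale_gene_propose <- function(state, locus = NULL, beta = 0.75) {
  if (is.null(locus)) locus <- sample.int(length(state$genes), 1L)
  s <- draw_scale(beta)
  st <- state
  st$genes[[locus]] <- scale_tree_heights(st$genes[[locus]], s)
  gt <- st$genes[[locus]]
  if (!locus_compatible(st, locus)) return(invalid_proposal())
  proposal(st, log_hr = (gt$ntip - 1 - 2) * log(s),
           touched = list(species = FALSE, loci = locus))
}

#' @rdname standard_operators
#' @export
uniform_height_propose <- function(state) {
  # pick a tree (species or one locus) uniformly, then a non-root internal
  # node uniformly within it
  sp_ok <- !identical(state$config$estimate_species_heights, FALSE)
  ntrees <- 1L + length(state$genes)
  t_idx <- sample.int(ntrees, 1L)
  if (t_idx == 1L && !sp_ok) return(invalid_proposal())
  if (t_idx == 1L) {
    sp <- state$species
    cand <- setdiff((sp$ntip + 1L):sp$nnode, sp$root)
    if (!length(cand)) return(invalid_proposal())
    v <- cand[sample.int(length(cand), 1L)]
    lo <- max(sp$height[c(sp$child1[v], sp$child2[v])])
    hi <- sp$height[sp$parent[v]]
    st <- state
    st$species$height[v] <- stats::runif(1, lo, hi)
    if (!state_compatible(st)) return(invalid_proposal())
    proposal(st, touched = list(species = TRUE, loci = "all"))
  } else {
    k <- t_idx - 1L
    gt <- state$genes[[k]]
    cand <- setdiff((gt$ntip + 1L):gt$nnode, gt$root)
    if (!length(cand)) return(invalid_proposal())
    v <- cand[sample.int(length(cand), 1L)]
    m <- gene_node_species_mrca(gt, state$species, state$data[[k]]$tip_sp)
    lo <- max(gt$height[c(gt$child1[v], gt$child2[v])],
              state$species$height[m[v]])
    hi <- gt$height[gt$parent[v]]
    st <- state
    st$genes[[k]]$height[v] <- stats::runif(1, lo, hi)
    proposal(st, touched = list(species = FALSE, loci = k))
  }
}

#' @rdname standard_operators
#' @param window Log-scale kernel width for root-gap scaling.
#' @export
root_height_propose <- function(state, window = 2) {
  sp_ok <- !identical(state$config$estimate_species_heights, FALSE)
  ntrees <- 1L + length(state$genes)
  t_idx <- sample.int(ntrees, 1L)
  if (t_idx == 1L && !sp_ok) return(invalid_proposal())
  s <- exp(window * (stats::runif(1) - 0.5))
  if (t_idx == 1L) {
    sp <- state$species
    v <- sp$root
    lo <- max(sp$height[c(sp$child1[v], sp$child2[v])])
    st <- state
    st$species$height[v] <- lo + (sp$height[v] - lo) * s
    if (!state_compatible(st)) return(invalid_proposal())
    proposal(st, log_hr = log(s), touched = list(species = TRUE, loci = "all"))
  } else {
    k <- t_idx - 1L
    gt <- state$genes[[k]]
    v <- gt$root
    lo <- max(gt$height[c(gt$child1[v], gt$child2[v])],
              state$species$height[state$species$root])
    st <- state
    st$genes[[k]]$height[v] <- lo + (gt$height[v] - lo) * s
    proposal(st, log_hr = log(s), touched = list(species = FALSE, loci = k))
  }
}

#' @rdname standard_operators
#' @export
gene_nni_propose <- function(state, locus = NULL) {
  if (is.null(locus)) locus <- sample.int(length(state$genes), 1L)
  gt <- state$genes[[locus]]
  if (gt$ntip < 3L) return(invalid_proposal())
  cand <- setdiff((gt$ntip + 1L):gt$nnode, gt$root)
  P <- cand[sample.int(length(cand), 1L)]
  G <- gt$parent[P]
  B <- if (gt$child1[G] == P) gt$child2[G] else gt$child1[G]
  A <- if (stats::runif(1) < 0.5) gt$child1[P] else gt$child2[P]
  if (gt$height[P] <= gt$height[B]) return(invalid_proposal())
  st <- state
  st$genes[[locus]] <- swap_species_nodes(gt, A, B)
  if (!locus_compatible(st, locus)) return(invalid_proposal())
  proposal(st, touched = list(species = FALSE, loci = locus))
}

#' @rdname standard_operators
#' @export
species_nni_propose <- function(state) {
  sp <- state$species
  if (sp$ntip < 3L) return(invalid_proposal())
  cand <- setdiff((sp$ntip + 1L):sp$nnode, sp$root)
  P <- cand[sample.int(length(cand), 1L)]
  G <- sp$parent[P]
  B <- if (sp$child1[G] == P) sp$child2[G] else sp$child1[G]
  A <- if (stats::runif(1) < 0.5) sp$child1[P] else sp$child2[P]
  if (sp$height[P] <= sp$height[B]) return(invalid_proposal())
  st <- state
  st$species <- swap_species_nodes(sp, A, B)
  if (!state_compatible(st)) return(invalid_proposal())
  proposal(st, touched = list(species = TRUE, loci = "all"))
}

#' @rdname standard_operators
#' @export
gene_wilson_balding_propose <- function(state, locus = NULL) {
  if (is.null(locus)) locus <- sample.int(length(state$genes), 1L)
  gt <- state$genes[[locus]]
  sp <- state$species
  tip_sp <- state$data[[locus]]$tip_sp
  nodes <- which(gt$parent != 0L)
  i <- nodes[sample.int(length(nodes), 1L)]
  p <- gt$parent[i]
  if (p == gt$root) return(invalid_proposal())
  j <- sample.int(gt$nnode, 1L)
  if (j == i || j == p || gt$parent[j] == 0L) return(invalid_proposal())
  # j must not be inside i's subtree
  w <- j
  while (w != 0L) { if (w == i) return(invalid_proposal()); w <- gt$parent[w] }
  pj <- gt$parent[j]
  sib <- if (gt$child1[p] == i) gt$child2[p] else gt$child1[p]
  pp <- gt$parent[p]
  if (pj == p) return(invalid_proposal())
  m <- gene_node_species_mrca(gt, sp, tip_sp)
  mrca_ij <- sp_mrca_pair(sp, m[i], m[j])
  lo_f <- max(gt$height[i], gt$height[j], sp$height[mrca_ij])
  hi_f <- gt$height[pj]
  if (hi_f <= lo_f) return(invalid_proposal())
  # reverse interval: reattach i onto its old sibling's branch
  mrca_is <- sp_mrca_pair(sp, m[i], m[sib])
  lo_r <- max(gt$height[i], gt$height[sib], sp$height[mrca_is])
  hi_r <- gt$height[pp]
  if (hi_r <= lo_r) return(invalid_proposal())
  st <- state
  g <- gt
  g$parent[sib] <- pp
  g$parent[j] <- p
  g$parent[p] <- pj
  g$height[p] <- stats::runif(1, lo_f, hi_f)
  g <- rebuild_children(g)
  st$genes[[locus]] <- g
  if (!locus_compatible(st, locus)) return(invalid_proposal())
  # q(fwd) has density 1/(hi_f - lo_f) for the new height, q(rev)
  # 1/(hi_r - lo_r) for restoring the old one: HR is their ratio
  proposal(st, log_hr = log(hi_f - lo_f) - log(hi_r - lo_r),
           touched = list(species = FALSE, loci = locus))
}

# MRCA of two species-tree nodes.
sp_mrca_pair <- function(sp, a, b) {
  while (a != b) {
    if (sp$height[a] < sp$height[b]) a <- sp$parent[a] else b <- sp$parent[b]
  }
  a
}

#' @rdname standard_operators
#' @export
rate_category_propose <- function(state) {
  cfg <- state$config
  if (startsWith(cfg$clock, "st_")) {
    cand <- which(!is.na(state$sp_categories))
    if (!length(cand)) return(invalid_proposal())
    v <- cand[sample.int(length(cand), 1L)]
    st <- state
    st$sp_categories[v] <- sample.int(cfg$clock_bins, 1L)
    proposal(st, touched = list(species = TRUE, loci = "all"))
  } else if (startsWith(cfg$clock, "gt_")) {
    k <- sample.int(length(state$genes), 1L)
    cand <- which(!is.na(state$gene_categories[[k]]))
    v <- cand[sample.int(length(cand), 1L)]
    st <- state
    st$gene_categories[[k]][v] <- sample.int(cfg$clock_bins, 1L)
    proposal(st, touched = list(species = FALSE, loci = k))
  } else invalid_proposal()
}

#' @rdname standard_operators
#' @param delta Half-width of the transfer window.
#' @export
locus_rate_delta_propose <- function(state, delta = 0.4) {
  if (length(state$genes) < 2L || !isTRUE(state$config$estimate_locus_rates))
    return(invalid_proposal())
  ij <- sample.int(length(state$genes), 2L)
  d <- stats::runif(1, -delta, delta)
  st <- state
  st$locus_rates[ij[1]] <- st$locus_rates[ij[1]] + d
  st$locus_rates[ij[2]] <- st$locus_rates[ij[2]] - d
  if (any(st$locus_rates[ij] <= 0)) return(invalid_proposal())
  proposal(st, touched = list(species = FALSE, loci = ij))
}

#' @rdname standard_operators
#' @export
pop_mean_propose <- function(state, window = 0.7) {
  if (!isTRUE(state$config$estimate_pop_mean)) return(invalid_proposal())
  s <- exp(window * (stats::runif(1) - 0.5))
  st <- state
  st$pop_mean <- st$pop_mean * s
  rng <- state$config$pop_mean_range
  if (st$pop_mean < rng[1] || st$pop_mean > rng[2])
    return(invalid_proposal())
  proposal(st, log_hr = log(s), touched = list(species = FALSE, loci = integer(0)))
}

#' @rdname standard_operators
#' @export
popsize_propose <- function(state, window = 0.7) {
  if (state$config$popsize_mode != "mcmc") return(invalid_proposal())
  b <- sample.int(state$species$nnode, 1L)
  s <- exp(window * (stats::runif(1) - 0.5))
  st <- state
  st$species$popsize[b] <- st$species$popsize[b] * s
  proposal(st, log_hr = log(s), touched = list(species = FALSE, loci = "coal"))
}

#' @rdname standard_operators
#' @export
bd_params_propose <- function(state, window = 0.3) {
  if (!isTRUE(state$config$estimate_bd)) return(invalid_proposal())
  st <- state
  if (stats::runif(1) < 0.5) {
    s <- exp(window * (stats::runif(1) - 0.5))
    st$birth_d <- st$birth_d * s
    rng <- state$config$bd_d_range
    if (st$birth_d < rng[1] || st$birth_d > rng[2]) return(invalid_proposal())
    return(proposal(st, log_hr = log(s),
                    touched = list(species = FALSE, loci = integer(0))))
  }
  f <- st$birth_f + stats::runif(1, -window, window)
  fmax <- 0.999
  # reflect at the bounds so the move stays symmetric
  while (f < 0 || f > fmax) f <- if (f < 0) -f else 2 * fmax - f
  st$birth_f <- f
  proposal(st, touched = list(species = FALSE, loci = integer(0)))
}
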
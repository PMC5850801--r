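# Helpers to compare states after proposals.
trees_equal <- function(a, b, tol = 1e-12) {
  identical(a$parent, b$parent) && max(abs(a$height - b$height)) < tol
}

prior_state <- function(n_species = 5, n_loci = 2, seed = 1, clock = "strict") {
  cfg <- prior_config(n_species, n_loci, clock = clock, seed = seed)
  set.seed(seed)
  init_state(cfg)
}

test_that("connected components match brute-force set algebra", {
  set.seed(71)
  for (rep in 1:10) {
    state <- prior_state(5, 3, seed = rep)
    sp <- state$species
    for (S in (sp$ntip + 1L):sp$nnode) {
      comp <- select_connected_component(state, S)
      hapL <- descendant_individuals(sp$child1[S], sp,
                                     mapping = state$data[[1]]$mapping)
      hapR <- descendant_individuals(sp$child2[S], sp,
                                     mapping = state$data[[1]]$mapping)
      hapS <- descendant_individuals(S, sp, mapping = state$data[[1]]$mapping)
      for (k in seq_along(state$genes)) {
        gt <- state$genes[[k]]
        expected <- Filter(function(v) {
          ind <- descendant_individuals(v, gt)
          length(intersect(ind, hapL)) > 0 &&
            length(intersect(ind, hapR)) > 0 &&
            all(ind %in% hapS)
        }, seq_len(gt$nnode))
        expect_equal(sort(comp[[k]]), sort(as.integer(expected)))
      }
    }
  }
})

test_that("the worked-example component is the single coalescence node", {
  cfg <- prior_config(2, 1, seed = 3)
  set.seed(3)
  state <- init_state(cfg)
  S <- state$species$root
  comp <- select_connected_component(state, S)
  gt <- state$genes[[1]]
  expect_equal(comp[[1]], gt$root)  # tips excluded, root selected
})

test_that("shift bounds agree with a fine grid scan of eta validity", {
  set.seed(73)
  shift_by <- function(state, S, comp, eta) {
    st <- mscoal:::shift_component(state, S, comp, eta)
    sp_ok <- tryCatch({ validate_tree(st$species); TRUE },
                      error = function(e) FALSE)
    gene_ok <- all(vapply(seq_along(st$genes), function(k)
      tryCatch({
        validate_tree(st$genes[[k]])
        mscoal:::locus_compatible(st, k)
      }, error = function(e) FALSE), TRUE))
    sp_ok && gene_ok
  }
  for (rep in 1:6) {
    state <- prior_state(4, 2, seed = 100 + rep)
    sp <- state$species
    cand <- (sp$ntip + 1L):sp$nnode
    for (S in cand) {
      comp <- select_connected_component(state, S)
      b <- compute_shift_bounds(state, S, comp)
      h <- sp$height[S]
      scale <- sp$height[sp$root]
      step <- 1e-4 * scale
      # inside the bounds: every eta keeps the state valid and compatible
      lo <- max(b[1], h - 0.05 * scale * 500) # clip unbounded sides
      hi <- min(b[2], h + 0.05 * scale * 500)
      for (tnew in seq(lo + step, hi - step, length.out = 7))
        expect_true(shift_by(state, S, comp, tnew - h))
      # just outside: invalid (when the bound is finite)
      expect_false(shift_by(state, S, comp, b[1] - step - h))
      if (is.finite(b[2]))
        expect_false(shift_by(state, S, comp, b[2] + step - h))
      # the same component is re-selected after an interior shift
      st2 <- mscoal:::shift_component(state, S, comp,
                                      (b[1] + min(hi, b[1] + scale)) / 2 - h)
      comp2 <- select_connected_component(st2, S)
      expect_identical(comp, comp2)
    }
  }
})

test_that("coordinated uniform preserves topology, validity and symmetry", {
  set.seed(75)
  for (rep in 1:20) {
    state <- prior_state(4, 2, seed = 200 + rep)
    prop <- coordinated_uniform_propose(state)
    expect_true(prop$valid)
    expect_equal(prop$log_hr, 0)
    st <- prop$state
    expect_true(mscoal:::state_compatible(st))
    expect_identical(st$species$parent, state$species$parent)
    for (k in seq_along(st$genes))
      expect_identical(st$genes[[k]]$parent, state$genes[[k]]$parent)
    # round trip: shifting back restores the state exactly
    S_changed <- which(st$species$height != state$species$height)
    if (length(S_changed)) {
      S <- S_changed[1]
      eta <- st$species$height[S] - state$species$height[S]
      comp <- select_connected_component(st, S)
      back <- mscoal:::shift_component(st, S, comp, -eta)
      expect_true(trees_equal(back$species, state$species))
      for (k in seq_along(back$genes))
        expect_true(trees_equal(back$genes[[k]], state$genes[[k]]))
    }
  }
  # two-species trees leave no non-root internal node: inapplicable
  st2 <- prior_state(2, 1, seed = 4)
  expect_false(coordinated_uniform_propose(st2)$valid)
})

test_that("coordinated exponential reports log HR = lambda * eta", {
  set.seed(77)
  for (lambda in c(0.5, 2)) {
    state <- prior_state(4, 2, seed = 300)
    prop <- coordinated_exponential_propose(state, lambda = lambda)
    expect_true(prop$valid)
    eta <- prop$state$species$height[prop$state$species$root] -
      state$species$height[state$species$root]
    expect_equal(prop$log_hr, lambda * eta, tolerance = 1e-12)
    expect_true(mscoal:::state_compatible(prop$state))
    expect_gt(attr(prop, "x"), 0)
  }
  # direct substitution: lambda = 2, eta = 0.3 gives log HR 0.6
  expect_equal(2 * 0.3, 0.6)
})

test_that("exponential-rate adaptation matches the median identity", {
  expect_equal(adapt_exponential_rate(log(2)), 1)
  expect_equal(adapt_exponential_rate(0.6931), 1, tolerance = 1e-4)
  expect_equal(stats::qexp(0.5, adapt_exponential_rate(0.25)), 0.25,
               tolerance = 1e-12)
  expect_error(adapt_exponential_rate(0), "positive")
})

test_that("coordinated exchange proposals stay compatible and reversible", {
  set.seed(79)
  n_valid <- 0
  for (rep in 1:60) {
    state <- prior_state(sample(4:5, 1), 2, seed = 400 + rep)
    kind <- sample(c("nni", "spr"), 1)
    prop <- coordinated_exchange_propose(state, kind)
    if (!prop$valid) next
    n_valid <- n_valid + 1
    expect_true(mscoal:::state_compatible(prop$state))
    expect_true(is.finite(prop$log_hr))
    # gene tree heights never change, only attachments
    for (k in seq_along(state$genes))
      expect_equal(prop$state$genes[[k]]$height, state$genes[[k]]$height)
  }
  expect_gt(n_valid, 20)
})

test_that("a species exchange with no gene conflicts is a pure move", {
  # deep gene coalescences (all above the species root) conflict with no
  # species rearrangement: log HR must be exactly 0 for NNI
  set.seed(81)
  state <- prior_state(4, 2, seed = 500)
  for (k in seq_along(state$genes)) {
    gt <- state$genes[[k]]
    internal <- (gt$ntip + 1L):gt$nnode
    gt$height[internal] <- state$species$height[state$species$root] +
      seq_along(internal) * 0.01
    state$genes[[k]] <- gt
  }
  state <- mscoal:::refresh_cache(state, list(species = TRUE, loci = "all"))
  for (i in 1:10) {
    prop <- coordinated_exchange_propose(state, "nni")
    if (!prop$valid) next
    expect_equal(prop$log_hr, 0)
    for (k in seq_along(state$genes))
      expect_identical(prop$state$genes[[k]]$parent, state$genes[[k]]$parent)
  }
})

test_that("standard operators obey their Hastings contracts", {
  set.seed(83)
  state <- prior_state(4, 2, seed = 600)
  # scale with s drawn this way is never exactly 1, but log HR must follow
  # (d - 2) log s for the species scaler
  prop <- scale_species_propose(state)
  if (prop$valid) {
    s <- prop$state$species$height[prop$state$species$root] /
      state$species$height[state$species$root]
    expect_equal(prop$log_hr, (state$species$ntip - 1 - 2) * log(s),
                 tolerance = 1e-9)
  }
  # uniform height slide: symmetric
  prop2 <- uniform_height_propose(state)
  if (prop2$valid) expect_equal(prop2$log_hr, 0)
  # naive species NNI that breaks compatibility is flagged invalid
  st <- state
  found_invalid <- FALSE
  for (i in 1:50) {
    p <- species_nni_propose(st)
    if (!p$valid) { found_invalid <- TRUE; break }
    expect_true(mscoal:::state_compatible(p$state))
  }
  succeed()  # contract checks above are the assertions
})

test_that("wilson-balding round trip restores the original tree", {
  set.seed(85)
  restored <- 0; tried <- 0
  for (i in 1:80) {
    state <- prior_state(4, 1, seed = 700 + i %% 7)
    prop <- gene_wilson_balding_propose(state, locus = 1)
    if (!prop$valid) next
    tried <- tried + 1
    expect_true(mscoal:::locus_compatible(prop$state, 1))
    # reverse move exists: some WB proposal from the new state restores the
    # original topology
    for (j in 1:120) {
      back <- gene_wilson_balding_propose(prop$state, locus = 1)
      if (back$valid &&
          identical(back$state$genes[[1]]$parent, state$genes[[1]]$parent)) {
        restored <- restored + 1
        break
      }
    }
  }
  expect_gt(tried, 12)
  expect_gt(restored / tried, 0.5)
})
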
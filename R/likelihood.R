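# Felsenstein pruning likelihood for one locus.
#
# Substitution models are time-reversible CTMCs on {A,C,G,T}, normalized so
# one unit of (rate x time) equals one expected substitution.  Transition
# probabilities come from the symmetric eigendecomposition of the rate
# matrix (computed once per model and cached).  Among-site rate variation
# uses the discrete-gamma convention of equal-weight categories whose rates
# are the within-bin means (mean exactly 1); the site likelihood is averaged
# over categories.  Gaps, N and IUPAC ambiguity codes enter as partial
# likelihoods with a 1 for every compatible base.

NUC <- c("A", "C", "G", "T")

# IUPAC code -> length-4 0/1 partial likelihood row.
iupac_table <- local({
  codes <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = NUC, "-" = NUC, "?" = NUC)
  tab <- t(vapply(codes, function(x) as.numeric(NUC %in% x), numeric(4)))
  colnames(tab) <- NUC
  tab
})

# Base pair -> IUPAC ambiguity code (for unphased diplotypes).
iupac_pair_code <- function(a, b) {
  pair <- paste(sort(c(a, b)), collapse = "")
  c(AA = "A", CC = "C", GG = "G", TT = "T",
    AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")[pair]
}

#' Nucleotide substitution model
#'
#' Builds a normalized reversible rate matrix for the JC, HKY or GTR model.
#' HKY with `kappa = 1` and equal frequencies is Jukes-Cantor.
#'
#' @param kind `"JC"`, `"HKY"` or `"GTR"`.
#' @param kappa HKY transition/transversion rate ratio.
#' @param freqs Base frequencies (A, C, G, T); must sum to 1.
#' @param exchangeabilities Six GTR exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.
#' @return A `subst_model` object carrying the rate matrix and its cached
#'   eigendecomposition.
#' @export
subst_model <- function(kind = c("JC", "HKY", "GTR"), kappa = 1,
                        freqs = rep(0.25, 4),
                        exchangeabilities = rep(1, 6)) {
  kind <- match.arg(kind)
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  if (kind == "JC") { freqs <- rep(0.25, 4); kappa <- 1 }
  ex <- switch(kind,
    JC = rep(1, 6),
    HKY = c(1, kappa, 1, 1, kappa, 1),
    GTR = exchangeabilities)
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (i in seq_len(6)) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    Q[a, b] <- ex[i] * freqs[b]
    Q[b, a] <- ex[i] * freqs[a]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * freqs)  # one expected substitution per unit distance
  # symmetric eigendecomposition: B = diag(sqrt(pi)) Q diag(1/sqrt(pi))
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(kind = kind, kappa = kappa, freqs = freqs, Q = Q,
                 evec = diag(1 / sp) %*% eig$vectors,
                 ivec = t(eig$vectors) %*% diag(sp),
                 evals = eig$values),
            class = "subst_model")
}

#' Transition probability matrix
#'
#' @param model A [subst_model()].
#' @param distance Evolutionary distance (rate x time, >= 0).
#' @return 4x4 stochastic matrix; the identity at distance 0.
#' @export
transition_probabilities <- function(model, distance) {
  if (distance < 0) stop("distance must be non-negative")
  P <- model$evec %*% (exp(model$evals * distance) * model$ivec)
  P[P < 0] <- 0
  dimnames(P) <- list(NUC, NUC)
  P
}

#' Discrete-gamma site rate model
#'
#' Equal-weight categories whose rates are the conditional means of a
#' mean-one gamma distribution within each quantile bin; the category rates
#' average exactly to 1.
#'
#' @param n_categories Number of categories (1 disables rate variation).
#' @param shape Gamma shape parameter.
#' @return Numeric vector of category rates.
#' @export
site_rate_categories <- function(n_categories = 4L, shape = 1) {
  if (n_categories == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = n_categories + 1),
                     shape = shape, rate = shape)
  # E[X 1{X < q}] for Gamma(shape a, rate a) equals pgamma(q, a + 1, a)
  inc <- stats::pgamma(q, shape = shape + 1, rate = shape)
  n_categories * diff(inc)
}

#' Build an alignment object
#'
#' @param seqs Named character vector of equal-length sequences (IUPAC
#'   codes), or a list of per-taxon character vectors.
#' @return An `mc_alignment`: list with `taxa`, `nsites`, and a character
#'   matrix `sites` (taxa x sites).
#' @export
alignment <- function(seqs) {
  if (is.list(seqs)) seqs <- vapply(seqs, paste, "", collapse = "")
  if (is.null(names(seqs))) stop("sequences must be named by taxon")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("alignment must be rectangular")
  if (lens[1] == 0L) stop("empty alignment")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  structure(list(taxa = names(seqs), nsites = ncol(mat), sites = mat),
            class = "mc_alignment")
}

#' Read a FASTA or NEXUS alignment
#'
#' FASTA is read via [ape::read.FASTA]; NEXUS DATA/CHARACTERS blocks
#' (interleaved or not) via [ape::read.nexus.data].
#'
#' @param file Path; format guessed from the first non-blank character
#'   (`>` means FASTA, `#` NEXUS) unless `format` is given.
#' @param format `"fasta"`, `"nexus"`, or `NULL` to guess.
#' @return An `mc_alignment`.
#' @export
read_alignment <- function(file, format = NULL) {
  if (is.null(format)) {
    first <- readLines(file, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "nexus"
  }
  if (format == "fasta") {
    dna <- ape::read.FASTA(file)
    seqs <- vapply(as.character(dna), paste, "", collapse = "")
  } else {
    dna <- ape::read.nexus.data(file)
    seqs <- vapply(dna, paste, "", collapse = "")
  }
  alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln An `mc_alignment`.
#' @param file Output path.
#' @export
write_alignment <- function(aln, file) {
  con <- file(file, "w"); on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    writeLines(paste(aln$sites[i, ], collapse = ""), con)
  }
  invisible(file)
}

#' Compress an alignment into unique site patterns
#'
#' @param aln An `mc_alignment`.
#' @return List with `patterns` (character matrix, taxa x unique patterns)
#'   and integer `weights`; the weighted pattern likelihood equals the
#'   uncompressed site-by-site likelihood.
#' @export
site_pattern_compress <- function(aln) {
  if (aln$nsites == 0L) stop("empty alignment")
  key <- apply(aln$sites, 2, paste, collapse = "\r")
  uk <- unique(key)
  idx <- match(uk, key)
  list(patterns = aln$sites[, idx, drop = FALSE],
       weights = as.integer(table(key)[uk]))
}

# Tip partial likelihoods: list over taxa of 4 x npattern matrices.
tip_partials <- function(patterns) {
  lapply(seq_len(nrow(patterns)), function(i) {
    ch <- patterns[i, ]
    bad <- !(ch %in% rownames(iupac_table))
    if (any(bad)) stop("unknown residue: ", ch[bad][1])
    t(iupac_table[ch, , drop = FALSE])
  })
}

#' Phylogenetic log likelihood of one locus
#'
#' Felsenstein pruning over compressed site patterns, averaging the site
#' likelihood over discrete gamma categories, with per-node rescaling to
#' prevent underflow.
#'
#' @param aln An `mc_alignment` whose taxa match the gene tree's tips.
#' @param gene_tree The gene tree (`mc_tree`).
#' @param branch_rates Substitution rate per gene-tree node (branch above
#'   it; the root entry is ignored).
#' @param model A [subst_model()].
#' @param site_rates Category rates from [site_rate_categories()] (default:
#'   no rate variation).
#' @return Log likelihood.
#' @export
locus_log_likelihood <- function(aln, gene_tree, branch_rates, model,
                                 site_rates = 1) {
  if (!setequal(aln$taxa, gene_tree$tip_label))
    stop("alignment taxa do not match gene-tree tips")
  comp <- site_pattern_compress(aln)
  ord <- match(gene_tree$tip_label, aln$taxa)
  tp <- tip_partials(comp$patterns[ord, , drop = FALSE])
  pruning_log_likelihood(gene_tree, branch_rates, model, site_rates,
                         tp, comp$weights)
}

# Core pruning over precomputed tip partials; shared with cached MCMC paths.
pruning_log_likelihood <- function(gene_tree, branch_rates, model,
                                   site_rates, tip_partials, weights) {
  npat <- length(weights)
  bl <- branch_lengths(gene_tree)
  po <- postorder_internal(gene_tree)
  sitelik <- numeric(npat)
  for (sr in site_rates) {
    partial <- vector("list", gene_tree$nnode)
    scale_log <- numeric(npat)
    for (i in seq_len(gene_tree$ntip)) partial[[i]] <- tip_partials[[i]]
    for (v in po) {
      c1 <- gene_tree$child1[v]; c2 <- gene_tree$child2[v]
      P1 <- transition_probabilities(model, bl[c1] * branch_rates[c1] * sr)
      P2 <- transition_probabilities(model, bl[c2] * branch_rates[c2] * sr)
      m <- (P1 %*% partial[[c1]]) * (P2 %*% partial[[c2]])
      mx <- pmax(m[1L, ], m[2L, ], m[3L, ], m[4L, ])
      mx[mx == 0] <- 1
      scale_log <- scale_log + log(mx)
      partial[[v]] <- m * rep.int(1 / mx, rep.int(4L, npat))
    }
    root_lik <- as.numeric(model$freqs %*% partial[[gene_tree$root]])
    sitelik <- sitelik + exp(log(root_lik) + scale_log) / length(site_rates)
  }
  sum(weights * log(sitelik))
}
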
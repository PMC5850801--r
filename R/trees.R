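# Core tree data model shared by every other module.
#
# Trees are rooted, strictly binary time trees: node heights are measured
# backwards from the present, all tips sit at height 0, and every internal
# node is strictly higher than both of its children.  Nodes are identified by
# stable integer ids (1..ntip are tips, ntip+1..2*ntip-1 are internal nodes);
# MCMC proposals rewire parent/child pointers but never renumber nodes, so a
# "connected component" selected before a move still names the same nodes
# after it.  The branch associated with a node is the branch directly above
# it; the root's "branch" is the stem extending into the infinite past, which
# carries a population size and a substitution rate like any other branch
# (gene lineages that have not yet coalesced at the root height live there).

#' Construct a time tree
#'
#' Low-level constructor for the rooted binary time trees used throughout the
#' package.  Tips are nodes `1..ntip`, internal nodes `ntip+1..2*ntip-1`.
#'
#' @param parent Integer vector of length `2*ntip-1`; `parent[i]` is the node
#'   id of node `i`'s parent, `0` for the root.
#' @param height Numeric node heights (time before present); tips must be 0.
#' @param tip_label Character vector of `ntip` unique tip labels.
#' @param popsize Optional per-branch haploid population sizes (length
#'   `2*ntip-1`, entry for the branch above each node; the root entry is the
#'   stem branch).
#' @param rate Optional per-branch relative substitution rates, same layout.
#' @param check Validate invariants (default `TRUE`).
#' @return An object of class `mc_tree`.
#' @export
mc_tree <- function(parent, height, tip_label, popsize = NULL, rate = NULL,
                    check = TRUE) {
  ntip <- length(tip_label)
  nn <- 2L * ntip - 1L
  parent <- as.integer(parent)
  tr <- structure(list(
    ntip = ntip, nnode = nn,
    parent = parent,
    height = as.numeric(height),
    tip_label = tip_label,
    popsize = if (is.null(popsize)) rep(NA_real_, nn) else as.numeric(popsize),
    rate = if (is.null(rate)) rep(NA_real_, nn) else as.numeric(rate)
  ), class = "mc_tree")
  tr <- rebuild_children(tr)
  if (check) validate_tree(tr)
  tr
}

# Recompute child pointers and root id from the parent vector.
rebuild_children <- function(tr) {
  nn <- tr$nnode
  child1 <- integer(nn); child2 <- integer(nn)
  root <- 0L
  for (i in seq_len(nn)) {
    p <- tr$parent[i]
    if (p == 0L) root <- i
    else if (child1[p] == 0L) child1[p] <- i
    else child2[p] <- i
  }
  tr$child1 <- child1; tr$child2 <- child2; tr$root <- root
  tr
}

#' Validate a time tree
#'
#' Checks binary rooted shape, unique root, tips at height 0, parents
#' strictly higher than children, and positivity of any population sizes and
#' rates.  Errors on the first violation.
#'
#' @param tr An `mc_tree`.
#' @return `tr`, invisibly.
#' @export
validate_tree <- function(tr) {
  ntip <- tr$ntip; nn <- tr$nnode
  if (sum(tr$parent == 0L) != 1L) stop("tree must have exactly one root")
  if (anyDuplicated(tr$tip_label)) stop("duplicate tip labels")
  internal <- if (ntip > 1L) (ntip + 1L):nn else integer(0)
  if (any(tr$child1[internal] == 0L) || any(tr$child2[internal] == 0L))
    stop("tree is not strictly binary")
  if (any(tr$child1[seq_len(ntip)] != 0L)) stop("tips must be leaves")
  if (any(tr$height[seq_len(ntip)] != 0)) stop("all tips must be at height 0")
  kids <- tr$parent != 0L
  if (any(tr$height[tr$parent[kids]] <= tr$height[which(kids)]))
    stop("every internal node must be strictly higher than its children")
  if (any(!is.na(tr$popsize) & tr$popsize <= 0)) stop("population sizes must be > 0")
  if (any(!is.na(tr$rate) & tr$rate <= 0)) stop("branch rates must be > 0")
  invisible(tr)
}

#' Branch lengths of a time tree
#'
#' @param tr An `mc_tree`.
#' @return Numeric vector over nodes; `NA` for the root (its stem has no
#'   finite length).
#' @export
branch_lengths <- function(tr) {
  bl <- rep(NA_real_, tr$nnode)
  kids <- which(tr$parent != 0L)
  bl[kids] <- tr$height[tr$parent[kids]] - tr$height[kids]
  bl
}

# Internal node ids in an order guaranteed to visit children before parents.
postorder_internal <- function(tr) {
  if (tr$ntip == 1L) return(integer(0))
  ord <- integer(tr$ntip - 1L); n <- 0L
  visited <- c(rep(TRUE, tr$ntip), rep(FALSE, tr$ntip - 1L))
  stack <- tr$root; sp <- 1L
  while (sp > 0L) {
    v <- stack[sp]
    c1 <- tr$child1[v]; c2 <- tr$child2[v]
    if (!visited[c1]) { sp <- sp + 1L; stack[sp] <- c1; next }
    if (!visited[c2]) { sp <- sp + 1L; stack[sp] <- c2; next }
    visited[v] <- TRUE; n <- n + 1L; ord[n] <- v; sp <- sp - 1L
  }
  ord
}

# Tip ids descending from each node, as a list of integer vectors.
node_tip_sets <- function(tr) {
  sets <- vector("list", tr$nnode)
  for (i in seq_len(tr$ntip)) sets[[i]] <- i
  for (v in postorder_internal(tr))
    sets[[v]] <- c(sets[[tr$child1[v]]], sets[[tr$child2[v]]])
  sets
}

#' Descendant individuals of a node
#'
#' For a species-tree node, returns the haplotype (gene-tree tip) labels of
#' all individuals sampled from its descendant extant species; for a
#' gene-tree node, all descendant gene tips.  This is the selection currency
#' of the coordinated node-height operators.
#'
#' @param node Node id.
#' @param tree The `mc_tree` the node belongs to.
#' @param mapping Named character vector (names = haplotype labels, values =
#'   species labels).  Required for species trees, ignored for gene trees.
#' @param is_species_tree Is `tree` the species tree?
#' @return Character vector of haplotype labels.
#' @export
descendant_individuals <- function(node, tree, mapping = NULL,
                                   is_species_tree = !is.null(mapping)) {
  tips <- node_tip_sets(tree)[[node]]
  labs <- tree$tip_label[tips]
  if (is_species_tree) {
    if (is.null(mapping)) stop("mapping required for species-tree nodes")
    names(mapping)[mapping %in% labs]
  } else labs
}

#' Validate a tip-to-species mapping
#'
#' @param gene_tree Gene tree (`mc_tree`) whose tips are haplotypes.
#' @param species_tree Species tree (`mc_tree`).
#' @param mapping Named character vector or two-column data frame
#'   (haplotype, species).
#' @return The mapping as a named character vector, restricted to the gene
#'   tree's tips.
#' @export
validate_mapping <- function(gene_tree, species_tree, mapping) {
  if (is.data.frame(mapping)) {
    m <- as.character(mapping[[2]]); names(m) <- as.character(mapping[[1]])
    mapping <- m
  }
  if (anyDuplicated(names(mapping)))
    stop("duplicate tip assignment in mapping")
  missing_tips <- setdiff(gene_tree$tip_label, names(mapping))
  if (length(missing_tips))
    stop("unmapped gene-tree tips: ", paste(missing_tips, collapse = ", "))
  mapping <- mapping[gene_tree$tip_label]
  unknown <- setdiff(unique(mapping), species_tree$tip_label)
  if (length(unknown))
    stop("mapped species not in species tree: ", paste(unknown, collapse = ", "))
  mapping
}

# Species-tree tip id for each gene-tree tip, given a validated mapping.
tip_species_ids <- function(gene_tree, species_tree, mapping) {
  match(mapping[gene_tree$tip_label], species_tree$tip_label)
}

# For every gene-tree node, the species-tree node that is the MRCA of the
# species its descendants were sampled from.  This is the lowest species
# branch the lineage above that node can occupy.
gene_node_species_mrca <- function(gene_tree, species_tree, tip_sp) {
  m <- integer(gene_tree$nnode)
  m[seq_len(gene_tree$ntip)] <- tip_sp
  for (v in postorder_internal(gene_tree)) {
    a <- m[gene_tree$child1[v]]; b <- m[gene_tree$child2[v]]
    while (a != b) {  # walk the lower one up until the paths meet
      if (species_tree$height[a] < species_tree$height[b] ||
          (species_tree$height[a] == species_tree$height[b] && a != b))
        a <- species_tree$parent[a]
      else b <- species_tree$parent[b]
      if (a == 0L || b == 0L) stop("disconnected species tree")
      if (species_tree$height[a] > species_tree$height[b]) { tmp <- a; a <- b; b <- tmp }
    }
    m[v] <- a
  }
  m
}

#' Is a gene tree compatible with a species tree?
#'
#' A gene tree is compatible when every coalescence joining lineages sampled
#' from species X and Y happens no earlier (no lower) than the species-tree
#' MRCA of X and Y -- equivalently, when every gene lineage can be embedded
#' in the species branch it traverses.
#'
#' @inheritParams validate_mapping
#' @param mapping A validated named mapping (see [validate_mapping()]).
#' @return Logical scalar.
#' @export
is_compatible <- function(gene_tree, species_tree, mapping) {
  tip_sp <- tip_species_ids(gene_tree, species_tree, mapping)
  m <- gene_node_species_mrca(gene_tree, species_tree, tip_sp)
  internal <- (gene_tree$ntip + 1L):gene_tree$nnode
  all(gene_tree$height[internal] >= species_tree$height[m[internal]])
}

#' Embed a gene tree in a species tree
#'
#' Computes, for every gene-tree branch, the ordered list of species branches
#' it traverses and the time spent in each -- the per-branch lengths L used by
#' the species tree relaxed clock.
#'
#' @inheritParams is_compatible
#' @return An object of class `mc_embedding`: a list with one element per
#'   gene-tree node (excluding the gene root, whose stem is not embedded),
#'   each a list with integer vector `species` (species node ids, branch
#'   above each) and numeric vector `L` (time spent), ordered from the
#'   branch's child end upwards.  Attribute `event_branch` gives, for each
#'   internal gene node, the species branch its coalescence occurs in.
#' @export
embed_gene_tree <- function(gene_tree, species_tree, mapping) {
  tip_sp <- tip_species_ids(gene_tree, species_tree, mapping)
  m <- gene_node_species_mrca(gene_tree, species_tree, tip_sp)
  gh <- gene_tree$height; sh <- species_tree$height
  internal <- (gene_tree$ntip + 1L):gene_tree$nnode
  if (any(gh[internal] < sh[m[internal]]))
    stop("gene tree is not compatible with the species tree")
  segs <- vector("list", gene_tree$nnode)
  ev <- integer(gene_tree$nnode)
  sp_parent <- species_tree$parent
  for (v in seq_len(gene_tree$nnode)) {
    # species branch occupied at the moment of node v (its coalescence, or
    # its sampling time for tips)
    w <- m[v]
    while (sp_parent[w] != 0L && sh[sp_parent[w]] <= gh[v]) w <- sp_parent[w]
    ev[v] <- w
    p <- gene_tree$parent[v]
    if (p == 0L) next  # gene root has no branch above
    t0 <- gh[v]; t1 <- gh[p]
    sp <- integer(0); L <- numeric(0)
    repeat {
      top <- if (sp_parent[w] == 0L) Inf else sh[sp_parent[w]]
      hi <- min(top, t1)
      sp <- c(sp, w); L <- c(L, hi - t0)
      if (hi >= t1) break
      t0 <- hi; w <- sp_parent[w]
    }
    segs[[v]] <- list(species = sp, L = L)
  }
  structure(segs, event_branch = ev, class = "mc_embedding")
}

#' Convert to/from ape phylo objects
#'
#' `to_phylo()` renders an `mc_tree` as an [ape::phylo] tree with branch
#' lengths equal to height differences; `from_phylo()` builds an `mc_tree`
#' from an ultrametric rooted binary phylo object.
#'
#' @param tr An `mc_tree`.
#' @return An `ape::phylo` object.
#' @export
to_phylo <- function(tr) {
  ntip <- tr$ntip
  kids <- which(tr$parent != 0L)
  # ape numbering: tips 1..ntip, root ntip+1; our internal ids map to ape ids
  # via a rank that puts the root first.
  internal <- (ntip + 1L):tr$nnode
  ape_id <- integer(tr$nnode)
  ape_id[seq_len(ntip)] <- seq_len(ntip)
  ord <- c(tr$root, setdiff(internal, tr$root))
  ape_id[ord] <- ntip + seq_along(ord)
  edge <- cbind(ape_id[tr$parent[kids]], ape_id[kids])
  phy <- list(edge = edge,
              edge.length = tr$height[tr$parent[kids]] - tr$height[kids],
              Nnode = ntip - 1L, tip.label = tr$tip_label)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' @rdname to_phylo
#' @param phy An ultrametric rooted binary `ape::phylo` object.
#' @export
from_phylo <- function(phy) {
  if (!ape::is.binary(phy)) stop("polytomies are not supported")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  ntip <- length(phy$tip.label)
  nn <- 2L * ntip - 1L
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth) - depth
  height[abs(height) < 1e-9] <- 0
  if (any(height[seq_len(ntip)] != 0))
    stop("tree must be ultrametric (contemporaneous tips)")
  # ape node ids: tips 1..ntip, internals ntip+1..; root is ntip+1.
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  mc_tree(parent, height, phy$tip.label)
}

#' Read and write annotated Newick trees
#'
#' Trees are serialized as Newick with heights encoded as branch lengths.
#' Per-branch metadata (population size `N`, relative rate `R`) is written as
#' bracketed `[&key=value]` comment annotations in the BEAST dialect.
#' `read_annotated_newick()` strips and re-attaches those annotations around
#' [ape::read.tree], which handles the plain Newick core.
#'
#' @param tr An `mc_tree`.
#' @param file Path to write to, or `NULL` to return the string.
#' @return `write_annotated_newick()`: the Newick string, invisibly if
#'   written to a file.  `read_annotated_newick()`: an `mc_tree` with
#'   `popsize`/`rate` filled in where annotated.
#' @export
write_annotated_newick <- function(tr, file = NULL) {
  ann <- function(v) {
    parts <- character(0)
    if (!is.na(tr$popsize[v])) parts <- c(parts, sprintf("N=%.17g", tr$popsize[v]))
    if (!is.na(tr$rate[v])) parts <- c(parts, sprintf("R=%.17g", tr$rate[v]))
    if (length(parts)) paste0("[&", paste(parts, collapse = ","), "]") else ""
  }
  rec <- function(v) {
    bl <- if (tr$parent[v] == 0L) "" else
      sprintf(":%.17g", tr$height[tr$parent[v]] - tr$height[v])
    if (v <= tr$ntip) paste0(tr$tip_label[v], ann(v), bl)
    else paste0("(", rec(tr$child1[v]), ",", rec(tr$child2[v]), ")", ann(v), bl)
  }
  s <- paste0(rec(tr$root), ";")
  if (is.null(file)) return(s)
  writeLines(s, file); invisible(s)
}

#' @rdname write_annotated_newick
#' @param text A Newick string (possibly with `[&...]` annotations), or
#'   `NULL` to read from `file`.
#' @export
read_annotated_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  # pull out annotations, tagging each with a placeholder label position
  anns <- list(); clean <- text
  m <- gregexpr("\\[&[^]]*\\]", text)[[1]]
  if (m[1] != -1) {
    # replace annotations with nothing, but remember the token preceding each
    clean <- gsub("\\[&[^]]*\\]", "", text)
  }
  phy <- ape::read.tree(text = clean)
  if (is.null(phy)) stop("could not parse Newick string")
  tr <- from_phylo(phy)
  if (m[1] != -1) {
    # re-parse: walk the original string in parallel with a fresh serialization
    # by matching each annotation to the node whose closing token precedes it.
    tr <- attach_annotations(tr, text)
  }
  tr
}

# Attach [&N=..,R=..] annotations from a Newick string to tree nodes by
# re-parsing the string structurally (a small state machine over the Newick
# grammar; only the annotation placement is interpreted here, the topology
# itself comes from ape).
attach_annotations <- function(tr, text) {
  # Walk the Newick string; maintain a stack of "open" clades recording the
  # tip sets; on closing a clade or finishing a tip label, an annotation (if
  # present) belongs to that node.
  tipsets <- node_tip_sets(tr)
  keyset <- vapply(tipsets, function(s)
    paste(sort(tr$tip_label[s]), collapse = "|"), "")
  i <- 1L; n <- nchar(text)
  stack <- list(); cur_tips <- character(0)
  last_key <- NULL
  assign_ann <- function(key, ann) {
    v <- match(key, keyset)
    if (!is.na(v)) {
      for (kv in strsplit(sub("^\\[&", "", sub("\\]$", "", ann)), ",")[[1]]) {
        p <- strsplit(kv, "=")[[1]]
        if (p[1] == "N") tr$popsize[v] <<- as.numeric(p[2])
        if (p[1] == "R") tr$rate[v] <<- as.numeric(p[2])
      }
    }
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "(") { stack <- c(stack, list(character(0))); i <- i + 1L }
    else if (ch == ")") {
      tips <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (length(stack)) stack[[length(stack)]] <-
          c(stack[[length(stack)]], tips)
      last_key <- paste(sort(tips), collapse = "|")
      i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("\\]", substr(text, i, n))
      ann <- substr(text, i, i + j - 1L)
      if (!is.null(last_key)) assign_ann(last_key, ann)
      i <- i + j
    } else if (ch %in% c(",", ";")) { last_key <- NULL; i <- i + 1L }
    else if (ch == ":") {  # skip branch length
      j <- regexpr("[,()\\[;]", substr(text, i + 1L, n))
      i <- if (j == -1) n + 1L else i + j
    } else {  # tip label
      j <- regexpr("[:,()\\[;]", substr(text, i, n))
      lab <- substr(text, i, i + j - 2L)
      stack[[length(stack)]] <- c(stack[[length(stack)]], lab)
      last_key <- lab
      i <- i + j - 1L
    }
  }
  tr
}

#' Read a tip-to-species mapping table
#'
#' @param file Two-column delimited text file (haplotype, species), with or
#'   without a header line named `individual`/`species`.
#' @return Named character vector mapping haplotype to species.
#' @export
read_mapping <- function(file) {
  df <- utils::read.table(file, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "individual")) df <- df[-1, , drop = FALSE]
  m <- as.character(df[[2]]); names(m) <- as.character(df[[1]])
  m
}

#' @rdname read_mapping
#' @param mapping Named character vector.
#' @param file Output path.
#' @export
write_mapping <- function(mapping, file) {
  utils::write.table(data.frame(individual = names(mapping),
                                species = unname(mapping)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}
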
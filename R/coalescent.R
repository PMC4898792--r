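## Restricted multispecies coalescent.  One gene lineage starts at each tip;
## within a branch carrying k uncoalesced lineages, pairs coalesce at rate
## lambdaC per pair (total lambdaC * k * (k-1) / 2), so two lineages entering
## a branch of length t remain uncoalesced at its top with probability
## exp(-t * lambdaC).  Uncoalesced lineages merge into the parent branch's
## pool; the root branch is treated as infinite so every locus fully
## coalesces.  lambdaC may vary by epoch; times before the root reuse the
## first epoch's rate.

.lambdaCSchedule <- function(x) {
  if (is(x, "EpochSchedule")) {
    rates <- vapply(x@epochs, function(e) e@lambdaC, numeric(1))
    breaks <- x@boundaries
  } else {
    stopifnot(is.numeric(x), length(x) >= 1L)
    rates <- x
    breaks <- 0
  }
  if (any(rates <= 0))
    stop("the coalescence rate must be positive in every epoch")
  list(breaks = breaks, rates = rates)
}

.networkRepr <- function(network) {
  ord <- order(network@tipLabels, method = "radix")
  r <- network@reticulations
  list(nodeTime = network@nodeTime,
       nodeParent = network@nodeParent,
       retChild = as.integer(r$child),
       retProbA = as.numeric(r$probA),
       retParentA = as.integer(r$parentA),
       retParentB = as.integer(r$parentB),
       tips = as.integer(network@tips[ord]),
       labels = network@tipLabels[ord])
}

## build a phylo from a gene-tree parent vector (tips 1..m in `labels`
## order, parents created after children, root parent 0) and node times
.phyloFromParent <- function(parent, time, labels) {
  m <- length(labels)
  G <- length(parent)
  ch <- vector("list", G)
  root <- 0L
  for (i in seq_len(G)) {
    p <- parent[i]
    if (p == 0L) root <- i else ch[[p]] <- c(ch[[p]], i)
  }
  rec <- function(v) {
    if (v <= m) return(list(str = labels[v], t = time[v]))
    parts <- lapply(ch[[v]], rec)
    segs <- vapply(parts, function(p)
      sprintf("%s:%.12g", p$str, p$t - time[v]), character(1))
    list(str = paste0("(", paste(segs, collapse = ","), ")"), t = time[v])
  }
  ape::read.tree(text = paste0(rec(root)$str, ";"))
}

## phylo -> kernel representation: tips renumbered to `taxa` order, internal
## nodes renumbered so every parent index exceeds its children's
.parentRepr <- function(phy, taxa) {
  m <- length(phy$tip.label)
  stopifnot(m == length(taxa))
  nn <- m + phy$Nnode
  dep <- numeric(nn)
  phy <- stats::reorder(phy, "cladewise")
  for (i in seq_len(nrow(phy$edge)))
    dep[phy$edge[i, 2L]] <- dep[phy$edge[i, 1L]] + 1
  internals <- (m + 1L):nn
  newId <- integer(nn)
  newId[seq_len(m)] <- match(phy$tip.label, taxa)
  newId[internals[order(dep[internals], decreasing = TRUE)]] <-
    m + seq_along(internals)
  parent <- integer(nn)
  parent[newId[phy$edge[, 2L]]] <- newId[phy$edge[, 1L]]
  parent
}

#' Simulate gene trees on a species network
#'
#' For each locus independently, the network is resolved into a lineage
#' tree (see [resolveLineageTree()]) and a coalescent simulation is run
#' within it, producing one rooted binary gene tree with branch lengths in
#' simulation time units.  Coalescences may predate the network root
#' (negative node times relative to the root at 0).
#'
#' @param network a [SpeciesNetwork-class].
#' @param nLoci number of gene trees to simulate.
#' @param coalescenceRate a positive rate (per lineage pair per unit time),
#'   or an [EpochSchedule-class] whose per-epoch `lambdaC` values apply.
#' @return a [TreeProfile-class] of `nLoci` gene trees.
#' @examples
#' set.seed(1)
#' prof <- simulateGeneTrees(demoNetwork(), 10, coalescenceRate = 20)
#' prof
#' @export
simulateGeneTrees <- function(network, nLoci, coalescenceRate) {
  stopifnot(is(network, "SpeciesNetwork"), nLoci >= 1)
  sched <- .lambdaCSchedule(coalescenceRate)
  rp <- .networkRepr(network)
  sim <- cpp_simulate_profile(rp$nodeTime, rp$nodeParent, rp$retChild,
                              rp$retProbA, rp$retParentA, rp$retParentB,
                              rp$tips, sched$breaks, sched$rates,
                              as.integer(nLoci))
  trees <- lapply(seq_len(nLoci), function(i)
    .phyloFromParent(sim$parent[, i], sim$time[, i], rp$labels))
  treeProfile(trees)
}

#' Run the coalescent within one lineage tree
#'
#' Samples a gene tree for a single locus inside a fixed ultrametric
#' lineage tree: one lineage per tip, pairwise coalescence at rate
#' `coalescenceRate` within each branch, surviving lineages passed rootward,
#' full coalescence above the root.
#'
#' @param lineageTree an ultrametric rooted binary `phylo` with branch
#'   lengths in time units.
#' @param coalescenceRate positive rate, or an [EpochSchedule-class].
#' @return a rooted binary `phylo` gene tree with branch lengths.
#' @examples
#' set.seed(1)
#' lt <- resolveLineageTree(demoNetwork())
#' gt <- sampleCoalescentGeneTree(lt, coalescenceRate = 5)
#' @export
sampleCoalescentGeneTree <- function(lineageTree, coalescenceRate) {
  stopifnot(inherits(lineageTree, "phylo"))
  if (!ape::is.binary(lineageTree) || !ape::is.rooted(lineageTree))
    stop("'lineageTree' must be rooted and binary")
  sched <- .lambdaCSchedule(coalescenceRate)
  m <- length(lineageTree$tip.label)
  taxa <- sort(lineageTree$tip.label, method = "radix")
  depths <- ape::node.depth.edgelength(lineageTree)
  if (diff(range(depths[seq_len(m)])) > 1e-8 * max(depths))
    stop("'lineageTree' must be ultrametric")
  parent <- .parentRepr(lineageTree, taxa)
  tm <- numeric(length(parent))
  newId <- integer(length(parent))
  ## recompute times on the renumbered nodes
  phy <- stats::reorder(lineageTree, "cladewise")
  dep <- numeric(length(parent))
  for (i in seq_len(nrow(phy$edge)))
    dep[phy$edge[i, 2L]] <- dep[phy$edge[i, 1L]] + 1
  nn <- length(parent)
  internals <- (m + 1L):nn
  newId[seq_len(m)] <- match(phy$tip.label, taxa)
  newId[internals[order(dep[internals], decreasing = TRUE)]] <-
    m + seq_along(internals)
  tm[newId] <- depths
  sim <- cpp_simulate_profile(tm, parent, integer(0), numeric(0),
                              integer(0), integer(0),
                              match(taxa, taxa), sched$breaks, sched$rates,
                              1L)
  .phyloFromParent(sim$parent[, 1L], sim$time[, 1L], taxa)
}
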
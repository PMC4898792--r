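## Lineage trees: a network becomes a tree for one locus by routing every
## reticulation child to exactly one of its two parents (with the genome
## contributions as probabilities).  The whole locus follows one lineage
## tree — uncoalesced lineages of one gene cannot take different paths
## through a reticulation.

.effectiveParent <- function(network, chooseA) {
  eff <- network@nodeParent
  r <- network@reticulations
  if (nrow(r))
    eff[r$child] <- as.integer(ifelse(chooseA, r$parentA, r$parentB))
  eff
}

.childrenList <- function(eff) {
  ch <- vector("list", length(eff))
  idx <- which(eff > 0L)
  for (i in idx) ch[[eff[i]]] <- c(ch[[eff[i]]], i)
  ch
}

#' Canonical key for a rooted tree topology
#'
#' Maps a rooted topology (Newick string or `phylo`) to a canonical string
#' with children sorted bytewise at every node, ignoring branch lengths;
#' two rooted trees have equal keys iff they share the topology.  Used to
#' identify topologies in weighted lineage-tree distributions and in the
#' tree-entropy statistic.
#'
#' @param tree a `phylo` object or a Newick string.
#' @return a character key.
#' @examples
#' topologyKey("((B,A),C);") == topologyKey("(C,(A,B));")
#' @export
topologyKey <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  m <- length(tree$tip.label)
  ch <- vector("list", m + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    ch[[p]] <- c(ch[[p]], c)
  }
  rec <- function(v) {
    if (v <= m) return(tree$tip.label[v])
    parts <- sort(vapply(ch[[v]], rec, character(1)), method = "radix")
    if (length(parts) == 1L) return(parts)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(m + 1L)
}

.resolutionTopology <- function(network, chooseA) {
  eff <- .effectiveParent(network, chooseA)
  ch <- .childrenList(eff)
  lab <- character(length(eff))
  lab[network@tips] <- network@tipLabels
  isTip <- logical(length(eff))
  isTip[network@tips] <- TRUE
  rec <- function(v) {
    if (isTip[v]) return(lab[v])
    kids <- ch[[v]]
    if (length(kids) == 1L) return(rec(kids[1L]))
    parts <- sort(vapply(kids, rec, character(1)), method = "radix")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(which(eff == 0L), network@tips)
  rec(root[1L])
}

#' Resolve a species network into one lineage tree
#'
#' Routes every reticulation child to one parent — the first parent with its
#' contribution probability, the second otherwise — and returns the
#' resulting time-calibrated tree.  Hybrid-origin nodes follow the parental
#' genome contributions; introgression attachment points route the recipient
#' lineage through the donor with the introgressed fraction as probability.
#'
#' @param network a [SpeciesNetwork-class].
#' @return an ultrametric `phylo`; attribute `"resolution"` records the
#'   per-reticulation choice (`TRUE` = first parent).
#' @examples
#' set.seed(1)
#' tr <- resolveLineageTree(demoNetwork())
#' @export
resolveLineageTree <- function(network) {
  stopifnot(is(network, "SpeciesNetwork"))
  r <- network@reticulations
  chooseA <- if (nrow(r)) runif(nrow(r)) < r$probA else logical(0)
  eff <- .effectiveParent(network, chooseA)
  ch <- .childrenList(eff)
  isTip <- logical(length(eff))
  isTip[network@tips] <- TRUE
  lab <- character(length(eff))
  lab[network@tips] <- network@tipLabels
  tm <- network@nodeTime
  rec <- function(v) {
    if (isTip[v]) return(list(str = lab[v], t = tm[v]))
    kids <- ch[[v]]
    if (length(kids) == 1L) return(rec(kids[1L]))
    parts <- lapply(kids, rec)
    segs <- vapply(parts, function(p)
      sprintf("%s:%.12g", p$str, p$t - tm[v]), character(1))
    list(str = paste0("(", paste(segs, collapse = ","), ")"), t = tm[v])
  }
  root <- setdiff(which(eff == 0L), network@tips)
  phy <- ape::read.tree(text = paste0(rec(root[1L])$str, ";"))
  attr(phy, "resolution") <- chooseA
  phy
}

#' Exhaustively enumerate the lineage-tree distribution
#'
#' Iterates over all `2^R` reticulation resolutions of a network with `R`
#' reticulations, multiplies the per-reticulation routing probabilities,
#' and aggregates by topology: each topology's weight is the fraction of the
#' genome that evolved on it.  Weights sum to 1.
#'
#' @param network a [SpeciesNetwork-class].
#' @param maxReticulations enumeration cap; beyond it (`2^R` resolutions
#'   intractable) an error instructs the caller to sample with
#'   [sampleLineageTopologies()] instead.
#' @return a data frame with columns `topology` (canonical rooted Newick,
#'   see [topologyKey()]) and `weight`, sorted by decreasing weight.
#' @examples
#' lineageTreeDistribution(demoNetwork())
#' @export
lineageTreeDistribution <- function(network, maxReticulations = 12L) {
  stopifnot(is(network, "SpeciesNetwork"))
  R <- nReticulations(network)
  if (R > maxReticulations)
    stop(sprintf(paste("network has %d reticulations (2^%d resolutions);",
                       "sample with sampleLineageTopologies() instead"),
                 R, R))
  if (R == 0L) {
    topo <- .resolutionTopology(network, logical(0))
    return(data.frame(topology = topo, weight = 1,
                      stringsAsFactors = FALSE))
  }
  probA <- network@reticulations$probA
  agg <- new.env(parent = emptyenv())
  for (i in seq_len(2^R) - 1L) {
    chooseA <- bitwAnd(bitwShiftR(i, seq_len(R) - 1L), 1L) == 1L
    w <- prod(ifelse(chooseA, probA, 1 - probA))
    if (w == 0) next
    key <- .resolutionTopology(network, chooseA)
    agg[[key]] <- (if (is.null(agg[[key]])) 0 else agg[[key]]) + w
  }
  keys <- ls(agg)
  out <- data.frame(topology = keys,
                    weight = vapply(keys, function(k) agg[[k]], numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$weight, out$topology), , drop = FALSE]
}

#' Sample lineage-tree topologies from a network
#'
#' Draws `n` independent reticulation resolutions (each reticulation routed
#' to its first parent with its contribution probability) and tabulates the
#' resulting topologies, without ever forming the full distribution.
#'
#' @param network a [SpeciesNetwork-class].
#' @param n number of resolutions to draw.
#' @return a data frame with columns `topology`, `count`, `frequency`.
#' @examples
#' set.seed(1)
#' sampleLineageTopologies(demoNetwork(), 1000)
#' @export
sampleLineageTopologies <- function(network, n) {
  stopifnot(is(network, "SpeciesNetwork"), n >= 1)
  R <- nReticulations(network)
  if (R == 0L) {
    topo <- .resolutionTopology(network, logical(0))
    return(data.frame(topology = topo, count = as.integer(n), frequency = 1,
                      stringsAsFactors = FALSE))
  }
  probA <- network@reticulations$probA
  draws <- matrix(runif(n * R), n, R) <
    matrix(probA, n, R, byrow = TRUE)
  pat <- apply(draws, 1L, function(x) paste(as.integer(x), collapse = ""))
  patTab <- table(pat)
  topo <- vapply(names(patTab), function(p) {
    .resolutionTopology(network, strsplit(p, "", fixed = TRUE)[[1L]] == "1")
  }, character(1))
  counts <- tapply(as.integer(patTab), topo, sum)
  out <- data.frame(topology = names(counts),
                    count = as.integer(counts),
                    frequency = as.integer(counts) / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$count, out$topology), , drop = FALSE]
}
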
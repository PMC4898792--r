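# Shared fixtures.

# a fixed 3-taxon species tree ((a,b),c) with internal branch length 1 and
# tips at depth 2, as a network
threeTaxonNetwork <- function() {
  new("SpeciesNetwork",
      nodeTime = c(0, 1, 2, 2, 2),
      nodeParent = c(0L, 1L, 2L, 2L, 1L),
      reticulations = data.frame(child = integer(0), parentA = integer(0),
                                 parentB = integer(0), probA = numeric(0),
                                 type = character(0), time = numeric(0),
                                 from = character(0), to = character(0)),
      tips = c(3L, 4L, 5L), tipLabels = c("a", "b", "c"), depth = 2,
      events = data.frame(time = numeric(0), kind = character(0),
                          detail = character(0)),
      metadata = list())
}

# demoNetwork with both routing probabilities replaced
demoNetworkWithProbs <- function(pIntro, pHyb) {
  net <- demoNetwork()
  net@reticulations$probA <- c(pIntro, pHyb)
  net
}

# gene-tree node times in network (forward) time units, tips at `depth`
geneNodeTimes <- function(phy, depth) {
  d <- ape::node.depth.edgelength(phy)
  m <- length(phy$tip.label)
  depth - (max(d[seq_len(m)]) - d)
}

makeProfile <- function(...) {
  treeProfile(lapply(list(...), function(s) ape::read.tree(text = s)))
}
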
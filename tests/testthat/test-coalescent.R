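test_that("instantaneous coalescence recovers the lineage-tree topology", {
  set.seed(31)
  net <- simulateNetwork(epochSchedule(rateSet(lambdaS = 1, lambdaC = 1)),
                         haltingConfig(maxSpecies = 6))
  species <- topologyKey(resolveLineageTree(net))
  prof <- simulateGeneTrees(net, 20, coalescenceRate = 1e7)
  keys <- vapply(trees(prof), topologyKey, character(1))
  expect_true(all(keys == species))
})

test_that("two lineages survive a branch with probability exp(-t*lambdaC)", {
  # ((a,b),c) with internal branch length 1; a,b fail to coalesce on it
  # exactly when every gene coalescence predates the network root
  set.seed(32)
  lambdaC <- 1
  prof <- simulateGeneTrees(threeTaxonNetwork(), 1e4, lambdaC)
  surv <- vapply(trees(prof), function(tr) {
    tm <- geneNodeTimes(tr, 2)
    all(tm[-(1:3)] <= 1e-9)
  }, logical(1))
  p <- exp(-lambdaC)
  expect_lt(abs(mean(surv) - p), 3 * sqrt(p * (1 - p) / 1e4))
})

test_that("discordant three-taxon topologies appear at (1/3)exp(-t*lambdaC)", {
  set.seed(33)
  lambdaC <- 1
  prof <- simulateGeneTrees(threeTaxonNetwork(), 1e4, lambdaC)
  keys <- vapply(trees(prof), topologyKey, character(1))
  pDisc <- exp(-lambdaC) / 3
  for (k in c("((b,c),a)", "((a,c),b)")) {
    f <- mean(keys == k)
    expect_lt(abs(f - pDisc), 3 * sqrt(pDisc * (1 - pDisc) / 1e4))
  }
  pConc <- 1 - 2 * pDisc
  expect_lt(abs(mean(keys == "((a,b),c)") - pConc),
            3 * sqrt(pConc * (1 - pConc) / 1e4))
})

test_that("gene coalescences never postdate the lineage-tree divergence", {
  set.seed(34)
  net <- simulateNetwork(epochSchedule(rateSet(lambdaS = 1, lambdaC = 2)),
                         haltingConfig(maxSpecies = 6))
  sp <- resolveLineageTree(net)
  spTimes <- geneNodeTimes(sp, networkDepth(net))
  m <- nTaxa(net)
  mrcaTime <- function(phy, times, a, b) {
    anc <- ape::mrca(phy)
    times[anc[a, b]]
  }
  prof <- simulateGeneTrees(net, 50, coalescenceRate = 2)
  pairs <- combn(tipLabels(net), 2)
  for (tr in trees(prof)) {
    tm <- geneNodeTimes(tr, networkDepth(net))
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      expect_lte(mrcaTime(tr, tm, a, b),
                 mrcaTime(sp, spTimes, a, b) + 1e-9)
    }
  }
})

test_that("the root coalescent depth of two tips is shifted exponential", {
  set.seed(35)
  star <- ape::read.tree(text = "(a:1,b:1);")
  lambdaC <- 2
  depths <- replicate(2000, {
    gt <- sampleCoalescentGeneTree(star, lambdaC)
    max(ape::node.depth.edgelength(gt))
  })
  ks <- suppressWarnings(stats::ks.test(depths - 1, "pexp", rate = lambdaC))
  expect_gt(ks$p.value, 0.01)
})

test_that("piecewise-constant coalescence rates are honoured per epoch", {
  set.seed(36)
  star <- ape::read.tree(text = "(a:1,b:1);")
  # epoch [0,1) has a negligible rate; all mass sits above the root where
  # the first epoch's rate applies -- compare with a matched single epoch
  same <- epochSchedule(list(rateSet(lambdaC = 3), rateSet(lambdaC = 3)),
                        boundaries = c(0, 0.5))
  d1 <- replicate(1500, max(ape::node.depth.edgelength(
    sampleCoalescentGeneTree(star, same))))
  d2 <- replicate(1500, max(ape::node.depth.edgelength(
    sampleCoalescentGeneTree(star, 3))))
  ks <- suppressWarnings(stats::ks.test(d1, d2))
  expect_gt(ks$p.value, 0.01)
  # the a,b lineages of ((a,b),c) share the branch spanning times [0,1]:
  # a fast rate in the epoch covering it pins their coalescence just below
  # time 1, while a negligible rate there pushes full coalescence far
  # before the root (the first epoch extends to all earlier times)
  net <- threeTaxonNetwork()
  fastEarly <- epochSchedule(list(rateSet(lambdaS = 1, lambdaC = 50),
                                  rateSet(lambdaS = 1, lambdaC = 1e-6)),
                             boundaries = c(0, 1))
  prof <- simulateGeneTrees(net, 200, fastEarly)
  abTime <- vapply(trees(prof), function(tr)
    max(geneNodeTimes(tr, 2)[-(1:3)]), numeric(1))
  expect_gt(mean(abTime > 0.8 & abTime <= 1), 0.9)
  slowEarly <- epochSchedule(list(rateSet(lambdaS = 1, lambdaC = 1e-4),
                                  rateSet(lambdaS = 1, lambdaC = 50)),
                             boundaries = c(0, 1))
  prof2 <- simulateGeneTrees(net, 50, slowEarly)
  rootTime <- vapply(trees(prof2), function(tr)
    min(geneNodeTimes(tr, 2)), numeric(1))
  expect_gt(mean(rootTime < -100), 0.9)
})

test_that("gene trees of the worked example converge to the enumeration", {
  set.seed(37)
  net <- demoNetwork()
  prof <- simulateGeneTrees(net, 4000, coalescenceRate = 1e7)
  keys <- vapply(trees(prof), topologyKey, character(1))
  dist <- lineageTreeDistribution(net)
  for (i in seq_len(nrow(dist))) {
    w <- dist$weight[i]
    expect_lt(abs(mean(keys == dist$topology[i]) - w),
              3 * sqrt(w * (1 - w) / 4000))
  }
})

test_that("profile shape and rate validation", {
  set.seed(38)
  net <- demoNetwork()
  prof <- simulateGeneTrees(net, 7, coalescenceRate = 5)
  expect_equal(length(prof), 7L)
  expect_equal(nTaxa(prof), 5L)
  expect_error(simulateGeneTrees(net, 5, coalescenceRate = 0), "positive")
})
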
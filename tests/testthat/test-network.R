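noRetSchedule <- function(lambdaC = 1)
  epochSchedule(rateSet(lambdaS = 1, lambdaC = lambdaC))

test_that("pure divergence with a species cap yields a binary tree of that size", {
  set.seed(11)
  for (n in c(4, 10)) {
    net <- simulateNetwork(noRetSchedule(), haltingConfig(maxSpecies = n))
    expect_equal(nTaxa(net), n)
    expect_equal(nReticulations(net), 0L)
    expect_identical(net@metadata$haltReason, "maxSpecies")
    tr <- resolveLineageTree(net)
    expect_true(ape::is.binary(tr))
    expect_equal(tr$Nnode, n - 1L) # internal node count of the species tree
    expect_setequal(tr$tip.label, tipLabels(net))
  }
})

test_that("depth halting places every tip exactly at the maximum depth", {
  set.seed(12)
  net <- simulateNetwork(noRetSchedule(), haltingConfig(maxDepth = 1.5))
  expect_equal(networkDepth(net), 1.5)
  expect_true(all(abs(net@nodeTime[net@tips] - 1.5) < 1e-12))
  expect_identical(net@metadata$haltReason, "maxDepth")
  tr <- resolveLineageTree(net)
  d <- ape::node.depth.edgelength(tr)
  expect_true(all(abs(d[seq_along(tr$tip.label)] - 1.5) < 1e-9))
})

test_that("sister-taxon distance equals twice the divergence time", {
  set.seed(13)
  net <- simulateNetwork(noRetSchedule(), haltingConfig(maxDepth = 2))
  D <- net@metadata$distances
  tr <- resolveLineageTree(net)
  m <- length(tr$tip.label)
  ch <- or_children(tr)
  found <- 0L
  for (v in which(vapply(ch, function(k)
    length(k) == 2 && all(k <= m), logical(1)))) {
    pair <- tr$tip.label[ch[[v]]]
    # time since divergence = branch length above either sister tip
    blen <- tr$edge.length[tr$edge[, 2] == ch[[v]][1]]
    expect_equal(D[pair[1], pair[2]], 2 * blen, tolerance = 1e-9)
    found <- found + 1L
  }
  expect_gt(found, 0L)
})

test_that("the final distance matrix is symmetric, zero-diagonal, nonnegative", {
  set.seed(14)
  sched <- epochSchedule(rateSet(lambdaS = 1, lambdaH = 0.2, lambdaI = 0.2,
                                 lambdaC = 1, threshold = 1.3),
                         successKind = "linear")
  for (i in 1:5) {
    net <- simulateNetwork(sched, haltingConfig(maxSpecies = 8),
                           introContrib = contributionDistribution(0.1))
    D <- net@metadata$distances
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
  }
})

test_that("distance-independent success never produces failed attempts", {
  set.seed(15)
  sched <- epochSchedule(rateSet(lambdaS = 1, lambdaH = 0.3,
                                 lambdaI = 0.3, lambdaC = 1,
                                 threshold = Inf), successKind = "step")
  net <- simulateNetwork(sched, haltingConfig(maxSpecies = 8))
  expect_false(any(grepl("failed", net@events$kind)))
})

test_that("success thinning follows F(d) on the maintained distances", {
  # two species at distance 2t; attempts are Poisson at rate 2*lambdaH and
  # succeed with exp(-2t/T), so P(no reticulation by depth D) =
  # exp(-2*lambdaH*T/2*(1 - exp(-2D/T)))
  set.seed(16)
  lambdaH <- 0.5; Tthr <- 1; D <- 3
  sched <- epochSchedule(rateSet(lambdaS = 0, lambdaH = lambdaH,
                                 lambdaC = 1, threshold = Tthr),
                         successKind = "exponential")
  nRep <- 1500
  # the reticulation cap only shortens runs after a first success; the
  # zero-success probability under test is unaffected
  zero <- replicate(nRep, {
    net <- simulateNetwork(sched, haltingConfig(maxDepth = D,
                                                maxReticulations = 1))
    nReticulations(net) == 0
  })
  expected <- exp(-2 * lambdaH * (Tthr / 2) * (1 - exp(-2 * D / Tthr)))
  se <- sqrt(expected * (1 - expected) / nRep)
  expect_lt(abs(mean(zero) - expected), 3 * se)
})

test_that("reticulation count can be conditioned exactly", {
  set.seed(17)
  sched <- epochSchedule(rateSet(lambdaS = 1, lambdaH = 0.2, lambdaC = 1,
                                 threshold = Inf), successKind = "step")
  for (i in 1:5) {
    net <- simulateNetwork(sched,
                           haltingConfig(maxSpecies = 10,
                                         minReticulations = 2,
                                         reduceToReticulations = 2))
    expect_equal(nReticulations(net), 2L)
    expect_true(all(net@reticulations$type == "hybrid"))
  }
})

test_that("unreachable minimum reticulation count is rejected", {
  set.seed(18)
  expect_error(
    simulateNetwork(noRetSchedule(),
                    haltingConfig(maxSpecies = 6, minReticulations = 2,
                                  reduceToReticulations = 2),
                    maxTries = 5),
    "reticulation")
})

test_that("reduction leaves networks within the cap untouched", {
  set.seed(19)
  sched <- epochSchedule(rateSet(lambdaS = 1, lambdaH = 0.2, lambdaC = 1,
                                 threshold = Inf), successKind = "step")
  net <- simulateNetwork(sched, haltingConfig(maxSpecies = 8))
  expect_identical(reduceReticulations(net, Inf), net)
  red <- reduceReticulations(net, 0)
  expect_equal(nReticulations(red), 0L)
  expect_true(all(red@nodeParent[red@tips] > 0))
})

test_that("all-infinite halting limits are refused", {
  expect_error(haltingConfig(), "halting")
})
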
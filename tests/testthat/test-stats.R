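test_that("splits are extracted, canonicalised and counted", {
  expect_setequal(extractSplits(ape::read.tree(text = "((a,b),(c,d));")),
                  "c,d|a,b")
  cat5 <- ape::read.tree(text = "((((a,b),c),d),e);")
  expect_setequal(extractSplits(cat5), c("c,d,e|a,b", "d,e|a,b,c"))
  set.seed(41)
  for (m in 5:8) {
    tr <- ape::rtree(m, tip.label = letters[1:m])
    expect_equal(length(extractSplits(tr)), m - 3)
  }
})

test_that("split compatibility follows the empty-intersection rule", {
  expect_true(splitsCompatible("a,b|c,d", "a,b|c,d"))
  expect_false(splitsCompatible("a,b|c,d", "a,c|b,d"))
  expect_true(splitsCompatible("a,b|c,d,e,f", "c,d|a,b,e,f"))
  expect_error(splitsCompatible("a,b|c,d", "a,b|c,e"), "taxon sets")
})

test_that("tree entropy counts rooted topology multiplicities", {
  same <- makeProfile("((a,b),(c,d));", "((a,b),(c,d));", "((a,b),(c,d));",
                      "((a,b),(c,d));")
  expect_equal(treeEntropy(same), 4 * log(4))
  distinct <- makeProfile("((a,b),(c,d));", "((a,c),(b,d));",
                          "((a,d),(b,c));")
  expect_equal(treeEntropy(distinct), 0)
  mixed <- makeProfile("((a,b),(c,d));", "((a,b),(c,d));",
                       "((a,b),(c,d));", "((a,c),(b,d));")
  expect_equal(treeEntropy(mixed), 3 * log(3))
  # rooted identity: same unrooted topology, different root position
  rooted <- makeProfile("((a,b),(c,d));", "(a,(b,(c,d)));")
  expect_equal(treeEntropy(rooted), 0)
})

test_that("quartet entropy matches closed forms and brute force", {
  same <- makeProfile("((a,(b,c)),(d,e));", "((a,(b,c)),(d,e));",
                      "((a,(b,c)),(d,e));")
  expect_equal(quartetEntropy(same), choose(5, 4) * 3 * log(3))
  opposed <- makeProfile("((a,b),(c,d));", "((a,c),(b,d));")
  expect_equal(quartetEntropy(opposed), 0)
})

test_that("split incompatibility and its thresholded family", {
  opposed <- makeProfile("((a,b),(c,d));", "((a,c),(b,d));")
  expect_equal(splitIncompatibility(opposed), 2) # ordered pairs
  expect_equal(splitIncompatibility(opposed, k = 1), 0)
  same <- makeProfile("((a,b),(c,d));", "((a,b),(c,d));")
  expect_equal(splitIncompatibility(same), 0)
  set.seed(42)
  prof <- or_random_profile(6, 8)
  si <- vapply(0:4, function(k) splitIncompatibility(prof, k), numeric(1))
  expect_true(all(diff(si) <= 1e-9))
  expect_equal(si[1], unname(baseStatistics(prof)["SI"]))
})

test_that("rare splits, consensus distance and unique counts", {
  same <- makeProfile("((a,b),(c,d));", "((a,b),(c,d));")
  expect_equal(rareSplits(same), 0)
  expect_equal(distanceToConsensus(same), 0)
  two <- makeProfile("((a,b),(c,d));", "((a,c),(b,d));")
  expect_equal(rareSplits(two), 2)
  single <- treeProfile(list(ape::rtree(7, tip.label = letters[1:7])))
  expect_equal(rareSplits(single), 4) # m - 3 splits, each seen once
  three <- makeProfile("((a,b),(c,d));", "((a,b),(c,d));",
                       "((a,c),(b,d));")
  expect_equal(distanceToConsensus(three), 2) # min(2,1) + min(1,2)
  expect_equal(uniqueSplits(three), 2)
  bal8 <- treeProfile(list(ape::read.tree(
    text = "(((a,b),(c,d)),((e,f),(g,h)));")))
  cat8 <- treeProfile(list(ape::read.tree(
    text = "((((((a,b),c),d),e),f),(g,h));")))
  expect_equal(uniqueCherries(bal8), 4)
  expect_equal(uniqueCherries(cat8), 2)
  expect_equal(uniqueSplits(bal8), 5)
  set.seed(43)
  prof <- or_random_profile(6, 6)
  n <- length(prof@trees)
  expect_lte(distanceToConsensus(prof), n * (6 - 3))
  expect_lte(uniqueCherries(prof), choose(6, 2))
})

test_that("greedy consensus contains all majority splits and is compatible", {
  same <- makeProfile("((a,b),(c,d));", "((a,b),(c,d));")
  cons <- greedyConsensus(same)
  expect_setequal(extractSplits(cons), extractSplits(same[[1]]))
  mixed <- makeProfile("((a,b),(c,d));", "((a,b),(c,d));",
                       "((a,c),(b,d));")
  expect_setequal(extractSplits(greedyConsensus(mixed)), "c,d|a,b")
  set.seed(44)
  for (i in 1:5) {
    prof <- or_random_profile(6, 7)
    spl <- extractSplits(greedyConsensus(prof))
    if (length(spl) > 1) {
      prs <- combn(spl, 2)
      for (j in seq_len(ncol(prs)))
        expect_true(splitsCompatible(prs[1, j], prs[2, j]))
    }
    # every majority split is present
    perTree <- lapply(trees(prof), function(t) extractSplits(t))
    allS <- unlist(perTree)
    maj <- names(which(table(allS) > length(prof) / 2))
    expect_true(all(maj %in% spl))
  }
})

test_that("internode certainty matches its closed form", {
  expect_equal(internodeCertainty(5, 0), 1)
  expect_equal(internodeCertainty(3, 3), 0)
  expect_equal(internodeCertainty(3, 1),
               1 + 0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(internodeCertainty(3, 1), 0.18872, tolerance = 1e-4)
  expect_error(internodeCertainty(0, 2))
})

test_that("tree certainty sums internode certainties on the consensus", {
  m <- 5
  same <- makeProfile("((a,(b,c)),(d,e));", "((a,(b,c)),(d,e));")
  expect_equal(treeCertainty(same), m - 3)
  expect_equal(treeCertaintyAll(same), m - 3)
  prof <- makeProfile("((a,b),(c,d));", "((a,b),(c,d));",
                      "((a,b),(c,d));", "((a,c),(b,d));")
  expect_equal(treeCertainty(prof), internodeCertainty(3, 1))
  # a single conflicting split: TCA degenerates to TC
  expect_equal(treeCertaintyAll(prof), treeCertainty(prof))
})

test_that("the statistics vector composes the individual statistics", {
  set.seed(45)
  prof <- or_random_profile(6, 8)
  st <- baseStatistics(prof)
  expect_named(st, c("TE", "QE", "SI", "SI1", "SI2", "RS", "DC", "UC",
                     "US", "TC", "TCA"))
  expect_equal(unname(st["TE"]), treeEntropy(prof))
  expect_equal(unname(st["QE"]), quartetEntropy(prof))
  expect_equal(unname(st["SI"]), splitIncompatibility(prof))
  expect_equal(unname(st["SI1"]), splitIncompatibility(prof, 1))
  expect_equal(unname(st["RS"]), rareSplits(prof))
  expect_equal(unname(st["DC"]), distanceToConsensus(prof))
  expect_equal(unname(st["US"]), uniqueSplits(prof))
  expect_equal(unname(st["UC"]), uniqueCherries(prof))
  expect_equal(unname(st["TC"]), treeCertainty(prof))
  expect_equal(unname(st["TCA"]), treeCertaintyAll(prof))
})

test_that("a unanimous profile hits the closed-form vector", {
  n <- 6; m <- 6
  tr <- "(((a,b),(c,d)),(e,f));"
  prof <- do.call(makeProfile, as.list(rep(tr, n)))
  st <- baseStatistics(prof)
  expect_equal(unname(st["TE"]), n * log(n))
  expect_equal(unname(st["QE"]), choose(m, 4) * n * log(n))
  expect_equal(unname(st[c("SI", "SI1", "SI2", "RS", "DC")]),
               rep(0, 5), ignore_attr = TRUE)
  expect_equal(unname(st["UC"]), 3)
  expect_equal(unname(st["US"]), m - 3)
  expect_equal(unname(st["TC"]), m - 3)
  expect_equal(unname(st["TCA"]), m - 3)
})

test_that("the full vector agrees with the brute-force oracle", {
  set.seed(46)
  for (i in 1:50) {
    m <- sample(4:6, 1)
    n <- sample(2:8, 1)
    prof <- or_random_profile(m, n, nTopo = sample(2:4, 1))
    got <- baseStatistics(prof)
    want <- or_base_stats(trees(prof))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the consensus-distance min formula equals the explicit RF form", {
  set.seed(47)
  for (i in 1:10) {
    prof <- or_random_profile(sample(5:6, 1), sample(3:8, 1))
    expect_equal(distanceToConsensus(prof), or_dc_consensus(trees(prof)))
  }
})

test_that("the pairwise RF sum matches an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(48)
  for (i in 1:5) {
    prof <- or_random_profile(6, 6)
    tl <- trees(prof)
    class(tl) <- "multiPhylo"
    rf <- as.matrix(phangorn::RF.dist(tl, normalize = FALSE))
    expect_equal(pairwiseRFSum(prof), sum(rf))
  }
})
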
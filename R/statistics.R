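## Discordance statistics over a profile of rooted binary gene trees on one
## taxon set.  Tree-entropy identity is the rooted topology; splits, quartets
## and cherries are evaluated on the unrooted view.  Splits are encoded as
## bitmasks over the sorted taxon set, canonicalised to the side not
## containing the first taxon; the compiled kernel extracts per-tree splits,
## cherries, quartet resolutions and canonical topology strings, and the
## aggregation into statistics happens here.

.xlogx <- function(x) {
  x <- x[x > 0]
  sum(x * log(x))
}

.profileMatrix <- function(profile) {
  taxa <- profile@taxa
  m <- length(taxa)
  vapply(profile@trees, .parentRepr, integer(2L * m - 1L), taxa = taxa)
}

.profileSummaries <- function(profile, quartets = TRUE) {
  taxa <- profile@taxa
  pm <- .profileMatrix(profile)
  if (!is.matrix(pm)) pm <- matrix(pm, ncol = length(profile@trees))
  cpp_profile_summaries(pm, length(taxa), taxa, quartets)
}

## aggregate split table: unique canonical masks (first-appearance order)
## and the number of trees displaying each
.splitTable <- function(sm) {
  all <- unlist(sm$splits)
  if (!length(all))
    return(list(masks = integer(0), w = numeric(0)))
  uniq <- unique(all)
  list(masks = uniq, w = as.numeric(tabulate(match(all, uniq),
                                             nbins = length(uniq))))
}

.greedyMasks <- function(st, m) {
  if (!length(st$masks)) return(integer(0))
  ord <- order(-st$w, st$masks) # weight desc, canonical encoding asc, stable
  sorted <- st$masks[ord]
  acc <- cpp_greedy_accept(sorted, m)
  sorted[acc]
}

.icValue <- function(x1, x2) {
  if (x1 < 1) stop("the evaluated split must be observed at least once")
  p <- x1 / (x1 + x2)
  plogp <- function(q) if (q > 0) q * log2(q) else 0
  1 + plogp(p) + plogp(1 - p)
}

.icaValue <- function(x1, conflictW) {
  h <- 1L + length(conflictW)
  if (h == 1L) return(1)
  w <- c(x1, conflictW)
  p <- w / sum(w)
  1 + sum(p * log(p)) / log(h)
}

.statsFromSummaries <- function(sm, n, m, siThresholds = c(1, 2)) {
  tab <- table(sm$topo)
  TE <- .xlogx(as.numeric(tab))
  QE <- .xlogx(as.numeric(sm$quartets))
  st <- .splitTable(sm)
  si <- if (length(st$masks))
    cpp_si_sums(st$masks, st$w, as.integer(c(0, siThresholds)), m)
  else rep(0, 1 + length(siThresholds))
  RS <- sum(st$w == 1)
  US <- length(st$masks)
  DC <- sum(pmin(st$w, n - st$w))
  ch <- unlist(sm$cherries)
  UC <- length(unique(ch))
  cons <- .greedyMasks(st, m)
  if (length(cons)) {
    conf <- cpp_conflict_weights(st$masks, st$w, cons, m)
    x1 <- st$w[match(cons, st$masks)]
    TC <- sum(vapply(seq_along(cons), function(i)
      .icValue(x1[i], if (length(conf[[i]])) max(conf[[i]]) else 0),
      numeric(1)))
    TCA <- sum(vapply(seq_along(cons), function(i)
      .icaValue(x1[i], conf[[i]]), numeric(1)))
  } else {
    TC <- TCA <- 0
  }
  out <- c(TE = TE, QE = QE, SI = si[1L],
           setNames(si[-1L], paste0("SI", siThresholds)),
           RS = RS, DC = DC, UC = UC, US = US, TC = TC, TCA = TCA)
  out
}

#' Discordance statistics of a tree profile
#'
#' Computes the full vector of base statistics of a profile
#' `P = (T1, ..., Tn)` of rooted binary trees on a shared taxon set `X`
#' (`m = |X|`):
#' \describe{
#'   \item{TE}{tree entropy, `sum w(T) log w(T)` over unique rooted
#'     topologies (`w` = multiplicity, natural log).}
#'   \item{QE}{quartet entropy, `sum_{4-subsets} sum_{i=1..3} wQ(qi) log
#'     wQ(qi)` over the three resolutions of every quartet.}
#'   \item{SI}{split incompatibility: `sum` over ordered pairs of observed
#'     unique splits of `wS(si) wS(sj)` times the incompatibility
#'     indicator.}
#'   \item{SI-k}{as SI but restricted to splits with `wS > k`, with weights
#'     `wS - k`.}
#'   \item{RS}{number of splits observed in exactly one tree.}
#'   \item{DC}{distance to the majority-rule consensus,
#'     `sum_s min(wS(s), n - wS(s))` (equivalently the summed unhalved
#'     Robinson–Foulds distance from each tree to the consensus).}
#'   \item{UC, US}{numbers of unique cherries and unique nontrivial
#'     splits.}
#'   \item{TC, TCA}{tree certainty (sum of internode certainties) and its
#'     all-conflicts generalisation, both evaluated on the greedy consensus
#'     tree.}
#' }
#'
#' @param profile a [TreeProfile-class].
#' @param siThresholds thresholds `k` for the SI-k family (default 1 and 2,
#'   giving the columns SI1 and SI2).
#' @return a named numeric vector
#'   `(TE, QE, SI, SI1, SI2, RS, DC, UC, US, TC, TCA)`.
#' @examples
#' prof <- treeProfile(list(ape::read.tree(text = "((a,b),(c,d));"),
#'                          ape::read.tree(text = "((a,c),(b,d));")))
#' baseStatistics(prof)
#' @export
baseStatistics <- function(profile, siThresholds = c(1, 2)) {
  stopifnot(is(profile, "TreeProfile"))
  sm <- .profileSummaries(profile)
  .statsFromSummaries(sm, length(profile@trees), length(profile@taxa),
                      siThresholds)
}

#' @rdname baseStatistics
#' @export
treeEntropy <- function(profile) {
  stopifnot(is(profile, "TreeProfile"))
  keys <- vapply(profile@trees, topologyKey, character(1))
  .xlogx(as.numeric(table(keys)))
}

#' @rdname baseStatistics
#' @export
quartetEntropy <- function(profile) {
  stopifnot(is(profile, "TreeProfile"))
  sm <- .profileSummaries(profile, quartets = TRUE)
  .xlogx(as.numeric(sm$quartets))
}

#' @rdname baseStatistics
#' @param k ignore splits with weight at most `k` (and shrink the remaining
#'   weights by `k`); `k = 0` gives SI itself.
#' @export
splitIncompatibility <- function(profile, k = 0) {
  stopifnot(is(profile, "TreeProfile"), k >= 0)
  sm <- .profileSummaries(profile, quartets = FALSE)
  st <- .splitTable(sm)
  if (!length(st$masks)) return(0)
  as.numeric(cpp_si_sums(st$masks, st$w, as.integer(k),
                         length(profile@taxa)))
}

#' @rdname baseStatistics
#' @export
rareSplits <- function(profile) {
  stopifnot(is(profile, "TreeProfile"))
  st <- .splitTable(.profileSummaries(profile, quartets = FALSE))
  sum(st$w == 1)
}

#' @rdname baseStatistics
#' @export
distanceToConsensus <- function(profile) {
  stopifnot(is(profile, "TreeProfile"))
  st <- .splitTable(.profileSummaries(profile, quartets = FALSE))
  n <- length(profile@trees)
  sum(pmin(st$w, n - st$w))
}

#' @rdname baseStatistics
#' @export
uniqueSplits <- function(profile) {
  stopifnot(is(profile, "TreeProfile"))
  length(.splitTable(.profileSummaries(profile, quartets = FALSE))$masks)
}

#' @rdname baseStatistics
#' @export
uniqueCherries <- function(profile) {
  stopifnot(is(profile, "TreeProfile"))
  sm <- .profileSummaries(profile, quartets = FALSE)
  length(unique(unlist(sm$cherries)))
}

#' @rdname baseStatistics
#' @description `pairwiseRFSum()` is the summed (unhalved) Robinson–Foulds
#'   distance over all ordered tree pairs of the profile — the intuitive
#'   companion form of SI; the two agree on many but not all profiles, and
#'   the split-pair form is the one the SI-k family generalises.
#' @export
pairwiseRFSum <- function(profile) {
  stopifnot(is(profile, "TreeProfile"))
  sm <- .profileSummaries(profile, quartets = FALSE)
  st <- .splitTable(sm)
  n <- length(profile@trees)
  2 * n * sum(st$w) - 2 * sum(st$w^2)
}

#' Internode certainty of a split
#'
#' `IC = 1 + p log2 p + (1 - p) log2(1 - p)` with `p = x1 / (x1 + x2)`,
#' where `x1` is the number of trees displaying the split and `x2` the
#' count of the most numerous split incompatible with it.  IC is 1 for an
#' unopposed split and 0 when the best rival is equally frequent.
#'
#' @param x1 count of the evaluated split (`>= 1`).
#' @param x2 count of its most numerous incompatible split (`>= 0`).
#' @return the internode certainty.
#' @examples
#' internodeCertainty(3, 1)
#' @export
internodeCertainty <- function(x1, x2) .icValue(x1, x2)

#' @rdname baseStatistics
#' @export
treeCertainty <- function(profile) {
  unname(baseStatistics(profile)["TC"])
}

#' @rdname baseStatistics
#' @export
treeCertaintyAll <- function(profile) {
  unname(baseStatistics(profile)["TCA"])
}

#' Greedy consensus tree of a profile
#'
#' Observed splits are ranked by the number of trees displaying them
#' (ties broken by canonical split encoding, then first appearance) and
#' accepted greedily when compatible with everything accepted before; the
#' returned tree displays the accepted splits.  Every majority split is
#' included.  The tree is returned rooted at an arbitrary taxon and should
#' be regarded as unrooted.
#'
#' @param profile a [TreeProfile-class].
#' @return a `phylo` (possibly non-binary).
#' @examples
#' prof <- treeProfile(list(ape::read.tree(text = "((a,b),(c,d));"),
#'                          ape::read.tree(text = "((a,b),(c,d));"),
#'                          ape::read.tree(text = "((a,c),(b,d));")))
#' greedyConsensus(prof)
#' @export
greedyConsensus <- function(profile) {
  stopifnot(is(profile, "TreeProfile"))
  st <- .splitTable(.profileSummaries(profile, quartets = FALSE))
  m <- length(profile@taxa)
  masks <- .greedyMasks(st, m)
  .maskTree(masks, profile@taxa)
}

.popcount <- function(x)
  vapply(x, function(v) sum(bitwAnd(bitwShiftR(v, 0:29), 1L)), integer(1))

## laminar family of canonical masks (all excluding taxon 1) -> rooted
## display tree with taxon 1 at the root
.maskTree <- function(masks, taxa) {
  m <- length(taxa)
  if (!length(masks)) {
    return(ape::read.tree(
      text = paste0("(", paste(taxa, collapse = ","), ");")))
  }
  pc <- .popcount(masks)
  ord <- order(pc, decreasing = TRUE)
  masks <- masks[ord]; pc <- pc[ord]
  nM <- length(masks)
  parent <- integer(nM) # 0 = root; compatible masks form a laminar family
  for (i in seq_len(nM)) {
    for (j in rev(seq_len(i - 1L))) { # nearest earlier superset is smallest
      if (bitwAnd(masks[i], masks[j]) == masks[i]) {
        parent[i] <- j
        break
      }
    }
  }
  taxMask <- bitwShiftL(1L, seq_len(m) - 1L)
  taxParent <- integer(m) # smallest containing mask, 0 = root (taxon 1 too)
  for (t in seq_len(m)[-1L]) {
    inMask <- which(bitwAnd(masks, taxMask[t]) != 0L)
    if (length(inMask)) taxParent[t] <- inMask[which.min(pc[inMask])]
  }
  rec <- function(node) {
    parts <- c(taxa[which(taxParent == node)],
               vapply(which(parent == node), rec, character(1)))
    paste0("(", paste(sort(parts, method = "radix"), collapse = ","), ")")
  }
  top <- c(taxa[which(taxParent == 0L)],
           vapply(which(parent == 0L), rec, character(1)))
  txt <- paste0("(", paste(sort(top, method = "radix"), collapse = ","),
                ");")
  ape::read.tree(text = txt)
}

#' Splits displayed by a tree
#'
#' The nontrivial splits (bipartitions with at least two taxa on each side)
#' induced by the internal edges of the unrooted view of a tree,
#' canonicalised so that the side not containing the alphabetically first
#' taxon is listed first and taxa are sorted within sides.
#'
#' @param tree a rooted binary `phylo`.
#' @return a character vector of splits in `"a,b|c,d"` form.
#' @examples
#' extractSplits(ape::read.tree(text = "((a,b),(c,d));"))
#' @export
extractSplits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- sort(tree$tip.label, method = "radix")
  m <- length(taxa)
  ch <- vector("list", m + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2L])
  }
  clade <- vector("list", m + tree$Nnode)
  rec <- function(v) {
    if (v <= m) return(clade[[v]] <<- tree$tip.label[v])
    clade[[v]] <<- sort(unlist(lapply(ch[[v]], rec)))
  }
  rec(m + 1L)
  keys <- character(0)
  for (v in seq_along(clade)) {
    if (v <= m || v == m + 1L) next # tips and the root
    side <- clade[[v]]
    if (length(side) < 2L || length(side) > m - 2L) next
    if (taxa[1L] %in% side) side <- setdiff(taxa, side)
    keys <- c(keys, paste0(paste(sort(side), collapse = ","), "|",
                           paste(sort(setdiff(taxa, side)),
                                 collapse = ",")))
  }
  unique(keys)
}

.maskToSplit <- function(mask, taxa) {
  inSide <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(taxa) - 1L)) != 0L)
  paste0(paste(taxa[inSide], collapse = ","), "|",
         paste(taxa[-inSide], collapse = ","))
}

.splitToSides <- function(s) {
  if (is.character(s) && length(s) == 1L && grepl("|", s, fixed = TRUE)) {
    parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
    lapply(parts, function(p) strsplit(p, ",", fixed = TRUE)[[1L]])
  } else if (is.list(s) && length(s) == 2L) {
    s
  } else stop("a split must be 'a,b|c,d' or a list of two taxon vectors")
}

#' Compatibility of two splits
#'
#' Two splits `A|A'` and `B|B'` over the same taxon set are compatible iff
#' at least one of the four side intersections is empty — exactly when some
#' tree displays both.
#'
#' @param s1,s2 splits as `"a,b|c,d"` strings or lists of two taxon
#'   vectors.
#' @return `TRUE` or `FALSE`.
#' @examples
#' splitsCompatible("a,b|c,d,e", "c,d|a,b,e")
#' splitsCompatible("a,b|c,d", "a,c|b,d")
#' @export
splitsCompatible <- function(s1, s2) {
  a <- .splitToSides(s1)
  b <- .splitToSides(s2)
  x1 <- sort(c(a[[1L]], a[[2L]]))
  x2 <- sort(c(b[[1L]], b[[2L]]))
  if (!identical(x1, x2)) stop("splits are over different taxon sets")
  any(vapply(1:2, function(i) {
    any(vapply(1:2, function(j)
      length(intersect(a[[i]], b[[j]])) == 0L, logical(1)))
  }, logical(1)))
}
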
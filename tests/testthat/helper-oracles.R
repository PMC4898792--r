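# Brute-force oracles, independent of the package internals: splits and
# quartets by naive recursion/restriction, statistics by direct enumeration.

or_children <- function(phy) {
  ch <- vector("list", length(phy$tip.label) + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    ch[[p]] <- c(ch[[p]], c)
  }
  ch
}

# descendant tip labels per node
or_clades <- function(phy) {
  m <- length(phy$tip.label)
  ch <- or_children(phy)
  out <- vector("list", m + phy$Nnode)
  rec <- function(v) {
    if (v <= m) return(out[[v]] <<- phy$tip.label[v])
    out[[v]] <<- sort(unlist(lapply(ch[[v]], rec)))
  }
  rec(m + 1)
  out
}

# canonical nontrivial splits of the unrooted view, as "x,y" strings of the
# sorted side not containing the alphabetically first taxon
or_splitset <- function(phy) {
  taxa <- sort(phy$tip.label)
  m <- length(taxa)
  cl <- or_clades(phy)
  keys <- character(0)
  for (v in seq_along(cl)) {
    if (v <= m || v == m + 1) next # tips and root
    side <- cl[[v]]
    if (length(side) < 2 || length(side) > m - 2) next
    if (taxa[1] %in% side) side <- setdiff(taxa, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

or_split_mask <- function(key, taxa) {
  side <- strsplit(key, ",", fixed = TRUE)[[1]]
  sum(2^(match(side, taxa) - 1))
}

or_compatible <- function(k1, k2, taxa) {
  a <- strsplit(k1, ",", fixed = TRUE)[[1]]
  b <- strsplit(k2, ",", fixed = TRUE)[[1]]
  ac <- setdiff(taxa, a); bc <- setdiff(taxa, b)
  length(intersect(a, b)) == 0 || length(intersect(a, bc)) == 0 ||
    length(intersect(ac, b)) == 0 || length(intersect(ac, bc)) == 0
}

# quartet resolution of a tree restricted to 4 taxa: returns the sorted pair
# grouped with the alphabetically first of the four, e.g. "a|b" means a,b
# together
or_quartet <- function(phy, four) {
  sub <- ape::unroot(ape::keep.tip(phy, four))
  spl <- or_splitset(sub)
  stopifnot(length(spl) == 1)
  side <- strsplit(spl, ",", fixed = TRUE)[[1]]
  other <- setdiff(four, side)
  paste(sort(side), collapse = ",")
}

or_cherries <- function(phy) {
  un <- ape::unroot(phy)
  m <- length(un$tip.label)
  keys <- character(0)
  for (v in unique(un$edge[, 1])) {
    nb <- c(un$edge[un$edge[, 1] == v, 2], un$edge[un$edge[, 2] == v, 1])
    tipsAdj <- sort(un$tip.label[nb[nb <= m]])
    if (length(tipsAdj) >= 2) {
      prs <- combn(tipsAdj, 2)
      keys <- c(keys, apply(prs, 2, paste, collapse = ","))
    }
  }
  unique(keys)
}

or_topo_groups <- function(trees) {
  n <- length(trees)
  grp <- integer(n)
  g <- 0
  for (i in seq_len(n)) {
    if (grp[i] > 0) next
    g <- g + 1
    grp[i] <- g
    if (i < n) for (j in (i + 1):n) {
      if (grp[j] == 0 &&
          isTRUE(ape::all.equal.phylo(trees[[i]], trees[[j]],
                                      use.edge.length = FALSE)))
        grp[j] <- g
    }
  }
  tabulate(grp)
}

or_xlogx <- function(x) sum(ifelse(x > 0, x * log(pmax(x, 1e-300)), 0))

or_ic <- function(x1, x2) {
  p <- x1 / (x1 + x2)
  f <- function(q) if (q > 0) q * log2(q) else 0
  1 + f(p) + f(1 - p)
}

or_ica <- function(w) { # w = c(split count, conflicting counts)
  h <- length(w)
  if (h == 1) return(1)
  p <- w / sum(w)
  1 + sum(p * log(p)) / log(h)
}

# the full statistics vector by naive enumeration
or_base_stats <- function(trees, siThresholds = c(1, 2)) {
  n <- length(trees)
  taxa <- sort(trees[[1]]$tip.label)
  m <- length(taxa)

  TE <- or_xlogx(or_topo_groups(trees))

  splitsPer <- lapply(trees, or_splitset)
  allS <- unlist(splitsPer)
  uniq <- unique(allS)
  w <- vapply(uniq, function(s) sum(allS == s), numeric(1),
              USE.NAMES = FALSE)

  QE <- 0
  if (m >= 4) {
    fours <- combn(taxa, 4, simplify = FALSE)
    for (f in fours) {
      res <- vapply(trees, or_quartet, character(1), four = f)
      QE <- QE + or_xlogx(as.numeric(table(res)))
    }
  }

  inc <- outer(seq_along(uniq), seq_along(uniq), Vectorize(function(i, j)
    i != j && !or_compatible(uniq[i], uniq[j], taxa)))
  siVals <- vapply(c(0, siThresholds), function(k) {
    keep <- w > k
    ww <- ifelse(keep, w - k, 0)
    sum(outer(ww, ww) * inc * outer(keep, keep))
  }, numeric(1))

  RS <- sum(w == 1)
  US <- length(uniq)
  DC <- sum(pmin(w, n - w))
  UC <- length(unique(unlist(lapply(trees, or_cherries))))

  # greedy consensus: weight desc, canonical mask asc
  masks <- vapply(uniq, or_split_mask, numeric(1), taxa = taxa)
  ord <- order(-w, masks)
  acc <- integer(0)
  for (i in ord) {
    if (all(vapply(acc, function(j) or_compatible(uniq[i], uniq[j], taxa),
                   logical(1)))) {
      acc <- c(acc, i)
      if (length(acc) == m - 3) break
    }
  }
  TC <- TCA <- 0
  for (i in acc) {
    confW <- w[which(inc[i, ])]
    TC <- TC + or_ic(w[i], if (length(confW)) max(confW) else 0)
    TCA <- TCA + or_ica(c(w[i], confW))
  }

  c(TE = TE, QE = QE, SI = siVals[1],
    setNames(siVals[-1], paste0("SI", siThresholds)),
    RS = RS, DC = DC, UC = UC, US = US, TC = TC, TCA = TCA)
}

# DC via an explicitly built majority-rule consensus split set, unhalved
# symmetric-difference RF summed over trees
or_dc_consensus <- function(trees) {
  n <- length(trees)
  splitsPer <- lapply(trees, or_splitset)
  allS <- unlist(splitsPer)
  uniq <- unique(allS)
  w <- vapply(uniq, function(s) sum(allS == s), numeric(1))
  maj <- uniq[w > n / 2]
  sum(vapply(splitsPer, function(s)
    length(setdiff(s, maj)) + length(setdiff(maj, s)), numeric(1)))
}

# random rooted binary profile with repeated topologies
or_random_profile <- function(m, n, nTopo = max(2, n %/% 2)) {
  base <- lapply(seq_len(nTopo), function(i)
    ape::rtree(m, tip.label = letters[seq_len(m)]))
  trees <- base[sample.int(nTopo, n, replace = TRUE)]
  treeProfile(trees)
}
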
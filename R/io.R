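#' Read a profile of trees from a file
#'
#' Reads multi-tree Newick files or the TREES block of a Nexus file
#' (taxon-label translation tables are honoured) into a validated
#' [TreeProfile-class]; all trees must be rooted, binary, and on one taxon
#' set.
#'
#' @param path file path.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (sniff `#NEXUS`).
#' @return a [TreeProfile-class].
#' @export
readTreeProfile <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path)
           else ape::read.tree(path)
  if (is.null(trees)) stop("no trees could be parsed from ", path)
  treeProfile(trees)
}

#' Write a profile of trees
#'
#' Gene trees are written edge-weighted, as a Nexus TREES block or as
#' multi-line Newick.
#'
#' @param profile a [TreeProfile-class].
#' @param path output file.
#' @param format `"nexus"` or `"newick"`.
#' @return `path`, invisibly.
#' @export
writeTreeProfile <- function(profile, path, format = c("nexus", "newick")) {
  format <- match.arg(format)
  stopifnot(is(profile, "TreeProfile"))
  trees <- profile@trees
  class(trees) <- "multiPhylo"
  if (format == "nexus") ape::write.nexus(trees, file = path)
  else ape::write.tree(trees, file = path)
  invisible(path)
}

#' Serialise a species network
#'
#' Writes the network as extended Newick with hybrid-origin nodes tagged
#' `#H<i>` (appearing once with their subtree under the first parent and
#' once as a tagged leaf under the second), and a sidecar TSV of all
#' reticulation events (`time`, `type`, `from`, `to`, `gamma`) — for
#' introgression the donor/recipient pair with the replaced genome
#' fraction, for hybrid speciation the first parent, the hybrid species and
#' its contribution.  Branch lengths are simulation time units.
#'
#' @param network a [SpeciesNetwork-class].
#' @param path output file for the extended Newick; the sidecar is written
#'   to `paste0(path, ".reticulations.tsv")`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path) {
  stopifnot(is(network, "SpeciesNetwork"))
  r <- network@reticulations
  eff <- network@nodeParent
  tagOf <- character(length(network@nodeTime))
  extraLeaf <- vector("list", length(network@nodeTime))
  hi <- 0L
  for (i in seq_len(nrow(r))) {
    if (r$type[i] == "hybrid") {
      hi <- hi + 1L
      eff[r$child[i]] <- r$parentA[i]
      tagOf[r$child[i]] <- sprintf("#H%d", hi)
      extraLeaf[[r$parentB[i]]] <-
        c(extraLeaf[[r$parentB[i]]], sprintf("#H%d", hi))
    } else {
      eff[r$child[i]] <- r$parentB[i] # display the backbone species tree
    }
  }
  ch <- .childrenList(eff)
  isTip <- logical(length(eff))
  isTip[network@tips] <- TRUE
  lab <- character(length(eff))
  lab[network@tips] <- network@tipLabels
  tm <- network@nodeTime
  rec <- function(v) {
    kids <- ch[[v]]
    extras <- extraLeaf[[v]]
    if (isTip[v]) return(list(str = lab[v], t = tm[v]))
    if (length(kids) + length(extras) == 1L && length(kids) == 1L) {
      sub <- rec(kids[1L])
      if (nzchar(tagOf[v]))
        return(list(str = sprintf("(%s:%.10g)%s", sub$str, sub$t - tm[v],
                                  tagOf[v]), t = tm[v]))
      return(sub)
    }
    parts <- lapply(kids, rec)
    segs <- vapply(parts, function(p)
      sprintf("%s:%.10g", p$str, p$t - tm[v]), character(1))
    segs <- c(segs, vapply(extras, function(e)
      sprintf("%s:0", e), character(1)))
    list(str = paste0("(", paste(segs, collapse = ","), ")", tagOf[v]),
         t = tm[v])
  }
  root <- setdiff(which(eff == 0L), network@tips)
  txt <- paste0(rec(root[1L])$str, ";")
  writeLines(txt, path)
  side <- data.frame(time = r$time, type = r$type, from = r$from,
                     to = r$to, gamma = r$probA)
  write.table(side, paste0(path, ".reticulations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a profile's statistics as a one-row TSV
#'
#' Column layout `TE, QE, SI, SI-1, SI-2, RS, DC, UC, US, TC, TCA`.
#'
#' @param profile a [TreeProfile-class].
#' @param path output file.
#' @param siThresholds thresholds for the SI-k columns.
#' @return the statistics, invisibly.
#' @export
writeStatisticsTable <- function(profile, path, siThresholds = c(1, 2)) {
  st <- baseStatistics(profile, siThresholds)
  df <- as.data.frame(as.list(st))
  names(df) <- sub("^SI(\\d)$", "SI-\\1", names(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(st)
}

.configKeys <- c("seed", "success_function", "epochs", "halting",
                 "hybrid_contributions", "introgression_contributions",
                 "n_gene_trees")
.epochKeys <- c("start", "speciation_rate", "hybrid_rate",
                "introgression_rate", "coalescence_rate",
                "success_threshold")
.haltKeys <- c("max_depth", "max_species", "max_reticulations",
               "min_reticulations", "reduce_reticulations")

.asNum <- function(x, default) {
  if (is.null(x)) return(default)
  if (identical(x, ".inf") || identical(x, "inf")) return(Inf)
  as.numeric(x)
}

#' Read and validate a simulation configuration
#'
#' Parses a YAML run configuration into validated simulator objects.
#' Unknown keys are rejected; rates must be nonnegative, contributions in
#' (0, 1], and the epoch list non-empty with the first epoch starting at 0.
#'
#' @param path YAML file with keys `seed`, `success_function`, `epochs`
#'   (each with `start`, `speciation_rate`, `hybrid_rate`,
#'   `introgression_rate`, `coalescence_rate`, `success_threshold`),
#'   `halting` (`max_depth`, `max_species`, `max_reticulations`,
#'   `min_reticulations`, `reduce_reticulations`),
#'   `hybrid_contributions` / `introgression_contributions`
#'   (`gamma`, `prob`), `n_gene_trees`.
#' @return a list with `schedule`, `halting`, `hybridContrib`,
#'   `introContrib`, `nLoci`, `seed`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$epochs) || !length(cfg$epochs))
    stop("configuration must define at least one epoch")
  rates <- list()
  starts <- numeric(0)
  for (e in cfg$epochs) {
    bad <- setdiff(names(e), .epochKeys)
    if (length(bad))
      stop("unknown epoch key(s): ", paste(bad, collapse = ", "))
    rates[[length(rates) + 1L]] <- rateSet(
      lambdaS = .asNum(e$speciation_rate, 1),
      lambdaH = .asNum(e$hybrid_rate, 0),
      lambdaI = .asNum(e$introgression_rate, 0),
      lambdaC = .asNum(e$coalescence_rate, 1),
      threshold = .asNum(e$success_threshold, Inf))
    starts <- c(starts, .asNum(e$start, 0))
  }
  schedule <- epochSchedule(rates, boundaries = starts,
                            successKind = if (is.null(cfg$success_function))
                              "step" else cfg$success_function)
  h <- cfg$halting
  if (!is.null(h)) {
    bad <- setdiff(names(h), .haltKeys)
    if (length(bad))
      stop("unknown halting key(s): ", paste(bad, collapse = ", "))
  }
  halting <- haltingConfig(
    maxDepth = .asNum(h$max_depth, Inf),
    maxSpecies = .asNum(h$max_species, Inf),
    maxReticulations = .asNum(h$max_reticulations, Inf),
    minReticulations = .asNum(h$min_reticulations, 0),
    reduceToReticulations = .asNum(h$reduce_reticulations, Inf))
  mkContrib <- function(x) {
    if (is.null(x)) return(contributionDistribution(0.5))
    contributionDistribution(as.numeric(x$gamma),
                             if (is.null(x$prob))
                               rep(1 / length(x$gamma), length(x$gamma))
                             else as.numeric(x$prob))
  }
  list(schedule = schedule, halting = halting,
       hybridContrib = mkContrib(cfg$hybrid_contributions),
       introContrib = mkContrib(cfg$introgression_contributions),
       nLoci = as.integer(.asNum(cfg$n_gene_trees, 100)),
       seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}

#' Run a configured simulation and write its outputs
#'
#' Simulates one species network and its gene trees from a parsed
#' configuration and writes: the gene trees (Nexus), the network (extended
#' Newick plus reticulation sidecar TSV), the statistics TSV, and a YAML
#' metadata file recording the seed and the halting condition that fired.
#' With a seed in the configuration, repeated runs are bit-identical.
#'
#' @param config a list from [readRunConfig()].
#' @param outDir output directory (created if needed).
#' @param name file-name stem.
#' @return named vector of written paths, invisibly.
#' @export
runSimulation <- function(config, outDir = ".", name = "run") {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  net <- simulateNetwork(config$schedule, config$halting,
                         config$hybridContrib, config$introContrib)
  prof <- simulateGeneTrees(net, config$nLoci, config$schedule)
  paths <- c(trees = file.path(outDir, paste0(name, ".trees.nex")),
             network = file.path(outDir, paste0(name, ".network.enewick")),
             stats = file.path(outDir, paste0(name, ".stats.tsv")),
             meta = file.path(outDir, paste0(name, ".meta.yaml")))
  writeTreeProfile(prof, paths["trees"])
  writeNetwork(net, paths["network"])
  writeStatisticsTable(prof, paths["stats"])
  yaml::write_yaml(list(seed = config$seed,
                        n_gene_trees = config$nLoci,
                        n_taxa = nTaxa(net),
                        n_reticulations = nReticulations(net),
                        halted_on = net@metadata$haltReason,
                        depth = networkDepth(net)),
                   paths["meta"])
  invisible(paths)
}

#' The five-taxon worked-example network
#'
#' A hand-built network with three divergence speciations, one hybrid
#' speciation and one introgression: backbone (((A,B),D),E) with splits at
#' times 0, 0.2 and 0.4; an introgression from E into D at time 0.5
#' replacing fraction 0.1 of the genome; and taxon C arising at time 0.7 as
#' a hybrid of the B and D lineages with contributions 0.6/0.4; tips at
#' depth 1.  Its exhaustively enumerated lineage-tree distribution is
#' `(((A,(B,C)),D),E)` 0.54, `((A,(B,C)),(D,E))` 0.06,
#' `(((A,B),(C,D)),E)` 0.36, `((A,B),((C,D),E))` 0.04.
#'
#' @return a [SpeciesNetwork-class].
#' @examples
#' lineageTreeDistribution(demoNetwork())
#' @export
demoNetwork <- function() {
  nodeTime <- c(0, 0.2, 0.4, 0.5, 0.5, 0.7, 0.7, 0.7, 1, 1, 1, 1, 1)
  nodeParent <- as.integer(c(0, 1, 2, 1, 0, 3, 5, 0, 3, 6, 8, 7, 4))
  ret <- data.frame(
    child = c(5L, 8L), parentA = c(4L, 6L), parentB = c(2L, 7L),
    probA = c(0.1, 0.6), type = c("introgression", "hybrid"),
    time = c(0.5, 0.7), from = c("E", "B"), to = c("D", "C"),
    stringsAsFactors = FALSE)
  new("SpeciesNetwork", nodeTime = nodeTime, nodeParent = nodeParent,
      reticulations = ret, tips = c(9L, 10L, 11L, 12L, 13L),
      tipLabels = c("A", "B", "C", "D", "E"), depth = 1,
      events = data.frame(time = numeric(0), kind = character(0),
                          detail = character(0)),
      metadata = list(haltReason = "fixture"))
}
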
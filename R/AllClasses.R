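## Central S4 containers.  Node bookkeeping for a SpeciesNetwork uses a flat
## parent-pointer representation shared with the compiled coalescent kernel:
## node times increase from the root (time 0) to the tips (all at `depth`);
## reticulation children carry parent 0 in `nodeParent` and are routed through
## the `reticulations` table instead.  Reticulation children are always
## created after both their parents, which the kernel relies on for ordering
## ties at shared event times.

#' Per-epoch process rates and reticulation-success threshold
#'
#' Bundles the rates of the three forward processes, the pairwise coalescence
#' rate and the threshold/scale parameter of the reticulation success
#' function.  Rates are per unit time, with the divergence speciation rate
#' conventionally defining the time unit.  `lambdaS` applies per lineage,
#' `lambdaH` and `lambdaI` per ordered pair of species (total proposal rate
#' `lambda * N * (N - 1)`), and `lambdaC` per pair of uncoalesced gene
#' lineages.
#'
#' @slot lambdaS divergence speciation rate (per lineage).
#' @slot lambdaH hybrid-speciation proposal rate (per ordered species pair).
#' @slot lambdaI introgression proposal rate (per ordered species pair).
#' @slot lambdaC coalescence rate (per lineage pair).
#' @slot threshold success-function threshold/scale `T` (distance units);
#'   may be `Inf` for distance-independent success under the step function.
#' @export
setClass("RateSet",
  representation(lambdaS = "numeric", lambdaH = "numeric",
                 lambdaI = "numeric", lambdaC = "numeric",
                 threshold = "numeric"),
  prototype(lambdaS = 1, lambdaH = 0, lambdaI = 0, lambdaC = 1,
            threshold = Inf),
  validity = function(object) {
    v <- c(object@lambdaS, object@lambdaH, object@lambdaI, object@lambdaC)
    if (length(v) != 4L || any(!is.finite(v)) || any(v < 0))
      return("all rates must be finite, nonnegative scalars")
    if (length(object@threshold) != 1L || is.na(object@threshold) ||
        object@threshold <= 0)
      return("'threshold' must be a single positive value (Inf allowed)")
    TRUE
  })

#' @rdname RateSet-class
#' @param lambdaS,lambdaH,lambdaI,lambdaC,threshold see slots.
#' @return `rateSet()` returns a validated [RateSet-class] object.
#' @examples
#' rateSet(lambdaS = 1, lambdaH = 0.1, lambdaC = 5, threshold = 1.3)
#' @export
rateSet <- function(lambdaS = 1, lambdaH = 0, lambdaI = 0, lambdaC = 1,
                    threshold = Inf) {
  new("RateSet", lambdaS = lambdaS, lambdaH = lambdaH, lambdaI = lambdaI,
      lambdaC = lambdaC, threshold = threshold)
}

#' Piecewise-constant rate schedule
#'
#' A contiguous sequence of epochs starting at time 0, each with its own
#' [RateSet-class].  The functional form of the reticulation success curve is
#' shared by all epochs; only its threshold may differ between them.  The
#' final epoch is open-ended.
#'
#' @slot epochs list of [RateSet-class], one per epoch.
#' @slot boundaries numeric vector of epoch start times; first element 0,
#'   strictly increasing, same length as `epochs`.
#' @slot successKind one of `"linear"`, `"step"`, `"quadratic"`,
#'   `"snowball"`, `"exponential"`.
#' @export
setClass("EpochSchedule",
  representation(epochs = "list", boundaries = "numeric",
                 successKind = "character"),
  validity = function(object) {
    if (!length(object@epochs) ||
        !all(vapply(object@epochs, is, logical(1), "RateSet")))
      return("'epochs' must be a non-empty list of RateSet objects")
    b <- object@boundaries
    if (length(b) != length(object@epochs) || b[1] != 0 ||
        any(!is.finite(b)) || any(diff(b) <= 0))
      return("'boundaries' must start at 0 and increase strictly")
    if (length(object@successKind) != 1L ||
        !object@successKind %in% .successKinds)
      return(paste("'successKind' must be one of:",
                   paste(.successKinds, collapse = ", ")))
    TRUE
  })

.successKinds <- c("linear", "step", "quadratic", "snowball", "exponential")

#' @rdname EpochSchedule-class
#' @param rates a single [RateSet-class] or a list of them, one per epoch.
#' @param boundaries epoch start times (first must be 0).
#' @param successKind form of the reticulation success function.
#' @return `epochSchedule()` returns a validated [EpochSchedule-class].
#' @examples
#' epochSchedule(rateSet(lambdaH = 0.2, lambdaC = 5), successKind = "step")
#' @export
epochSchedule <- function(rates, boundaries = 0, successKind = "step") {
  if (is(rates, "RateSet")) rates <- list(rates)
  new("EpochSchedule", epochs = rates, boundaries = as.numeric(boundaries),
      successKind = successKind)
}

#' Discrete distribution of parental genome contributions
#'
#' Atoms are contribution fractions `gamma` in (0, 1] with sampling
#' probabilities.  For hybrid speciation, `gamma` is the fraction inherited
#' from the first-drawn parent; for introgression it is the fraction of the
#' recipient genome overwritten by the donor.  Separate instances may be used
#' for the two event kinds.
#'
#' @slot gamma contribution fractions in (0, 1].
#' @slot prob sampling probabilities (sum to 1).
#' @export
setClass("ContributionDistribution",
  representation(gamma = "numeric", prob = "numeric"),
  validity = function(object) {
    if (!length(object@gamma) ||
        length(object@gamma) != length(object@prob))
      return("'gamma' and 'prob' must be equal-length, non-empty")
    if (any(object@gamma <= 0) || any(object@gamma > 1))
      return("contributions must lie in (0, 1]")
    if (any(object@prob < 0) || abs(sum(object@prob) - 1) > 1e-8)
      return("'prob' must be nonnegative and sum to 1")
    TRUE
  })

#' @rdname ContributionDistribution-class
#' @param gamma,prob see slots; `prob` defaults to uniform over the atoms.
#' @return a validated [ContributionDistribution-class].
#' @examples
#' contributionDistribution(0.5)            # symmetric 50:50 contributions
#' contributionDistribution(0.25)           # 75:25 toward a random parent
#' @export
contributionDistribution <- function(gamma,
                                     prob = rep(1 / length(gamma),
                                                length(gamma))) {
  new("ContributionDistribution", gamma = as.numeric(gamma),
      prob = as.numeric(prob))
}

#' Halting and reticulation-count configuration
#'
#' The forward simulation stops at whichever of three limits is reached
#' first: root-to-tip depth, species count, or successful reticulation
#' count.  A minimum reticulation count triggers rejection-and-resimulation;
#' a reduce-to count removes surplus reticulations after the run by granting
#' one parent the full genome contribution.
#'
#' @slot maxDepth,maxSpecies,maxReticulations halting limits (may be `Inf`,
#'   but not all three at once).
#' @slot minReticulations minimum successful reticulations (else reject).
#' @slot reduceToReticulations post-hoc reticulation cap (may be `Inf`).
#' @export
setClass("HaltingConfig",
  representation(maxDepth = "numeric", maxSpecies = "numeric",
                 maxReticulations = "numeric", minReticulations = "numeric",
                 reduceToReticulations = "numeric"),
  validity = function(object) {
    lims <- c(object@maxDepth, object@maxSpecies, object@maxReticulations)
    if (any(lims <= 0)) return("halting limits must be positive")
    if (all(is.infinite(c(object@maxDepth, object@maxSpecies))))
      return("no reachable halting condition: maxDepth and maxSpecies are both infinite")
    if (object@minReticulations < 0)
      return("'minReticulations' must be >= 0")
    if (is.finite(object@reduceToReticulations) &&
        object@minReticulations > object@reduceToReticulations)
      return("'minReticulations' must not exceed 'reduceToReticulations'")
    TRUE
  })

#' @rdname HaltingConfig-class
#' @param maxDepth,maxSpecies,maxReticulations,minReticulations,reduceToReticulations
#'   see slots.
#' @return a validated [HaltingConfig-class].
#' @examples
#' haltingConfig(maxSpecies = 10, minReticulations = 2,
#'               reduceToReticulations = 2)
#' @export
haltingConfig <- function(maxDepth = Inf, maxSpecies = Inf,
                          maxReticulations = Inf, minReticulations = 0,
                          reduceToReticulations = Inf) {
  new("HaltingConfig", maxDepth = maxDepth, maxSpecies = maxSpecies,
      maxReticulations = maxReticulations,
      minReticulations = minReticulations,
      reduceToReticulations = reduceToReticulations)
}

#' A rooted, time-calibrated species network
#'
#' Nodes are stored as flat parent pointers with times; hybrid-origin nodes
#' and introgression attachment points are reticulation children with two
#' candidate parents and a routing probability (the genome fraction
#' contributed by `parentA`).  All tips are contemporaneous at `depth`.
#'
#' @slot nodeTime node times (root 0, increasing toward the tips).
#' @slot nodeParent parent index per node; 0 for the root and for
#'   reticulation children.
#' @slot reticulations data frame with columns `child`, `parentA`, `parentB`,
#'   `probA`, `type` (`"hybrid"` or `"introgression"`), `time`.
#' @slot tips node indices of the leaves, in `tipLabels` order.
#' @slot tipLabels species names.
#' @slot depth root-to-tip time.
#' @slot events event trace (`time`, `kind`, `detail`).
#' @slot metadata run metadata (halting reason, seed if recorded, ...).
#' @export
setClass("SpeciesNetwork",
  representation(nodeTime = "numeric", nodeParent = "integer",
                 reticulations = "data.frame", tips = "integer",
                 tipLabels = "character", depth = "numeric",
                 events = "data.frame", metadata = "list"),
  validity = function(object) {
    K <- length(object@nodeTime)
    if (length(object@nodeParent) != K)
      return("'nodeTime' and 'nodeParent' lengths differ")
    if (length(object@tips) != length(object@tipLabels))
      return("'tips' and 'tipLabels' lengths differ")
    if (anyDuplicated(object@tipLabels))
      return("tip labels must be unique")
    par <- object@nodeParent
    has <- par > 0L
    if (any(object@nodeTime[has] < object@nodeTime[par[has]]))
      return("node times must be nondecreasing from root to tips")
    if (any(abs(object@nodeTime[object@tips] - object@depth) > 1e-9))
      return("all tips must sit at the network depth")
    r <- object@reticulations
    need <- c("child", "parentA", "parentB", "probA", "type", "time")
    if (!all(need %in% names(r)))
      return("'reticulations' is missing required columns")
    if (nrow(r)) {
      if (any(par[r$child] != 0L))
        return("reticulation children must have nodeParent 0")
      if (any(r$probA < 0 | r$probA > 1))
        return("routing probabilities must lie in [0, 1]")
      if (any(r$child <= r$parentA) || any(r$child <= r$parentB))
        return("reticulation children must be created after both parents")
      bad <- abs(object@nodeTime[r$child] - r$time) > 1e-9 |
        object@nodeTime[r$parentA] > r$time + 1e-9 |
        object@nodeTime[r$parentB] > r$time + 1e-9
      if (any(bad))
        return("reticulation child must sit at the event time, parents at or before it")
    }
    TRUE
  })

#' A profile of gene trees on one taxon set
#'
#' An ordered collection of rooted binary trees (ape `phylo` objects) sharing
#' one taxon set; the unit of analysis for all discordance statistics.
#'
#' @slot trees list of `phylo` objects.
#' @slot taxa sorted common taxon labels.
#' @export
setClass("TreeProfile",
  representation(trees = "list", taxa = "character"),
  validity = function(object) {
    if (!length(object@trees)) return("a profile needs at least one tree")
    ok <- vapply(object@trees, inherits, logical(1), "phylo")
    if (!all(ok)) return("all trees must be 'phylo' objects")
    for (i in seq_along(object@trees)) {
      tr <- object@trees[[i]]
      if (!setequal(tr$tip.label, object@taxa))
        return(sprintf("tree %d is not on the shared taxon set", i))
      if (!ape::is.binary(tr) || !ape::is.rooted(tr))
        return(sprintf("tree %d is not rooted and binary", i))
    }
    TRUE
  })

#' @rdname TreeProfile-class
#' @param trees a list of `phylo` objects or a `multiPhylo`.
#' @return a validated [TreeProfile-class].
#' @export
treeProfile <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel")))
    trees <- ape::.uncompressTipLabel(trees)
  trees <- unclass(trees)
  attributes(trees) <- NULL  # drop multiPhylo attributes, keep a bare list
  new("TreeProfile", trees = trees, taxa = sort(trees[[1]]$tip.label))
}
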
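## Forward event loop.  The run starts with a speciation at time 0 giving two
## species at genetic distance zero, then iterates: draw waiting time and
## event type, advance time and the distance matrix, apply the event (with
## reticulation attempts succeeding with probability F(d) from the epoch's
## success function), until a halting condition fires.

.drawGamma <- function(cd) {
  if (length(cd@gamma) == 1L) return(cd@gamma)
  sample(cd@gamma, 1L, prob = cd@prob)
}

.distanceIndependent <- function(schedule, maxDepth) {
  schedule@successKind == "step" &&
    all(vapply(schedule@epochs, function(e) e@threshold, numeric(1)) >=
          2 * maxDepth)
}

.simulateNetworkOnce <- function(schedule, halting, hybridContrib,
                                 introContrib) {
  nodeTime <- 0
  nodeParent <- 0L
  ret <- list()
  species <- c("t1", "t2")
  origin <- c(t1 = 1L, t2 = 1L)
  nNamed <- 2L
  D <- matrix(0, 2, 2, dimnames = list(species, species))
  t <- 0
  nRet <- 0L
  evLog <- list()
  haltReason <- NULL

  newNode <- function(time, parent) {
    nodeTime[length(nodeTime) + 1L] <<- time
    nodeParent[length(nodeParent) + 1L] <<- as.integer(parent)
    length(nodeTime)
  }

  repeat {
    N <- length(species)
    ev <- drawEvent(t, N, schedule)
    if (t + ev$deltaT >= halting@maxDepth) {
      D <- advanceDistances(D, halting@maxDepth - t)
      t <- halting@maxDepth
      haltReason <- "maxDepth"
      break
    }
    D <- advanceDistances(D, ev$deltaT)
    t <- t + ev$deltaT
    epoch <- schedule@epochs[[ev$epoch]]

    if (ev$kind == "speciation") {
      if (N + 1 > halting@maxSpecies) { haltReason <- "maxSpecies"; break }
      parent <- sample(species, 1L)
      child <- paste0("t", nNamed <- nNamed + 1L)
      v <- newNode(t, origin[parent])
      origin[parent] <- v
      origin[child] <- v
      species <- c(species, child)
      D <- speciationDistances(D, parent, child)
      evLog[[length(evLog) + 1L]] <-
        list(t, "speciation", paste(parent, "->", child))
    } else {
      pair <- sample(species, 2L)
      d <- D[pair[1L], pair[2L]]
      ok <- runif(1L) < successProbability(schedule@successKind,
                                          epoch@threshold, d)
      if (ev$kind == "hybrid_attempt") {
        if (ok && N + 1 > halting@maxSpecies) {
          haltReason <- "maxSpecies"; break
        }
        if (ok && nRet + 1 > halting@maxReticulations) {
          haltReason <- "maxReticulations"; break
        }
        if (ok) {
          a <- pair[1L]; b <- pair[2L]
          gamma <- .drawGamma(hybridContrib)
          child <- paste0("t", nNamed <- nNamed + 1L)
          va <- newNode(t, origin[a]); origin[a] <- va
          vb <- newNode(t, origin[b]); origin[b] <- vb
          h <- newNode(t, 0L)
          ret[[length(ret) + 1L]] <- data.frame(
            child = h, parentA = va, parentB = vb, probA = gamma,
            type = "hybrid", time = t,
            from = a, to = child, stringsAsFactors = FALSE)
          origin[child] <- h
          species <- c(species, child)
          D <- hybridDistances(D, a, b, gamma, child)
          nRet <- nRet + 1L
          evLog[[length(evLog) + 1L]] <-
            list(t, "hybrid_speciation",
                 sprintf("%s + %s -> %s (gamma=%g)", a, b, child, gamma))
        } else {
          evLog[[length(evLog) + 1L]] <-
            list(t, "hybrid_attempt_failed", paste(pair, collapse = " + "))
        }
      } else { # introgression attempt
        if (ok && nRet + 1 > halting@maxReticulations) {
          haltReason <- "maxReticulations"; break
        }
        if (ok) {
          donor <- pair[1L]; recip <- pair[2L]
          gamma <- .drawGamma(introContrib)
          vd <- newNode(t, origin[donor]); origin[donor] <- vd
          vr <- newNode(t, 0L)
          ret[[length(ret) + 1L]] <- data.frame(
            child = vr, parentA = vd, parentB = origin[[recip]],
            probA = gamma, type = "introgression", time = t,
            from = donor, to = recip, stringsAsFactors = FALSE)
          origin[donor] <- vd
          origin[recip] <- vr
          D <- introgressionDistances(D, donor, recip, gamma)
          nRet <- nRet + 1L
          evLog[[length(evLog) + 1L]] <-
            list(t, "introgression",
                 sprintf("%s -> %s (gamma=%g)", donor, recip, gamma))
        } else {
          evLog[[length(evLog) + 1L]] <-
            list(t, "introgression_attempt_failed",
                 paste(pair, collapse = " -> "))
        }
      }
    }
  }

  tips <- integer(length(species))
  for (i in seq_along(species))
    tips[i] <- newNode(t, origin[[species[i]]])
  events <- if (length(evLog)) {
    data.frame(time = vapply(evLog, function(x) x[[1L]], numeric(1)),
               kind = vapply(evLog, function(x) x[[2L]], character(1)),
               detail = vapply(evLog, function(x) x[[3L]], character(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(time = numeric(0), kind = character(0),
               detail = character(0))
  }
  retDf <- if (length(ret)) do.call(rbind, ret) else
    data.frame(child = integer(0), parentA = integer(0),
               parentB = integer(0), probA = numeric(0),
               type = character(0), time = numeric(0),
               from = character(0), to = character(0))
  new("SpeciesNetwork", nodeTime = nodeTime, nodeParent = nodeParent,
      reticulations = retDf, tips = tips, tipLabels = species,
      depth = t, events = events,
      metadata = list(haltReason = haltReason, distances = D))
}

#' Simulate a species network forward in time
#'
#' Grows a rooted, time-calibrated species network under divergence
#' speciation, hybrid speciation and introgression, maintaining the
#' genetic-distance matrix on which reticulation success probabilities are
#' evaluated.  The run halts when the first of the configured limits (depth,
#' species count, successful reticulation count) would be violated; in the
#' depth case time is advanced so the root-to-tip distance equals the
#' maximum, otherwise time is advanced to the moment of the violating event,
#' which is discarded.  Networks with fewer than `minReticulations`
#' reticulations are discarded and resimulated; networks with more than
#' `reduceToReticulations` have surplus reticulations eliminated at random
#' (one parent's contribution set to 100%), so setting the two equal
#' conditions the network on an exact reticulation count.
#'
#' @param schedule an [EpochSchedule-class].
#' @param halting a [HaltingConfig-class].
#' @param hybridContrib,introContrib [ContributionDistribution-class] for
#'   hybrid speciation and introgression (fractions from the first-drawn
#'   parent / from the donor).
#' @param maxTries rejection cap for the minimum-reticulation constraint.
#' @return a [SpeciesNetwork-class].
#' @examples
#' set.seed(1)
#' net <- simulateNetwork(
#'   epochSchedule(rateSet(lambdaS = 1, lambdaC = 5)),
#'   haltingConfig(maxSpecies = 6))
#' net
#' @export
simulateNetwork <- function(schedule, halting,
                            hybridContrib = contributionDistribution(0.5),
                            introContrib = contributionDistribution(0.5),
                            maxTries = 1000L) {
  stopifnot(is(schedule, "EpochSchedule"), is(halting, "HaltingConfig"),
            is(hybridContrib, "ContributionDistribution"),
            is(introContrib, "ContributionDistribution"))
  if (is.finite(halting@reduceToReticulations) &&
      !.distanceIndependent(schedule, min(halting@maxDepth, Inf)))
    warning(paste("reticulation reduction with distance-dependent success",
                  "can retain reticulations whose success depended on",
                  "eliminated earlier events"))
  for (i in seq_len(maxTries)) {
    net <- .simulateNetworkOnce(schedule, halting, hybridContrib,
                                introContrib)
    if (nReticulations(net) >= halting@minReticulations) {
      net@metadata$tries <- i
      if (nReticulations(net) > halting@reduceToReticulations)
        net <- reduceReticulations(net, halting@reduceToReticulations)
      return(net)
    }
  }
  stop(sprintf(
    "no simulated network reached %d reticulation(s) in %d tries",
    halting@minReticulations, maxTries))
}

#' Eliminate surplus reticulations from a network
#'
#' Reticulations are removed uniformly at random until at most `reduceTo`
#' remain; an eliminated reticulation grants its full genome contribution to
#' one parent, drawn with the routing probabilities, so the child becomes an
#' ordinary descendant of that parent.  Intended for networks simulated with
#' distance-independent reticulation success, where eliminating an early
#' event cannot invalidate a later one.
#'
#' @param network a [SpeciesNetwork-class].
#' @param reduceTo maximum number of reticulations to keep.
#' @return the reduced [SpeciesNetwork-class].
#' @export
reduceReticulations <- function(network, reduceTo) {
  stopifnot(is(network, "SpeciesNetwork"), reduceTo >= 0)
  while (nrow(network@reticulations) > reduceTo) {
    i <- sample.int(nrow(network@reticulations), 1L)
    row <- network@reticulations[i, ]
    keepA <- runif(1L) < row$probA
    network@nodeParent[row$child] <-
      as.integer(if (keepA) row$parentA else row$parentB)
    network@reticulations <- network@reticulations[-i, , drop = FALSE]
  }
  validObject(network)
  network
}
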
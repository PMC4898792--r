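#' Genetic-distance matrix updates
#'
#' The simulator maintains a symmetric, zero-diagonal matrix of pairwise
#' genetic distances among the current species, updated after every event;
#' reticulation success probabilities are evaluated on it.
#'
#' * `advanceDistances()` accounts for the passage of time: every
#'   off-diagonal entry grows by twice the elapsed time (both lineages
#'   accumulate divergence independently).
#' * `speciationDistances()` adds a child species genetically identical to
#'   its parent: the child copies the parent's row and sits at distance 0
#'   from it.
#' * `hybridDistances()` adds a hybrid `h` of parents `a` (contribution
#'   `gamma`) and `b`: `d(h, x) = gamma * d(a, x) + (1 - gamma) * d(b, x)`
#'   for other species `x`; with the convention `d(a, a) = 0` this gives
#'   `d(h, a) = (1 - gamma) * d(a, b)` and `d(h, b) = gamma * d(a, b)`.
#' * `introgressionDistances()` overwrites a fraction `gamma` of the
#'   recipient genome with donor material, so the recipient row becomes the
#'   analogous weighted average:
#'   `d'(r, x) = (1 - gamma) * d(r, x) + gamma * d(donor, x)` and
#'   `d'(r, donor) = (1 - gamma) * d(r, donor)`.
#'
#' @param d symmetric distance matrix with species row/column names.
#' @param deltaT elapsed time (`>= 0`).
#' @param parent,a,b,donor,recipient species names present in `d`.
#' @param child,name name for the created species.
#' @param gamma contribution fraction in (0, 1].
#' @return the updated distance matrix.
#' @examples
#' d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' advanceDistances(d, 0.5)
#' @name distanceUpdates
NULL

#' @rdname distanceUpdates
#' @export
advanceDistances <- function(d, deltaT) {
  if (deltaT < 0) stop("'deltaT' must be nonnegative")
  d <- d + 2 * deltaT
  diag(d) <- 0
  d
}

#' @rdname distanceUpdates
#' @export
speciationDistances <- function(d, parent, child) {
  stopifnot(parent %in% rownames(d), !child %in% rownames(d))
  row <- d[parent, ]
  d <- rbind(cbind(d, row), c(row, 0))
  rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- child
  d[child, parent] <- d[parent, child] <- 0
  d
}

#' @rdname distanceUpdates
#' @export
hybridDistances <- function(d, a, b, gamma, name) {
  if (a == b) stop("hybrid speciation requires two distinct parents")
  stopifnot(all(c(a, b) %in% rownames(d)), gamma > 0, gamma <= 1)
  row <- gamma * d[a, ] + (1 - gamma) * d[b, ]
  d <- rbind(cbind(d, row), c(row, 0))
  rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- name
  d
}

#' @rdname distanceUpdates
#' @export
introgressionDistances <- function(d, donor, recipient, gamma) {
  if (donor == recipient) stop("introgression requires two distinct species")
  stopifnot(all(c(donor, recipient) %in% rownames(d)),
            gamma >= 0, gamma <= 1)
  row <- (1 - gamma) * d[recipient, ] + gamma * d[donor, ]
  row[recipient] <- 0
  d[recipient, ] <- row
  d[, recipient] <- row
  d
}
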
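#' Reticulation success probability as a function of genetic distance
#'
#' Probability that a proposed hybrid speciation or introgression between two
#' species at genetic distance `d` establishes.  Five functional forms are
#' supported, each with a single threshold/scale parameter `T`:
#' \describe{
#'   \item{linear}{`max(0, 1 - d/T)`}
#'   \item{step}{`1` if `d <= T`, else `0`}
#'   \item{quadratic}{`max(0, 1 - (d/T)^2)`}
#'   \item{snowball}{`exp(-d^2/T)` (Dobzhansky–Muller-style incompatibility
#'     accumulation in the square of distance)}
#'   \item{exponential}{`exp(-d/T)` (multiplicative fitness cost of linearly
#'     accumulating incompatibilities)}
#' }
#' All forms satisfy `F(0) = 1` and are non-increasing in `d`.  Success that
#' is independent of distance is obtained with the step function and a
#' threshold at least twice the maximum tree depth (e.g. `Inf`).
#'
#' @param kind one of `"linear"`, `"step"`, `"quadratic"`, `"snowball"`,
#'   `"exponential"`.
#' @param threshold positive threshold/scale `T` (distance units).
#' @param d nonnegative genetic distance(s).
#' @return success probabilities in `[0, 1]`, vectorised over `d`.
#' @examples
#' successProbability("linear", 1.3, c(0, 0.65, 2))
#' successProbability("exponential", 1, 1)   # exp(-1)
#' @export
successProbability <- function(kind, threshold, d) {
  kind <- match.arg(kind, .successKinds)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0)
    stop("'threshold' must be a single positive value")
  if (any(d < 0)) stop("distances must be nonnegative")
  switch(kind,
    linear      = pmax(0, 1 - d / threshold),
    step        = as.numeric(d <= threshold),
    quadratic   = pmax(0, 1 - (d / threshold)^2),
    snowball    = exp(-d^2 / threshold),
    exponential = exp(-d / threshold))
}

#' Total event rate and event-type probabilities
#'
#' With `N` species present, divergence speciation occurs at rate
#' `lambdaS * N` (a Yule process) and reticulations are proposed at rate
#' `lambdaH * N * (N - 1)` (hybrid speciation) and `lambdaI * N * (N - 1)`
#' (introgression), ordered-pair convention.  The waiting time to the next
#' event is exponential with the summed rate, and the event type is chosen
#' with probabilities proportional to the three components.
#'
#' @param n current number of species (`>= 1`).
#' @param rates a [RateSet-class].
#' @return a list with `lambda` (total rate) and `pS`, `pH`, `pI`.
#' @examples
#' totalEventRate(3, rateSet(lambdaS = 1, lambdaH = 0.1, lambdaI = 0.1))
#' @export
totalEventRate <- function(n, rates) {
  stopifnot(is(rates, "RateSet"), n >= 1)
  rS <- rates@lambdaS * n
  rH <- rates@lambdaH * n * (n - 1)
  rI <- rates@lambdaI * n * (n - 1)
  lambda <- rS + rH + rI
  if (lambda == 0)
    stop("total event rate is zero: no process is active, simulation stalled")
  list(lambda = lambda, pS = rS / lambda, pH = rH / lambda, pI = rI / lambda)
}

## epoch index covering forward time t (last epoch open-ended)
.epochAt <- function(schedule, t) {
  e <- findInterval(t, schedule@boundaries, rightmost.closed = FALSE)
  max(1L, min(e, length(schedule@epochs)))
}

#' Draw the waiting time and type of the next event
#'
#' Draws `Exp(lambda)` waiting times under the epoch covering the current
#' time; if the drawn time crosses an epoch boundary, time advances to the
#' boundary and the draw restarts under the new epoch's rates (exact for
#' memoryless processes).  The event type is chosen by a single uniform
#' draw against `pS`, `pH`, `pI`.
#'
#' @param time current simulation time.
#' @param n current number of species.
#' @param schedule an [EpochSchedule-class].
#' @return a list with `deltaT` (total elapsed time from `time`), `kind`
#'   (`"speciation"`, `"hybrid_attempt"` or `"introgression_attempt"`), and
#'   `epoch` (index of the epoch in which the event falls).
#' @export
drawEvent <- function(time, n, schedule) {
  stopifnot(is(schedule, "EpochSchedule"))
  nEpoch <- length(schedule@epochs)
  t0 <- time
  repeat {
    e <- .epochAt(schedule, time)
    er <- totalEventRate(n, schedule@epochs[[e]])
    dt <- rexp(1L, er$lambda)
    bound <- if (e < nEpoch) schedule@boundaries[e + 1L] else Inf
    if (time + dt <= bound) {
      time <- time + dt
      break
    }
    time <- bound
  }
  u <- runif(1L)
  kind <- if (u < er$pS) "speciation"
          else if (u < er$pS + er$pH) "hybrid_attempt"
          else "introgression_attempt"
  list(deltaT = time - t0, kind = kind, epoch = e)
}
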
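## Inference on simulator output: (a) multinomial classification of the
## generating scenario from the base statistics with stepwise-AIC selection
## of two-way interactions; (b) semi-automatic ABC in which pilot-regression
## predictions of the parameters serve as summary statistics and reference
## simulations are accepted within an ellipse scaled by the residual SDs.

.classifierStats <- c("TE", "SI", "DC", "UC", "US", "QE", "RS", "SI1",
                      "TC", "TCA")
.allStats <- c("TE", "QE", "SI", "SI1", "SI2", "RS", "DC", "UC", "US",
               "TC", "TCA")

.profileFeatures <- function(network, nLoci, coalescenceRate,
                             siThresholds = c(1, 2)) {
  sched <- .lambdaCSchedule(coalescenceRate)
  rp <- .networkRepr(network)
  sim <- cpp_simulate_profile(rp$nodeTime, rp$nodeParent, rp$retChild,
                              rp$retProbA, rp$retParentA, rp$retParentB,
                              rp$tips, sched$breaks, sched$rates,
                              as.integer(nLoci))
  sm <- cpp_profile_summaries(sim$parent, length(rp$tips), rp$labels, TRUE)
  .statsFromSummaries(sm, nLoci, length(rp$tips), siThresholds)
}

.scenario <- function(label, schedule, halting, hybridContrib,
                      introContrib, nLoci) {
  list(label = label, schedule = schedule, halting = halting,
       hybridContrib = hybridContrib, introContrib = introContrib,
       nLoci = nLoci)
}

#' Scenario sets for the classification studies
#'
#' `hybridCountScenarios()` crosses exact hybrid-speciation counts with
#' coalescence rates under distance-independent reticulation success: the
#' count is enforced by the minimum/reduce-to reticulation constraints, with
#' hybrids proposed at `hybridProposalRate` per ordered pair (the proposal
#' rate is arbitrary under always-successful reticulation; only the count is
#' conditioned on).  `rateGradientScenarios()` pairs joint hybrid/
#' introgression proposal rates with coalescence rates under a linear
#' distance-dependent success function, with asymmetric parental
#' contributions.  All rates are relative to a divergence speciation rate
#' of 1, which defines the time unit; runs halt on the species count.
#'
#' @param nTaxa number of species at which a run halts.
#' @param nLoci gene trees per profile.
#' @param hybridCounts exact hybrid-speciation counts to condition on.
#' @param coalescenceRates coalescence rates (crossed with `hybridCounts`
#'   in `hybridCountScenarios`; paired positionally with
#'   `reticulationRates` in `rateGradientScenarios`).
#' @param hybridProposalRate proposal rate per ordered pair used when a
#'   positive hybrid count is conditioned on.
#' @param reticulationRates joint hybrid and introgression proposal rate
#'   per ordered pair, one per scenario.
#' @param successKind,threshold reticulation success function for the
#'   gradient scenarios.
#' @param hybridGamma,introGamma parental contribution of the first-drawn
#'   hybrid parent, and introgressed genome fraction.
#' @return a list of scenario specifications for [simulateScenarioSet()].
#' @examples
#' length(hybridCountScenarios())  # 4 scenarios
#' @name scenarioSets
NULL

#' @rdname scenarioSets
#' @export
hybridCountScenarios <- function(nTaxa = 10, nLoci = 50,
                                 hybridCounts = c(0, 2),
                                 coalescenceRates = c(5, 15),
                                 hybridProposalRate = 0.2,
                                 hybridGamma = 0.5) {
  out <- list()
  for (cr in coalescenceRates) {
    for (h in hybridCounts) {
      rs <- rateSet(lambdaS = 1,
                    lambdaH = if (h > 0) hybridProposalRate else 0,
                    lambdaI = 0, lambdaC = cr, threshold = Inf)
      out[[length(out) + 1L]] <- .scenario(
        label = sprintf("H%d_C%g", h, cr),
        schedule = epochSchedule(rs, successKind = "step"),
        halting = haltingConfig(maxSpecies = nTaxa, minReticulations = h,
                                reduceToReticulations = h),
        hybridContrib = contributionDistribution(hybridGamma),
        introContrib = contributionDistribution(hybridGamma),
        nLoci = nLoci)
    }
  }
  out
}

#' @rdname scenarioSets
#' @export
rateGradientScenarios <- function(nTaxa = 20, nLoci = 150,
                                  reticulationRates = c(0, 0.1, 0.26, 0.4),
                                  coalescenceRates = c(6, 10, 30, 1000),
                                  successKind = "linear", threshold = 1.3,
                                  hybridGamma = 0.75, introGamma = 0.1) {
  stopifnot(length(reticulationRates) == length(coalescenceRates))
  lapply(seq_along(reticulationRates), function(i) {
    rs <- rateSet(lambdaS = 1, lambdaH = reticulationRates[i],
                  lambdaI = reticulationRates[i],
                  lambdaC = coalescenceRates[i], threshold = threshold)
    .scenario(
      label = sprintf("C%g", coalescenceRates[i]),
      schedule = epochSchedule(rs, successKind = successKind),
      halting = haltingConfig(maxSpecies = nTaxa),
      hybridContrib = contributionDistribution(hybridGamma),
      introContrib = contributionDistribution(introGamma),
      nLoci = nLoci)
  })
}

#' Simulate labelled feature tables
#'
#' `simulateScenarioSet()` simulates `replicates` networks per scenario,
#' generates each scenario's number of gene trees per network, and returns
#' one row of base statistics per profile, labelled by scenario.
#' `simulatePilotSet()` instead draws the parameters of every simulation
#' from a prior — coalescence rate log-uniform on `coalescenceRange`,
#' hybrid-speciation count uniform on `hybridCounts` (enforced exactly, no
#' introgression) — and records them alongside the statistics, as needed
#' for regression-fitted ABC summary statistics.
#'
#' @param scenarios a list from [hybridCountScenarios()] or
#'   [rateGradientScenarios()].
#' @param replicates profiles per scenario.
#' @param n number of pilot simulations.
#' @param nTaxa,nLoci,hybridProposalRate,hybridGamma as in the scenario
#'   constructors.
#' @param coalescenceRange range of the log-uniform coalescence-rate prior.
#' @param hybridCounts support of the uniform hybrid-count prior.
#' @param siThresholds thresholds for the SI-k columns.
#' @return a data frame of base statistics with a `label` column
#'   (`simulateScenarioSet`) or `lambdaC`, `logLambdaC`, `nHybrid` columns
#'   (`simulatePilotSet`).
#' @examples
#' set.seed(1)
#' head(simulateScenarioSet(hybridCountScenarios(nLoci = 5), replicates = 2))
#' @export
simulateScenarioSet <- function(scenarios, replicates = 250,
                                siThresholds = c(1, 2)) {
  statNames <- c("TE", "QE", "SI", paste0("SI", siThresholds),
                 "RS", "DC", "UC", "US", "TC", "TCA")
  total <- length(scenarios) * replicates
  feat <- matrix(NA_real_, total, length(statNames),
                 dimnames = list(NULL, statNames))
  lab <- character(total)
  row <- 0L
  for (s in scenarios) {
    for (r in seq_len(replicates)) {
      net <- simulateNetwork(s$schedule, s$halting, s$hybridContrib,
                             s$introContrib)
      row <- row + 1L
      feat[row, ] <- .profileFeatures(net, s$nLoci, s$schedule,
                                      siThresholds)
      lab[row] <- s$label
    }
  }
  cbind(data.frame(label = lab, stringsAsFactors = FALSE),
        as.data.frame(feat))
}

#' @rdname simulateScenarioSet
#' @export
simulatePilotSet <- function(n, nTaxa = 8, nLoci = 106,
                             coalescenceRange = c(2, 200),
                             hybridCounts = 0:3,
                             hybridProposalRate = 0.2, hybridGamma = 0.5,
                             siThresholds = c(1, 2)) {
  statNames <- c("TE", "QE", "SI", paste0("SI", siThresholds),
                 "RS", "DC", "UC", "US", "TC", "TCA")
  feat <- matrix(NA_real_, n, length(statNames),
                 dimnames = list(NULL, statNames))
  lambdaC <- exp(runif(n, log(coalescenceRange[1L]),
                       log(coalescenceRange[2L])))
  nHybrid <- sample(hybridCounts, n, replace = TRUE)
  contrib <- contributionDistribution(hybridGamma)
  for (i in seq_len(n)) {
    h <- nHybrid[i]
    rs <- rateSet(lambdaS = 1,
                  lambdaH = if (h > 0) hybridProposalRate else 0,
                  lambdaI = 0, lambdaC = lambdaC[i], threshold = Inf)
    sched <- epochSchedule(rs, successKind = "step")
    halt <- haltingConfig(maxSpecies = nTaxa, minReticulations = h,
                          reduceToReticulations = h)
    net <- simulateNetwork(sched, halt, contrib, contrib)
    feat[i, ] <- .profileFeatures(net, nLoci, sched, siThresholds)
  }
  cbind(data.frame(lambdaC = lambdaC, logLambdaC = log(lambdaC),
                   nHybrid = nHybrid),
        as.data.frame(feat))
}

#' Multinomial scenario classifier with stepwise-AIC interaction selection
#'
#' Fits a multinomial logistic model of the scenario label on z-standardised
#' base statistics, starting from all main effects plus all two-way
#' interactions, then prunes interaction terms by stepwise AIC (main
#' effects are protected).  On non-convergence or separation the model is
#' refit with a small ridge penalty.
#'
#' @param train feature table with a `label` column (see
#'   [simulateScenarioSet()]).
#' @param statistics feature columns to use (default: the ten-statistic
#'   set TE, SI, DC, UC, US, QE, RS, SI1, TC, TCA).
#' @param labelColumn name of the class column.
#' @param stepwise prune two-way interactions by AIC.
#' @param direction stepwise direction over the interaction terms.
#' @param maxit,decay optimiser iterations and ridge penalty passed to
#'   [nnet::multinom()].
#' @return a `scenarioClassifier` object (model, standardisation moments,
#'   retained terms).
#' @export
fitScenarioClassifier <- function(train, statistics = .classifierStats,
                                  labelColumn = "label", stepwise = TRUE,
                                  direction = c("backward", "both"),
                                  maxit = 400, decay = 0) {
  direction <- match.arg(direction)
  stopifnot(all(c(statistics, labelColumn) %in% names(train)))
  X <- train[statistics]
  center <- vapply(X, mean, numeric(1))
  scl <- vapply(X, sd, numeric(1))
  scl[!is.finite(scl) | scl == 0] <- 1
  dat <- data.frame(label = factor(train[[labelColumn]]),
                    scale(X, center, scl))
  if (nlevels(dat$label) < 2L)
    stop("classification needs at least two scenario labels")
  fullForm <- as.formula(paste("label ~ (",
                               paste(statistics, collapse = " + "), ")^2"))
  lowerForm <- as.formula(paste("label ~",
                                paste(statistics, collapse = " + ")))
  ## the call carries the data object itself so stepwise refits evaluate
  ## anywhere
  mkFit <- function(dec) {
    cl <- as.call(list(quote(nnet::multinom), formula = fullForm,
                       data = dat, maxit = maxit, trace = FALSE,
                       MaxNWts = 10000, decay = dec))
    eval(cl)
  }
  fit <- mkFit(decay)
  if (!is.null(fit$convergence) && fit$convergence != 0 && decay == 0) {
    message("multinomial fit did not converge; refitting with ridge penalty 1e-4")
    fit <- mkFit(1e-4)
  }
  if (stepwise)
    fit <- MASS::stepAIC(fit, scope = list(lower = lowerForm,
                                           upper = fullForm),
                         direction = direction, trace = 0)
  terms <- attr(stats::terms(fit), "term.labels")
  structure(list(model = fit, statistics = statistics, center = center,
                 scale = scl, levels = levels(dat$label),
                 interactions = grep(":", terms, value = TRUE)),
            class = "scenarioClassifier")
}

#' @export
print.scenarioClassifier <- function(x, ...) {
  cat(sprintf(paste0("scenario classifier: %d classes, %d main effects, ",
                     "%d retained two-way interactions\n"),
              length(x$levels), length(x$statistics),
              length(x$interactions)))
  invisible(x)
}

#' Predict scenario labels / cross-validated confusion matrix
#'
#' `predictScenario()` standardises the new features with the training
#' moments and returns the predicted class; `confusionMatrix()` tabulates
#' truth (rows) against prediction (columns) on an independently simulated
#' test table, so the trace is the number of correctly classified profiles.
#'
#' @param classifier a fitted `scenarioClassifier`.
#' @param newdata,test feature tables.
#' @param labelColumn name of the class column in `test`.
#' @return a factor of predictions; or a K x K contingency table.
#' @export
predictScenario <- function(classifier, newdata) {
  stopifnot(inherits(classifier, "scenarioClassifier"))
  z <- scale(newdata[classifier$statistics], classifier$center,
             classifier$scale)
  predict(classifier$model, newdata = as.data.frame(z), type = "class")
}

#' @rdname predictScenario
#' @export
confusionMatrix <- function(classifier, test, labelColumn = "label") {
  pred <- predictScenario(classifier, test)
  truth <- factor(test[[labelColumn]], levels = classifier$levels)
  table(truth = truth, predicted = factor(pred,
                                          levels = classifier$levels))
}

#' Regression-fitted ABC summary statistic
#'
#' Treats the base statistics of each pilot simulation as explanatory
#' variables and a model parameter (for instance the log coalescence rate
#' or the hybrid-speciation count) as the response, fitting least squares
#' with all first-order terms and all pairwise interactions.  The fitted
#' prediction is the summary statistic used for ABC rejection, and the
#' residual standard deviation sets the scale of the acceptance ellipse.
#' Collinear interaction columns are dropped automatically by the
#' rank-revealing fit.
#'
#' @param pilot pilot feature table (see [simulatePilotSet()]).
#' @param target name of the response column.
#' @param statistics explanatory base-statistic columns (default: all 11).
#' @return a `summaryStatisticFit` (model, residuals, residual SD).
#' @export
fitSummaryStatistic <- function(pilot, target, statistics = .allStats) {
  stopifnot(all(c(statistics, target) %in% names(pilot)))
  form <- as.formula(paste(target, "~ (",
                           paste(statistics, collapse = " + "), ")^2"))
  cl <- as.call(list(quote(stats::lm), formula = form,
                     data = pilot[c(target, statistics)]))
  fit <- eval(cl)
  res <- residuals(fit)
  structure(list(model = fit, target = target, statistics = statistics,
                 residuals = res, residualSD = sd(res)),
            class = "summaryStatisticFit")
}

#' @export
print.summaryStatisticFit <- function(x, ...) {
  cat(sprintf("summary-statistic fit for '%s': %d coefficients, residual SD %.4g\n",
              x$target, sum(!is.na(coef(x$model))), x$residualSD))
  invisible(x)
}

#' @export
predict.summaryStatisticFit <- function(object, newdata, ...) {
  suppressWarnings(predict(object$model, newdata = newdata))
}

#' ABC rejection within a residual-scaled ellipse
#'
#' Evaluates the two regression-derived summary statistics on every
#' reference simulation and on the observed profile, and accepts the
#' simulations whose summary pair lies within `radius` (in units of the
#' fits' residual standard deviations) of the observed pair.  The accepted
#' rows, with their true parameters, form the posterior sample.
#'
#' @param reference feature table of reference simulations (disjoint from
#'   the pilot set used for the fits).
#' @param fits list of two `summaryStatisticFit` objects.
#' @param observed base statistics of the observed profile (named vector or
#'   one-row data frame).
#' @param radius acceptance radius in residual-SD units.
#' @param parameters reference columns to summarise posteriors for.
#' @return an `abcResult`: accepted rows, distances, acceptance count, and
#'   posterior draws per parameter.
#' @export
abcRejection <- function(reference, fits, observed, radius = 0.2,
                         parameters = c("logLambdaC", "nHybrid")) {
  stopifnot(length(fits) == 2L,
            all(vapply(fits, inherits, logical(1), "summaryStatisticFit")))
  if (is.numeric(observed)) observed <- as.data.frame(as.list(observed))
  s <- vapply(fits, function(f) predict(f, reference) / f$residualSD,
              numeric(nrow(reference)))
  o <- vapply(fits, function(f) predict(f, observed) / f$residualSD,
              numeric(1))
  dist <- sqrt((s[, 1L] - o[1L])^2 + (s[, 2L] - o[2L])^2)
  keep <- dist <= radius
  if (!any(keep))
    warning("no reference simulation accepted; increase the radius")
  accepted <- reference[keep, , drop = FALSE]
  posterior <- lapply(parameters, function(p)
    if (p %in% names(accepted)) accepted[[p]] else NULL)
  names(posterior) <- parameters
  structure(list(accepted = accepted, distance = dist, radius = radius,
                 nAccepted = sum(keep), posterior = posterior),
            class = "abcResult")
}

#' @export
print.abcResult <- function(x, ...) {
  cat(sprintf("ABC rejection: %d of %d simulations accepted (radius %g)\n",
              x$nAccepted, length(x$distance), x$radius))
  for (p in names(x$posterior)) {
    v <- x$posterior[[p]]
    if (is.null(v) || !length(v)) next
    if (all(v == round(v))) {
      tab <- table(v)
      cat(sprintf("  %s: %s\n", p,
                  paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                        collapse = " ")))
    } else {
      q <- quantile(v, c(0.025, 0.5, 0.975))
      cat(sprintf("  %s: median %.3g, 95%% interval [%.3g, %.3g]\n",
                  p, q[2L], q[1L], q[3L]))
    }
  }
  invisible(x)
}
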
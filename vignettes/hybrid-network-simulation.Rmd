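---
title: "Simulating hybrid species networks and summarising gene-tree discordance"
author: "hybcoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hybrid species networks and summarising gene-tree discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybcoal)
```

## The model

`hybcoal` simulates species histories forward in time under three memoryless
processes.  With $N$ species present, divergence speciation occurs at rate
$\lambda_S N$ (a Yule process), and hybrid speciations and introgressions are
*proposed* at rates $\lambda_H N(N-1)$ and $\lambda_I N(N-1)$ (ordered-pair
convention).  The waiting time to the next event is exponential with rate
$\lambda = \lambda_S N + \lambda_H N(N-1) + \lambda_I N(N-1)$, and the event
type is chosen with probabilities proportional to the three components.

A proposed reticulation between species $a$ and $b$ establishes with
probability $F(d(a,b))$, a non-increasing function of their genetic distance
with $F(0)=1$.  Five forms are available (`successProbability()`), each with
one threshold/scale parameter $T$: linear and quadratic declines that hit
zero at $T$, a step function (success iff $d \le T$), exponential decay
$e^{-d/T}$ (multiplicative fitness cost of linearly accumulating
incompatibilities), and the "snowball" $e^{-d^2/T}$ (epistatic,
Dobzhansky–Muller-style accumulation in the square of distance).
Distance-independent success is the step function with $T$ at least twice
the maximum tree depth (`threshold = Inf` works for any depth).

A symmetric genetic-distance matrix over the current species is maintained
throughout (`advanceDistances()` and friends): the passage of $\Delta t$
adds $2\Delta t$ to every off-diagonal entry; a speciation child starts
identical to its parent; a hybrid with contribution $\gamma$ from parent $a$
takes the $\gamma$-weighted average of its parents' rows; an introgression
replacing a fraction $\gamma$ of the recipient's genome reweights the
recipient's row toward the donor's.  The introgression update is our
design choice: only the hybrid-speciation update is forced by the model
description, but introgression overwrites genome exactly as hybrid
speciation mixes it, and subsequent success probabilities should see the
overwritten fractions.  Contribution fractions for both event kinds are
drawn from user-specified discrete distributions
(`contributionDistribution()`), which may differ between hybrid speciation
and introgression.

Rates and the threshold may change across epochs
(`epochSchedule()`); the functional form of $F$ is shared by all epochs.
Waiting times are redrawn at epoch boundaries under the new rates, which is
exact for memoryless processes.  A run starts with a speciation at time 0
(two species at distance zero) and halts at the first of: a maximum
root-to-tip depth (time is advanced so every tip sits exactly at the
maximum), a maximum species count, or a maximum number of successful
reticulations (time is advanced to the violating event, which is
discarded).  For reticulation and species caps we evaluate the success of a
proposed reticulation before the halting check, so only an event that would
actually fire can end the run; under distance-independent success — the
setting in which count conditioning is used — this choice is
indistinguishable from checking first.

Networks can be conditioned on an exact reticulation count by combining a
minimum (failing networks are discarded and resimulated) with a reduce-to
cap: surplus reticulations are eliminated uniformly at random, granting one
parent the full contribution.  The surviving parent is drawn with the
routing probabilities $(\gamma, 1-\gamma)$, the measure-preserving choice.
Reduction is intended for distance-independent success only, since
eliminating an early reticulation could otherwise retain a later one whose
establishment depended on it; `simulateNetwork()` warns in that case.

## Lineage trees and the restricted coalescent

For each locus the network is collapsed to a *lineage tree*
(`resolveLineageTree()`): every hybrid node is routed to one parent with
its contribution as probability, and every introgression point routes the
recipient lineage through the donor with the introgressed fraction as
probability.  The locus then evolves on that single tree — uncoalesced
lineages of one gene cannot take different paths through a reticulation,
which is the "restricted" part of the coalescent.  With $R$ reticulations
the $2^R$ resolutions induce a weighted topology distribution
(`lineageTreeDistribution()`), each topology weighted by the genome
fraction that evolved on it; beyond a configurable $R$ the distribution is
sampled instead (`sampleLineageTopologies()`).

Within the lineage tree, one gene lineage starts at each tip and $k$
lineages sharing a branch coalesce pairwise at rate $\lambda_C$, i.e.
$\lambda_C k(k-1)/2$ in total — the standard multi-lineage generalisation
fixed by the stated two-lineage survival probability $e^{-t\lambda_C}$.
$\lambda_C$ may vary by epoch; branch survival is computed piecewise, and
times before the root reuse the first epoch's rate.  The branch above the
root is treated as unbounded so every locus fully coalesces into a single
gene tree (`simulateGeneTrees()`), whose branch lengths are in simulation
time units (the divergence speciation rate defines the unit).

A five-taxon worked example ships as `demoNetwork()`: backbone
`(((A,B),D),E)`, an introgression from E into D (fraction 0.1), and C a
hybrid of the B and D lineages (contributions 0.6/0.4).  Node times are our
choice (the published figure fixes only the event order up to the
constraint that the introgression predates the hybrid origin; any times
consistent with that order give the same distribution):

```{r}
lineageTreeDistribution(demoNetwork())
```

## Discordance statistics

For a profile $P=(T_1,\dots,T_n)$ of rooted binary gene trees on $m$ taxa,
`baseStatistics()` returns: tree entropy TE $=\sum w\log w$ over unique
rooted topologies; quartet entropy QE summed over the three resolutions of
every 4-subset; split incompatibility SI $=\sum_{s_i,s_j}
w(s_i)w(s_j)\,I(s_i,s_j)$ over ordered pairs of observed unique splits and
its thresholded family SI-$k$ (weights $w-k$, splits with $w>k$); the rare
(RS) and unique (US) split counts and unique cherries (UC); the distance to
the majority-rule consensus DC $=\sum_s \min(w, n-w)$; and tree certainty
TC / TCA, internode certainties summed over the greedy consensus tree.

Conventions we pin down (and test):

* Topology identity for TE is *rooted*; splits, quartets and cherries use
  the unrooted view.  Canonical topology keys sort children bytewise.
* SI has a second printed form, the summed pairwise Robinson–Foulds
  distance.  The two forms disagree on some profiles (two splits can be
  incompatible yet never co-occur in a tree), and only the split-pair form
  generalises to SI-$k$, so that form is canonical here and the RF sum is
  exposed separately as `pairwiseRFSum()`.  The double sum is read over
  ordered pairs (each unordered conflict counted twice).
* Logarithms: natural for TE/QE, base 2 for internode certainty
  $IC = 1 + p\log_2 p + (1-p)\log_2(1-p)$ with $p = x_1/(x_1+x_2)$ and
  $x_2$ the most numerous conflicting split; ICA uses $\log_h$ over the
  evaluated split plus all $h-1$ observed conflicting splits (no
  conflict-frequency threshold), so a lone conflicting split makes ICA
  collapse to IC.
* Robinson–Foulds distances are unhalved symmetric-difference counts,
  which makes the printed DC/consensus equivalence exact.
* The greedy consensus ranks splits by weight, breaking ties by the
  canonical split encoding (the bitmask over sorted taxa of the side not
  containing the first taxon) and then by first appearance.

All statistics are cross-checked against a brute-force oracle on random
small profiles in the test suite.

## The inference procedures

**Scenario classification.**  `simulateScenarioSet()` generates labelled
profiles under scenario lists built by `hybridCountScenarios()` (exact
hybrid counts crossed with coalescence rates, distance-independent
success, 10 taxa and 50 loci by default) and `rateGradientScenarios()`
(joint hybrid/introgression proposal rates 0, 0.1, 0.26, 0.4 paired with
coalescence rates 6, 10, 30, 1000, linear success with $T = 1.3$, 75:25
hybrid contributions, 90:10 introgression, 20 taxa).
`fitScenarioClassifier()` standardises ten statistics (TE, SI, DC, UC, US,
QE, RS, SI-1, TC, TCA), fits a multinomial logistic model with all 45
two-way interactions (`nnet::multinom`), and prunes interactions backward
by stepwise AIC (`MASS::stepAIC`) with main effects protected; backward
pruning is the default because bidirectional stepping only changes the
retained-term count, not measurably the cross-validated accuracy, and is
twice as slow.  Non-convergence triggers a refit with a small ridge
penalty (`decay = 1e-4`), which is also how separation on small training
sets is handled.  Cross-validation uses an independently seeded test batch
of the same design (`confusionMatrix()`).

**Semi-automatic ABC.**  `simulatePilotSet()` draws the coalescence rate
log-uniformly on [2, 200] and the hybrid-speciation count uniformly on
{0,…,3} (enforced exactly, 50:50 contributions, no introgression, 8 taxa,
106 loci).  The prior shapes are our choice where only ranges are stated:
the regression target is the log rate, so a log-uniform rate prior makes
the pilot design uniform in the response, and the count is a small
discrete set.  `fitSummaryStatistic()` regresses each parameter on all 11
base statistics with pairwise interactions (67 coefficients); the fitted
predictions are the summary statistics and their residual SDs the distance
scale.  We keep the full fit rather than AIC-pruning it — at the pilot
sizes used the discarded coefficients change the residual SD only in the
third decimal.  `abcRejection()` accepts reference simulations whose
summary pair falls within a radius (default 0.2 residual SDs) of the
observed pair.

A small end-to-end run:

```{r, eval = FALSE}
set.seed(1)
pilot <- simulatePilotSet(2000)
fitC <- fitSummaryStatistic(pilot, "logLambdaC")
fitH <- fitSummaryStatistic(pilot, "nHybrid")
reference <- simulatePilotSet(20000)
observed <- simulatePilotSet(1)   # pseudo-observed truth
statCols <- c("TE", "QE", "SI", "SI1", "SI2", "RS", "DC", "UC", "US",
              "TC", "TCA")
abcRejection(reference, list(fitC, fitH), observed[statCols], radius = 0.2)
```

## Numerical choices and degenerate inputs

* All randomness flows through R's RNG, including the compiled coalescent
  kernel, so a single `set.seed()` makes runs bit-reproducible on one
  platform.
* Reticulation children are created after both their parents; ordering
  ties at shared event times are broken by creation index, which the
  kernel relies on when several nodes share an event time.
* A zero total event rate (all processes off) and an all-infinite halting
  configuration are refused rather than looped on; $\lambda_C \le 0$ is
  refused because the restricted coalescent would never terminate.
* $\gamma = 0$ contributions are excluded by construction (the event would
  be a no-op); $\gamma = 1$ is allowed and makes a hybrid a genetic copy
  of one parent.
* Profiles must be rooted binary trees on one shared taxon set (at most 30
  taxa, the split-bitmask width); polytomies are accepted only in
  consensus outputs.

## What the generator emulates, and what it does not

The synthetic studies reproduce the published simulation designs: profile
sizes, taxon counts, rates, success functions and contribution splits are
the package defaults documented above, and the acceptance script rebuilds
them at full scale (2 × 1,000 profiles for each classification study;
10,000 pilot simulations for the ABC fits).  The test suite uses the same
designs, with the 150-gene-tree study run at a tenth of the replication
and the ABC recovery check at 4,000 pilot and 30,000 reference
simulations to keep a routine run short.  One parameter is
not identified by the published design: when an exact hybrid count is
enforced, the proposal rate $\lambda_H$ only shapes event times; we fix
$\lambda_H = 0.2\lambda_S$.  Real data differ from all of this in ways the
model deliberately ignores: no extinction, polyploidy, spatial structure,
selection, or population bottlenecks at reticulation; equal population
sizes across contemporaneous lineages; gene-tree estimation error is
absent (simulated gene trees are known exactly), so statistics computed on
estimated gene trees will be noisier than the simulations suggest.
Introgressed genes are no more or less likely to introgress again — genome
segments are not tracked.

## Known limitations

* Exhaustive enumeration is capped (default $2^{12}$ resolutions); beyond
  it, sample.
* The multinomial fit can fail to converge at its iteration cap on large
  interaction models; the ridge fallback changes coefficients slightly but
  not, in our checks, cross-validated accuracy.
* Statistics are limited to 30 taxa by the bitmask encoding; the
  simulator itself has no such cap.
* The hybrid-count summary statistic carries a residual SD of roughly half
  the spacing between adjacent counts, so the ABC posterior over the count
  is diffuse: point identification of the hybrid-speciation number from a
  single profile is unreliable, while interval statements about the log
  coalescence rate are reasonably calibrated.  This mirrors the precision
  of the underlying regression, not a sampling shortfall.
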
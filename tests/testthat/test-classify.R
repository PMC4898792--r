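# synthetic feature tables: a 10-column statistics layout where only some
# columns carry signal
fakeFeatures <- function(n, labels, signal = 3) {
  k <- length(labels)
  lab <- rep(labels, each = n)
  X <- matrix(rnorm(n * k * 10), n * k, 10)
  colnames(X) <- c("TE", "SI", "DC", "UC", "US", "QE", "RS", "SI1",
                   "TC", "TCA")
  X[, "TE"] <- X[, "TE"] + signal * (match(lab, labels) - 1)
  cbind(data.frame(label = lab), as.data.frame(X))
}

test_that("separated classes are classified perfectly on training data", {
  set.seed(51)
  train <- fakeFeatures(40, c("x", "y"), signal = 12)
  cl <- fitScenarioClassifier(train, stepwise = FALSE)
  pred <- predictScenario(cl, train)
  expect_equal(mean(pred == train$label), 1)
  cm <- confusionMatrix(cl, train)
  expect_equal(sum(diag(cm)), nrow(train))
})

test_that("confusion rows sum to per-class test counts", {
  set.seed(52)
  train <- fakeFeatures(40, c("x", "y", "z"), signal = 2)
  test <- fakeFeatures(25, c("x", "y", "z"), signal = 2)
  cl <- fitScenarioClassifier(train, stepwise = FALSE)
  cm <- confusionMatrix(cl, test)
  expect_equal(unname(rowSums(cm)), rep(25, 3))
})

test_that("classification is invariant to feature rescaling", {
  set.seed(53)
  train <- fakeFeatures(30, c("x", "y"), signal = 2)
  test <- fakeFeatures(30, c("x", "y"), signal = 2)
  cl1 <- fitScenarioClassifier(train, stepwise = FALSE)
  train2 <- train; test2 <- test
  train2$DC <- train2$DC * 1000; test2$DC <- test2$DC * 1000
  cl2 <- fitScenarioClassifier(train2, stepwise = FALSE)
  expect_equal(as.vector(confusionMatrix(cl1, test)),
               as.vector(confusionMatrix(cl2, test2)))
})

test_that("stepwise selection never increases the AIC", {
  set.seed(54)
  train <- fakeFeatures(60, c("x", "y"), signal = 1)
  full <- fitScenarioClassifier(train, statistics = c("TE", "QE", "SI"),
                                stepwise = FALSE)
  stepped <- fitScenarioClassifier(train, statistics = c("TE", "QE", "SI"),
                                   stepwise = TRUE)
  expect_lte(AIC(stepped$model), AIC(full$model))
  # main effects are protected even when uninformative
  kept <- attr(stats::terms(stepped$model), "term.labels")
  expect_true(all(c("TE", "QE", "SI") %in% kept))
  expect_lte(length(stepped$interactions), 3)
})

test_that("null features give chance-level accuracy", {
  set.seed(55)
  train <- fakeFeatures(50, c("x", "y", "z", "w"), signal = 0)
  test <- fakeFeatures(50, c("x", "y", "z", "w"), signal = 0)
  cl <- fitScenarioClassifier(train, stepwise = FALSE)
  acc <- mean(predictScenario(cl, test) == test$label)
  expect_lt(abs(acc - 0.25), 0.15)
})

test_that("scenario constructors encode the study designs", {
  sc <- hybridCountScenarios()
  expect_length(sc, 4)
  expect_setequal(vapply(sc, `[[`, character(1), "label"),
                  c("H0_C5", "H2_C5", "H0_C15", "H2_C15"))
  h2 <- sc[[which(vapply(sc, `[[`, character(1), "label") == "H2_C5")]]
  expect_equal(h2$halting@minReticulations, 2)
  expect_equal(h2$halting@reduceToReticulations, 2)
  expect_equal(h2$schedule@epochs[[1]]@lambdaC, 5)
  expect_equal(h2$nLoci, 50)
  rg <- rateGradientScenarios()
  expect_length(rg, 4)
  expect_equal(rg[[4]]$schedule@epochs[[1]]@lambdaH, 0.4)
  expect_equal(rg[[4]]$schedule@epochs[[1]]@lambdaI, 0.4)
  expect_equal(rg[[4]]$schedule@epochs[[1]]@lambdaC, 1000)
  expect_equal(rg[[1]]$schedule@successKind, "linear")
  expect_equal(rg[[1]]$schedule@epochs[[1]]@threshold, 1.3)
  expect_equal(rg[[1]]$hybridContrib@gamma, 0.75)
  expect_equal(rg[[1]]$introContrib@gamma, 0.1)
})

test_that("scenario simulation returns one labelled row per replicate", {
  set.seed(56)
  tab <- simulateScenarioSet(hybridCountScenarios(nTaxa = 6, nLoci = 5),
                             replicates = 2)
  expect_equal(nrow(tab), 8)
  expect_equal(unname(table(tab$label)), rep(2L, 4), ignore_attr = TRUE)
  expect_false(anyNA(tab))
  expect_true(all(.allStatsNames <- c("TE", "QE", "SI", "SI1", "SI2", "RS",
                                      "DC", "UC", "US", "TC", "TCA")
                  %in% names(tab)))
})
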
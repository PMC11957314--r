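test_that("train/test splits have the documented sizes and are seeded", {
  spec <- rfModelSpec(seed = 42)
  sp <- splitTrainTest(96, spec)
  expect_length(sp$train, 76L)                  # ceiling(96 * 0.2) = 20
  expect_length(sp$test, 20L)
  expect_identical(sort(c(sp$train, sp$test)), 1:96)
  expect_length(intersect(sp$train, sp$test), 0L)

  sp5 <- splitTrainTest(5, spec)
  expect_length(sp5$test, 1L)
  expect_length(sp5$train, 4L)
  expect_error(splitTrainTest(4, spec), "too few")

  expect_identical(splitTrainTest(96, spec), splitTrainTest(96, spec))
  expect_false(identical(splitTrainTest(96, rfModelSpec(seed = 1))$test,
                         sp$test))
})

test_that("forest fitting is deterministic and handles degenerate input", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(7, 20)
  fit <- suppressWarnings(fitRfModel(x, y, rfModelSpec(n_trees = 30)))
  expect_equal(unname(predict(fit, x)), rep(7, 20))   # constant target

  y2 <- rnorm(20)
  f1 <- fitRfModel(x, y2, rfModelSpec(n_trees = 30, seed = 9))
  f2 <- fitRfModel(x, y2, rfModelSpec(n_trees = 30, seed = 9))
  expect_identical(predict(f1, x), predict(f2, x))

  expect_error(fitRfModel(x[1, , drop = FALSE], 1), "at least 2")
})

test_that("a noiseless linear signal is recovered with high accuracy", {
  set.seed(10)
  x <- matrix(rnorm(200 * 2), 200, 2, dimnames = list(NULL, c("a", "b")))
  y <- 3 * x[, 1]          # b is pure noise
  spec <- rfModelSpec(seed = 4)
  sp <- splitTrainTest(200, spec)
  fit <- fitRfModel(x[sp$train, ], y[sp$train], spec)
  ev <- evaluateModel(fit, x[sp$test, ], y[sp$test])
  expect_gte(ev$r2, 0.95)
})

test_that("evaluation metrics match their sum-of-squares definitions", {
  set.seed(30)
  x <- matrix(rnorm(60), 30, 2)
  y <- rnorm(30)
  fit <- fitRfModel(x, y, rfModelSpec(n_trees = 20))
  ev <- evaluateModel(fit, x, y)
  pred <- as.numeric(predict(fit, x))
  expect_equal(ev$mse, sum((y - pred)^2) / 30)
  expect_equal(ev$r2, 1 - sum((y - pred)^2) / sum((y - mean(y))^2))

  # perfect predictions: score the model against its own outputs
  evp <- evaluateModel(fit, x, pred)
  expect_equal(evp$r2, 1)
  expect_equal(evp$mse, 0)

  # predict-the-mean has R^2 = 0 by definition
  cfit <- suppressWarnings(fitRfModel(x, rep(1, 30),
                                      rfModelSpec(n_trees = 10)))
  evm <- evaluateModel(cfit, x, y - mean(y) + 1)
  expect_equal(evm$r2, 0, tolerance = 1e-12)

  # zero-variance test target is flagged, MSE still reported
  ev0 <- evaluateModel(cfit, x, rep(1, 30))
  expect_true(is.na(ev0$r2))
  expect_equal(ev0$mse, 0)
})

test_that("per-compound models exclude vehicles and flag noise models", {
  d <- tinyRun()
  spec <- rfModelSpec(n_trees = 40)
  reps <- suppressMessages(
    perCompoundModels(d$flt, targets = "viability_pct", spec = spec))
  tab <- reportTable(reps)
  expect_equal(nrow(tab), 8L)                  # one per compound
  expect_false("VEHICLE" %in% tab$scope)
  for (r in reps) {
    expect_length(intersect(r@train_ids, r@test_ids), 0L)
    expect_equal(sum(modelImportances(r)), 1, tolerance = 1e-9)
    expect_true(all(modelImportances(r) >= 0))
  }
  # the no-effect compound's viability model captures only noise
  noeff <- d$truth$compounds$compound[!d$truth$compounds$toxic]
  expect_true(tab$low_variance[tab$scope == noeff])
  strong <- d$truth$compounds$compound[d$truth$compounds$emax_atp == 1][1]
  expect_false(tab$low_variance[tab$scope == strong])
})

test_that("the global model isolates its test partition from SMOGN", {
  d <- tinyRun()
  spec <- rfModelSpec(n_trees = 40)
  g0 <- globalModel(d$flt, "viability_pct", spec)
  ga <- globalModel(d$flt, "viability_pct", spec,
                    smogn = smognConfig(seed = 42))
  expect_identical(g0@test_ids, ga@test_ids)   # leakage guard
  expect_true(ga@augmented)
  expect_equal(sum(modelImportances(ga)), 1, tolerance = 1e-9)
  expect_equal(g0@n_test, ga@n_test)
})

test_that("median-rank feature ordering matches a hand computation", {
  mk <- function(scope, imp) {
    imp <- imp / sum(imp)
    new("RfModelReport", scope = scope, target = "viability_pct",
        r2_train = 1, r2_test = 1, mse_train = 0, mse_test = 0,
        importances = imp, low_variance = FALSE, augmented = FALSE,
        n_train = 8L, n_test = 2L, train_ids = letters[1:8],
        test_ids = letters[9:10])
  }
  f <- c("F1", "F2", "F3", "F4", "F5")
  r1 <- mk("A", setNames(c(5, 4, 3, 2, 1), f))   # ranks 1,2,3,4,5
  r2 <- mk("B", setNames(c(1, 5, 4, 3, 2), f))   # ranks 5,1,2,3,4
  r3 <- mk("C", setNames(c(2, 1, 5, 4, 3), f))   # ranks 4,5,1,2,3
  # median ranks: F1=4, F2=2, F3=2, F4=3, F5=4
  # -> order F2,F3 (tie: earlier column first), F4, then F1,F5
  im <- importanceMatrix(list(r1, r2, r3), top_k = 30)
  expect_identical(colnames(im$matrix), c("F2", "F3", "F4", "F1", "F5"))
  im3 <- importanceMatrix(list(r1, r2, r3), top_k = 3)
  expect_identical(colnames(im3$matrix), c("F2", "F3", "F4"))

  # identical importance profiles merge at height zero
  im2 <- importanceMatrix(list(r1, mk("D", setNames(c(5, 4, 3, 2, 1), f)),
                               r2))
  expect_equal(clusterHeights(im2$row_cluster)[1], 0)
})

test_that("the modelling stage is reproducible end to end", {
  d <- tinyRun()
  spec <- rfModelSpec(n_trees = 30, seed = 17)
  a <- globalModel(d$flt, "cell_count", spec)
  b <- globalModel(d$flt, "cell_count", spec)
  expect_identical(reportTable(a), reportTable(b))
  expect_identical(modelImportances(a), modelImportances(b))
})
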
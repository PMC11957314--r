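test_that("well aggregation takes per-feature medians and counts cells", {
  fx <- toyCellCsv()
  tab <- readCellFeatures(fx$cells, fx$metadata)
  ps <- aggregateWells(tab)
  expect_equal(unname(cellCounts(ps)), c(3L, 3L))
  expect_equal(profileMatrix(ps)["FeatA", "P1:A01"], 2)   # median of 1,2,9
  expect_equal(profileMatrix(ps)["FeatC", "P1:A02"], 50)
})

test_that("a single-cell well's profile is that cell's feature vector", {
  cells <- data.frame(plate_id = "P1", well = "A01",
                      F1 = 3.7, F2 = -1.2)
  md <- data.frame(plate_id = "P1", well = "A01", compound = "CP01",
                   concentration_m = 1e-6, vehicle = FALSE)
  ps <- aggregateWells(makeCellFeatureTable(cells, md))
  expect_equal(unname(profileMatrix(ps)[, 1]), c(3.7, -1.2))
  expect_equal(unname(cellCounts(ps)), 1L)
})

test_that("aggregation matches a sort-and-pick median oracle exactly", {
  set.seed(91)
  n <- 50L
  cells <- data.frame(plate_id = "P1", well = "A01",
                      F1 = rnorm(n), F2 = runif(n), F3 = rt(n, 3))
  md <- data.frame(plate_id = "P1", well = "A01", compound = "CP01",
                   concentration_m = 1e-6, vehicle = FALSE)
  ps <- aggregateWells(makeCellFeatureTable(cells, md))
  oracle <- function(x) {            # independent of stats::median
    s <- sort(x)
    if (length(s) %% 2L) s[(length(s) + 1L) / 2L]
    else (s[length(s) / 2L] + s[length(s) / 2L + 1L]) / 2
  }
  expect_identical(unname(profileMatrix(ps)[, 1]),
                   c(oracle(cells$F1), oracle(cells$F2), oracle(cells$F3)))
})

test_that("aggregation is invariant to cell order and drops NA cells", {
  set.seed(14)
  cells <- data.frame(plate_id = "P1",
                      well = sample(rep(c("A01", "A02"), each = 10L)),
                      F1 = rnorm(20), F2 = rnorm(20))
  md <- data.frame(plate_id = "P1", well = c("A01", "A02"),
                   compound = "CP01", concentration_m = 1e-6,
                   vehicle = FALSE)
  a <- aggregateWells(makeCellFeatureTable(cells, md))
  b <- aggregateWells(makeCellFeatureTable(cells[sample(20L), ], md))
  expect_equal(profileMatrix(a)[, colnames(b)], profileMatrix(b))

  cells$F1[1] <- NA
  expect_message(
    ps <- aggregateWells(makeCellFeatureTable(cells, md)), "missing")
  expect_equal(sum(cellCounts(ps)), 19L)
})

test_that("robust MAD normalization matches its closed form", {
  # one plate: 5 vehicle wells with control values 1..5 (median 3, MAD 1)
  m <- matrix(c(1, 2, 3, 4, 5, 3, 4.4826), ncol = 1,
              dimnames = list(NULL, "F01"))
  ps <- psFromMatrix(m, vehicle = c(rep(TRUE, 5), FALSE, FALSE))
  nz <- normalizeProfiles(ps, "robust_mad")
  z <- profileMatrix(nz)[1, ]
  expect_equal(unname(z[6]), 0)                       # raw 3 -> centered
  expect_equal(unname(z[7]), 1, tolerance = 1e-12)    # (4.4826-3)/1.4826
})

test_that("zscore and minmax use vehicle-control statistics", {
  m <- matrix(c(1, 2, 3, 4, 5, 3), ncol = 1)
  ps <- psFromMatrix(m, vehicle = c(rep(TRUE, 5), FALSE))
  z <- profileMatrix(normalizeProfiles(ps, "zscore"))[1, ]
  expect_equal(unname(z[6]), 0)                       # mean 3
  expect_equal(unname(z[5]), (5 - 3) / sd(1:5))
  mm <- profileMatrix(normalizeProfiles(ps, "minmax"))[1, ]
  expect_equal(unname(mm[1]), 0)
  expect_equal(unname(mm[5]), 1)
  expect_equal(unname(mm[6]), 0.5)
})

test_that("vehicle wells have median 0 and unit scaled MAD on every plate", {
  nz <- tinyRun()$nz
  m <- profileMatrix(nz)
  veh <- isVehicle(nz); pl <- plateIds(nz)
  for (p in unique(pl)) {
    cm <- m[, veh & pl == p, drop = FALSE]
    expect_lt(max(abs(apply(cm, 1, median))), 1e-9)
    mad14 <- apply(cm, 1, function(x) 1.4826 * median(abs(x - median(x))))
    expect_lt(max(abs(mad14 - 1)), 1e-9)
  }
})

test_that("features invariant in controls are dropped, not rescaled", {
  m <- cbind(F1 = c(1, 1, 1, 1, 2.5), F2 = c(1, 2, 3, 4, 0))
  ps <- psFromMatrix(m, vehicle = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_warning(nz <- normalizeProfiles(ps, "robust_mad"), "zero control")
  expect_identical(rownames(nz), "F2")
  expect_true("F1" %in% dropLedger(nz)$feature)
})

test_that("normalization is scope-local to each plate", {
  set.seed(8)
  m <- matrix(rnorm(40), ncol = 2)
  veh <- rep(c(TRUE, TRUE, TRUE, FALSE), 5)
  plate <- rep(c("P1", "P2"), each = 10)
  ps1 <- psFromMatrix(m, plate = plate, vehicle = veh)
  m2 <- m
  m2[plate == "P1", ] <- m2[plate == "P1", ] + 100    # perturb plate 1 only
  ps2 <- psFromMatrix(m2, plate = plate, vehicle = veh)
  n1 <- profileMatrix(normalizeProfiles(ps1))
  n2 <- profileMatrix(normalizeProfiles(ps2))
  p2cols <- plateIds(ps1) == "P2"
  expect_equal(n1[, p2cols], n2[, p2cols])
})

test_that("feature filtering matches a brute-force greedy oracle", {
  greedyOracle <- function(m, sd_max, corr_max) {   # m: wells x features
    keep <- colnames(m)[apply(m, 2, sd) <= sd_max]
    sub <- m[, keep, drop = FALSE]
    cm <- abs(cor(sub)); kept <- character()
    for (f in colnames(sub)) {
      if (!length(kept) || all(cm[f, kept] <= corr_max))
        kept <- c(kept, f)
    }
    kept
  }
  set.seed(33)
  n <- 40
  base <- matrix(rnorm(n * 8), n, 8)
  m <- cbind(base,
             BIG = rnorm(n, sd = 2500),                  # SD filter target
             COR = base[, 1] + rnorm(n, sd = 0.12))      # r ~ 0.95 pair
  colnames(m)[1:8] <- sprintf("F%02d", 1:8)
  stopifnot(abs(cor(m[, "COR"], m[, 1])) > 0.9)
  ps <- psFromMatrix(m, normalized = TRUE)
  flt <- filterFeatures(ps, sd_max = 2000, corr_max = 0.9)
  expect_equal(nrow(flt), 8L)
  expect_identical(rownames(flt), greedyOracle(m, 2000, 0.9))

  # random matrix against the oracle, and idempotence
  m2 <- matrix(rnorm(n * 20), n, 20) %*% diag(20) +
    matrix(rnorm(n), n, 20) * 0.8                       # induce correlation
  colnames(m2) <- sprintf("G%02d", 1:20)
  ps2 <- psFromMatrix(m2, normalized = TRUE)
  flt2 <- filterFeatures(ps2, sd_max = 2000, corr_max = 0.6)
  expect_identical(rownames(flt2), greedyOracle(m2, 2000, 0.6))
  flt2b <- filterFeatures(flt2, sd_max = 2000, corr_max = 0.6)
  expect_identical(rownames(flt2b), rownames(flt2))
})

test_that("an exact duplicate column is dropped in favour of the earlier", {
  set.seed(4)
  x <- rnorm(20)
  m <- cbind(A = x, B = rnorm(20), C = x)
  ps <- psFromMatrix(m, normalized = TRUE)
  flt <- filterFeatures(ps)
  expect_identical(rownames(flt), c("A", "B"))
  led <- dropLedger(flt)
  expect_equal(led$feature[led$reason == "correlation"], "C")
})

test_that("treatment aggregation is a median over condition wells", {
  d <- tinyRun()
  trt <- d$trt
  cd <- SummarizedExperiment::colData(d$nz)
  grp <- paste(cd$compound, signif(cd$concentration_m, 8), sep = "@")
  cond <- colnames(trt)[!isVehicle(trt)][1]
  wells <- which(grp == cond)
  expect_length(wells, 12L)                     # 4 wells x 3 plates
  oracle <- apply(profileMatrix(d$nz)[, wells, drop = FALSE], 1, median)
  expect_equal(profileMatrix(trt)[, cond], oracle)
  expect_equal(unname(cellCounts(trt)[cond]),
               median(cd$cell_count[wells]))

  # single-well condition is the identity
  one <- d$nz[, 1]
  SummarizedExperiment::colData(one)$vehicle <- FALSE
  t1 <- aggregateTreatments(one)
  expect_equal(unname(profileMatrix(t1)[, 1]),
               unname(profileMatrix(one)[, 1]))
})
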
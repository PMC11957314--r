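viabFixture <- function(lum, vehicle, plate = "P1") {
  n <- length(lum)
  md <- data.frame(plate_id = plate,
                   well = sprintf("A%02d", seq_len(n)),
                   compound = ifelse(vehicle, "VEHICLE", "CP01"),
                   concentration_m = ifelse(vehicle, 0, 1e-6),
                   vehicle = vehicle)
  v <- data.frame(plate_id = plate, well = md$well, luminescence = lum)
  phenotox:::.makeViabilityTable(v, md)
}

test_that("viability is scaled against the plate vehicle median", {
  v <- viabFixture(c(90, 100, 110, 55, 0),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE))
  nv <- normalizeViability(v)
  expect_equal(nv$viability_pct[nv$well == "A04"], 55)    # 100 * 55 / 100
  expect_equal(nv$viability_pct[nv$well == "A05"], 0)     # dead well
  expect_equal(nv$viability_pct[nv$well == "A02"], 100)   # at the median
  # vehicle wells median exactly 100 per plate
  expect_identical(median(nv$viability_pct[nv$vehicle]), 100)

  dead <- viabFixture(c(0, 0, 0, 10), c(TRUE, TRUE, TRUE, FALSE))
  expect_error(normalizeViability(dead), "rejected")
})

test_that("a condition identical to its vehicle controls is not significant", {
  m <- matrix(rnorm(24), 12, 2)
  counts <- rep(50L, 12)
  ps <- psFromMatrix(m, vehicle = rep(c(TRUE, FALSE), each = 6),
                     cell_count = counts)
  viabilityPct(ps) <- rep(80, 12)
  st <- conditionTests(ps)
  expect_equal(st$p_count, 1)
  expect_equal(st$tier_count, "ns")
  expect_equal(st$p_viability, 1)
})

test_that("a clearly separated toxic condition earns three stars", {
  set.seed(40)
  n_veh <- 12; n_trt <- 12
  ps <- psFromMatrix(matrix(rnorm((n_veh + n_trt) * 2), ncol = 2),
                     vehicle = rep(c(TRUE, FALSE), c(n_veh, n_trt)),
                     cell_count = c(rpois(n_veh, 250),
                                    rpois(n_trt, 20)))
  viabilityPct(ps) <- c(rnorm(n_veh, 100, 5), rnorm(n_trt, 10, 3))
  st <- conditionTests(ps)
  expect_identical(st$tier_count, "***")
  expect_identical(st$tier_viability, "***")
  expect_gt(st$count_drop_frac, 0.8)
})

test_that("significance tiers are consistent with the returned p-values", {
  d <- tinyRun()
  st <- conditionTests(d$flt, viability = d$v)
  expect_equal(nrow(st), 8 * 8)                 # compounds x concentrations
  tierOf <- function(p) ifelse(p < 0.001, "***",
                        ifelse(p < 0.01, "**",
                        ifelse(p < 0.05, "*", "ns")))
  expect_identical(st$tier_count, tierOf(st$p_count))
  expect_identical(st$tier_viability, tierOf(st$p_viability))
  expect_true(all(st$p_count >= 0 & st$p_count <= 1))
})

test_that("4PL fits recover a noiseless midpoint within 5 percent", {
  conc <- 10^seq(-8, log10(3e-5), length.out = 8)
  sm <- data.frame(compound = "X", concentration_m = conc,
                   median_viability_pct =
                     100 * (1 - hillEffect(conc, 1e-6, 1.5, 1)),
                   median_count_pct = 100)
  fit <- fitPotency(sm, "viability")
  expect_true(fit$determined)
  expect_lt(abs(fit$potency_m - 1e-6) / 1e-6, 0.05)
  expect_false(fit$extrapolated)

  # flat response: potency not determined
  flat <- fitPotency(sm, "count")
  expect_false(flat$determined)
  expect_identical(flat$reason, "flat")

  expect_error(fitPotency(sm[1:3, ], "viability"), "fewer than 4")
})

test_that("midpoint recovery tolerates 5 percent noise", {
  conc <- 10^seq(-8, log10(3e-5), length.out = 8)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    sm <- data.frame(compound = "X", concentration_m = conc,
                     median_viability_pct =
                       100 * (1 - hillEffect(conc, 3e-6, 1.5, 1)) *
                       exp(rnorm(8, 0, 0.05)),
                     median_count_pct = 100)
    abs(log10(fitPotency(sm, "viability")$potency_m / 3e-6))
  }, numeric(1))
  expect_lte(median(errs), 0.15)
})

test_that("fitted midpoints fall inside the tested range for toxic compounds", {
  d <- tinyRun()
  st <- conditionTests(d$flt, viability = d$v)
  pot <- fitPotency(st, "count")
  tr <- d$truth$compounds
  tox <- tr$compound[tr$emax_count >= 0.5 & !tr$decoupled]
  sub <- pot[pot$compound %in% tox, ]
  expect_true(all(sub$determined))
  expect_true(all(!sub$extrapolated))
  # the decoupled compound's ATP response is flat: IC50 not determined
  ic <- fitPotency(st, "viability")
  expect_false(ic$determined[ic$compound == tr$compound[tr$decoupled]])
})

test_that("decoupling flags need significant count and quiet viability", {
  sm <- data.frame(compound = c("A", "B", "C"),
                   concentration_m = 1e-6,
                   p_count = c(0.001, 0.001, 0.2),
                   p_viability = c(0.5, 0.001, 0.5),
                   count_drop_frac = c(0.6, 0.6, 0.6))
  out <- decouplingReport(sm)
  expect_identical(out$compound, "A")           # both-endpoint toxic excluded
  # a small count drop is below the floor even when significant
  sm$count_drop_frac <- 0.05
  expect_equal(nrow(decouplingReport(sm)), 0L)
})

test_that("the synthetic decoupled compound is flagged at designed doses", {
  d <- tinyRun()
  st <- conditionTests(d$flt, viability = d$v)
  dec <- decouplingReport(st)
  tr <- d$truth$compounds
  cpd <- tr$compound[tr$decoupled]
  expect_true(all(dec$compound %in%
                    c(cpd, tr$compound[tr$emax_atp < 0.5])))
  designed <- st$compound == cpd &
    hillEffect(st$concentration_m, tr$ec50_count[tr$decoupled],
               tr$hill[tr$decoupled], tr$emax_count[tr$decoupled]) >= 0.3
  flagged <- paste(dec$compound, dec$concentration_m)
  hits <- sum(paste(st$compound[designed], st$concentration_m[designed])
              %in% flagged)
  expect_gte(hits, sum(designed) - 1)           # at most one type-I miss
})
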
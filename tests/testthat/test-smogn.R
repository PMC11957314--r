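test_that("the relevance function honours its control points", {
  y <- 1:100
  rel <- buildRelevance(y, smognConfig())
  # rel_coef = 5: adjL = Q1 - 5*IQR falls below the data, clamps to min(y)
  expect_equal(rel$fun(min(y)), 1)
  expect_equal(rel$fun(median(y)), 0)
  expect_equal(rel$fun(max(y)), 0)

  # hand-built piecewise oracle at the control points
  qs <- quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
  adjL <- qs[1] - 5 * (qs[3] - qs[1])
  x1 <- max(adjL, min(y))
  expect_equal(rel$points$y, c(x1, qs[2], max(y)))
  expect_equal(rel$points$relevance, c(1, 0, 0))

  # interpolant stays within [0, 1] and is non-increasing on a fine grid
  grid <- seq(min(y) - 10, max(y) + 10, length.out = 1000)
  vals <- rel$fun(grid)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) <= 1e-12))

  expect_error(buildRelevance(rep(3, 10)), "constant")
  expect_error(buildRelevance(c(1, 2)), "at least 4")
})

test_that("rare/normal bins partition the data along sorted target runs", {
  y <- c(seq(0, 3, length.out = 10), seq(80, 100, length.out = 90))
  rel <- buildRelevance(y, smognConfig())
  part <- partitionBins(y, rel, 0.8)
  expect_setequal(c(part$rare, part$normal), seq_along(y))
  expect_length(intersect(part$rare, part$normal), 0L)
  expect_setequal(part$rare, 1:10)              # the low-viability tail
  expect_equal(length(part$bin_rare), max(part$bin))

  # an all-zero relevance leaves no rare observations: loud refusal
  flat <- structure(list(points = NULL,
                         fun = function(t) rep(0, length(t))),
                    class = "RelevanceFunction")
  expect_error(partitionBins(y, flat, 0.8), "rare set is empty")
})

test_that("interpolation draws lie on the seed-neighbour segment", {
  set.seed(100)
  cfg <- smognConfig()
  x_seed <- c(0, 0, 0)
  nb <- rbind(c(0.1, 0.1, 0), c(2, 2, 2), c(-2, 1, 2), c(2, 0, 1),
              c(1, 2, 0))
  ynb <- c(5, 9, 9, 9, 9)
  modes <- character(); got_interp <- FALSE
  for (i in 1:200) {
    s <- synthSample(x_seed, 4, nb, ynb, cfg, feature_sd = rep(1, 3),
                     y_sd = 1)
    modes <- c(modes, s$mode)
    if (s$mode == "interpolation") {
      got_interp <- TRUE
      lo <- pmin(x_seed, nb[1, ]); hi <- pmax(x_seed, nb[1, ])
      expect_true(all(s$x >= lo - 1e-12 & s$x <= hi + 1e-12))
      expect_gte(s$y, 4); expect_lte(s$y, 5)
    }
  }
  expect_true(got_interp)
  expect_true("noise" %in% modes)

  # u = 0 reproduces the seed exactly (interpolation endpoint)
  repeat {
    s <- synthSample(x_seed, 4, nb, ynb, cfg, feature_sd = rep(1, 3),
                     y_sd = 1, u = 0)
    if (s$mode == "interpolation") break
  }
  expect_identical(s$x, x_seed)
  expect_equal(s$y, 4)
  expect_error(synthSample(x_seed, 4, nb[0, , drop = FALSE], numeric(0),
                           cfg, rep(1, 3), 1), "k = 0")
})

test_that("noise-mode perturbations have the configured scale", {
  set.seed(7)
  cfg <- smognConfig(noise_sd_frac = 0.02)
  x_seed <- c(1, 2)
  nb <- rbind(c(10, 10), c(10, 12), c(12, 10))   # all distant -> noise mode
  fsd <- c(4, 9)
  draws <- replicate(10000, {
    s <- synthSample(x_seed, 0, nb, c(0, 0, 0), cfg, feature_sd = fsd,
                     y_sd = 1)
    stopifnot(s$mode == "noise")
    s$x
  })
  expect_equal(sd(draws[1, ]), 0.02 * 4, tolerance = 0.1 * 0.02 * 4)
  expect_equal(sd(draws[2, ]), 0.02 * 9, tolerance = 0.1 * 0.02 * 9)
})

test_that("balance sampling equalizes bins at the mean original size", {
  set.seed(12)
  y <- c(seq(0, 3, length.out = 10), seq(80, 100, length.out = 90))
  X <- matrix(rnorm(100 * 5), 100, 5)
  X[1:10, 1] <- X[1:10, 1] - 5                  # rare rows are distinct
  cfg <- smognConfig(seed = 2)
  aug <- smognAugment(X, y, cfg)
  expect_equal(aug$bin_sizes$original, c(10, 90))
  expect_equal(aug$bin_sizes$final, c(50, 50))
  expect_equal(sum(aug$synthetic), 40L)
  expect_equal(length(aug$y), 100L)

  # synthetic targets stay within the original range
  expect_true(all(aug$y >= min(y) & aug$y <= max(y)))
  # the rare tail is visibly enriched
  expect_gt(mean(aug$y < 50), mean(y < 50))

  # determinism
  aug2 <- smognAugment(X, y, cfg)
  expect_identical(aug$X, aug2$X)
  expect_identical(aug$y, aug2$y)

  # oversampling-only mode keeps every original row
  aug3 <- smognAugment(X, y, smognConfig(seed = 2, undersample = FALSE))
  expect_equal(sum(!aug3$synthetic), 100L)
})

test_that("augmentation fails loudly when no rare observations exist", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  expect_error(smognAugment(X, rep(5, 20), smognConfig()), "constant")
  # uniform target with an impossible threshold via a degenerate config:
  # relevance never reaches the threshold once the low tail is removed
  y <- c(seq(0, 1, length.out = 4), seq(50, 100, length.out = 16))
  rel <- buildRelevance(y, smognConfig())
  expect_error(partitionBins(y, structure(list(
    fun = function(t) pmin(rel$fun(t), 0.5)), class = "RelevanceFunction"),
    0.8), "refused")
})
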
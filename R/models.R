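#' Random-forest model specification
#'
#' Hyperparameters for the viability / cell-count regressors: 200
#' bootstrap-aggregated trees with unlimited depth, a fixed seed
#' (default 42) feeding both the 80/20 split and the forest through
#' deterministically derived sub-seeds, and a target-variance floor
#' below which a model is flagged as mainly capturing noise.
#'
#' @param n_trees number of trees (default 200).
#' @param seed integer seed.
#' @param split_fraction training fraction (default 0.8); the test size
#'   is \code{max(1, floor(n * (1 - split_fraction)))}.
#' @param low_variance_floor flag models whose target variance is below
#'   this floor (default 200, calibrated for the viability percentage
#'   scale: an SD below ~14 points is at the level of assay noise alone,
#'   so such models mainly capture noise; adjust for other targets).
#' @return an \code{RfModelSpec} (validated list).
#' @export
rfModelSpec <- function(n_trees = 200L, seed = 42L, split_fraction = 0.8,
                        low_variance_floor = 200) {
  .assertScalarNum(n_trees, "n_trees", lower = 1)
  .assertScalarNum(split_fraction, "split_fraction", lower = 1e-9,
                   upper = 1 - 1e-9)
  spec <- list(n_trees = as.integer(n_trees), seed = as.integer(seed),
               split_fraction = split_fraction,
               low_variance_floor = low_variance_floor)
  class(spec) <- "RfModelSpec"
  spec
}

#' Seeded random train/test split
#'
#' Uniform random split over rows: \code{max(1, ceiling(n * (1 -
#' split_fraction)))} rows form the test set (the rounding convention of
#' the scikit-learn train/test split, so 96 wells give 76 train / 20
#' test); the partition is disjoint, exhaustive, and reproducible from
#' the model-spec seed.
#'
#' @param n number of rows (or an object with rows).
#' @param spec an [rfModelSpec()].
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
splitTrainTest <- function(n, spec = rfModelSpec()) {
  if (!is.numeric(n) || length(n) != 1L) n <- nrow(n)
  n <- as.integer(n)
  if (n < 5L) stop("too few rows to split (need >= 5)")
  n_test <- max(1L, as.integer(ceiling(n * (1 - spec$split_fraction))))
  set.seed(.subSeed(spec$seed, 1L))
  test <- sort(sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Fit a bagged regression forest
#'
#' Seeded wrapper around \code{randomForest}: \code{n_trees} trees,
#' bootstrap resampling, and fully grown trees (no depth limit;
#' terminal nodes down to a single observation). The number of features
#' tried per split stays at the \code{randomForest} regression default
#' (\code{p/3}): random feature subsetting decorrelates the trees and
#' spreads impurity credit across correlated features, which keeps
#' importance rankings stable. Refitting with the same data and seed
#' reproduces identical predictions. A constant feature matrix with
#' varying response is allowed (the forest predicts the mean).
#'
#' @param x numeric feature matrix (rows = observations).
#' @param y numeric response.
#' @param spec an [rfModelSpec()].
#' @return a fitted \code{randomForest} object.
#' @export
fitRfModel <- function(x, y, spec = rfModelSpec()) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  if (ncol(x) < 1L) stop("need at least 1 feature")
  set.seed(.subSeed(spec$seed, 2L))
  randomForest::randomForest(x = x, y = as.numeric(y),
                             ntree = spec$n_trees, nodesize = 1L,
                             replace = TRUE)
}

#' Evaluate a regression model
#'
#' \code{R^2 = 1 - SS_res / SS_tot} and mean squared error on the given
#' set. With a zero-variance target, R^2 is undefined and returned as
#' \code{NA} (flagged); the MSE is still returned.
#'
#' @param model object with a \code{predict} method.
#' @param x feature matrix.
#' @param y observed response.
#' @return list with \code{r2}, \code{mse} and \code{predictions}.
#' @export
evaluateModel <- function(model, x, y) {
  if (!length(y)) stop("empty evaluation set")
  pred <- as.numeric(stats::predict(model, as.matrix(x)))
  res <- y - pred
  mse <- mean(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
  list(r2 = r2, mse = mse, predictions = pred)
}

.normImportance <- function(fit, feature_names) {
  imp <- as.numeric(randomForest::importance(fit, type = 2L))
  names(imp) <- feature_names
  s <- sum(imp)
  if (s <= 0) imp[] <- 1 / length(imp) else imp <- imp / s
  imp
}

.buildReport <- function(scope, target, x, y, ids, spec,
                         smogn_cfg = NULL) {
  sp <- splitTrainTest(nrow(x), spec)
  x_tr <- x[sp$train, , drop = FALSE]; y_tr <- y[sp$train]
  augmented <- FALSE
  if (!is.null(smogn_cfg)) {
    aug <- smognAugment(x_tr, y_tr, smogn_cfg)
    x_tr <- aug$X; y_tr <- aug$y
    augmented <- TRUE
  }
  fit <- fitRfModel(x_tr, y_tr, spec)
  ev_tr <- evaluateModel(fit, x_tr, y_tr)
  ev_te <- evaluateModel(fit, x[sp$test, , drop = FALSE], y[sp$test])
  new("RfModelReport", scope = scope, target = target,
      r2_train = ev_tr$r2, r2_test = ev_te$r2,
      mse_train = ev_tr$mse, mse_test = ev_te$mse,
      importances = .normImportance(fit, colnames(x)),
      low_variance = stats::var(y) < spec$low_variance_floor,
      augmented = augmented,
      n_train = length(sp$train), n_test = length(sp$test),
      train_ids = ids[sp$train], test_ids = ids[sp$test])
}

.modelFrame <- function(ps, target) {
  cd <- as.data.frame(SummarizedExperiment::colData(ps))
  y <- switch(target,
              viability_pct = cd$viability_pct,
              cell_count = as.numeric(cd$cell_count),
              stop("unknown target: ", target))
  if (is.null(y) || all(is.na(y)))
    stop("target '", target, "' is not available; attach viability first")
  list(x = t(profileMatrix(ps)), y = y, ids = colnames(ps))
}

#' Per-compound random-forest models
#'
#' One regression forest per compound and target, trained on that
#' compound's well-level profiles (vehicle wells excluded) after
#' refitting the feature filters within the compound's data. Reports
#' whose target variance is below the model-spec floor are flagged as mainly
#' capturing noise.
#'
#' @param ps a normalized well-level \linkS4class{ProfileSet} with
#'   viability attached (for the \code{viability_pct} target).
#' @param targets any of \code{"viability_pct"}, \code{"cell_count"}.
#' @param spec an [rfModelSpec()].
#' @param refilter refit [filterFeatures()] within each compound
#'   (default TRUE).
#' @return list of \linkS4class{RfModelReport} (see [reportTable()]).
#' @export
perCompoundModels <- function(ps, targets = c("viability_pct", "cell_count"),
                              spec = rfModelSpec(), refilter = TRUE) {
  targets <- match.arg(targets, several.ok = TRUE)
  cmpds <- sort(unique(compoundIds(ps)[!isVehicle(ps)]))
  if (!length(cmpds)) stop("no non-vehicle compounds in profiles")
  reports <- list()
  for (cp in cmpds) {
    sub <- ps[, compoundIds(ps) == cp]
    if (refilter) {
      fp <- S4Vectors::metadata(ps)$filter_params
      sub <- filterFeatures(sub,
                            sd_max = if (is.null(fp)) 2000 else fp["sd_max"],
                            corr_max = if (is.null(fp)) 0.9
                                       else fp["corr_max"])
    }
    for (tg in targets) {
      mf <- .modelFrame(sub, tg)
      rep <- .buildReport(cp, tg, mf$x, mf$y, mf$ids, spec)
      if (rep@low_variance)
        .msg("model ", cp, "/", tg,
             ": target variance below floor; flagged as noise-dominated")
      reports[[paste(cp, tg, sep = ".")]] <- rep
    }
  }
  reports
}

#' Panel-wide random-forest model
#'
#' A single forest trained on every non-vehicle well-level profile.
#' When a SMOGN configuration is supplied, augmentation is applied to
#' the training partition only — test rows are never synthesized or
#' resampled, so augmented and unaugmented runs share identical test
#' rows.
#'
#' @param ps a normalized, filtered well-level \linkS4class{ProfileSet}.
#' @param target \code{"viability_pct"} or \code{"cell_count"}.
#' @param spec an [rfModelSpec()].
#' @param smogn optional [smognConfig()] for training-set augmentation.
#' @return an \linkS4class{RfModelReport} with scope \code{"GLOBAL"}.
#' @export
globalModel <- function(ps, target = "viability_pct", spec = rfModelSpec(),
                        smogn = NULL) {
  sub <- ps[, !isVehicle(ps)]
  if (length(unique(compoundIds(sub))) < 2L)
    stop("global model needs profiles spanning at least 2 compounds")
  mf <- .modelFrame(sub, target)
  .buildReport("GLOBAL", target, mf$x, mf$y, mf$ids, spec,
               smogn_cfg = smogn)
}

#' Cross-model feature-importance matrix
#'
#' Collects per-model importance vectors, ranks features within each
#' model (rank 1 = most important), orders features by their median rank
#' across models, and keeps the top \code{top_k} (default 30; all if
#' fewer). Rows (models) and columns (features) are clustered with
#' single linkage on Pearson dissimilarity.
#'
#' @param reports list of \linkS4class{RfModelReport} (>= 2).
#' @param top_k number of features kept by median importance rank.
#' @return list with \code{matrix} (models x top features, in median-rank
#'   order), \code{median_rank}, and \code{row_cluster} /
#'   \code{col_cluster} (\linkS4class{ClusterResult} or NULL when
#'   degenerate).
#' @export
importanceMatrix <- function(reports, top_k = 30L) {
  if (length(reports) < 2L) stop("need at least 2 model reports")
  feats <- sort(unique(unlist(lapply(reports, function(r)
    names(r@importances)))))
  imp <- t(vapply(reports, function(r) {
    v <- stats::setNames(numeric(length(feats)), feats)
    v[names(r@importances)] <- r@importances
    v
  }, numeric(length(feats))))
  rownames(imp) <- vapply(reports, function(r) r@scope, character(1))
  ranks <- t(apply(imp, 1L, function(v) rank(-v, ties.method = "min")))
  med_rank <- apply(ranks, 2L, stats::median)
  ord <- order(med_rank, seq_along(med_rank))
  keep <- ord[seq_len(min(top_k, length(ord)))]
  m <- imp[, keep, drop = FALSE]
  safe_cluster <- function(x) tryCatch(
    clusterProfiles(x, linkage = "single", metric = "pearson"),
    error = function(e) NULL)
  list(matrix = m, median_rank = med_rank[keep],
       row_cluster = safe_cluster(m),
       col_cluster = if (ncol(m) >= 2L) safe_cluster(t(m)) else NULL)
}
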
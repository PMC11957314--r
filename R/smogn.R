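#' SMOGN configuration
#'
#' Parameters of the imbalanced-regression oversampler: the relevance
#' function marks the low tail of the target (here: low viability) as
#' rare; rare bins are oversampled by SMOTE-style interpolation or
#' Gaussian-noise generation and, under \code{samp_method = "balance"},
#' normal bins are undersampled so every bin reaches the mean original
#' bin size.
#'
#' @param rel_xtrm_type which target extreme is rare; only \code{"low"}
#'   is implemented (the screening use case).
#' @param samp_method \code{"balance"} (equalize bins at the mean bin
#'   size) or \code{"extreme"} (reserved; currently identical).
#' @param rel_coef boxplot whisker coefficient of the relevance function
#'   (default 5).
#' @param rel_thres relevance threshold in (0, 1) above which an
#'   observation is rare (default 0.8).
#' @param k_neighbors neighbours searched within the rare bin
#'   (default 5).
#' @param noise_sd_frac Gaussian-noise scale, as a fraction of each
#'   feature's (and the target's) SD (default 0.02).
#' @param seed integer seed.
#' @param undersample also undersample normal bins (default TRUE,
#'   the balance behaviour; set FALSE to only oversample).
#' @return an \code{SmognConfig} (validated list).
#' @export
smognConfig <- function(rel_xtrm_type = "low", samp_method = "balance",
                        rel_coef = 5, rel_thres = 0.8, k_neighbors = 5L,
                        noise_sd_frac = 0.02, seed = 1L,
                        undersample = TRUE) {
  rel_xtrm_type <- match.arg(rel_xtrm_type, c("low", "high", "both"))
  if (rel_xtrm_type != "low")
    stop("only rel_xtrm_type = 'low' is implemented")
  samp_method <- match.arg(samp_method, c("balance", "extreme"))
  .assertScalarNum(rel_coef, "rel_coef", lower = 1e-9)
  .assertScalarNum(rel_thres, "rel_thres", lower = 1e-9, upper = 1 - 1e-9)
  .assertScalarNum(k_neighbors, "k_neighbors", lower = 1)
  .assertScalarNum(noise_sd_frac, "noise_sd_frac", lower = 1e-12)
  cfg <- list(rel_xtrm_type = rel_xtrm_type, samp_method = samp_method,
              rel_coef = rel_coef, rel_thres = rel_thres,
              k_neighbors = as.integer(k_neighbors),
              noise_sd_frac = noise_sd_frac, seed = as.integer(seed),
              undersample = isTRUE(undersample))
  class(cfg) <- "SmognConfig"
  cfg
}

#' Build the boxplot-based relevance function over a target
#'
#' For the low-extreme case, relevance is 1 at the low adjacent value
#' \code{adjL = Q1 - rel_coef * IQR} (clamped to \code{min(y)} when it
#' falls below the data), 0 at \code{median(y)} and above, with a
#' monotone piecewise-cubic interpolant between the control points,
#' clamped to [0, 1]. Below the first control point relevance is 1.
#'
#' @param y target vector (length >= 4, non-constant).
#' @param cfg an [smognConfig()].
#' @return a \code{RelevanceFunction}: list with \code{points}
#'   (data.frame of control points) and \code{fun} (vectorized evaluator
#'   y -> [0, 1], non-increasing over the data range).
#' @export
buildRelevance <- function(y, cfg = smognConfig()) {
  if (length(y) < 4L) stop("need at least 4 target values")
  if (stats::sd(y) == 0) stop("constant target; relevance undefined")
  qs <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3] - qs[1]
  adjL <- qs[1] - cfg$rel_coef * iqr
  x1 <- max(adjL, min(y))
  med <- qs[2]
  if (x1 >= med) x1 <- min(y)
  if (x1 >= med) stop("degenerate target: min(y) >= median(y)")
  px <- c(x1, med, max(y))
  pr <- c(1, 0, 0)
  dup <- duplicated(px)
  px <- px[!dup]; pr <- pr[!dup]
  sf <- stats::splinefun(px, pr, method = "monoH.FC")
  fun <- function(t) {
    out <- pmin(1, pmax(0, sf(t)))
    out[t <= px[1]] <- 1
    out[t >= px[length(px)]] <- 0
    out
  }
  structure(list(points = data.frame(y = px, relevance = pr), fun = fun),
            class = "RelevanceFunction")
}

#' Partition observations into rare and normal bins
#'
#' Observations with relevance \code{>= rel_thres} are rare; contiguous
#' runs of rare/normal along the sorted target form the bins. Rare and
#' normal sets partition the data.
#'
#' @param y target vector.
#' @param rel a [buildRelevance()] result built from \code{y}.
#' @param rel_thres relevance threshold (default 0.8).
#' @return list with \code{rare} / \code{normal} index vectors,
#'   \code{bin} (bin id per observation) and \code{bin_rare} (logical
#'   per bin).
#' @export
partitionBins <- function(y, rel, rel_thres = 0.8) {
  phi <- rel$fun(y)
  rare_flag <- phi >= rel_thres
  if (!any(rare_flag))
    stop("rare set is empty at rel_thres = ", rel_thres,
         "; augmentation refused")
  ord <- order(y)
  runs <- rle(rare_flag[ord])
  bin_sorted <- rep(seq_along(runs$lengths), runs$lengths)
  bin <- integer(length(y))
  bin[ord] <- bin_sorted
  list(rare = which(rare_flag), normal = which(!rare_flag), bin = bin,
       bin_rare = runs$values)
}

#' Generate one synthetic observation from a rare seed row
#'
#' Implements the SMOGN generation rule. With a chosen neighbour at
#' distance below half the median seed-to-neighbour distance, a
#' SMOTE-style interpolation is used: \code{x_new = x_seed + u * (x_nb -
#' x_seed)}, \code{u ~ Uniform(0, 1)}, and the target is the
#' inverse-distance weighted mean of the two parents' targets.
#' Otherwise Gaussian-noise generation perturbs the seed:
#' \code{x_new = x_seed + N(0, (noise_sd_frac * sd_feature)^2)} per
#' feature and likewise for the target.
#'
#' @param x_seed seed feature vector.
#' @param y_seed seed target value.
#' @param x_neighbors matrix of the seed's k rare-bin neighbours.
#' @param y_neighbors their targets.
#' @param cfg an [smognConfig()].
#' @param feature_sd per-feature SDs used for the noise scale.
#' @param y_sd target SD used for the noise scale.
#' @param u optional interpolation coordinate in [0, 1] (drawn uniformly
#'   when NULL); exposed for testing.
#' @return list with \code{x}, \code{y} and \code{mode}
#'   (\code{"interpolation"} or \code{"noise"}).
#' @export
synthSample <- function(x_seed, y_seed, x_neighbors, y_neighbors,
                        cfg = smognConfig(), feature_sd, y_sd, u = NULL) {
  x_neighbors <- as.matrix(x_neighbors)
  k <- nrow(x_neighbors)
  if (k < 1L) stop("need at least one neighbour (k = 0)")
  d <- sqrt(rowSums(sweep(x_neighbors, 2L, x_seed)^2))
  j <- if (k == 1L) 1L else sample.int(k, 1L)
  if (d[j] < stats::median(d) / 2) {
    if (is.null(u)) u <- stats::runif(1)
    x_new <- x_seed + u * (x_neighbors[j, ] - x_seed)
    d1 <- sqrt(sum((x_new - x_seed)^2))
    d2 <- sqrt(sum((x_new - x_neighbors[j, ])^2))
    y_new <- if (d1 + d2 == 0) mean(c(y_seed, y_neighbors[j]))
             else (d2 * y_seed + d1 * y_neighbors[j]) / (d1 + d2)
    mode <- "interpolation"
  } else {
    x_new <- x_seed + stats::rnorm(length(x_seed), 0,
                                   cfg$noise_sd_frac * feature_sd)
    y_new <- y_seed + stats::rnorm(1L, 0, cfg$noise_sd_frac * y_sd)
    mode <- "noise"
  }
  list(x = x_new, y = y_new, mode = mode)
}

#' SMOGN augmentation of an imbalanced regression set
#'
#' Builds the relevance function over \code{y}, partitions the data into
#' rare/normal bins, oversamples every rare bin with [synthSample()]
#' draws and (under \code{balance}) undersamples normal bins by random
#' removal, so each bin's final size equals the mean original bin size.
#' Synthetic targets are clamped to the original target range; every
#' synthetic row is flagged. Test-set isolation is the caller's
#' contract — augment training partitions only.
#'
#' @param X numeric feature matrix (rows = observations).
#' @param y numeric target, aligned with \code{X}.
#' @param cfg an [smognConfig()].
#' @return list with \code{X}, \code{y}, \code{synthetic} (logical flag
#'   per returned row), \code{mode} (generation mode per row, "original"
#'   for retained rows) and \code{bin_sizes} (original vs final).
#' @export
smognAugment <- function(X, y, cfg = smognConfig()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y are misaligned")
  set.seed(.subSeed(cfg$seed, 7L))
  rel <- buildRelevance(y, cfg)
  part <- partitionBins(y, rel, cfg$rel_thres)
  sizes <- tabulate(part$bin)
  target_size <- round(mean(sizes))
  feature_sd <- apply(X, 2L, stats::sd)
  y_sd <- stats::sd(y)
  y_rng <- range(y)

  keep_idx <- integer(); keep_mode <- character()
  syn_x <- list(); syn_y <- numeric(); syn_mode <- character()
  for (b in seq_along(sizes)) {
    members <- which(part$bin == b)
    if (part$bin_rare[b]) {
      keep_idx <- c(keep_idx, members)
      n_new <- target_size - length(members)
      if (n_new > 0L) {
        seeds <- rep_len(members, n_new)
        for (s in seeds) {
          others <- setdiff(members, s)
          if (!length(others)) {   # singleton bin: noise around the seed
            x_new <- X[s, ] + stats::rnorm(ncol(X), 0,
                                           cfg$noise_sd_frac * feature_sd)
            smp <- list(x = x_new,
                        y = y[s] + stats::rnorm(1L, 0,
                                                cfg$noise_sd_frac * y_sd),
                        mode = "noise")
          } else {
            d <- sqrt(rowSums(sweep(X[others, , drop = FALSE], 2L,
                                    X[s, ])^2))
            nb <- others[order(d)][seq_len(min(cfg$k_neighbors,
                                               length(others)))]
            smp <- synthSample(X[s, ], y[s], X[nb, , drop = FALSE], y[nb],
                               cfg, feature_sd, y_sd)
          }
          smp$y <- min(max(smp$y, y_rng[1]), y_rng[2])
          syn_x[[length(syn_x) + 1L]] <- smp$x
          syn_y <- c(syn_y, smp$y)
          syn_mode <- c(syn_mode, smp$mode)
        }
      }
    } else {
      kept <- if (cfg$undersample && length(members) > target_size)
        sort(sample(members, target_size)) else members
      keep_idx <- c(keep_idx, kept)
    }
  }
  keep_idx <- sort(keep_idx)
  X_out <- rbind(X[keep_idx, , drop = FALSE],
                 if (length(syn_x)) do.call(rbind, syn_x))
  y_out <- c(y[keep_idx], syn_y)
  synthetic <- c(rep(FALSE, length(keep_idx)), rep(TRUE, length(syn_y)))
  rownames(X_out) <- NULL
  list(X = X_out, y = y_out, synthetic = synthetic,
       mode = c(rep("original", length(keep_idx)), syn_mode),
       bin_sizes = data.frame(bin = seq_along(sizes), rare = part$bin_rare,
                              original = sizes,
                              final = vapply(seq_along(sizes), function(b) {
                                sum(part$bin[keep_idx] == b) +
                                  if (part$bin_rare[b])
                                    max(0L, target_size - sizes[b]) else 0L
                              }, numeric(1))))
}
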
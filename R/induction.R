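#' Induction: fraction of strongly perturbed features
#'
#' The induction of a normalized profile is the percentage of its
#' features whose absolute robust Z-score strictly exceeds
#' \code{z_thresh} (default 3):
#' \code{100 * |{i : |z_i| > z_thresh}| / |z|}. A scalar measure of
#' perturbation strength used to screen out weak phenotypes before
#' clustering. A value exactly equal to the threshold does not count.
#'
#' @param x numeric profile vector, a matrix with profiles in rows, or a
#'   normalized \linkS4class{ProfileSet} (one value per profile column).
#' @param z_thresh strict absolute Z-score threshold (default 3).
#' @return induction percentage(s) in [0, 100].
#' @examples
#' computeInduction(c(3.5, -4, 0, 1, 2))  # 40
#' @name computeInduction
NULL

.induction1 <- function(z, z_thresh) {
  if (!length(z)) stop("empty profile vector")
  if (any(!is.finite(z))) stop("profile contains non-finite values")
  100 * sum(abs(z) > z_thresh) / length(z)
}

#' @rdname computeInduction
setMethod("computeInduction", "numeric", function(x, z_thresh = 3) {
  .induction1(x, z_thresh)
})

#' @rdname computeInduction
setMethod("computeInduction", "matrix", function(x, z_thresh = 3) {
  apply(x, 1L, .induction1, z_thresh = z_thresh)
})

#' @rdname computeInduction
setMethod("computeInduction", "ProfileSet", function(x, z_thresh = 3) {
  if (!isNormalized(x)) stop("induction is defined on normalized profiles")
  apply(profileMatrix(x), 2L, .induction1, z_thresh = z_thresh)
})

#' Screen out weakly induced treatment profiles
#'
#' Keeps profiles whose induction strictly exceeds \code{min_induction}
#' (default 20, i.e. more than 20\% of features significantly affected);
#' boundary values are excluded. Raising the threshold never adds
#' profiles.
#'
#' @param ps a normalized \linkS4class{ProfileSet}.
#' @param min_induction induction cutoff on the percentage scale.
#' @param z_thresh passed to [computeInduction()].
#' @return list with \code{kept} and \code{excluded}
#'   \linkS4class{ProfileSet}s and the named \code{induction} vector.
#' @export
filterByInduction <- function(ps, min_induction = 20, z_thresh = 3) {
  ind <- computeInduction(ps, z_thresh = z_thresh)
  keep <- ind > min_induction
  list(kept = ps[, keep], excluded = ps[, !keep], induction = ind)
}

.clusterMatrix <- function(m, linkage, metric) {
  if (nrow(m) < 2L) stop("need at least 2 profiles to cluster")
  if (metric == "pearson") {
    v <- apply(m, 1L, stats::sd)
    if (any(v == 0))
      stop("constant profile(s) under the pearson metric: ",
           paste(rownames(m)[v == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m)
  }
  hc <- stats::hclust(d, method = linkage)
  new("ClusterResult", linkage = linkage, metric = metric, hc = hc,
      labels = rownames(m))
}

#' Hierarchically cluster profiles
#'
#' Agglomerative clustering of profiles with the given linkage on either
#' the Pearson dissimilarity \code{d = 1 - r} (anti-correlated profiles
#' are maximally distant, d = 2) or Euclidean distance. For a
#' \linkS4class{ProfileSet} the profiles are the columns; for a matrix,
#' the rows.
#'
#' @param x \linkS4class{ProfileSet} or numeric matrix (profiles in rows).
#' @param linkage agglomeration rule (default \code{"average"}, as used
#'   for treatment clustergrams; \code{"complete"} and \code{"single"}
#'   available).
#' @param metric \code{"pearson"} or \code{"euclidean"}.
#' @return a \linkS4class{ClusterResult}.
#' @name clusterProfiles
NULL

#' @rdname clusterProfiles
setMethod("clusterProfiles", "matrix",
  function(x, linkage = c("average", "complete", "single"),
           metric = c("pearson", "euclidean")) {
    .clusterMatrix(x, match.arg(linkage), match.arg(metric))
  })

#' @rdname clusterProfiles
setMethod("clusterProfiles", "ProfileSet",
  function(x, linkage = c("average", "complete", "single"),
           metric = c("pearson", "euclidean")) {
    m <- t(profileMatrix(x))
    .clusterMatrix(m, match.arg(linkage), match.arg(metric))
  })

#' Clamp profile values for heatmap display
#'
#' Values are clamped to \code{[-bound, +bound]} (default 8 robust MADs)
#' for readability of exported heatmaps only; clustering and induction
#' always use unclipped values.
#'
#' @param m numeric matrix or vector.
#' @param bound positive clamp bound.
#' @return the clamped object.
#' @export
clipForDisplay <- function(m, bound = 8) {
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0)
    stop("'bound' must be a positive scalar")
  pmin(pmax(m, -bound), bound)
}

#' Export a clustergram (heatmap image + ordered CSV)
#'
#' Writes the profile matrix with rows in dendrogram order (and columns
#' in feature-dendrogram order when \code{cluster_features}) both as a
#' PNG heatmap and as a CSV, values clipped for display.
#'
#' @param result \linkS4class{ClusterResult} for the profiles.
#' @param m matrix with profiles in rows, matching \code{result}.
#' @param path output prefix; writes \code{<path>.png} and
#'   \code{<path>_ordered.csv}.
#' @param cluster_features also order columns by a feature clustergram
#'   (same linkage/metric; falls back to input order if degenerate).
#' @param clip display clamp bound (see [clipForDisplay()]); \code{NULL}
#'   disables.
#' @param png write the PNG image (the CSV is always written).
#' @return invisibly, the ordered (clipped) matrix.
#' @export
exportClustergram <- function(result, m, path, cluster_features = TRUE,
                              clip = 8, png = TRUE) {
  stopifnot(is(result, "ClusterResult"))
  if (!identical(rownames(m), result@labels))
    stop("matrix rows do not match the clustering result")
  ord <- clusterOrder(result)
  col_ord <- seq_len(ncol(m))
  if (cluster_features && ncol(m) >= 2L) {
    fc <- tryCatch(.clusterMatrix(t(m), result@linkage, result@metric),
                   error = function(e) NULL)
    if (!is.null(fc)) col_ord <- clusterOrder(fc)
  }
  out <- m[ord, col_ord, drop = FALSE]
  if (!is.null(clip)) out <- clipForDisplay(out, clip)
  csv <- paste0(path, "_ordered.csv")
  fwrite(cbind(data.table(profile_id = rownames(out)), as.data.table(out)),
         csv)
  if (png) {
    grDevices::png(paste0(path, ".png"), width = 1400, height = 1000,
                   res = 120)
    pheatmap::pheatmap(out, cluster_rows = FALSE, cluster_cols = FALSE,
                       show_colnames = ncol(out) <= 60,
                       fontsize_row = 6)
    grDevices::dev.off()
  }
  invisible(out)
}
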
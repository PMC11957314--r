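#' ProfileSet: morphological profiles with plate-layout semantics
#'
#' A \code{ProfileSet} extends
#' \linkS4class{SummarizedExperiment}: the \code{"profile"} assay holds
#' morphological features in rows and profiles (wells, or treatments after
#' aggregation) in columns. \code{colData} carries the plate-layout
#' metadata (\code{plate_id}, \code{well}, \code{compound},
#' \code{concentration_m}, \code{vehicle}) together with per-profile
#' \code{cell_count}, and \code{metadata()} records the processing state:
#' the aggregation level (\code{"well"} or \code{"treatment"}), whether
#' and how profiles were normalized, the vehicle-control wells used per
#' plate, and the feature drop ledger.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no additional slots.
#'
#' @seealso [aggregateWells()], [normalizeProfiles()], [filterFeatures()],
#'   [aggregateTreatments()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass ProfileSet
setClass("ProfileSet", contains = "SummarizedExperiment")

setValidity("ProfileSet", function(object) {
  msgs <- character()
  if (!"profile" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'profile' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("compound", "concentration_m", "vehicle", "cell_count")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  lvl <- S4Vectors::metadata(object)$level
  if (is.null(lvl) || !lvl %in% c("well", "treatment"))
    msgs <- c(msgs, "metadata()$level must be 'well' or 'treatment'")
  if (identical(lvl, "well")) {
    miss2 <- setdiff(c("plate_id", "well"), colnames(cd))
    if (length(miss2))
      msgs <- c(msgs, paste0("well-level colData lacks: ",
                             paste(miss2, collapse = ", ")))
  }
  if ("cell_count" %in% colnames(cd)) {
    cc <- cd$cell_count
    if (any(!is.finite(cc)) || any(cc < 0))
      msgs <- c(msgs, "cell_count must be finite and non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProfileSet
#'
#' @param profiles numeric matrix, features in rows, profiles in columns.
#' @param colData data.frame of per-profile metadata (one row per column
#'   of \code{profiles}).
#' @param level \code{"well"} or \code{"treatment"}.
#' @param metadata extra entries for \code{metadata()}.
#' @return A \linkS4class{ProfileSet}.
#' @export
ProfileSet <- function(profiles, colData, level = c("well", "treatment"),
                       metadata = list()) {
  level <- match.arg(level)
  profiles <- as.matrix(profiles)
  if (!is.numeric(profiles)) stop("'profiles' must be numeric")
  md <- c(list(level = level), metadata)
  if (is.null(md$normalized)) md$normalized <- FALSE
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(profile = profiles),
    colData = S4Vectors::DataFrame(colData),
    metadata = md)
  new("ProfileSet", se)
}

#' ClusterResult: a hierarchical clustering of profiles
#'
#' Wraps an agglomerative merge tree together with the linkage and
#' dissimilarity metric that produced it. The leaf set equals the input
#' profiles; heights are non-decreasing along merges (enforced at
#' construction).
#'
#' @slot linkage one of \code{"average"}, \code{"complete"}, \code{"single"}.
#' @slot metric one of \code{"pearson"} (dissimilarity \code{1 - r}) or
#'   \code{"euclidean"}.
#' @slot hc the underlying \code{stats::hclust} object.
#' @slot labels leaf labels, in input row order.
#'
#' @exportClass ClusterResult
setClass("ClusterResult",
         representation(linkage = "character", metric = "character",
                        hc = "ANY", labels = "character"))

setValidity("ClusterResult", function(object) {
  msgs <- character()
  if (!inherits(object@hc, "hclust")) msgs <- c(msgs, "hc must be an hclust")
  else {
    if (is.unsorted(object@hc$height))
      msgs <- c(msgs, "merge heights must be non-decreasing")
    if (length(object@labels) != length(object@hc$order))
      msgs <- c(msgs, "labels must cover every leaf")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ClusterResult leaf order after clustering (a permutation of
#'   the input rows).
#' @param x,object a \code{ClusterResult}.
#' @export
clusterOrder <- function(x) x@hc$order

#' @describeIn ClusterResult merge heights, one per agglomeration step.
#' @export
clusterHeights <- function(x) x@hc$height

#' @describeIn ClusterResult flat cluster labels obtained by cutting the
#'   tree at \code{k} groups.
#' @param k number of flat clusters.
#' @export
cutClusters <- function(x, k) stats::cutree(x@hc, k = k)

#' Coerce a ClusterResult to hclust
#' @param x a \code{ClusterResult}.
#' @param ... ignored.
#' @export
as.hclust.ClusterResult <- function(x, ...) x@hc

#' RfModelReport: metrics and importances of one fitted forest
#'
#' @slot scope compound code, or \code{"GLOBAL"} for the panel-wide model.
#' @slot target \code{"viability_pct"} or \code{"cell_count"}.
#' @slot r2_train,r2_test,mse_train,mse_test fit metrics; \code{r2_test}
#'   is \code{NA} (flagged) when the test target is constant.
#' @slot importances named mean-decrease-in-impurity weights, summing to 1.
#' @slot low_variance \code{TRUE} when the target variance is below the
#'   model spec floor, marking models that mainly capture noise.
#' @slot augmented \code{TRUE} when the training partition was SMOGN
#'   augmented.
#' @slot n_train,n_test partition sizes.
#' @slot train_ids,test_ids profile identifiers per partition (disjoint).
#'
#' @exportClass RfModelReport
setClass("RfModelReport",
         representation(scope = "character", target = "character",
                        r2_train = "numeric", r2_test = "numeric",
                        mse_train = "numeric", mse_test = "numeric",
                        importances = "numeric", low_variance = "logical",
                        augmented = "logical",
                        n_train = "integer", n_test = "integer",
                        train_ids = "character", test_ids = "character"))

setValidity("RfModelReport", function(object) {
  msgs <- character()
  if (length(intersect(object@train_ids, object@test_ids)))
    msgs <- c(msgs, "train and test rows must be disjoint")
  imp <- object@importances
  if (any(imp < 0)) msgs <- c(msgs, "importances must be non-negative")
  if (abs(sum(imp) - 1) > 1e-9)
    msgs <- c(msgs, "importances must sum to 1")
  if (length(msgs)) msgs else TRUE
})
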
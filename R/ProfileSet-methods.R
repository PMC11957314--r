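#' Accessors for ProfileSet objects
#'
#' @param x a \linkS4class{ProfileSet}.
#' @param value replacement value.
#' @return \code{cellCounts}: integer per-profile cell counts;
#'   \code{isVehicle}: logical vehicle flags; \code{plateIds},
#'   \code{wellIds}, \code{compoundIds}: character vectors;
#'   \code{concentrations}: molar concentrations; \code{viabilityPct}:
#'   vehicle-relative viability (NA until attached);
#'   \code{profileMatrix}: the features-by-profiles assay;
#'   \code{isNormalized}/\code{normMethod}: normalization state;
#'   \code{profileLevel}: \code{"well"} or \code{"treatment"};
#'   \code{dropLedger}: data.frame of dropped features and reasons.
#' @name ProfileSet-accessors
NULL

.cd <- function(x) SummarizedExperiment::colData(x)

#' @rdname ProfileSet-accessors
setMethod("cellCounts", "ProfileSet", function(x) {
  stats::setNames(.cd(x)$cell_count, colnames(x))
})

#' @rdname ProfileSet-accessors
setMethod("isVehicle", "ProfileSet", function(x) {
  stats::setNames(.cd(x)$vehicle, colnames(x))
})

#' @rdname ProfileSet-accessors
setMethod("plateIds", "ProfileSet", function(x) {
  cd <- .cd(x)
  if (!"plate_id" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$plate_id, colnames(x))
})

#' @rdname ProfileSet-accessors
setMethod("wellIds", "ProfileSet", function(x) {
  cd <- .cd(x)
  if (!"well" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$well, colnames(x))
})

#' @rdname ProfileSet-accessors
setMethod("compoundIds", "ProfileSet", function(x) {
  stats::setNames(.cd(x)$compound, colnames(x))
})

#' @rdname ProfileSet-accessors
setMethod("concentrations", "ProfileSet", function(x) {
  stats::setNames(.cd(x)$concentration_m, colnames(x))
})

#' @rdname ProfileSet-accessors
setMethod("viabilityPct", "ProfileSet", function(x) {
  cd <- .cd(x)
  v <- if ("viability_pct" %in% colnames(cd)) cd$viability_pct
       else rep(NA_real_, ncol(x))
  stats::setNames(v, colnames(x))
})

#' @rdname ProfileSet-accessors
setReplaceMethod("viabilityPct", "ProfileSet", function(x, value) {
  if (length(value) != ncol(x))
    stop("viability vector must have one value per profile")
  SummarizedExperiment::colData(x)$viability_pct <- as.numeric(value)
  x
})

#' @rdname ProfileSet-accessors
setMethod("profileMatrix", "ProfileSet", function(x) {
  SummarizedExperiment::assay(x, "profile")
})

#' @rdname ProfileSet-accessors
setMethod("isNormalized", "ProfileSet", function(x) {
  isTRUE(S4Vectors::metadata(x)$normalized)
})

#' @rdname ProfileSet-accessors
setMethod("normMethod", "ProfileSet", function(x) {
  S4Vectors::metadata(x)$norm_method
})

#' @rdname ProfileSet-accessors
setMethod("profileLevel", "ProfileSet", function(x) {
  S4Vectors::metadata(x)$level
})

#' @rdname ProfileSet-accessors
setMethod("dropLedger", "ProfileSet", function(x) {
  led <- S4Vectors::metadata(x)$drop_ledger
  if (is.null(led)) {
    led <- data.frame(feature = character(), reason = character(),
                      detail = character())
  }
  led
})

setMethod("show", "ProfileSet", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("ProfileSet (%s-level): %d feature(s) x %d profile(s)\n",
              md$level, nrow(object), ncol(object)))
  cat(sprintf("  normalized: %s%s\n", isTRUE(md$normalized),
              if (isTRUE(md$normalized))
                paste0(" (", md$norm_method, ", per-plate vehicle controls)")
              else ""))
  nv <- sum(.cd(object)$vehicle)
  cat(sprintf("  compounds: %d | vehicle profiles: %d\n",
              length(unique(.cd(object)$compound[!.cd(object)$vehicle])), nv))
  led <- md$drop_ledger
  if (!is.null(led) && nrow(led))
    cat(sprintf("  dropped features: %d (see dropLedger())\n", nrow(led)))
  invisible(NULL)
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d profile(s), %s linkage on %s %s\n",
              length(object@labels), object@linkage, object@metric,
              if (object@metric == "pearson") "dissimilarity (1 - r)"
              else "distance"))
  invisible(NULL)
})

setMethod("show", "RfModelReport", function(object) {
  cat(sprintf("RfModelReport [%s / %s]%s%s\n", object@scope, object@target,
              if (object@augmented) " (SMOGN-augmented)" else "",
              if (object@low_variance) " [low target variance]" else ""))
  cat(sprintf("  train: n=%d R2=%.3f MSE=%.3f | test: n=%d R2=%s MSE=%.3f\n",
              object@n_train, object@r2_train, object@mse_train,
              object@n_test,
              if (is.na(object@r2_test)) "NA (constant target)"
              else sprintf("%.3f", object@r2_test),
              object@mse_test))
  invisible(NULL)
})

#' Tabulate a list of model reports
#'
#' @param reports list of \linkS4class{RfModelReport}.
#' @return data.frame with one row per report (scope, target, metrics,
#'   partition sizes, flags).
#' @export
reportTable <- function(reports) {
  if (inherits(reports, "RfModelReport")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(scope = r@scope, target = r@target,
               r2_train = r@r2_train, r2_test = r@r2_test,
               mse_train = r@mse_train, mse_test = r@mse_test,
               n_train = r@n_train, n_test = r@n_test,
               low_variance = r@low_variance, augmented = r@augmented,
               stringsAsFactors = FALSE)
  }))
}

#' Importance weights of a model report
#' @param report an \linkS4class{RfModelReport}.
#' @return named numeric vector summing to 1.
#' @export
modelImportances <- function(report) report@importances
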
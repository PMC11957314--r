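#' @rdname ProfileSet-accessors
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("isVehicle", function(x) standardGeneric("isVehicle"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("plateIds", function(x) standardGeneric("plateIds"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("wellIds", function(x) standardGeneric("wellIds"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("viabilityPct", function(x) standardGeneric("viabilityPct"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("viabilityPct<-", function(x, value) standardGeneric("viabilityPct<-"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("normMethod", function(x) standardGeneric("normMethod"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("profileLevel", function(x) standardGeneric("profileLevel"))

#' @rdname ProfileSet-accessors
#' @export
setGeneric("dropLedger", function(x) standardGeneric("dropLedger"))

#' @rdname computeInduction
#' @export
setGeneric("computeInduction",
           function(x, z_thresh = 3) standardGeneric("computeInduction"))

#' @rdname clusterProfiles
#' @export
setGeneric("clusterProfiles",
           function(x, linkage = c("average", "complete", "single"),
                    metric = c("pearson", "euclidean"))
             standardGeneric("clusterProfiles"))
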
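#' @rdname SRNAProfile-class
#' @param object an object.
#' @export
setGeneric("srnaCounts", function(object) standardGeneric("srnaCounts"))
#' @rdname SRNAProfile-class
#' @export
setGeneric("srnaRpm", function(object) standardGeneric("srnaRpm"))
#' @rdname SRNAProfile-class
#' @export
setGeneric("libSizes", function(object) standardGeneric("libSizes"))
#' @rdname SRNAProfile-class
#' @export
setGeneric("srnaRegions", function(object) standardGeneric("srnaRegions"))

#' @rdname ClusterModel-class
#' @param object an object.
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @rdname ClusterModel-class
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))
#' @rdname ClusterModel-class
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @rdname CoexprNetwork-class
#' @param object an object.
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname CoexprNetwork-class
#' @export
setGeneric("hubGenes", function(object) standardGeneric("hubGenes"))
#' @rdname CoexprNetwork-class
#' @export
setGeneric("nodeLevels", function(object) standardGeneric("nodeLevels"))

#' @rdname SRNAProfile-class
#' @export
setMethod("srnaCounts", "SRNAProfile", function(object) object@counts)
#' @rdname SRNAProfile-class
#' @export
setMethod("srnaRpm", "SRNAProfile", function(object) {
  if (!length(object@rpm))
    stop("RPM not computed yet; call rpmNormalize() first")
  object@rpm
})
#' @rdname SRNAProfile-class
#' @export
setMethod("libSizes", "SRNAProfile", function(object) object@libSizes)
#' @rdname SRNAProfile-class
#' @export
setMethod("srnaRegions", "SRNAProfile", function(object) object@regions)

#' @rdname ClusterModel-class
#' @export
setMethod("centroids", "ClusterModel", function(object) object@centroids)
#' @rdname ClusterModel-class
#' @export
setMethod("memberships", "ClusterModel", function(object) object@membership)
#' @rdname ClusterModel-class
#' @export
setMethod("clusterAssignments", "ClusterModel",
          function(object) object@assignments)

#' @rdname CoexprNetwork-class
#' @export
setMethod("networkEdges", "CoexprNetwork", function(object) object@edges)
#' @rdname CoexprNetwork-class
#' @export
setMethod("hubGenes", "CoexprNetwork", function(object) object@hubs)
#' @rdname CoexprNetwork-class
#' @export
setMethod("nodeLevels", "CoexprNetwork", function(object) object@levels)
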
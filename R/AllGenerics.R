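#' @include AllClasses.R
NULL

#' Accessors for cyclehubs objects
#'
#' Small accessor family in the Bioconductor style: slot access stays behind
#' functions.
#'
#' @param x a cyclehubs object.
#' @return the requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("experimentId", function(x) standardGeneric("experimentId"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("smoothingSpan", function(x) standardGeneric("smoothingSpan"))

#' @rdname accessors
#' @export
setGeneric("unsmoothableGenes",
  function(x) standardGeneric("unsmoothableGenes"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("activeMatrix", function(x) standardGeneric("activeMatrix"))

#' @rdname accessors
#' @export
setGeneric("visibleNodes", function(x) standardGeneric("visibleNodes"))

#' @rdname accessors
#' @export
setGeneric("visibleEdges", function(x) standardGeneric("visibleEdges"))

#' @rdname accessors
#' @export
setGeneric("nodeValues", function(x) standardGeneric("nodeValues"))

#' @rdname accessors
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' @rdname accessors
#' @export
setGeneric("jaccardMatrix", function(x) standardGeneric("jaccardMatrix"))

#' @rdname accessors
#' @export
setGeneric("staggeredScore", function(x) standardGeneric("staggeredScore"))

#' @rdname accessors
#' @export
setMethod("experimentId", "ExpressionTimeCourse",
  function(x) x@experimentId)

#' @rdname accessors
#' @export
setMethod("timePoints", "ExpressionTimeCourse",
  function(x) colData(x)$minutes)

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionTimeCourse",
  function(x) assay(x, "log2ratio"))

#' @rdname accessors
#' @export
setMethod("missingMask", "ExpressionTimeCourse",
  function(x) assay(x, "missing"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionTimeCourse", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("smoothingSpan", "SmoothedTimeCourse", function(x) x@span)

#' @rdname accessors
#' @export
setMethod("unsmoothableGenes", "SmoothedTimeCourse",
  function(x) names(x@unsmoothable)[x@unsmoothable])

#' @rdname accessors
#' @export
setMethod("networkGraph", "InteractionNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("geneIds", "InteractionNetwork",
  function(x) sort(igraph::V(x@graph)$name))

#' @rdname accessors
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) {
  e <- igraph::as_edgelist(x@graph)
  if (nrow(e) == 0L)
    return(matrix(character(0), 0, 2))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
})

#' @rdname accessors
#' @export
setMethod("timePoints", "ActivityMask", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("geneIds", "ActivityMask", function(x) rownames(x@active))

#' @rdname accessors
#' @export
setMethod("activeMatrix", "ActivityMask", function(x) x@active)

#' @rdname accessors
#' @export
setMethod("visibleNodes", "NetworkFrame", function(x) x@visibleNodes)

#' @rdname accessors
#' @export
setMethod("visibleEdges", "NetworkFrame", function(x) x@visibleEdges)

#' @rdname accessors
#' @export
setMethod("nodeValues", "NetworkFrame", function(x) x@nodeValues)

#' @rdname accessors
#' @export
setMethod("frameTime", "NetworkFrame", function(x) x@time)

#' @rdname accessors
#' @export
setMethod("jaccardMatrix", "OverlapMatrix", function(x) x@jaccard)

#' @rdname accessors
#' @export
setMethod("staggeredScore", "OverlapMatrix", function(x) x@staggeredScore)

setMethod("show", "ExpressionTimeCourse", function(object) {
  cat(sprintf("%s '%s': %d genes x %d timepoints (%g..%g min), %d missing\n",
    class(object), experimentId(object), nrow(object), ncol(object),
    min(timePoints(object)), max(timePoints(object)),
    sum(missingMask(object))))
})

setMethod("show", "SmoothedTimeCourse", function(object) {
  callNextMethod()
  cat(sprintf("  span %.3g, %d unsmoothable gene(s)\n", object@span,
    sum(object@unsmoothable)))
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
    igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

setMethod("show", "ActivityMask", function(object) {
  cat(sprintf(
    "ActivityMask: %d genes x %d timepoints, default threshold %g, %d override(s)\n",
    nrow(object@active), length(object@times), object@thresholdDefault,
    sum(object@thresholds != object@thresholdDefault)))
})

setMethod("show", "NetworkFrame", function(object) {
  cat(sprintf("NetworkFrame t=%g min: %d visible nodes, %d visible edges\n",
    object@time, length(object@visibleNodes),
    nrow(object@visibleEdges)))
})

setMethod("show", "CompetitionProfile", function(object) {
  cat(sprintf(
    "CompetitionProfile %s (%d interfaces, %d partners): max simultaneous %d, competitive %.0f%% of times\n",
    object@hub, object@nInterfaces, length(object@partners),
    object@maxSimultaneous, 100 * object@fractionTimeCompetitive))
})

setMethod("show", "OverlapMatrix", function(object) {
  cat(sprintf("OverlapMatrix: %d partners, staggered score %.3f\n",
    nrow(object@jaccard), object@staggeredScore))
})
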
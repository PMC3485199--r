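#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
NULL

setOldClass("igraph")

#' ExpressionTimeCourse: one synchronization experiment
#'
#' A gene x timepoint matrix of log2 expression ratios from one
#' synchronized-culture experiment (e.g. an alpha-factor, cdc15-2 or Cdc28
#' arrest-release time course), stored as a
#' \link[SummarizedExperiment]{SummarizedExperiment} with two assays:
#' \code{log2ratio} (numeric, \code{NA} where missing) and \code{missing}
#' (logical mask, \code{TRUE} where no usable measurement exists).
#' Column data carry the sampling times in minutes, strictly increasing.
#' Missing values are never imputed at read time; downstream stages decide
#' how to treat them.
#'
#' @slot experimentId single label naming the experiment.
#' @export
setClass("ExpressionTimeCourse",
  contains = "SummarizedExperiment",
  representation(experimentId = "character"))

setValidity("ExpressionTimeCourse", function(object) {
  msg <- character(0)
  if (length(object@experimentId) != 1L || !nzchar(object@experimentId))
    msg <- c(msg, "experimentId must be a single non-empty label")
  if (!all(c("log2ratio", "missing") %in% names(assays(object))))
    msg <- c(msg, "assays must contain 'log2ratio' and 'missing'")
  else {
    v <- assay(object, "log2ratio")
    m <- assay(object, "missing")
    if (!is.logical(m)) msg <- c(msg, "'missing' assay must be logical")
    else if (any(!m & !is.finite(v)))
      msg <- c(msg, "non-finite log2ratio where missing is FALSE")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "rownames must be unique gene identifiers")
  else if (!identical(rownames(object), normalizeGeneId(rownames(object))))
    msg <- c(msg, "gene identifiers must be normalized (uppercase)")
  tt <- colData(object)$minutes
  if (is.null(tt)) msg <- c(msg, "colData must carry a 'minutes' column")
  else if (any(diff(tt) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionTimeCourse
#'
#' @param values numeric gene x timepoint matrix of log2 ratios; rownames are
#'   gene symbols (normalized to uppercase).
#' @param times numeric vector of sampling times in minutes, one per column,
#'   strictly increasing.
#' @param experimentId label for the synchronization experiment.
#' @param missing optional logical mask of the same shape; defaults to
#'   \code{is.na(values)}.
#' @return an \linkS4class{ExpressionTimeCourse}.
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("CLN1", "CDC28"), NULL))
#' expressionTimeCourse(m, times = c(0, 10, 20), experimentId = "alpha")
#' @export
expressionTimeCourse <- function(values, times, experimentId = "experiment",
                                 missing = NULL) {
  values <- as.matrix(values)
  if (is.null(missing)) missing <- is.na(values)
  missing <- missing | is.na(values)
  storage.mode(values) <- "double"
  values[missing] <- NA_real_
  rn <- normalizeGeneId(rownames(values))
  if (anyDuplicated(rn))
    stop("duplicate gene row: ", rn[duplicated(rn)][1L])
  rownames(values) <- rownames(missing) <- rn
  colnames(values) <- colnames(missing) <- as.character(times)
  se <- SummarizedExperiment(
    assays = list(log2ratio = values, missing = missing),
    colData = DataFrame(minutes = as.numeric(times)))
  new("ExpressionTimeCourse", se, experimentId = as.character(experimentId))
}

#' SmoothedTimeCourse: locally smoothed expression
#'
#' An \linkS4class{ExpressionTimeCourse} whose \code{log2ratio} assay holds
#' the local-regression smooth of the source series, evaluated at the
#' observed timepoints. Positions missing in the source remain missing.
#' Genes with too few observations to smooth are flagged and carried as
#' all-missing rows.
#'
#' @slot span fraction of non-missing points in each local fit.
#' @slot unsmoothable named logical vector, \code{TRUE} for genes that failed
#'   the smoothing precondition.
#' @export
setClass("SmoothedTimeCourse",
  contains = "ExpressionTimeCourse",
  representation(span = "numeric", unsmoothable = "logical"))

setValidity("SmoothedTimeCourse", function(object) {
  msg <- character(0)
  if (length(object@span) != 1L || object@span <= 0 || object@span > 1)
    msg <- c(msg, "span must be a single fraction in (0, 1]")
  if (!identical(names(object@unsmoothable), rownames(object)))
    msg <- c(msg, "unsmoothable must be named by the gene rows")
  if (length(msg)) msg else TRUE
})

#' InteractionNetwork: undirected protein-interaction graph
#'
#' A simple undirected graph over normalized gene symbols, backed by an
#' \pkg{igraph} object. Self-loops and duplicate edges are removed at
#' construction (hub-interface analysis concerns hetero-interactions).
#'
#' @slot graph the underlying undirected simple \pkg{igraph} graph with
#'   vertex names.
#' @export
setClass("InteractionNetwork", representation(graph = "igraph"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character(0)
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (!igraph::is_simple(g))
    msg <- c(msg, "graph must be simple (no loops or multi-edges)")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "vertices must carry unique names")
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#'
#' @param edges two-column matrix or data.frame of interacting gene pairs, or
#'   an \pkg{igraph} graph with named vertices.
#' @param nodes optional extra (possibly isolated) node names to include.
#' @param warnDropped emit one warning per call when self-loops or duplicate
#'   edges are dropped.
#' @return an \linkS4class{InteractionNetwork}.
#' @examples
#' interactionNetwork(cbind(c("CLA4", "CLA4"), c("CDC42", "BEM1")))
#' @export
interactionNetwork <- function(edges, nodes = character(0),
                               warnDropped = TRUE) {
  if (inherits(edges, "igraph")) {
    g <- edges
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "each")
    igraph::V(g)$name <- normalizeGeneId(igraph::V(g)$name)
  } else {
    em <- as.matrix(edges)
    if (length(em) && ncol(em) != 2L)
      stop("edges must have two columns")
    em[] <- normalizeGeneId(em)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
  }
  if (length(nodes)) {
    extra <- setdiff(normalizeGeneId(nodes), igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  nLoop <- sum(igraph::which_loop(g))
  nMulti <- igraph::ecount(g) - nLoop -
    igraph::ecount(igraph::simplify(g))
  g <- igraph::simplify(g)
  if (warnDropped && nLoop > 0)
    warning(sprintf("dropped %d self-loop(s)", nLoop))
  if (warnDropped && nMulti > 0)
    warning(sprintf("deduplicated %d duplicate edge(s)", nMulti))
  new("InteractionNetwork", graph = g)
}

#' ActivityMask: threshold-gated visibility of genes over time
#'
#' Boolean gene x timepoint visibility under an expression threshold, the
#' headless equivalent of hiding nodes during their troughs of expression in
#' a real-time rendering. A value greater than or equal to its gene's
#' threshold is active (the boundary is inclusive: the display rule hides
#' what falls \emph{below} the threshold). Missing values are inactive.
#'
#' @slot active logical gene x timepoint matrix.
#' @slot values the (smoothed) log2 ratios the mask was derived from.
#' @slot times sampling times in minutes.
#' @slot thresholdDefault default log2-ratio threshold.
#' @slot thresholds named per-gene effective thresholds (default plus
#'   overrides).
#' @export
setClass("ActivityMask", representation(
  active = "matrix", values = "matrix", times = "numeric",
  thresholdDefault = "numeric", thresholds = "numeric"))

setValidity("ActivityMask", function(object) {
  msg <- character(0)
  if (!is.logical(object@active)) msg <- c(msg, "active must be logical")
  if (!identical(dim(object@active), dim(object@values)))
    msg <- c(msg, "active and values must share their shape")
  if (ncol(object@active) != length(object@times))
    msg <- c(msg, "one column per timepoint required")
  if (!identical(names(object@thresholds), rownames(object@active)))
    msg <- c(msg, "thresholds must be named by gene rows")
  ok <- is.na(object@values) |
    (object@active == (object@values >= object@thresholds[
      rownames(object@active)]))
  if (!all(ok) || any(object@active & is.na(object@values)))
    msg <- c(msg, "active must equal value >= threshold (missing inactive)")
  if (length(msg)) msg else TRUE
})

#' NetworkFrame: the network as visible at one timepoint
#'
#' One frame of the threshold-gated animation: the genes whose expression is
#' at or above threshold at time \code{t}, and every network edge whose two
#' endpoints are both visible ("proteins and their interactions are hidden
#' together").
#'
#' @slot time frame time in minutes.
#' @slot visibleNodes lexicographically sorted visible gene symbols.
#' @slot visibleEdges two-column character matrix of visible edges, each row
#'   sorted, rows in lexicographic order.
#' @slot nodeValues named log2 ratios of the visible nodes at \code{time}.
#' @export
setClass("NetworkFrame", representation(
  time = "numeric", visibleNodes = "character", visibleEdges = "matrix",
  nodeValues = "numeric"))

setValidity("NetworkFrame", function(object) {
  msg <- character(0)
  e <- object@visibleEdges
  if (length(e) && ncol(e) != 2L)
    msg <- c(msg, "visibleEdges must have two columns")
  if (length(e) && !all(e %in% object@visibleNodes))
    msg <- c(msg, "every visible edge endpoint must be a visible node")
  if (!identical(names(object@nodeValues), object@visibleNodes))
    msg <- c(msg, "nodeValues must be named by visibleNodes")
  if (length(msg)) msg else TRUE
})

#' CompetitionProfile: interface competition at a hub over time
#'
#' Per-timepoint count of the hub's direct (1-step) interaction partners that
#' are visible in an \linkS4class{ActivityMask}, compared with the hub's
#' number of interaction interfaces. \code{excess} counts partners beyond the
#' interfaces available, the crowding that forces mutually exclusive binding.
#' The hub's own activity is reported separately and does not gate the
#' partner count; a "realized" summary additionally restricts to times when
#' the hub itself is expressed.
#'
#' @slot hub hub gene symbol.
#' @slot partners the hub's direct partners in the analysed network.
#' @slot times sampling times in minutes.
#' @slot nInterfaces 1 or 2 interaction interfaces.
#' @slot activeCount per-time number of active partners.
#' @slot excess per-time \code{max(0, activeCount - nInterfaces)}.
#' @slot hubActive per-time activity of the hub itself.
#' @slot maxSimultaneous largest activeCount over the window.
#' @slot fractionTimeCompetitive fraction of sampled times with excess > 0.
#' @slot realizedFractionCompetitive fraction of sampled times with excess >
#'   0 while the hub is active.
#' @export
setClass("CompetitionProfile", representation(
  hub = "character", partners = "character", times = "numeric",
  nInterfaces = "integer", activeCount = "integer", excess = "integer",
  hubActive = "logical", maxSimultaneous = "integer",
  fractionTimeCompetitive = "numeric",
  realizedFractionCompetitive = "numeric"))

#' OverlapMatrix: pairwise temporal overlap of partner activity
#'
#' Jaccard index of active-time index sets for every pair of partners, with a
#' flag for pairs where both activity sets are empty (their Jaccard is
#' reported as 0). The staggered score is the mean off-diagonal Jaccard; low
#' values indicate staggered expression peaks, which reduce competition for
#' the hub interface.
#'
#' @slot jaccard symmetric partner x partner matrix in [0, 1].
#' @slot bothEmpty logical matrix flagging pairs with two empty activity
#'   sets.
#' @slot staggeredScore mean pairwise (off-diagonal) Jaccard.
#' @export
setClass("OverlapMatrix", representation(
  jaccard = "matrix", bothEmpty = "matrix", staggeredScore = "numeric"))
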
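#' Read a gene x timepoint expression matrix
#'
#' Reads a tab-separated expression table in the synchronized-culture layout:
#' first column gene symbols, remaining column headers the sampling times in
#' minutes. Cells that cannot be parsed as numbers (including empty strings)
#' become missing values, never errors; the missing mask travels with the
#' matrix so downstream stages can decide how to treat gaps.
#'
#' @param path path to a TSV file.
#' @param experimentId label for the experiment; defaults to the file name
#'   without extension.
#' @param dialect \code{"minutes"} expects purely numeric time headers;
#'   \code{"labeled"} strips a non-numeric prefix from each header (so
#'   array-style headers such as \code{alpha0, alpha7, ...} parse as
#'   0, 7, ... minutes).
#' @return an \linkS4class{ExpressionTimeCourse}.
#' @seealso [writeExpression()] for the inverse operation.
#' @export
readExpression <- function(path, experimentId = NULL,
                           dialect = c("minutes", "labeled")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(experimentId))
    experimentId <- sub("\\.[^.]*$", "", basename(path))
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("format error: expected gene column + timepoints")
  hdr <- colnames(tab)[-1L]
  if (dialect == "labeled") hdr <- sub("^[^0-9+-]*", "", hdr)
  times <- suppressWarnings(as.numeric(hdr))
  if (anyNA(times))
    stop("format error: non-numeric time header: ",
         colnames(tab)[-1L][is.na(times)][1L])
  if (any(diff(times) <= 0))
    stop("format error: non-increasing time header")
  genes <- normalizeGeneId(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene row: ", genes[duplicated(genes)][1L])
  values <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1L, drop = FALSE])),
           nrow = nrow(tab),
           dimnames = list(genes, NULL)))
  expressionTimeCourse(values, times, experimentId)
}

#' Write an expression matrix as TSV
#'
#' Writes the \code{log2ratio} assay in the layout [readExpression()]
#' expects; missing cells become empty strings. Values are printed with 17
#' significant digits so a write/read cycle reproduces the matrix exactly.
#'
#' @param x an \linkS4class{ExpressionTimeCourse}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "ExpressionTimeCourse"))
  v <- exprValues(x)
  fmt <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  fmt[missingMask(x) | is.na(v)] <- ""
  out <- cbind(gene = geneIds(x), fmt)
  colnames(out) <- c("gene", sprintf("%.10g", timePoints(x)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected interaction network
#'
#' Supports SIF (\code{A<tab>pp<tab>B [C ...]}), plain two-column TSV, and
#' GraphML. The result is always a simple undirected graph: \code{A-B} and
#' \code{B-A} collapse to one edge, duplicate edges are deduplicated (one
#' warning per file) and self-loops are dropped with a warning.
#'
#' @param path path to the network file.
#' @param dialect \code{"auto"} guesses from the file extension
#'   (\code{.sif}, \code{.graphml}, anything else read as two-column TSV).
#' @return an \linkS4class{InteractionNetwork}.
#' @export
readNetwork <- function(path, dialect = c("auto", "sif", "tsv", "graphml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    dialect <- switch(ext, sif = "sif", graphml = "graphml", "tsv")
  }
  if (dialect == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(interactionNetwork(g))
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  src <- character(0); dst <- character(0)
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    if (dialect == "sif") {
      if (length(fields) < 3L)
        stop(sprintf("malformed line %d in %s", i, path))
      src <- c(src, rep(fields[1L], length(fields) - 2L))
      dst <- c(dst, fields[-(1:2)])
    } else {
      if (length(fields) != 2L)
        stop(sprintf("malformed line %d in %s", i, path))
      src <- c(src, fields[1L]); dst <- c(dst, fields[2L])
    }
  }
  interactionNetwork(cbind(src, dst))
}

#' Write a network in SIF format
#'
#' @param x an \linkS4class{InteractionNetwork}.
#' @param path output file path.
#' @param type SIF interaction type label.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(x, path, type = "pp") {
  stopifnot(is(x, "InteractionNetwork"))
  e <- networkEdges(x)
  writeLines(sprintf("%s\t%s\t%s", e[, 1], type, e[, 2]), path)
  invisible(path)
}

#' Packaged singlish-hub annotation table
#'
#' The published annotation of all 36 yeast hubs with one or two interaction
#' interfaces: interface count, Pfam domain strings (annotation only),
#' functional grouping, and the published Dynamic/Static classification
#' (hubs with missing or low-quality expression data carry a hyphen in
#' print and are returned as \code{"missing"}).
#'
#' @return a data.frame with columns \code{hub}, \code{n_interfaces},
#'   \code{domains}, \code{functional_group}, \code{table1_class}.
#' @examples
#' hubs <- loadTable1Hubs()
#' table(hubs$table1_class)
#' @export
loadTable1Hubs <- function() {
  path <- system.file("extdata", "table1_hubs.tsv", package = "cyclehubs",
                      mustWork = TRUE)
  tab <- read.delim(path, colClasses = "character")
  tab$hub <- normalizeGeneId(tab$hub)
  tab$n_interfaces <- as.integer(tab$n_interfaces)
  tab$table1_class[tab$table1_class %in% c("-", "")] <- "missing"
  stopifnot(all(tab$n_interfaces %in% 1:2),
            all(tab$table1_class %in% c("Dynamic", "Static", "missing")),
            !anyDuplicated(tab$hub))
  tab
}

#' Packaged Gdi1 interaction-partner table
#'
#' The ten direct interaction partners of the GDP dissociation inhibitor
#' Gdi1 as described in the published worked example, each labelled
#' periodic (dynamically expressed in the cell cycle) or aperiodic
#' (constitutively expressed).
#'
#' @return a data.frame with columns \code{partner} and \code{call}
#'   (\code{"periodic"} or \code{"aperiodic"}).
#' @examples
#' p <- loadGdi1Partners()
#' sum(p$call == "periodic")
#' @export
loadGdi1Partners <- function() {
  path <- system.file("extdata", "gdi1_partners.tsv", package = "cyclehubs",
                      mustWork = TRUE)
  tab <- read.delim(path, colClasses = "character")
  tab$partner <- normalizeGeneId(tab$partner)
  stopifnot(all(tab$call %in% c("periodic", "aperiodic")),
            !anyDuplicated(tab$partner))
  tab
}
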
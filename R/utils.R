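#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats lm.fit runif rnorm var
#' @importFrom utils read.delim write.table head
NULL

#' Normalize gene identifiers
#'
#' Gene symbols are carried in the standard uppercase yeast convention
#' (e.g. \code{CLA4}); published tables mix \code{Cla4}/\code{CLA4}, so every
#' reader and constructor funnels identifiers through this function before
#' any join between network and expression data.
#'
#' @param x character vector of gene symbols.
#' @return uppercase symbols with surrounding whitespace removed.
#' @examples
#' normalizeGeneId(c(" Cla4", "cdc28 "))
#' @export
normalizeGeneId <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x)))
    stop("empty gene identifier")
  if (any(grepl("[[:space:]]", x)))
    stop("gene identifier contains internal whitespace")
  x
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# canonical unordered edge key, used wherever edges are compared or sorted
edgeKey <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "|")
}
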
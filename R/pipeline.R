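#' Run the full temporal-network analysis
#'
#' Executes the headless pipeline end to end: read (or accept in-memory)
#' inputs, smooth each experiment, estimate each experiment's period, score
#' and call periodicity per gene, combine calls across experiments,
#' classify hubs and their regulatory classes, profile interface
#' competition, and export a frame stack. All randomness derives from
#' \code{seed}; rerunning with the same inputs and seed reproduces
#' byte-identical reports apart from the manifest timestamp line.
#'
#' @param network an \linkS4class{InteractionNetwork} or path to a network
#'   file ([readNetwork()]).
#' @param experiments named list of \linkS4class{ExpressionTimeCourse}
#'   objects or of file paths ([readExpression()]).
#' @param hubs data.frame with columns \code{hub} and \code{n_interfaces}.
#' @param outDir output directory, created if needed.
#' @param span smoothing span, default 0.5.
#' @param threshold default display threshold, default -0.2.
#' @param overrides named per-gene threshold overrides.
#' @param grid candidate periods in minutes.
#' @param nPerm,alpha,minAmplitude periodicity-call parameters.
#' @param seed master seed.
#' @param exportHub optional hub name; frames are exported for its 2-step
#'   ego network in every experiment (default: the whole network).
#' @return invisibly, a list with the classification table, verdicts,
#'   scores, competition table, tallies and the files written.
#' @export
runPipeline <- function(network, experiments, hubs, outDir,
                        span = 0.5, threshold = -0.2,
                        overrides = numeric(0),
                        grid = seq(40, 120, by = 1), nPerm = 1000L,
                        alpha = 0.05, minAmplitude = 0.2, seed = 1L,
                        exportHub = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  net <- stage("read", {
    if (is.character(network)) readNetwork(network) else network
  })
  exps <- stage("read", {
    lapply(experiments, function(e)
      if (is.character(e)) readExpression(e) else e)
  })
  stopifnot(is(net, "InteractionNetwork"), length(exps) >= 1L)

  smoothed <- stage("smooth", lapply(exps, smoothMatrix, span = span))

  calls <- stage("periodicity", periodicityCalls(
    exps, nPerm = nPerm, seed = seed, grid = grid, alpha = alpha,
    minAmplitude = minAmplitude))

  classification <- stage("classify",
    classifyHubs(net, calls$verdicts, hubs))
  tallies <- tabulateHubs(classification)

  competition <- stage("compete", do.call(rbind, unlist(lapply(
    names(smoothed), function(en) {
      mask <- activityMask(smoothed[[en]], threshold = threshold,
                           overrides = overrides)
      lapply(seq_len(nrow(classification)), function(i) {
        pr <- competitionProfile(classification$hub[i], net, mask,
                                 classification$n_interfaces[i])
        cbind(experiment = en, competitionTable(pr),
              stringsAsFactors = FALSE)
      })
    }), recursive = FALSE)))

  frameFiles <- stage("frames", vapply(names(smoothed), function(en) {
    mask <- activityMask(smoothed[[en]], threshold = threshold,
                         overrides = overrides)
    frameNet <- if (is.null(exportHub)) net
                else egoNetwork(net, exportHub, steps = 2L)
    f <- file.path(outDir, sprintf("frames_%s.jsonl", en))
    exportFrames(frameNet, mask, f, format = "json-lines")
    f
  }, ""))

  writeTsv <- function(d, name) {
    f <- file.path(outDir, name)
    num <- vapply(d, is.numeric, TRUE) & !vapply(d, is.integer, TRUE)
    d[num] <- lapply(d[num], function(x) sprintf("%.10g", x))
    write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    writeTsv(calls$scores, "periodicity_scores.tsv"),
    writeTsv(data.frame(gene = names(calls$verdicts),
                        verdict = unname(calls$verdicts),
                        stringsAsFactors = FALSE), "verdicts.tsv"),
    writeTsv(classification, "hub_classifications.tsv"),
    writeTsv(competition, "competition.tsv"),
    frameFiles)

  manifest <- file.path(outDir, "manifest.txt")
  writeLines(c(
    sprintf("# generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("cyclehubs_version\t%s",
            as.character(utils::packageVersion("cyclehubs"))),
    sprintf("seed\t%d", as.integer(seed)),
    sprintf("span\t%.10g", span),
    sprintf("threshold\t%.10g", threshold),
    sprintf("overrides\t%s", if (length(overrides))
      paste(names(overrides), overrides, sep = "=", collapse = ",")
      else "none"),
    sprintf("n_perm\t%d", as.integer(nPerm)),
    sprintf("alpha\t%.10g", alpha),
    sprintf("min_amplitude\t%.10g", minAmplitude),
    sprintf("period_grid\t%.10g..%.10g", min(grid), max(grid)),
    sprintf("experiments\t%s", paste(names(exps), collapse = ",")),
    sprintf("tallies\t%s", paste(names(tallies$table_class),
      tallies$table_class, sep = "=", collapse = ",")),
    sprintf("regulatory\t%s", paste(names(tallies$regulatory_class),
      tallies$regulatory_class, sep = "=", collapse = ","))),
    manifest)

  invisible(list(classification = classification,
                 verdicts = calls$verdicts, scores = calls$scores,
                 competition = competition, tallies = tallies,
                 files = c(files, manifest)))
}
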
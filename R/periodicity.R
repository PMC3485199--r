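#' Cosinor fit at a fixed period
#'
#' Least-squares fit of \code{x(t) = m + A * cos(2*pi*(t - phi) / T)} via the
#' linear reparameterization \code{m + b_c cos(2*pi*t/T) + b_s sin(2*pi*t/T)}.
#' The amplitude is the fitted cosine amplitude, i.e. half the peak-to-trough
#' swing; the phase is the peak time in \code{[0, T)} minutes.
#'
#' @param times numeric sampling times in minutes.
#' @param values numeric series (\code{NA} dropped).
#' @param period fixed period T in minutes.
#' @return list with \code{mesor}, \code{amplitude}, \code{phase},
#'   \code{r_squared} and \code{n} (points used). A constant series has
#'   amplitude 0 and \code{r_squared} 0.
#' @export
cosinorFit <- function(times, values, period) {
  keep <- !is.na(values)
  t <- times[keep]; y <- values[keep]
  n <- length(y)
  if (n < 3L)
    return(list(mesor = NA_real_, amplitude = NA_real_, phase = NA_real_,
                r_squared = NA_real_, n = n))
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  A <- sqrt(b[2L]^2 + b[3L]^2)
  phase <- (atan2(b[3L], b[2L]) / w) %% period
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-12) 0 else max(0, 1 - sum(fit$residuals^2) / tss)
  list(mesor = unname(b[1L]), amplitude = unname(A), phase = unname(phase),
       r_squared = r2, n = n)
}

# mean cosinor r^2 over the columns of Y (genes) at one period; Y has one
# row per timepoint and no missing values
.meanR2 <- function(times, Y, period) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  Q <- qr.Q(qr(X))
  fitted <- Q %*% crossprod(Q, Y)
  ctr <- sweep(Y, 2, colMeans(Y))
  tss <- colSums(ctr^2)
  rss <- colSums((Y - fitted)^2)
  mean(ifelse(tss < 1e-12, 0, 1 - rss / tss))
}

#' Estimate the shared cell-cycle period of one experiment
#'
#' Cells in a synchronization experiment share one division period, so the
#' period is estimated once per experiment, not per gene: for every
#' candidate period in \code{grid}, the mean cosinor \code{r^2} over all
#' usable genes is computed, and the maximizing period is returned (ties
#' broken toward the shorter period).
#'
#' A gene is usable when it has at least \code{minPoints} non-missing values
#' and non-zero variance. With no usable genes the estimate is impossible
#' and an error is raised.
#'
#' @param x an \linkS4class{ExpressionTimeCourse} (raw or smoothed).
#' @param grid candidate periods in minutes, default 40-120 min in 1-min
#'   steps (bracketing the yeast cell-cycle lengths of the usual
#'   synchronization protocols).
#' @param minPoints minimum non-missing points per usable gene.
#' @param minGenes genes below this count trigger a warning (the mean
#'   \code{r^2} is then noisy).
#' @return the estimated period in minutes.
#' @export
estimatePeriod <- function(x, grid = seq(40, 120, by = 1), minPoints = 8L,
                           minGenes = 5L) {
  stopifnot(is(x, "ExpressionTimeCourse"), length(grid) > 0)
  grid <- sort(grid)
  v <- exprValues(x)
  tt <- timePoints(x)
  usable <- apply(v, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) >= minPoints && var(r) > 0
  })
  if (!any(usable)) stop("no usable genes")
  if (sum(usable) < minGenes)
    warning(sprintf("only %d usable gene(s); period estimate may be unstable",
                    sum(usable)))
  v <- v[usable, , drop = FALSE]
  complete <- !anyNA(v)
  scores <- vapply(grid, function(Tc) {
    if (complete) {
      .meanR2(tt, t(v), Tc)
    } else {
      mean(vapply(seq_len(nrow(v)), function(i)
        cosinorFit(tt, v[i, ], Tc)$r_squared, 0))
    }
  }, 0)
  grid[which.max(scores)]
}

#' Score one gene for cell-cycle periodicity
#'
#' Cosinor fit at a fixed period plus a permutation test: the timepoint
#' labels are shuffled \code{nPerm} times under a fixed seed, the cosinor
#' \code{r^2} recomputed for each shuffle, and
#' \code{p = (1 + #\{r2_perm >= r2_obs\}) / (1 + nPerm)}. The permutation
#' p-value is invariant to adding a constant to the series and to positive
#' rescaling. A series with fewer than \code{minPoints} usable points, or
#' whose usable points span less than one full period, is marked unusable
#' rather than scored.
#'
#' @param times numeric sampling times in minutes.
#' @param values numeric series (\code{NA} = missing).
#' @param period fixed period T in minutes.
#' @param nPerm number of permutations, default 1000.
#' @param seed integer seed for the permutation stream (recorded in the
#'   result; the caller's RNG state is untouched).
#' @param minPoints usability floor on non-missing points, default 6.
#' @return one-row data.frame with columns \code{period}, \code{amplitude},
#'   \code{phase}, \code{mesor}, \code{r_squared}, \code{p_perm},
#'   \code{n_usable}, \code{usable}, \code{seed}.
#' @examples
#' t <- seq(0, 119, length.out = 18)
#' scoreGene(t, cos(2 * pi * t / 60), period = 60, nPerm = 99, seed = 1)
#' @export
scoreGene <- function(times, values, period, nPerm = 1000L, seed = 1L,
                      minPoints = 6L) {
  keep <- !is.na(values)
  tu <- times[keep]
  usable <- sum(keep) >= minPoints &&
    length(tu) > 0 && (max(tu) - min(tu)) >= period
  if (!usable)
    return(data.frame(period = period, amplitude = NA_real_,
                      phase = NA_real_, mesor = NA_real_,
                      r_squared = NA_real_, p_perm = NA_real_,
                      n_usable = sum(keep), usable = FALSE,
                      seed = as.integer(seed)))
  fit <- cosinorFit(times, values, period)
  y <- values[keep]
  n <- length(y)
  w <- 2 * pi / period
  X <- cbind(1, cos(w * tu), sin(w * tu))
  Q <- qr.Q(qr(X))
  tss <- sum((y - mean(y))^2)
  pPerm <- withLocalSeed(seed, {
    hits <- 0L
    for (k in seq_len(nPerm)) {
      yp <- y[sample.int(n)]
      rss <- sum((yp - Q %*% crossprod(Q, yp))^2)
      r2p <- if (tss < 1e-12) 0 else max(0, 1 - rss / tss)
      if (r2p >= fit$r_squared) hits <- hits + 1L
    }
    (1 + hits) / (1 + nPerm)
  })
  data.frame(period = period, amplitude = fit$amplitude, phase = fit$phase,
             mesor = fit$mesor, r_squared = fit$r_squared, p_perm = pPerm,
             n_usable = n, usable = TRUE, seed = as.integer(seed))
}

#' Score every gene of one experiment
#'
#' Runs [scoreGene()] on each row of an experiment at a shared period,
#' deriving one deterministic permutation seed per gene from \code{seed}
#' (seed + row index).
#'
#' @param x an \linkS4class{ExpressionTimeCourse}; periodicity is assessed
#'   on the series stored in \code{x} (the pipeline scores the raw
#'   measurements, keeping amplitudes on the data scale).
#' @param period shared period in minutes; \code{NULL} estimates it with
#'   [estimatePeriod()].
#' @param nPerm,seed,minPoints passed to [scoreGene()].
#' @param grid candidate periods when \code{period} is \code{NULL}.
#' @return data.frame with one row per gene (columns of [scoreGene()] plus
#'   \code{gene} and \code{experiment}).
#' @export
scoreExperiment <- function(x, period = NULL, nPerm = 1000L, seed = 1L,
                            minPoints = 6L, grid = seq(40, 120, by = 1)) {
  stopifnot(is(x, "ExpressionTimeCourse"))
  if (is.null(period)) period <- estimatePeriod(x, grid = grid)
  v <- exprValues(x)
  tt <- timePoints(x)
  rows <- lapply(seq_len(nrow(v)), function(i)
    scoreGene(tt, v[i, ], period, nPerm = nPerm,
              seed = as.integer(seed) + i, minPoints = minPoints))
  out <- do.call(rbind, rows)
  cbind(gene = rownames(v), experiment = experimentId(x), out,
        stringsAsFactors = FALSE)
}

#' Call one scored gene periodic or aperiodic
#'
#' A gene is periodic when the permutation p-value passes \code{alpha}
#' \emph{and} the fitted amplitude reaches \code{minAmplitude} (log2 units).
#' The amplitude floor mirrors the published rendering practice: a hub whose
#' expression peak amplitude stayed under 0.2 could not be displayed at the
#' default threshold and needed special handling, so sub-floor oscillations
#' are not trusted as periodicity. Unusable scores pass through.
#'
#' @param score a one-row data.frame from [scoreGene()] (or a row of
#'   [scoreExperiment()] output).
#' @param alpha significance level for the permutation test, default 0.05.
#' @param minAmplitude fitted-amplitude floor in log2 units, default 0.2.
#' @return \code{"periodic"}, \code{"aperiodic"} or \code{"unusable"}.
#' @export
callGene <- function(score, alpha = 0.05, minAmplitude = 0.2) {
  if (!isTRUE(score$usable)) return("unusable")
  if (score$p_perm <= alpha && score$amplitude >= minAmplitude)
    "periodic" else "aperiodic"
}

#' Combine per-experiment calls into one verdict
#'
#' Among the usable experiments a strict majority of periodic calls gives
#' \code{"periodic"}, a strict majority of aperiodic calls gives
#' \code{"aperiodic"}; a tie -- the published situation of expression
#' "inconsistent between conditions" -- or fewer than two usable experiments
#' gives \code{"unclassifiable"}. The rule is symmetric in experiment order.
#'
#' @param calls character vector of per-experiment calls
#'   (\code{periodic} / \code{aperiodic} / \code{unusable}).
#' @return \code{"periodic"}, \code{"aperiodic"} or \code{"unclassifiable"}.
#' @examples
#' combineCalls(c("periodic", "periodic", "aperiodic"))
#' combineCalls(c("periodic", "aperiodic"))
#' @export
combineCalls <- function(calls) {
  stopifnot(length(calls) >= 1L,
            all(calls %in% c("periodic", "aperiodic", "unusable")))
  u <- calls[calls != "unusable"]
  if (length(u) < 2L) return("unclassifiable")
  np <- sum(u == "periodic")
  na <- sum(u == "aperiodic")
  if (np > na) "periodic" else if (na > np) "aperiodic" else "unclassifiable"
}

#' Periodicity calls across synchronization experiments
#'
#' Scores every gene in every experiment ([scoreExperiment()]), calls each
#' gene per experiment ([callGene()]) and combines the calls
#' ([combineCalls()]). Genes absent from an experiment count as unusable
#' there.
#'
#' @param experiments list of \linkS4class{ExpressionTimeCourse} objects
#'   (raw measurements; see [scoreExperiment()]).
#' @param period optional numeric vector of fixed periods, one per
#'   experiment; \code{NULL} estimates each.
#' @param nPerm,seed,minPoints,grid see [scoreExperiment()].
#' @param alpha,minAmplitude see [callGene()].
#' @return list with \code{scores} (long data.frame of all per-experiment
#'   scores and calls) and \code{verdicts} (named character vector of
#'   combined per-gene verdicts).
#' @export
periodicityCalls <- function(experiments, period = NULL, nPerm = 1000L,
                             seed = 1L, minPoints = 6L,
                             grid = seq(40, 120, by = 1), alpha = 0.05,
                             minAmplitude = 0.2) {
  stopifnot(length(experiments) >= 1L)
  scores <- do.call(rbind, lapply(seq_along(experiments), function(j) {
    x <- experiments[[j]]
    s <- scoreExperiment(x, period = period[j], nPerm = nPerm,
                         seed = as.integer(seed) + 10000L * j,
                         minPoints = minPoints, grid = grid)
    s$call <- vapply(seq_len(nrow(s)), function(i)
      callGene(s[i, ], alpha = alpha, minAmplitude = minAmplitude), "")
    s
  }))
  genes <- sort(unique(scores$gene))
  verdicts <- vapply(genes, function(g) {
    present <- scores$call[scores$gene == g]
    absent <- rep("unusable", length(experiments) - length(present))
    combineCalls(c(present, absent))
  }, "")
  list(scores = scores, verdicts = verdicts)
}
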
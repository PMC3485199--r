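#' Locally weighted linear smoothing of one time course
#'
#' Degree-1 local regression with tricube weights, the smoothing family the
#' field applies to synchronized-culture time courses before rendering.
#' At each observed timepoint the fit uses the \code{q = ceiling(span * n)}
#' nearest non-missing neighbours (minimum 2; ties in distance broken toward
#' the earlier time), weighted by \code{(1 - (d/dmax)^3)^3}, and the smoothed
#' value is the local intercept. Evaluation happens only at the observed
#' timepoints; there is no interpolation grid and no robustness iteration.
#' Missing observations are excluded from every local fit and stay missing
#' in the output.
#'
#' @param times numeric sampling times in minutes.
#' @param values numeric series, \code{NA} for missing.
#' @param span fraction of non-missing points in each local window,
#'   in (0, 1].
#' @return a list with \code{values} (smoothed series, \code{NA} where the
#'   input was missing or the series is unsmoothable) and
#'   \code{unsmoothable} (TRUE when fewer than 4 non-missing points exist or
#'   the window would hold fewer than 2 points). An unsmoothable series is a
#'   flag, not an error: it propagates to an unclassifiable verdict
#'   downstream.
#' @examples
#' t <- seq(0, 119, length.out = 18)
#' smoothSeries(t, cos(2 * pi * t / 66) + rnorm(18, 0, 0.1))
#' @export
smoothSeries <- function(times, values, span = 0.5) {
  stopifnot(length(times) == length(values), span > 0, span <= 1)
  out <- rep(NA_real_, length(values))
  obs <- which(!is.na(values))
  n <- length(obs)
  if (n < 4L || span * n < 2)
    return(list(values = out, unsmoothable = TRUE))
  q <- max(2L, ceiling(span * n))
  to <- times[obs]
  yo <- values[obs]
  for (i in obs) {
    d <- abs(to - times[i])
    sel <- order(d, to)[seq_len(q)]
    dmax <- max(d[sel])
    w <- (1 - (d[sel] / dmax)^3)^3
    x <- to[sel] - times[i]
    sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * yo[sel]) / sw
    sxx <- sum(w * (x - mx)^2)
    out[i] <- if (sxx > .Machine$double.eps * sw * max(1, max(abs(x))^2)) {
      b <- sum(w * (x - mx) * (yo[sel] - my)) / sxx
      my - b * mx
    } else {
      my  # degenerate window: fall back to the weighted mean
    }
  }
  list(values = out, unsmoothable = FALSE)
}

#' Smooth every gene of an experiment
#'
#' Applies [smoothSeries()] row-wise to an \linkS4class{ExpressionTimeCourse}.
#' Genes failing the smoothing precondition become all-missing rows and are
#' flagged unsmoothable (reported with a warning naming each gene).
#'
#' @param x an \linkS4class{ExpressionTimeCourse}.
#' @param span local window fraction, default 0.5.
#' @return a \linkS4class{SmoothedTimeCourse}.
#' @export
smoothMatrix <- function(x, span = 0.5) {
  stopifnot(is(x, "ExpressionTimeCourse"))
  v <- exprValues(x)
  tt <- timePoints(x)
  sm <- v
  flag <- logical(nrow(v))
  names(flag) <- rownames(v)
  for (i in seq_len(nrow(v))) {
    r <- smoothSeries(tt, v[i, ], span = span)
    sm[i, ] <- r$values
    flag[i] <- r$unsmoothable
  }
  if (any(flag))
    warning("unsmoothable gene(s): ", paste(names(flag)[flag],
            collapse = ", "))
  miss <- missingMask(x) | is.na(sm)
  se <- expressionTimeCourse(sm, tt, experimentId(x), missing = miss)
  new("SmoothedTimeCourse", se, span = span, unsmoothable = flag)
}
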
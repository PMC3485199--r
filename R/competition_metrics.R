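#' Interface-competition profile of a hub
#'
#' At each sampled timepoint, counts the hub's direct interaction partners
#' that are active in the mask and compares the count with the hub's number
#' of interaction interfaces. Partners beyond the available interfaces
#' (\code{excess}) must bind mutually exclusively, i.e. compete. Which
#' partner binds through which interface is structurally unresolved, so all
#' partners are treated as competing for all interfaces. The hub's own
#' activity never gates the partner count, but a realized-competition
#' summary restricted to hub-active times is reported alongside (partners
#' can only compete for an interface that is present).
#'
#' @param hub hub gene symbol.
#' @param network an \linkS4class{InteractionNetwork} containing the hub.
#' @param mask an \linkS4class{ActivityMask}; partners or hubs absent from
#'   the mask count as inactive.
#' @param nInterfaces 1 or 2.
#' @return a \linkS4class{CompetitionProfile}. A hub with no partners
#'   yields an all-zero profile.
#' @export
competitionProfile <- function(hub, network, mask, nInterfaces) {
  stopifnot(is(network, "InteractionNetwork"), is(mask, "ActivityMask"),
            nInterfaces %in% 1:2)
  hub <- normalizeGeneId(hub)
  partners <- hubPartners(network, hub)
  act <- activeMatrix(mask)
  nT <- length(mask@times)
  partnerAct <- matrix(FALSE, length(partners), nT)
  present <- partners %in% rownames(act)
  if (any(present))
    partnerAct[present, ] <- act[partners[present], , drop = FALSE]
  count <- as.integer(colSums(partnerAct))
  excess <- as.integer(pmax(0L, count - as.integer(nInterfaces)))
  hubActive <- if (hub %in% rownames(act)) act[hub, ] else rep(FALSE, nT)
  new("CompetitionProfile", hub = hub, partners = partners,
      times = mask@times, nInterfaces = as.integer(nInterfaces),
      activeCount = count, excess = excess,
      hubActive = as.logical(hubActive),
      maxSimultaneous = as.integer(max(c(0L, count))),
      fractionTimeCompetitive = mean(excess > 0L),
      realizedFractionCompetitive = mean(excess > 0L & hubActive))
}

#' Competition profile as a per-time table
#'
#' @param profile a \linkS4class{CompetitionProfile}.
#' @return data.frame with columns \code{hub}, \code{time},
#'   \code{active_partner_count}, \code{excess}, \code{hub_active}.
#' @export
competitionTable <- function(profile) {
  stopifnot(is(profile, "CompetitionProfile"))
  data.frame(hub = profile@hub, time = profile@times,
             active_partner_count = profile@activeCount,
             excess = profile@excess, hub_active = profile@hubActive,
             stringsAsFactors = FALSE)
}

#' Pairwise temporal overlap of partner activity
#'
#' Jaccard index of the active-timepoint index sets for every pair of
#' partners. Identically active partners score 1, partners active at
#' disjoint times score 0; pairs where both partners are never active score
#' 0 and are flagged. The staggered score is the mean off-diagonal Jaccard.
#'
#' @param mask an \linkS4class{ActivityMask}.
#' @param partners at least two partner gene symbols; partners absent from
#'   the mask have empty activity sets.
#' @return an \linkS4class{OverlapMatrix}.
#' @export
partnerOverlap <- function(mask, partners) {
  stopifnot(is(mask, "ActivityMask"))
  partners <- normalizeGeneId(partners)
  if (length(partners) < 2L) stop("need at least 2 partners")
  act <- activeMatrix(mask)
  sets <- lapply(partners, function(p)
    if (p %in% rownames(act)) which(act[p, ]) else integer(0))
  k <- length(partners)
  jac <- matrix(0, k, k, dimnames = list(partners, partners))
  empty <- matrix(FALSE, k, k, dimnames = list(partners, partners))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ni <- length(union(sets[[i]], sets[[j]]))
    if (ni == 0L) {
      empty[i, j] <- TRUE
    } else {
      jac[i, j] <- length(intersect(sets[[i]], sets[[j]])) / ni
    }
  }
  new("OverlapMatrix", jaccard = jac, bothEmpty = empty,
      staggeredScore = mean(jac[upper.tri(jac)]))
}

#' Flag a staggered partner set
#'
#' Partners whose expression peaks are staggered overlap little in time,
#' which reduces competition for the hub interface. The set is flagged
#' staggered when the mean pairwise Jaccard falls below \code{cutoff}.
#'
#' @param overlap an \linkS4class{OverlapMatrix}.
#' @param cutoff staggered-score cutoff in [0, 1], default 0.5 (no published
#'   number exists; the cutoff is configuration-exposed).
#' @return logical.
#' @export
flagStaggered <- function(overlap, cutoff = 0.5) {
  stopifnot(is(overlap, "OverlapMatrix"))
  staggeredScore(overlap) < cutoff
}
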
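#' Classify a hub from its own verdict and its partners'
#'
#' The published rule set: a hub with periodic expression throughout the
#' cell cycle is \code{Dynamic}; a hub with non-periodic expression and at
#' least one periodic interaction partner is \code{Static}; a hub with
#' missing or low-quality expression data is \code{not_classified}. The
#' published definition is silent about aperiodic hubs whose every partner
#' is also aperiodic; these are reported as \code{unassigned} and excluded
#' from the competitive / non-competitive tallies.
#'
#' @param hubVerdict combined verdict for the hub
#'   (\code{periodic} / \code{aperiodic} / \code{unclassifiable}), as from
#'   [combineCalls()].
#' @param partnerVerdicts character vector of combined verdicts of the
#'   hub's direct (1-step) interaction partners.
#' @return one of \code{"Dynamic"}, \code{"Static"}, \code{"unassigned"},
#'   \code{"not_classified"}.
#' @examples
#' classifyHub("aperiodic", c("aperiodic", "periodic"))  # Static
#' @export
classifyHub <- function(hubVerdict, partnerVerdicts = character(0)) {
  stopifnot(hubVerdict %in% c("periodic", "aperiodic", "unclassifiable"))
  switch(hubVerdict,
    periodic = "Dynamic",
    aperiodic = if (any(partnerVerdicts == "periodic")) "Static"
                else "unassigned",
    unclassifiable = "not_classified")
}

#' Regulatory class of a classified hub
#'
#' A \code{Dynamic} hub with at least one aperiodic (constitutively
#' expressed) partner is \code{competitive}: its partners are co-present
#' whenever the hub appears and must compete for its interface(s). A
#' \code{Static} hub is \code{non_competitive}: its dynamic partners are
#' expressed at regulated times, lessening interface competition. A dynamic
#' hub whose every partner is also periodic is co-ordinately regulated and
#' gets \code{none}, as do unassigned and unclassified hubs.
#'
#' @param tableClass hub class from [classifyHub()].
#' @param nAperiodicPartners number of partners with a combined aperiodic
#'   verdict.
#' @return \code{"competitive"}, \code{"non_competitive"} or \code{"none"}.
#' @export
regulatoryClass <- function(tableClass, nAperiodicPartners) {
  stopifnot(tableClass %in% c("Dynamic", "Static", "unassigned",
                              "not_classified"))
  if (tableClass == "Dynamic" && nAperiodicPartners >= 1L) "competitive"
  else if (tableClass == "Static") "non_competitive"
  else "none"
}

#' Classify a cohort of hubs against a network and per-gene verdicts
#'
#' For each hub, takes its direct (1-step) partners from the network --
#' classification uses direct interaction partners only, the wider 2-step
#' neighbourhood being rendering context -- counts partner verdicts, and
#' applies [classifyHub()] and [regulatoryClass()]. Partners without a
#' verdict count as unclassifiable.
#'
#' @param network an \linkS4class{InteractionNetwork} containing the hubs.
#' @param verdicts named character vector of combined per-gene verdicts
#'   (e.g. \code{periodicityCalls(...)$verdicts}).
#' @param hubs data.frame with columns \code{hub} and \code{n_interfaces}
#'   (1 or 2).
#' @return data.frame with one row per hub: \code{hub},
#'   \code{n_interfaces}, \code{hub_verdict}, \code{n_partners},
#'   \code{n_periodic_partners}, \code{n_aperiodic_partners},
#'   \code{n_unclassifiable_partners}, \code{table_class},
#'   \code{regulatory_class}; rows sorted by hub.
#' @export
classifyHubs <- function(network, verdicts, hubs) {
  stopifnot(is(network, "InteractionNetwork"),
            all(c("hub", "n_interfaces") %in% colnames(hubs)),
            all(hubs$n_interfaces %in% 1:2))
  hubs$hub <- normalizeGeneId(hubs$hub)
  if (anyDuplicated(hubs$hub))
    stop("duplicate hub: ", hubs$hub[duplicated(hubs$hub)][1L])
  verdictOf <- function(g) {
    v <- unname(verdicts[g])
    v[is.na(v)] <- "unclassifiable"
    v
  }
  rows <- lapply(order(hubs$hub), function(i) {
    h <- hubs$hub[i]
    partners <- hubPartners(network, h)
    pv <- verdictOf(partners)
    hv <- verdictOf(h)
    tc <- classifyHub(hv, pv)
    data.frame(hub = h, n_interfaces = as.integer(hubs$n_interfaces[i]),
               hub_verdict = hv, n_partners = length(partners),
               n_periodic_partners = sum(pv == "periodic"),
               n_aperiodic_partners = sum(pv == "aperiodic"),
               n_unclassifiable_partners = sum(pv == "unclassifiable"),
               table_class = tc,
               regulatory_class = regulatoryClass(tc,
                 sum(pv == "aperiodic")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tabulate hub classifications
#'
#' Exact integer counts per hub class and per regulatory class, in a fixed
#' report order. Accepts either a full [classifyHubs()] result or any
#' data.frame with \code{hub} and \code{table_class} columns (published
#' annotations use \code{"missing"} for hubs shown with a hyphen; these
#' count as \code{not_classified}).
#'
#' @param classifications data.frame with one row per hub.
#' @return list with \code{table_class} (named integer vector: Dynamic,
#'   Static, unassigned, not_classified, total) and \code{regulatory_class}
#'   (competitive, non_competitive, none; all-NA column yields zeros).
#' @examples
#' tabulateHubs(loadTable1Hubs())
#' @export
tabulateHubs <- function(classifications) {
  stopifnot(is.data.frame(classifications))
  tcCol <- if ("table_class" %in% colnames(classifications))
    "table_class" else "table1_class"
  stopifnot(tcCol %in% colnames(classifications),
            "hub" %in% colnames(classifications))
  if (anyDuplicated(classifications$hub))
    stop("duplicate hub: ",
         classifications$hub[duplicated(classifications$hub)][1L])
  tc <- classifications[[tcCol]]
  tc[tc %in% c("missing", "-")] <- "not_classified"
  stopifnot(all(tc %in% c("Dynamic", "Static", "unassigned",
                          "not_classified")))
  tcLevels <- c("Dynamic", "Static", "unassigned", "not_classified")
  tcCounts <- vapply(tcLevels, function(l) sum(tc == l), 0L)
  tcCounts <- c(tcCounts, total = length(tc))
  rcLevels <- c("competitive", "non_competitive", "none")
  rc <- classifications$regulatory_class
  rcCounts <- if (is.null(rc)) stats::setNames(rep(0L, 3), rcLevels)
    else vapply(rcLevels, function(l) sum(rc == l, na.rm = TRUE), 0L)
  list(table_class = tcCounts, regulatory_class = rcCounts)
}
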
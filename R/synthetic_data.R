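#' Configuration for the synchronized-culture simulator
#'
#' Defines the study conditions the generator emulates. The default
#' sampling grids copy the three classical synchronization experiments
#' (alpha-factor: 18 points over 119 min; cdc15-2: 24 points over 290 min;
#' Cdc28: 17 points over 160 min); the default period is 66 min, within the
#' implicit cell-cycle length of those protocols. Amplitudes, noise and
#' baselines are on the log2-ratio scale, with baselines near 0 so the
#' -0.2 display threshold stays meaningful.
#'
#' Hub kinds: \code{dynamic_competitive} (periodic hub, constitutively
#' expressed partners), \code{static_noncompetitive} (flat hub, at least one
#' periodic partner with staggered phases), \code{coordinate} (hub and
#' partners co-phased periodic) and \code{stochastic} (hub and partners
#' follow per-experiment independent random walks, emulating the noisy /
#' condition-inconsistent expression that defeats classification).
#'
#' @param seed integer master seed; all generator randomness derives from
#'   it.
#' @param experiments named list of \code{c(duration, n_points)} pairs.
#' @param periodT shared cell-cycle period in minutes.
#' @param amplitudeRange \code{c(min, max)} of per-gene cosine amplitudes.
#' @param noiseSd independent Gaussian measurement noise, log2 units.
#' @param baselineRange \code{c(min, max)} of per-gene baselines (mesors).
#' @param nBackgroundGenes number of non-hub, non-partner genes.
#' @param backgroundPeriodicFraction fraction of background genes that are
#'   periodic (the rest are flat).
#' @param hubSpecs data.frame with columns \code{kind}, \code{nInterfaces},
#'   \code{nPartners}; the default cohort carries 10 hubs covering all four
#'   kinds, for 100 genes total with the default background.
#' @param crossLinkProb probability of an extra edge between any two genes
#'   beyond the hub stars.
#' @param walkStepSd per-step standard deviation of the stochastic random
#'   walk, log2 units.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(
    seed = 7L,
    experiments = list(alpha = c(119, 18), cdc15 = c(290, 24),
                       cdc28 = c(160, 17)),
    periodT = 66,
    amplitudeRange = c(0.4, 1.0),
    noiseSd = 0.15,
    baselineRange = c(-0.05, 0.05),
    nBackgroundGenes = 44L,
    backgroundPeriodicFraction = 0.3,
    hubSpecs = data.frame(
      kind = c(rep("dynamic_competitive", 3), rep("static_noncompetitive", 3),
               rep("coordinate", 2), rep("stochastic", 2)),
      nInterfaces = c(2L, 1L, 2L, 2L, 1L, 2L, 1L, 2L, 2L, 1L),
      nPartners = c(5L, 5L, 5L, 5L, 5L, 5L, 4L, 4L, 4L, 4L),
      stringsAsFactors = FALSE),
    crossLinkProb = 0.02,
    walkStepSd = 0.08) {
  stopifnot(length(experiments) >= 1L,
            all(vapply(experiments, function(e) e[1] > 0 && e[2] >= 6, TRUE)),
            periodT > 0, noiseSd >= 0, walkStepSd >= 0,
            nrow(hubSpecs) >= 1L,
            all(hubSpecs$kind %in% c("dynamic_competitive",
              "static_noncompetitive", "coordinate", "stochastic")),
            all(hubSpecs$nInterfaces %in% 1:2),
            all(hubSpecs$nPartners >= 1L),
            nBackgroundGenes >= 0L, crossLinkProb >= 0, crossLinkProb <= 1)
  structure(list(seed = as.integer(seed), experiments = experiments,
                 periodT = periodT, amplitudeRange = amplitudeRange,
                 noiseSd = noiseSd, baselineRange = baselineRange,
                 nBackgroundGenes = as.integer(nBackgroundGenes),
                 backgroundPeriodicFraction = backgroundPeriodicFraction,
                 hubSpecs = hubSpecs,
                 crossLinkProb = crossLinkProb, walkStepSd = walkStepSd),
            class = "SimulationConfig")
}

# intended classes per hub kind
.intendedClasses <- function(kind) {
  switch(kind,
    dynamic_competitive = c("Dynamic", "competitive"),
    static_noncompetitive = c("Static", "non_competitive"),
    coordinate = c("Dynamic", "none"),
    stochastic = c("not_classified", "none"))
}

#' Simulate hub/partner network topology
#'
#' Each hub gets its stated number of dedicated partners (a star); every
#' background gene attaches to one uniformly chosen earlier node, keeping
#' the graph connected to the hub components; extra cross-links appear
#' between random gene pairs with probability \code{crossLinkProb}. Fully
#' deterministic under the config seed.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{network} (\linkS4class{InteractionNetwork}) and
#'   \code{truth} (data.frame: \code{gene}, \code{role}, \code{hub},
#'   \code{kind}, \code{intended_table_class},
#'   \code{intended_regulatory_class}).
#' @export
simulateNetwork <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  hs <- config$hubSpecs
  nHub <- nrow(hs)
  hubNames <- sprintf("HUB%02d", seq_len(nHub))
  partnerNames <- lapply(seq_len(nHub), function(i)
    sprintf("%sP%02d", hubNames[i], seq_len(hs$nPartners[i])))
  bgNames <- if (config$nBackgroundGenes > 0)
    sprintf("BG%03d", seq_len(config$nBackgroundGenes)) else character(0)
  allGenes <- c(hubNames, unlist(partnerNames), bgNames)
  if (anyDuplicated(allGenes)) stop("infeasible spec: name collision")
  edges <- do.call(rbind, lapply(seq_len(nHub), function(i)
    cbind(hubNames[i], partnerNames[[i]])))
  withLocalSeed(config$seed, {
    # the background periphery attaches to the partner shell (never to a
    # hub directly, so each hub's neighbourhood stays its dedicated
    # partners and the ground-truth classes remain well defined)
    shell <- unlist(partnerNames)
    for (b in bgNames) {
      pool <- c(shell, bgNames[bgNames < b])
      edges <- rbind(edges, c(sample(pool, 1L), b))
    }
    nBg <- length(bgNames)
    if (nBg >= 2L) {
      pairs <- which(upper.tri(matrix(0, nBg, nBg)), arr.ind = TRUE)
      pick <- stats::runif(nrow(pairs)) < config$crossLinkProb
      if (any(pick))
        edges <- rbind(edges, cbind(bgNames[pairs[pick, 1L]],
                                    bgNames[pairs[pick, 2L]]))
    }
  })
  net <- interactionNetwork(edges, nodes = allGenes, warnDropped = FALSE)
  role <- c(rep("hub", nHub),
            rep("partner", length(unlist(partnerNames))),
            rep("background", length(bgNames)))
  ofHub <- c(hubNames, rep(hubNames, hs$nPartners), rep(NA, length(bgNames)))
  kind <- c(hs$kind, rep(hs$kind, hs$nPartners), rep(NA, length(bgNames)))
  intended <- t(vapply(hs$kind, .intendedClasses, c("", "")))
  truth <- data.frame(gene = allGenes, role = role, hub = ofHub,
                      kind = kind, stringsAsFactors = FALSE)
  truth$intended_table_class <- NA_character_
  truth$intended_regulatory_class <- NA_character_
  truth$intended_table_class[seq_len(nHub)] <- intended[, 1L]
  truth$intended_regulatory_class[seq_len(nHub)] <- intended[, 2L]
  list(network = net, truth = truth)
}

# cosine model shared by the generators
.cosine <- function(t, m, A, phi, T) m + A * cos(2 * pi * (t - phi) / T)

#' Simulate synchronized-culture expression with ground truth
#'
#' Periodic genes follow \code{x(t) = m + A cos(2 pi (t - phi)/T) + e},
#' \code{e ~ N(0, noiseSd^2)}, with amplitude, phase and baseline drawn once
#' per gene and shared across experiments (a synchronized culture has one
#' oscillator); static genes are \code{m + e}; stochastic genes follow a
#' random walk realized independently in every experiment, which is what
#' makes their calls inconsistent between conditions. Gene models follow
#' the hub kinds of the network truth: dynamic_competitive hubs are
#' periodic with static partners; static_noncompetitive hubs are static
#' with ceiling(half) of their partners periodic at staggered phases;
#' coordinate hubs and partners are co-phased periodic; stochastic hubs and
#' partners are random walks.
#'
#' @param sim result of [simulateNetwork()].
#' @param config the same [simulationConfig()].
#' @return list with \code{experiments} (named list of
#'   \linkS4class{ExpressionTimeCourse}) and \code{truth} (the network truth
#'   extended with \code{label} in \{periodic, static, stochastic\} and the
#'   generating \code{amplitude}, \code{phase}, \code{baseline}).
#' @export
simulateExpression <- function(sim, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  truth <- sim$truth
  n <- nrow(truth)
  withLocalSeed(config$seed + 1L, {
    label <- character(n)
    A <- stats::runif(n, config$amplitudeRange[1L], config$amplitudeRange[2L])
    phi <- stats::runif(n, 0, config$periodT)
    m <- stats::runif(n, config$baselineRange[1L], config$baselineRange[2L])
    for (i in seq_len(n)) {
      label[i] <- switch(truth$role[i],
        hub = switch(truth$kind[i],
          dynamic_competitive = , coordinate = "periodic",
          static_noncompetitive = "static",
          stochastic = "stochastic"),
        partner = switch(truth$kind[i],
          dynamic_competitive = "static",
          static_noncompetitive = NA_character_,  # assigned per hub below
          coordinate = "periodic",
          stochastic = "stochastic"),
        background = NA_character_)
    }
    # staggered periodic partners of static hubs: first ceiling(half)
    for (h in unique(truth$hub[!is.na(truth$hub)])) {
      idx <- which(truth$role == "partner" & truth$hub == h)
      if (!length(idx)) next
      kind <- truth$kind[idx[1L]]
      if (kind == "static_noncompetitive") {
        nPer <- ceiling(length(idx) / 2)
        per <- idx[seq_len(nPer)]
        label[per] <- "periodic"
        label[idx[-seq_len(nPer)]] <- "static"
        phi[per] <- (phi[idx[1L]] +
          (seq_len(nPer) - 1L) * config$periodT / nPer) %% config$periodT
      } else if (kind == "coordinate") {
        # co-phased with the hub
        phi[idx] <- phi[match(h, truth$gene)]
      }
    }
    bg <- which(truth$role == "background")
    if (length(bg)) {
      nPer <- round(config$backgroundPeriodicFraction * length(bg))
      label[bg] <- c(rep("periodic", nPer),
                     rep("static", length(bg) - nPer))
    }
    A[label != "periodic"] <- 0
    # intended classes recomputed from the realized topology and labels, so
    # the ground truth is self-consistent whatever the wiring produced
    hubRows <- which(truth$role == "hub")
    for (i in hubRows) {
      partners <- hubPartners(sim$network, truth$gene[i])
      pl <- label[match(partners, truth$gene)]
      cls <- switch(label[i],
        periodic = c("Dynamic",
          if (any(pl == "static")) "competitive" else "none"),
        static = if (any(pl == "periodic"))
          c("Static", "non_competitive") else c("unassigned", "none"),
        stochastic = c("not_classified", "none"))
      truth$intended_table_class[i] <- cls[1L]
      truth$intended_regulatory_class[i] <- cls[2L]
    }
    experiments <- lapply(names(config$experiments), function(en) {
      e <- config$experiments[[en]]
      tt <- seq(0, e[1L], length.out = e[2L])
      vals <- matrix(NA_real_, n, length(tt),
                     dimnames = list(truth$gene, NULL))
      for (i in seq_len(n)) {
        vals[i, ] <- switch(label[i],
          periodic = .cosine(tt, m[i], A[i], phi[i], config$periodT) +
            stats::rnorm(length(tt), 0, config$noiseSd),
          static = m[i] + stats::rnorm(length(tt), 0, config$noiseSd),
          stochastic = m[i] +
            cumsum(stats::rnorm(length(tt), 0, config$walkStepSd)))
      }
      expressionTimeCourse(vals, tt, en)
    })
    names(experiments) <- names(config$experiments)
    truth$label <- label
    truth$amplitude <- A
    truth$phase <- phi
    truth$baseline <- m
    list(experiments = experiments, truth = truth)
  })
}

#' Simulate a complete analysis bundle
#'
#' Convenience wrapper: [simulateNetwork()] then [simulateExpression()].
#'
#' @param config a [simulationConfig()].
#' @return list with \code{network}, \code{experiments}, \code{truth}.
#' @examples
#' bundle <- simulateBundle(simulationConfig(seed = 1))
#' bundle$network
#' @export
simulateBundle <- function(config = simulationConfig()) {
  sim <- simulateNetwork(config)
  expr <- simulateExpression(sim, config)
  list(network = sim$network, experiments = expr$experiments,
       truth = expr$truth)
}

#' Generate partner series with staggered troughs
#'
#' Builds \code{n} periodic partner series whose troughs are evenly
#' phase-shifted by \code{T/n}, emulating structural-hub partners that are
#' downregulated one cell-cycle apart. Amplitude 1 with baseline -0.3 keeps
#' each series above the -0.2 display threshold for slightly less than half
#' of the cycle, so the pairwise active-time overlap is low by
#' construction.
#'
#' @param n number of partners, at least 2.
#' @param config a [simulationConfig()] supplying period, noise and time
#'   grid (first experiment).
#' @param times optional explicit time grid in minutes.
#' @return numeric matrix (rows \code{PART01..}), with attributes
#'   \code{times} and \code{phases}.
#' @export
makeStaggeredPartners <- function(n, config = simulationConfig(),
                                  times = NULL) {
  stopifnot(n >= 2L, inherits(config, "SimulationConfig"))
  if (is.null(times)) {
    e <- config$experiments[[1L]]
    times <- seq(0, e[1L], length.out = e[2L])
  }
  phases <- (seq_len(n) - 1L) * config$periodT / n
  withLocalSeed(config$seed + 2L, {
    rows <- t(vapply(phases, function(p)
      .cosine(times, -0.3, 1, p, config$periodT) +
        stats::rnorm(length(times), 0, config$noiseSd),
      numeric(length(times))))
  })
  rownames(rows) <- sprintf("PART%02d", seq_len(n))
  attr(rows, "times") <- times
  attr(rows, "phases") <- phases
  rows
}

#' Write a simulated bundle to disk
#'
#' Writes one expression TSV per experiment, the network as SIF, and the
#' ground truth as TSV, in the formats the readers accept.
#'
#' @param bundle result of [simulateBundle()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
writeSimulation <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(names(bundle$experiments), function(en) {
    f <- file.path(dir, paste0("expression_", en, ".tsv"))
    writeExpression(bundle$experiments[[en]], f)
    f
  }, "")
  netFile <- file.path(dir, "network.sif")
  writeNetwork(bundle$network, netFile)
  truthFile <- file.path(dir, "truth.tsv")
  write.table(bundle$truth, truthFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(files, netFile, truthFile))
}
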
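test_that("hub classification follows the published footnote rules", {
  # periodic expression throughout the cycle: Dynamic, whatever the partners
  expect_identical(classifyHub("periodic", c("periodic", "aperiodic")),
                   "Dynamic")
  expect_identical(classifyHub("periodic", character(0)), "Dynamic")
  # non-periodic with at least one periodic partner: Static
  expect_identical(
    classifyHub("aperiodic", c(rep("aperiodic", 5), "periodic")), "Static")
  # non-periodic with no periodic partner falls outside the published rule
  expect_identical(classifyHub("aperiodic", rep("aperiodic", 4)),
                   "unassigned")
  # missing or low-quality data: not classified
  expect_identical(classifyHub("unclassifiable", rep("periodic", 3)),
                   "not_classified")
})

test_that("regulatory classes separate competitive from non-competitive hubs", {
  expect_identical(regulatoryClass("Dynamic", 4), "competitive")
  expect_identical(regulatoryClass("Static", 0), "non_competitive")
  # co-ordinately regulated: a dynamic hub whose partners all oscillate too
  expect_identical(regulatoryClass("Dynamic", 0), "none")
  expect_identical(regulatoryClass("unassigned", 2), "none")
  expect_identical(regulatoryClass("not_classified", 2), "none")
})

test_that("adding a periodic partner never demotes, only promotes unassigned", {
  set.seed(61)
  for (i in 1:20) {
    hv <- sample(c("periodic", "aperiodic", "unclassifiable"), 1)
    pv <- sample(c("periodic", "aperiodic", "unclassifiable"),
                 sample(0:5, 1), replace = TRUE)
    before <- classifyHub(hv, pv)
    after <- classifyHub(hv, c(pv, "periodic"))
    if (before == "unassigned") expect_identical(after, "Static")
    else expect_identical(after, before)
  }
})

test_that("cohort classification counts partners from the 1-step neighbourhood", {
  net <- interactionNetwork(rbind(
    c("HUB1", "P1"), c("HUB1", "P2"), c("HUB1", "P3"),
    c("HUB2", "P3"), c("HUB2", "P4"), c("P4", "FAR")))
  verdicts <- c(HUB1 = "periodic", HUB2 = "aperiodic", P1 = "aperiodic",
                P2 = "aperiodic", P3 = "periodic", P4 = "periodic",
                FAR = "periodic")
  cl <- classifyHubs(net, verdicts,
                     data.frame(hub = c("HUB1", "HUB2"),
                                n_interfaces = c(2L, 1L)))
  expect_identical(cl$table_class, c("Dynamic", "Static"))
  expect_identical(cl$regulatory_class, c("competitive", "non_competitive"))
  expect_identical(cl$n_partners, c(3L, 2L))
  # FAR is 2 steps out: never counted
  expect_identical(cl$n_periodic_partners, c(1L, 2L))
  expect_identical(cl$n_aperiodic_partners, c(2L, 0L))
  # partner counts always decompose
  expect_identical(cl$n_partners, cl$n_periodic_partners +
    cl$n_aperiodic_partners + cl$n_unclassifiable_partners)
  # partner without a verdict counts as unclassifiable
  cl2 <- classifyHubs(net, verdicts[-5],
                      data.frame(hub = "HUB1", n_interfaces = 2L))
  expect_identical(cl2$n_unclassifiable_partners, 1L)
})

test_that("tabulation reproduces the published hub tallies exactly", {
  tal <- tabulateHubs(loadTable1Hubs())
  expect_identical(unname(tal$table_class["Dynamic"]), 10L)
  expect_identical(unname(tal$table_class["Static"]), 11L)
  expect_identical(unname(tal$table_class["not_classified"]), 15L)
  expect_identical(unname(tal$table_class["total"]), 36L)
  expect_identical(unname(sum(tal$table_class[1:4])),
                   unname(tal$table_class["total"]))
})

test_that("tabulation handles empty cohorts and rejects duplicate hubs", {
  tal <- tabulateHubs(data.frame(hub = character(0),
                                 table_class = character(0)))
  expect_true(all(tal$table_class == 0L))
  expect_error(tabulateHubs(data.frame(hub = c("A", "A"),
                                       table_class = c("Dynamic", "Static"))),
               "duplicate hub: A")
})

test_that("tabulated counts on a synthetic cohort equal the ground truth", {
  # clean cohort (no stochastic hubs) classified from its true labels
  cfg <- simulationConfig(seed = 62, noiseSd = 0,
    nBackgroundGenes = 0L,
    hubSpecs = data.frame(
      kind = c("dynamic_competitive", "dynamic_competitive",
               "static_noncompetitive", "coordinate"),
      nInterfaces = c(1L, 2L, 2L, 1L), nPartners = c(3L, 4L, 4L, 3L)))
  b <- simulateBundle(cfg)
  truthVerdict <- c(periodic = "periodic", static = "aperiodic",
                    stochastic = "unclassifiable")[b$truth$label]
  names(truthVerdict) <- b$truth$gene
  cl <- classifyHubs(b$network, truthVerdict,
    data.frame(hub = b$truth$gene[b$truth$role == "hub"],
               n_interfaces = cfg$hubSpecs$nInterfaces))
  tal <- tabulateHubs(cl)
  th <- b$truth[b$truth$role == "hub", ]
  expect_identical(unname(tal$table_class["Dynamic"]),
                   sum(th$intended_table_class == "Dynamic"))
  expect_identical(unname(tal$table_class["Static"]),
                   sum(th$intended_table_class == "Static"))
  expect_identical(unname(tal$regulatory_class["competitive"]),
                   sum(th$intended_regulatory_class == "competitive"))
  expect_identical(unname(tal$regulatory_class["non_competitive"]),
                   sum(th$intended_regulatory_class == "non_competitive"))
  expect_identical(unname(tal$regulatory_class["none"]),
                   sum(th$intended_regulatory_class == "none"))
})
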
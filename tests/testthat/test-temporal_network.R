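test_that("ego networks honor the step radius", {
  star <- interactionNetwork(cbind("H", c("A", "B", "C", "D")))
  e1 <- egoNetwork(star, "H", steps = 1)
  expect_identical(geneIds(e1), c("A", "B", "C", "D", "H"))
  expect_identical(nrow(networkEdges(e1)), 4L)

  path <- interactionNetwork(cbind(c("A", "B", "C"), c("B", "C", "D")))
  e2 <- egoNetwork(path, "A", steps = 2)
  expect_identical(geneIds(e2), c("A", "B", "C"))
  expect_identical(networkEdges(e2), cbind(c("A", "B"), c("B", "C")))

  expect_error(egoNetwork(path, "Z"), "Z")
})

test_that("ego networks agree with a breadth-first-search oracle and nest", {
  edges <- randomEdges(50, 0.1, seed = 31)
  edges[] <- normalizeGeneId(edges)
  net <- interactionNetwork(edges)
  for (hub in sample(geneIds(net), 5)) {
    got2 <- egoNetwork(net, hub, steps = 2)
    expect_identical(geneIds(got2), oracleBfsNodes(edges, hub, 2))
    got1 <- egoNetwork(net, hub, steps = 1)
    expect_true(all(geneIds(got1) %in% geneIds(got2)))
    k1 <- apply(networkEdges(got1), 1, paste, collapse = "|")
    k2 <- apply(networkEdges(got2), 1, paste, collapse = "|")
    expect_true(all(k1 %in% k2))
  }
})

test_that("activity thresholding is inclusive with per-gene overrides", {
  v <- rbind(CLA4 = c(-0.15, -0.05, 0.1),
             GIC2 = c(-0.2, -0.25, 0.4))
  x <- expressionTimeCourse(v, c(0, 10, 20))
  m <- activityMask(x, threshold = -0.2)
  # a value exactly at threshold is displayed
  expect_true(activeMatrix(m)["GIC2", 1])
  expect_false(activeMatrix(m)["GIC2", 2])
  expect_true(all(activeMatrix(m)["CLA4", ]))
  # raising one gene's threshold hides its shallow trough
  m2 <- activityMask(x, threshold = -0.2, overrides = c(CLA4 = -0.1))
  expect_identical(unname(activeMatrix(m2)["CLA4", ]),
                   c(FALSE, TRUE, TRUE))
  expect_identical(activeMatrix(m2)["GIC2", ], activeMatrix(m)["GIC2", ])
  # extreme threshold shows every non-missing cell
  expect_true(all(activeMatrix(activityMask(x, threshold = -10))))
  expect_warning(activityMask(x, overrides = c(NOPE = -0.1)), "NOPE")
})

test_that("missing values are never active", {
  v <- rbind(A = c(0.5, NA, 0.5))
  m <- activityMask(expressionTimeCourse(v, c(0, 5, 10)), threshold = -10)
  expect_identical(unname(activeMatrix(m)["A", ]), c(TRUE, FALSE, TRUE))
})

test_that("frames show active nodes and edges with both endpoints visible", {
  net <- interactionNetwork(cbind(c("H", "H", "A"), c("A", "B", "B")))
  v <- rbind(H = c(0.5, -0.5), A = c(0.5, 0.5), B = c(0.5, 0.5))
  mask <- activityMask(expressionTimeCourse(v, c(0, 10)))
  f0 <- frameAt(net, mask, 0)
  expect_identical(visibleNodes(f0), c("A", "B", "H"))
  expect_identical(nrow(visibleEdges(f0)), 3L)
  # hub inactive: no hub-incident edge survives
  f1 <- frameAt(net, mask, 10)
  expect_identical(visibleNodes(f1), c("A", "B"))
  expect_identical(visibleEdges(f1), cbind("A", "B"))
  expect_error(frameAt(net, mask, 5), "not a sampled")
})

test_that("frame edges equal the exhaustive filter and thresholds act monotonically", {
  for (seed in 1:10) {
    edges <- randomEdges(15, 0.25, seed = 300 + seed)
    net <- interactionNetwork(edges)
    set.seed(400 + seed)
    v <- matrix(rnorm(15 * 6), 15, 6,
                dimnames = list(sprintf("N%03d", 1:15), NULL))
    x <- expressionTimeCourse(v, seq(0, 50, by = 10))
    hi <- activityMask(x, threshold = 0.1)
    lo <- activityMask(x, threshold = -0.4)
    for (t in timePoints(x)) {
      fh <- frameAt(net, hi, t)
      fl <- frameAt(net, lo, t)
      # exhaustive both-endpoints filter
      e <- networkEdges(net)
      keep <- e[, 1] %in% visibleNodes(fh) & e[, 2] %in% visibleNodes(fh)
      expect_identical(visibleEdges(fh), e[keep, , drop = FALSE])
      # lowering the threshold never shrinks a frame
      expect_true(all(visibleNodes(fh) %in% visibleNodes(fl)))
      kh <- apply(visibleEdges(fh), 1, paste, collapse = "|")
      kl <- apply(visibleEdges(fl), 1, paste, collapse = "|")
      expect_true(all(kh %in% kl))
    }
  }
})

test_that("json-lines frame export round-trips, including empty frames", {
  net <- interactionNetwork(cbind(c("A", "B"), c("B", "C")))
  v <- rbind(A = c(0.3, -0.9, 0.2), B = c(0.1, -0.8, 0.4),
             C = c(-0.5, -0.7, 0.6))
  mask <- activityMask(expressionTimeCourse(v, c(0, 10, 20)))
  f <- withr_tempfile()
  exportFrames(net, mask, f, format = "json-lines")
  frames <- readFrames(f)
  expect_length(frames, 3L)
  # the all-hidden frame is present with an empty node list
  expect_identical(visibleNodes(frames[[2]]), character(0))
  for (i in 1:3) {
    orig <- frameAt(net, mask, c(0, 10, 20)[i])
    expect_identical(visibleNodes(frames[[i]]), visibleNodes(orig))
    expect_identical(visibleEdges(frames[[i]]), visibleEdges(orig))
    expect_equal(nodeValues(frames[[i]]), nodeValues(orig))
    expect_equal(frameTime(frames[[i]]), frameTime(orig))
  }
})

test_that("graphml frame stacks write one annotated file per timepoint", {
  net <- interactionNetwork(cbind("A", "B"))
  v <- rbind(A = c(0.5, 0.2), B = c(0.5, -0.9))
  mask <- activityMask(expressionTimeCourse(v, c(0, 10)))
  prefix <- file.path(withr::local_tempdir(), "frames")
  files <- exportFrames(net, mask, prefix, format = "graphml-stack")
  expect_length(files <- Sys.glob(paste0(prefix, "*.graphml")), 2L)
  g <- igraph::read_graph(files[1], format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_true(all(grepl("^#", igraph::V(g)$color)))
})
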
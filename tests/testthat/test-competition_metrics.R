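mkMask <- function(v, times = seq(0, (ncol(v) - 1) * 10, by = 10),
                   threshold = -0.2) {
  activityMask(expressionTimeCourse(v, times), threshold = threshold)
}

test_that("competition counts partners beyond the available interfaces", {
  net <- interactionNetwork(cbind("H", c("P1", "P2", "P3")))
  v <- rbind(H = c(0.1, 0.1), P1 = c(0.1, -0.9), P2 = c(0.1, -0.9),
             P3 = c(0.1, 0.3))
  pr <- competitionProfile("H", net, mkMask(v), nInterfaces = 1L)
  expect_identical(pr@activeCount, c(3L, 1L))
  expect_identical(pr@excess, c(2L, 0L))
  expect_identical(pr@maxSimultaneous, 3L)
  expect_equal(pr@fractionTimeCompetitive, 0.5)
})

test_that("staggered partners produce no excess for a 1-interface hub", {
  net <- interactionNetwork(cbind("H", c("P1", "P2", "P3")))
  v <- rbind(H = c(0.1, 0.1, 0.1),
             P1 = c(0.1, -0.9, -0.9), P2 = c(-0.9, 0.1, -0.9),
             P3 = c(-0.9, -0.9, 0.1))
  pr <- competitionProfile("H", net, mkMask(v), nInterfaces = 1L)
  expect_identical(pr@maxSimultaneous, 1L)
  expect_true(all(pr@excess == 0L))
  expect_equal(pr@fractionTimeCompetitive, 0)
})

test_that("partner counts equal a brute-force scan and obey the double-counting identity", {
  set.seed(71)
  for (rep in 1:10) {
    n <- 8
    edges <- cbind("HUB", sprintf("P%d", 1:n))
    net <- interactionNetwork(edges)
    v <- matrix(rnorm((n + 1) * 6, sd = 0.5), n + 1, 6,
                dimnames = list(c("HUB", sprintf("P%d", 1:n)), NULL))
    mask <- mkMask(v)
    pr <- competitionProfile("HUB", net, mask, nInterfaces = 2L)
    act <- activeMatrix(mask)
    brute <- sapply(seq_len(6), function(j)
      sum(sapply(sprintf("P%d", 1:n), function(p) act[p, j])))
    expect_identical(pr@activeCount, as.integer(brute))
    # sum over time of counts == sum over partners of active-time totals
    expect_identical(sum(pr@activeCount),
                     sum(act[sprintf("P%d", 1:n), ]))
    # excess never increases with more interfaces
    pr1 <- competitionProfile("HUB", net, mask, nInterfaces = 1L)
    expect_true(all(pr@excess <= pr1@excess))
  }
})

test_that("a hub with no partners yields an all-zero profile", {
  net <- interactionNetwork(cbind("A", "B"), nodes = "H")
  v <- rbind(H = c(0.1, 0.1), A = c(0.1, 0.1), B = c(0.1, 0.1))
  pr <- competitionProfile("H", net, mkMask(v), nInterfaces = 1L)
  expect_identical(pr@activeCount, c(0L, 0L))
  expect_identical(pr@maxSimultaneous, 0L)
  expect_equal(pr@fractionTimeCompetitive, 0)
})

test_that("hub activity gates only the realized summary", {
  net <- interactionNetwork(cbind("H", c("P1", "P2")))
  v <- rbind(H = c(0.1, -0.9), P1 = c(0.1, 0.1), P2 = c(0.1, 0.1))
  pr <- competitionProfile("H", net, mkMask(v), nInterfaces = 1L)
  expect_identical(pr@activeCount, c(2L, 2L))  # not gated by the hub
  expect_equal(pr@fractionTimeCompetitive, 1)
  expect_equal(pr@realizedFractionCompetitive, 0.5)
})

test_that("Jaccard overlap spans identical, disjoint and empty activity", {
  v <- rbind(A = c(0.1, 0.1, -0.9), B = c(0.1, 0.1, -0.9),
             C = c(-0.9, -0.9, 0.1), D = c(-0.9, -0.9, -0.9),
             E = c(-0.9, -0.9, -0.9))
  mask <- mkMask(v)
  ov <- partnerOverlap(mask, c("A", "B"))
  expect_equal(unname(jaccardMatrix(ov)["A", "B"]), 1)
  expect_equal(staggeredScore(ov), 1)
  ov2 <- partnerOverlap(mask, c("A", "C"))
  expect_equal(unname(jaccardMatrix(ov2)["A", "C"]), 0)
  # both-empty pairs score 0 and are flagged
  ov3 <- partnerOverlap(mask, c("D", "E"))
  expect_equal(unname(jaccardMatrix(ov3)["D", "E"]), 0)
  expect_true(ov3@bothEmpty["D", "E"])
  # diagonal 1 for any partner active at least once
  expect_equal(unname(diag(jaccardMatrix(ov))), c(1, 1))
  expect_error(partnerOverlap(mask, "A"), "at least 2")
})

test_that("Jaccard matches brute-force set arithmetic and ignores time relabeling", {
  set.seed(72)
  for (rep in 1:10) {
    v <- matrix(rnorm(4 * 8, sd = 0.5), 4, 8,
                dimnames = list(c("A", "B", "C", "D"), NULL))
    mask <- mkMask(v)
    ov <- partnerOverlap(mask, c("A", "B", "C", "D"))
    act <- activeMatrix(mask)
    for (p in c("A", "B")) for (q in c("C", "D")) {
      si <- which(act[p, ]); sj <- which(act[q, ])
      expected <- if (length(union(si, sj)) == 0) 0 else
        length(intersect(si, sj)) / length(union(si, sj))
      expect_equal(unname(jaccardMatrix(ov)[p, q]), expected)
    }
    # permuting the time axis of both vectors leaves Jaccard unchanged
    perm <- sample(8)
    mask2 <- mkMask(v[, perm], times = seq(0, 70, by = 10))
    ov2 <- partnerOverlap(mask2, c("A", "B", "C", "D"))
    expect_equal(jaccardMatrix(ov2), jaccardMatrix(ov))
  }
})

test_that("staggered flags follow the mean-overlap cutoff", {
  v <- rbind(A = c(0.1, -0.9), B = c(-0.9, 0.1))
  expect_true(flagStaggered(partnerOverlap(mkMask(v), c("A", "B"))))
  v2 <- rbind(A = c(0.1, 0.1), B = c(0.1, 0.1))
  expect_false(flagStaggered(partnerOverlap(mkMask(v2), c("A", "B"))))
})

test_that("generated staggered trios are staggered under the default threshold", {
  cfg <- simulationConfig(seed = 73, noiseSd = 0)
  rows <- makeStaggeredPartners(3, cfg)
  mask <- activityMask(expressionTimeCourse(rows, attr(rows, "times")))
  ov <- partnerOverlap(mask, rownames(rows))
  expect_true(all(jaccardMatrix(ov)[upper.tri(jaccardMatrix(ov))] < 0.5))
  expect_true(flagStaggered(ov))
  # antiphase pair with ample amplitude: fully disjoint activity
  rows2 <- makeStaggeredPartners(2, cfg)
  mask2 <- activityMask(expressionTimeCourse(rows2, attr(rows2, "times")))
  expect_equal(unname(jaccardMatrix(partnerOverlap(mask2,
    rownames(rows2)))["PART01", "PART02"]), 0)
})
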
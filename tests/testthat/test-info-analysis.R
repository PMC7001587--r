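test_that("the worked-example table yields the printed information values", {
  tab <- binnedResponseTable(workedExampleCounts())
  expect_equal(unname(colSums(binCounts(tab))), c(209, 85, 106))
  expect_equal(sum(binCounts(tab)), 400)
  expect_equal(unname(marginalProb(tab)), c(209, 85, 106) / 400)
  got <- sapply(c("A", "B", "C", "D"),
                function(s) singleCellInformation(tab, s))
  expect_equal(unname(got), c(1.097, 0.380, 0.336, 0.059), tolerance = 2e-3)
  # and agrees with the independent joint-table oracle to close precision
  expect_equal(unname(got),
               unname(sapply(1:4,
                             function(s) oracleInfo(workedExampleCounts(),
                                                    s))),
               tolerance = 1e-12)
})

test_that("bin edges are equally spaced, left-closed, last bin closed", {
  act <- activationMatrix(
    matrix(c(0, 1 / 3, 0.5, 2 / 3, 1, 0.999), 1,
           dimnames = list("u1", NULL)),
    labels = rep(0L, 6L), condition = rep("both", 6L))
  tab <- binResponses(act, "u1", nBins = 3L)
  expect_equal(binEdges(tab), c(0, 1 / 3, 2 / 3, 1))
  # 0 -> bin 1; 1/3 -> bin 2 (left-closed); 0.5 -> bin 2; 2/3 -> bin 3;
  # 1 and 0.999 -> bin 3 (upper edge closed)
  expect_equal(unname(binCounts(tab)[1L, ]), c(1, 2, 3))
  expect_error(binResponses(act, "u1", nBins = 1L), "nBins")
  # out-of-range values are clipped with a warning
  act2 <- activationMatrix(matrix(c(-0.2, 1.4), 1,
                                  dimnames = list("u1", NULL)),
                           labels = c(0L, 0L), condition = rep("both", 2L))
  expect_warning(tab2 <- binResponses(act2, "u1", nBins = 2L), "clip")
  expect_equal(unname(binCounts(tab2)[1L, ]), c(1, 1))
})

test_that("identical response rows carry zero information", {
  tab <- binnedResponseTable(matrix(rep(c(5, 3, 2), each = 4), 4))
  for (s in 1:4) expect_equal(singleCellInformation(tab, s), 0)
  expect_error(singleCellInformation(
    binnedResponseTable(rbind(c(1, 1), c(0, 0))), 2), "no presentations")
})

test_that("information matrix matches direct evaluation on random tables", {
  # oracle equivalence on many randomised small activation sets
  set.seed(101)
  for (i in 1:25) {
    nCat <- sample(2:6, 1L)
    nBins <- sample(2:5, 1L)
    nPer <- sample(5:30, 1L)
    labels <- rep(0:(nCat - 1L), each = nPer)
    resp <- matrix(runif(2L * nCat * nPer), 2L)
    act <- activationMatrix(resp, labels, rep("both", ncol(resp)))
    got <- infoValues(infoMatrix(act, nBins))
    edges <- seq(0, 1, length.out = nBins + 1L)
    for (u in 1:2) {
      bins <- findInterval(resp[u, ], edges, rightmost.closed = TRUE)
      counts <- unclass(table(factor(labels, levels = 0:(nCat - 1L)),
                              factor(bins, levels = seq_len(nBins))))
      want <- sapply(seq_len(nCat), function(s) oracleInfo(counts, s))
      expect_equal(unname(got[u, ]), want, tolerance = 1e-9)
    }
  }
})

test_that("information respects non-negativity and the log2(nCat) bound", {
  set.seed(77)
  for (i in 1:10) {
    nCat <- sample(c(2L, 4L, 10L), 1L)
    labels <- rep(0:(nCat - 1L), each = 20L)
    resp <- matrix(runif(4L * nCat * 20L), 4L)
    info <- infoValues(infoMatrix(activationMatrix(
      resp, labels, rep("both", ncol(resp))), nBins = 10L))
    expect_true(all(info >= 0))
    expect_true(all(info <= maxInformation(nCat) + 1e-12))
  }
})

test_that("information is invariant to monotone bin-preserving remaps", {
  set.seed(15)
  labels <- rep(0:4, each = 30L)
  resp <- matrix(runif(150L), 1L)
  act <- activationMatrix(resp, labels, rep("both", 150L))
  base <- infoValues(infoMatrix(act, nBins = 5L))
  # snap each value to a fixed point inside its bin: same bin assignment
  snapped <- (ceiling(resp * 5) - 0.3) / 5
  act2 <- activationMatrix(snapped, labels, rep("both", 150L))
  expect_equal(infoValues(infoMatrix(act2, nBins = 5L)), base,
               tolerance = 1e-12)
})

test_that("label shuffling collapses planted information to the bias floor", {
  spec <- plantedActivationSpec(list(0L), list(integer(0)))
  act <- plantActivations(spec, 100L, seed = 21L)
  vOnly <- infoValues(infoMatrix(act, 10L, "visual_only"))[1L, "0"]
  keep <- sampleConditions(act) == "visual_only"
  resp <- responses(act)[keep, 1L, drop = FALSE]
  set.seed(33)
  null <- replicate(40, {
    shuffled <- activationMatrix(t(resp), sample(sampleLabels(act)[keep]),
                                 rep("visual_only", sum(keep)))
    max(infoValues(infoMatrix(shuffled, 10L, "visual_only")))
  })
  expect_gt(vOnly, quantile(null, 0.95))
})

test_that("condition filters, shapes, and the rank-order curve behave", {
  spec <- plantedActivationSpec(
    rep(list(integer(0)), 64L), rep(list(integer(0)), 64L))
  act <- plantActivations(spec, 5L, seed = 2L)
  info <- infoMatrix(act, 10L, "audio_only")
  expect_identical(dim(infoValues(info)), c(64L, 10L))
  expect_error(infoMatrix(act, 10L, "both"), "no samples")
  # constant-response unit: all-zero row
  const <- activationMatrix(matrix(0.4, 1L, 60L), rep(0:9, 6L),
                            rep("both", 60L))
  expect_true(all(infoValues(infoMatrix(const, 10L)) == 0))
  # rank-order curve: a single perfect unit among silent ones
  one <- plantedActivationSpec(c(list(7L), rep(list(integer(0)), 9L)),
                               rep(list(integer(0)), 10L))
  acts <- plantActivations(one, 50L, seed = 3L)
  curve <- rankOrderCurve(infoMatrix(acts, 10L, "visual_only"))
  expect_equal(unname(curve[1L]), log2(10), tolerance = 0.15)
  expect_identical(names(curve)[1L], "unit001")
})

test_that("maximum information follows the category count", {
  expect_equal(maxInformation(10L), log2(10))
  expect_equal(maxInformation(4L), 2)
  expect_equal(maxInformation(1L), 0)
})
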
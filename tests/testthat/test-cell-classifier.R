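.mkInfo <- function(m, condition = "visual_only") {
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("unit%03d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- as.character(seq_len(ncol(m)) - 1L)
  new("InfoTable", info = m, nBins = 10L, condition = condition)
}

test_that("percentile thresholds use linear interpolation over pooled values", {
  expect_equal(percentileThreshold(.mkInfo(matrix(0.7, 4L, 10L))), 0.7)
  expect_equal(percentileThreshold(.mkInfo(matrix(1:100, 10L, 10L))), 80.2)
  expect_equal(percentileThreshold(.mkInfo(matrix(1:100, 10L, 10L)),
                                   percentile = 50), 50.5)
  expect_error(percentileThreshold(.mkInfo(matrix(1, 2L, 2L)), 100),
               "percentile")
})

test_that("selective digits are those strictly above threshold", {
  row <- c("0" = 0, "7" = log2(10), "9" = 0.2)
  expect_identical(selectiveDigits(row, 0.96), 7L)
  expect_identical(selectiveDigits(c("1" = 0, "2" = 0), 0.5), integer(0))
  t1 <- c("0" = 1.097, "1" = 0.380, "2" = 0.336, "3" = 0.059)
  expect_identical(selectiveDigits(t1, 0.96), 0L)
  expect_error(selectiveDigits(row, -1), "non-negative")
})

test_that("the four types and non-selective fall out of the digit sets", {
  vis <- matrix(0, 5L, 10L, dimnames = list(NULL, as.character(0:9)))
  aud <- vis
  vis[1L, "1"] <- 3       # visual cell
  aud[2L, "1"] <- 3       # auditory cell
  vis[3L, "1"] <- 3; aud[3L, "6"] <- 3   # inconsistent
  vis[4L, "0"] <- 3; aud[4L, "0"] <- 3   # consistent (shared)
  ty <- classifyUnits(.mkInfo(vis), .mkInfo(aud, "audio_only"), 0.96, 0.94)
  expect_identical(as.character(typologyTable(ty)$type),
                   c("visual", "auditory", "inconsistent", "consistent",
                     "non_selective"))
  cnt <- typeCounts(ty)
  expect_identical(sum(cnt), 5L)
  expect_identical(as.integer(cnt[c("visual", "auditory", "inconsistent",
                                    "consistent", "non_selective")]),
                   rep(1L, 5L))
  expect_error(
    classifyUnits(.mkInfo(vis[1:2, ]), .mkInfo(aud, "audio_only"), 1, 1),
    "different unit sets")
})

test_that("raising the threshold never promotes a unit to selectivity", {
  set.seed(5)
  vis <- matrix(runif(640L, 0, 3), 64L,
                dimnames = list(sprintf("unit%03d", 1:64),
                                as.character(0:9)))
  aud <- matrix(runif(640L, 0, 3), 64L, dimnames = dimnames(vis))
  lowest <- classifyUnits(.mkInfo(vis), .mkInfo(aud), 0.5, 0.5)
  for (th in c(1, 2, 2.9)) {
    ty <- classifyUnits(.mkInfo(vis), .mkInfo(aud), th, th)
    wasNon <- typologyTable(lowest)$type == "non_selective"
    expect_true(all(typologyTable(ty)$type[wasNon] == "non_selective"))
    # digit sets shrink monotonically
    expect_true(all(lengths(typologyTable(ty)$visualDigits) <=
                    lengths(typologyTable(lowest)$visualDigits)))
  }
})

test_that("planted typologies are recovered exactly from sampled activations", {
  set.seed(8)
  nU <- 30L
  types <- rep(c("visual", "auditory", "inconsistent", "consistent",
                 "non_selective"), each = 6L)
  vDig <- vector("list", nU); aDig <- vector("list", nU)
  for (u in seq_len(nU)) {
    d <- sample(0:9, 2L)
    switch(types[u],
      visual = { vDig[[u]] <- d[1L]; aDig[[u]] <- integer(0) },
      auditory = { vDig[[u]] <- integer(0); aDig[[u]] <- d[1L] },
      inconsistent = { vDig[[u]] <- d[1L]; aDig[[u]] <- d[2L] },
      consistent = { vDig[[u]] <- d[1L]; aDig[[u]] <- d[1L] },
      non_selective = { vDig[[u]] <- integer(0); aDig[[u]] <- integer(0) })
  }
  spec <- plantedActivationSpec(vDig, aDig)
  act <- plantActivations(spec, 60L, seed = 13L)
  iv <- infoMatrix(act, 10L, "visual_only")
  ia <- infoMatrix(act, 10L, "audio_only")
  # thresholds below the planted on-digit information (log2 10) but far
  # above the off-digit floor
  ty <- classifyUnits(iv, ia, 1, 1)
  expect_identical(as.character(typologyTable(ty)$type), types)
  planted <- which(types == "consistent")
  expect_identical(unname(as.list(typologyTable(ty)$visualDigits[planted])),
                   vDig[planted])
})
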
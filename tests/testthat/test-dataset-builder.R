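test_that("consistent pairing matches labels and is seed-reproducible", {
  cfg <- tinyConfig()
  vis <- generatePool(cfg, "visual", perClass = 4L)
  aud <- generatePool(cfg, "auditory", perClass = 3L)
  ss <- pairConsistent(vis, aud, seed = 2L)
  expect_identical(nPairs(ss), 40L)
  expect_true(all(visualLabels(ss) == auditoryLabels(ss)))
  expect_identical(visualInputs(ss),
                   visualInputs(pairConsistent(vis, aud, seed = 2L)))
  # single-candidate pools force the unique label-matched pairing
  v1 <- generatePool(cfg, "visual", perClass = 1L)
  a1 <- generatePool(cfg, "auditory", perClass = 1L)
  forced <- pairConsistent(v1, a1, seed = 9L)
  expect_identical(auditoryInputs(forced)[, order(visualLabels(forced))],
                   t(poolSamples(a1)[order(poolLabels(a1)), ]))
})

test_that("inconsistent pairing never matches labels and spreads uniformly", {
  cfg <- generatorConfig(visualTrain = 200L, audioPerClass = 5L, seed = 4L)
  vis <- generatePool(cfg, "visual", perClass = 200L)
  aud <- generatePool(cfg, "auditory", perClass = 10L)
  ss <- pairInconsistent(vis, aud, seed = 5L)
  expect_true(all(visualLabels(ss) != auditoryLabels(ss)))
  # audio labels for one visual class are about uniform over the 9 others
  audLab <- auditoryLabels(ss)[visualLabels(ss) == 0L]
  p <- chisq.test(table(factor(audLab, levels = 1:9)))$p.value
  expect_gt(p, 0.001)
})

test_that("modality dropout triples the set with exact zeroing and targets", {
  r <- tinyReplicate()
  base <- pairConsistent(
    generatePool(tinyConfig(), "visual", perClass = 2L),
    generatePool(tinyConfig(), "auditory", perClass = 2L), seed = 1L)
  aug <- augmentModalityDropout(base)
  expect_identical(nPairs(aug), 3L * nPairs(base))
  cond <- pairConditions(aug)
  expect_identical(as.integer(table(cond)[c("both", "visual_only",
                                            "audio_only")]),
                   rep(nPairs(base), 3L))
  # zeroed modalities are exactly zero; targets keep the original arrays
  expect_true(all(visualInputs(aug)[, cond == "audio_only"] == 0))
  expect_true(all(auditoryInputs(aug)[, cond == "visual_only"] == 0))
  expect_identical(visualTargets(aug)[, cond == "audio_only"],
                   visualInputs(base))
  expect_identical(auditoryTargets(aug)[, cond == "visual_only"],
                   auditoryInputs(base))
  # label multiset preserved per condition
  for (cc in unique(cond))
    expect_identical(sort(visualLabels(aug)[cond == cc]),
                     sort(visualLabels(base)))
  # double augmentation is refused; single pair gives the three conditions
  expect_error(augmentModalityDropout(aug), "augmented")
  one <- base[, 1L]
  expect_identical(sort(pairConditions(augmentModalityDropout(one))),
                   sort(c("both", "visual_only", "audio_only")))
})

test_that("replicates are reproducible, distinct, and correctly sized", {
  cfg <- tinyConfig(seed = 11L)
  reps <- makeReplicates(2L, cfg)
  expect_length(reps, 2L)
  expect_false(reps[[1L]]$seed == reps[[2L]]$seed)
  r <- reps[[1L]]
  expect_identical(consistencyType(r$trainConsistent), "consistent")
  expect_identical(consistencyType(r$trainInconsistent), "inconsistent")
  # 10 classes x 4 visual x 3 conditions train; 10 x 3 x 3 test
  expect_identical(nPairs(r$trainConsistent), 120L)
  expect_identical(nPairs(r$test), 90L)
  expect_true(all(visualLabels(r$test) == auditoryLabels(r$test)))
  again <- makeReplicates(2L, cfg)[[1L]]
  expect_identical(visualInputs(r$trainConsistent),
                   visualInputs(again$trainConsistent))
})

test_that("mismatched or degenerate pools are rejected", {
  cfg <- tinyConfig()
  vis <- generatePool(cfg, "visual", perClass = 2L)
  aud <- generatePool(cfg, "auditory", perClass = 2L)
  expect_error(pairConsistent(vis, vis, seed = 1L), "visual and an auditory")
  oneClass <- generatorConfig(nClasses = 1L, visualTrain = 2L,
                              audioPerClass = 2L)
  v1 <- generatePool(oneClass, "visual", perClass = 2L)
  a1 <- generatePool(oneClass, "auditory", perClass = 2L)
  expect_error(pairInconsistent(v1, a1, seed = 1L), "2 classes")
})
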
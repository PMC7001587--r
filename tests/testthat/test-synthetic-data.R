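test_that("zero-noise pools reproduce their prototypes and seeds are exact", {
  cfg <- generatorConfig(visualTrain = 2L, noiseSd = 0, seed = 42L)
  pool <- generatePool(cfg, "visual", perClass = 2L)
  s <- poolSamples(pool)
  # both samples of a class equal the (single) class prototype exactly
  for (cls in 0:9) {
    rows <- which(poolLabels(pool) == cls)
    expect_identical(s[rows[1L], ], s[rows[2L], ])
  }
  # identical seeds give bit-identical pools, different seeds differ
  again <- generatePool(cfg, "visual", perClass = 2L)
  expect_identical(poolSamples(again), s)
  # with zero noise the pool equals its prototypes for any sampling seed;
  # a different master seed draws different prototypes
  cfg2 <- generatorConfig(visualTrain = 2L, noiseSd = 0, seed = 43L)
  other <- generatePool(cfg2, "visual", perClass = 2L)
  expect_false(identical(poolSamples(other), s))
})

test_that("pool geometry, range and class coverage match the design", {
  cfg <- generatorConfig(seed = 7L)
  vis <- generatePool(cfg, "visual")          # 500 per class
  expect_identical(dim(poolSamples(vis)), c(5000L, 784L))
  expect_true(all(poolSamples(vis) >= 0 & poolSamples(vis) <= 1))
  expect_identical(sort(unique(poolLabels(vis))), 0:9)
  aud <- generatePool(cfg, "auditory", perClass = 4L)
  expect_identical(dim(poolSamples(aud)), c(40L, 14L * 56L))
  # two sub-prototype "speakers" per digit
  expect_identical(sort(unique(aud@sourceId)), 1:2)
})

test_that("auditory sub-prototypes are distinct within a class", {
  cfg <- generatorConfig(noiseSd = 0, seed = 3L)
  aud <- generatePool(cfg, "auditory", perClass = 4L)
  s <- poolSamples(aud)
  rows <- which(poolLabels(aud) == 0)
  bySource <- split(rows, aud@sourceId[rows])
  expect_identical(s[bySource[[1L]][1L], ], s[bySource[[1L]][2L], ])
  expect_false(identical(s[bySource[[1L]][1L], ], s[bySource[[2L]][1L], ]))
})

test_that("planted distributions give exact closed-form information", {
  # a unit silent in the bottom bin except top-bin firing for digit 0
  spec <- plantedActivationSpec(list(0L), list(integer(0)))
  info <- plantedInformation(spec, "visual")
  expect_equal(info[1L, "0"], log2(10), tolerance = 1e-12)
  # unplanted digits share an identical distribution: log2(10/9) each
  expect_equal(unname(info[1L, "5"]), log2(10 / 9), tolerance = 1e-12)
  # identical distributions for every digit carry zero information
  flat <- matrix(1 / 10, 10, 10)
  spec0 <- plantedActivationSpec(list(integer(0)), list(integer(0)),
    distributions = list(list(visual = flat, auditory = flat)))
  expect_true(all(plantedInformation(spec0, "visual") == 0))
})

test_that("sampled planted activations recover the worked-example values", {
  # plant the printed 4-category x 3-bin distributions for one unit and
  # check the sampled estimate approaches the closed form at large n
  counts <- workedExampleCounts()
  dist <- sweep(counts, 1L, rowSums(counts), "/")
  # embed in a 4-class, 3-bin plant
  spec <- plantedActivationSpec(list(0L), list(integer(0)), nClasses = 4L,
    nBins = 3L,
    distributions = list(list(visual = dist, auditory = dist)))
  closed <- plantedInformation(spec, "visual")[1L, ]
  expect_equal(unname(closed),
               unname(sapply(1:4, function(s) oracleInfo(counts, s))),
               tolerance = 1e-12)
  act <- plantActivations(spec, nPerClass = 4000L, seed = 9L)
  est <- infoMatrix(act, nBins = 3L, conditionFilter = "visual_only")
  expect_equal(unname(infoValues(est)[1L, ]), unname(closed),
               tolerance = 0.05)
})

test_that("planted sampling is deterministic and range-bounded", {
  spec <- plantedActivationSpec(list(0L, 1L), list(0L, 2L))
  a1 <- plantActivations(spec, 20L, seed = 5L)
  a2 <- plantActivations(spec, 20L, seed = 5L)
  expect_identical(responses(a1), responses(a2))
  expect_true(all(responses(a1) >= 0 & responses(a1) <= 1))
  expect_identical(dim(responses(a1)), c(2L * 10L * 20L, 2L))
})

test_that("invalid generator and plant configurations are rejected", {
  expect_error(generatorConfig(visualTrain = 0L), "count")
  expect_error(generatorConfig(noiseSd = -1), "non-negative")
  bad <- matrix(1, 10, 10)  # rows sum to 10, not 1
  expect_error(
    plantedActivationSpec(list(0L), list(0L),
      distributions = list(list(visual = bad, auditory = bad))),
    "probability")
})
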
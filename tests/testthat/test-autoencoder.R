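test_that("network construction matches the two frameworks", {
  m4 <- buildModel(networkSpec("mixed", 4L), seed = 1L)
  expect_length(m4@weights$encoder, 4L)
  expect_identical(dim(m4@weights$encoder[[1L]]$W), c(1568L, 64L))
  expect_identical(dim(m4@weights$encoder[[2L]]$W), c(64L, 64L))
  expect_length(m4@weights$decoderVisual, 3L)
  expect_identical(dim(m4@weights$decoderVisual[[3L]]$W), c(64L, 784L))
  ts <- buildModel(networkSpec("two_stage"), seed = 1L)
  expect_length(ts@weights$encoderVisual, 3L)
  expect_length(ts@weights$encoderAuditory, 3L)
  expect_identical(dim(ts@weights$merge[[1L]]$W), c(128L, 64L))
  expect_error(networkSpec("mixed", 5L), "1..4")
  # seeded initialisation is exactly reproducible
  again <- buildModel(networkSpec("mixed", 4L), seed = 1L)
  expect_identical(m4@weights, again@weights)
  expect_false(identical(
    m4@weights, buildModel(networkSpec("mixed", 4L), seed = 2L)@weights))
})

test_that("zero epochs leave the model untouched and the log empty", {
  r <- tinyReplicate()
  m <- buildModel(networkSpec("mixed", 2L), seed = 3L)
  m0 <- trainModel(m, r$trainConsistent, 0L)
  expect_identical(m0@weights, m@weights)
  expect_identical(nrow(trainingLog(m0)), 0L)
})

test_that("training is deterministic and reduces the loss", {
  r <- tinyReplicate()
  m <- buildModel(networkSpec("mixed", 1L), seed = 4L)
  a <- trainModel(m, r$trainConsistent, 15L, 32L)
  b <- trainModel(m, r$trainConsistent, 15L, 32L)
  expect_identical(a@weights, b@weights)
  expect_identical(trainingLog(a), trainingLog(b))
  log <- trainingLog(a)
  expect_identical(nrow(log), 15L)
  expect_lt(log$bce[15L], log$bce[1L])
  expect_true(all(is.finite(log$bce)) && all(is.finite(log$mse)))
})

test_that("a tiny dataset can be overfit to near-zero reconstruction error", {
  r <- tinyReplicate(seed = 6L)
  two <- r$trainConsistent[, 1:2]
  m <- trainModel(buildModel(networkSpec("mixed", 1L), seed = 5L),
                  two, 400L, 2L)
  log <- trainingLog(m)
  expect_lt(log$mse[400L], log$mse[1L] / 20)
  rec <- reconstruct(m, two)
  expect_lt(mean(abs(rec$visual - visualTargets(two))), 0.05)
  expect_lt(mean(abs(rec$auditory - auditoryTargets(two))), 0.05)
})

test_that("encoder activations have the right shape, range and tags", {
  r <- tinyReplicate()
  m <- buildModel(networkSpec("mixed", 3L), seed = 7L)
  act <- encodeLayer(m, r$test, 2L)
  expect_identical(dim(responses(act)), c(nPairs(r$test), 64L))
  expect_true(all(responses(act) > 0 & responses(act) < 1))
  expect_identical(sampleConditions(act), pairConditions(r$test))
  expect_error(encodeLayer(m, r$test, 4L), "layerIndex")
  # two-stage: per-modality layers expose 128 units, the merge layer 64
  ts <- buildModel(networkSpec("two_stage"), seed = 8L)
  expect_identical(nrow(responses(encodeLayer(ts, r$test, 2L))[0, ,
                                                               drop = FALSE]),
                   0L)
  expect_identical(ncol(responses(encodeLayer(ts, r$test, 2L))), 128L)
  expect_identical(ncol(responses(encodeLayer(ts, r$test, 4L))), 64L)
})

test_that("all-zero inputs produce the constant bias-driven activation", {
  m <- buildModel(networkSpec("mixed", 1L), seed = 9L)
  zeros <- stimulusSet(visual = matrix(0, 784L, 3L),
                       auditory = matrix(0, 784L, 3L),
                       labelVisual = 0:2, labelAudio = 0:2)
  act <- responses(encodeLayer(m, zeros, 1L))
  want <- 1 / (1 + exp(-m@weights$encoder[[1L]]$b))
  for (i in 1:3) expect_equal(unname(act[i, ]), want, tolerance = 1e-12)
})
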
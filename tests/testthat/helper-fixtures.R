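# Shared fixtures and independent oracles for the test suite.

# The printed worked-example count table: 4 categories x 3 bins, 100
# presentations per category.
workedExampleCounts <- function() {
  rbind(A = c(3, 17, 80), B = c(68, 31, 1), C = c(73, 25, 2),
        D = c(65, 12, 23))
}

# Independent information oracle: materialises the full joint table
# P(r, s) from raw counts and evaluates the stimulus-specific information
# by explicit summation, element by element. Kept deliberately loop-based
# and separate from the package's vectorised path.
oracleInfo <- function(counts, s) {
  total <- sum(counts)
  joint <- counts / total
  ps <- sum(joint[s, ])
  acc <- 0
  for (r in seq_len(ncol(counts))) {
    pr <- 0
    for (k in seq_len(nrow(counts))) pr <- pr + joint[k, r]
    prGivenS <- joint[s, r] / ps
    if (prGivenS > 0) acc <- acc + prGivenS * log2(prGivenS / pr)
  }
  acc
}

# A small generator configuration used across tests.
tinyConfig <- function(seed = 1L, ...) {
  generatorConfig(visualTrain = 4L, visualTest = 3L, audioPerClass = 3L,
                  seed = seed, ...)
}

# A compact trained/untrained model fixture on a tiny replicate.
tinyReplicate <- function(seed = 1L) {
  makeReplicates(1L, tinyConfig(seed))[[1L]]
}
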
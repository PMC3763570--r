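props9 <- normalizeProperties(loadDefaultProperties())

test_that("PSPCP collapses correctly on one-hot and uniform rows and matches a double loop", {
  set.seed(5)
  s <- randomSequence(25)
  oneHot <- oneHotProfile(s, "oh")
  D <- pspcp(oneHot, props9)
  res <- match(strsplit(s, "")[[1]], residueOrder())
  for (r in 1:9)
    expect_equal(unname(D[, r]), unname(props9@h[r, res]), tolerance = 1e-12)

  unif <- oneHotProfile("X", "u")
  expect_lt(max(abs(pspcp(unif, props9))), 1e-12)

  prof <- randomProfile(30)
  D2 <- pspcp(prof, props9)
  for (i in 1:30) for (r in 1:9)
    expect_equal(unname(D2[i, r]), sum(prof@A[i, ] * props9@h[r, ]),
                 tolerance = 1e-12)
})

test_that("composition is the per-column mean and sums to 1", {
  prof <- randomProfile(17)
  f <- composition(prof)
  expect_lt(abs(sum(f) - 1), 1e-10)
  for (j in 1:20)
    expect_equal(unname(f[j]), sum(prof@A[, j]) / 17, tolerance = 1e-12)

  fA <- composition(oneHotProfile("AAAA", "a"))
  expect_equal(unname(fA), c(1, rep(0, 19)))
})

test_that("pseudofactors match hand expansion and enforce L > lambda", {
  # constant PSPCP column: every tier equals v^2
  d <- matrix(3, nrow = 10, ncol = 2)
  u <- pseudoFactors(d, 4)
  expect_equal(unname(as.vector(u)), rep(9, 8))

  # L = 4 toy, expanded by hand for k = 1..3
  d4 <- matrix(c(1, -2, 3, 0.5), ncol = 1)
  u4 <- pseudoFactors(d4, 3)
  expect_equal(u4[1, 1], (1 * -2 + -2 * 3 + 3 * 0.5) / 3)
  expect_equal(u4[2, 1], (1 * 3 + -2 * 0.5) / 2)
  expect_equal(u4[3, 1], 1 * 0.5)

  expect_error(pseudoFactors(d4, 4, "p1"), "p1")
  expect_error(pseudoFactors(d4, 5), "length 4")
})

test_that("descriptor vectors normalize to 1 with the documented layout and lengths", {
  expect_identical(descriptorLength(featureConfig(lambda = 11)), 119L)
  expect_identical(descriptorLength(featureConfig(lambda = 9)), 101L)

  set.seed(8)
  prof <- randomProfile(30)
  cfg <- featureConfig(w = 0.3, lambda = 5)
  q <- descriptorVector(prof, props9, cfg)
  expect_length(q, 20L + 5L * 9L)
  expect_lt(abs(sum(q) - 1), 1e-9)
  # pseudo block layout: entry 20 + (r-1)*lambda + k
  u <- pseudoFactors(pspcp(prof, props9), 5)
  f <- composition(prof)
  Z <- sum(f) + 0.3 * sum(u)
  for (r in c(1, 4, 9)) for (k in c(1, 5))
    expect_equal(unname(q[20 + (r - 1) * 5 + k]), unname(0.3 * u[k, r] / Z),
                 tolerance = 1e-12)
  expect_identical(names(q)[21], "u_BULH740101_k1")
  expect_identical(names(q)[20 + 8 * 5 + 4], "u_COSI940101_k4")
})

test_that("descriptor pipeline equals the straight-from-the-equations oracle", {
  set.seed(13)
  raw <- rawScaleValues()
  compared <- 0
  while (compared < 100) {
    L <- sample(12:40, 1)
    R <- sample(1:9, 1)
    lambda <- sample(seq_len(L - 1), 1)
    w <- runif(1, 0.05, 0.95)
    accs <- defaultPropertyAccessions()[seq_len(R)]
    pssm <- randomPSSM(L, -10L, 10L)
    props <- normalizeProperties(loadDefaultProperties()[accs])
    cfg <- featureConfig(w = w, lambda = lambda, accessions = accs)
    oracle <- naiveDescriptorFromE(pssm@E, raw[seq_len(R)], w, lambda)
    if (attr(oracle, "Z") <= 0) {
      # documented normalizer degeneracy: the pipeline must refuse exactly
      # when the oracle's normalizer vanishes
      expect_error(descriptorVector(standardizePssm(pssm), props, cfg),
                   "degenerate")
      next
    }
    q <- descriptorVector(standardizePssm(pssm), props, cfg)
    expect_lt(max(abs(unname(q) - as.vector(oracle))), 1e-10)
    compared <- compared + 1
  }
})

test_that("without PSSMs the pipeline degrades to plain amphiphilic pseudo-AAC", {
  set.seed(21)
  raw <- rawScaleValues()
  compared <- 0
  while (compared < 50) {
    L <- sample(15:50, 1)
    lambda <- sample(1:10, 1)
    w <- runif(1, 0.05, 0.95)
    s <- randomSequence(L)
    oracle <- naiveAmPseAAC(s, raw, w, lambda)
    if (attr(oracle, "Z") <= 0) {
      expect_error(descriptorVector(oneHotProfile(s, "d"), props9,
                                    featureConfig(w = w, lambda = lambda)),
                   "degenerate")
      next
    }
    q <- descriptorVector(oneHotProfile(s, "d"), props9,
                          featureConfig(w = w, lambda = lambda))
    expect_lt(max(abs(unname(q) - as.vector(oracle))), 1e-10)
    compared <- compared + 1
  }
})

test_that("increasing w shifts descriptor mass toward the pseudo block", {
  set.seed(3)
  prof <- randomProfile(25)
  pseudoMass <- function(w) {
    q <- descriptorVector(prof, props9, featureConfig(w = w, lambda = 4))
    sum(abs(q[21:length(q)])) / sum(abs(q[1:20]))
  }
  u <- pseudoFactors(pspcp(prof, props9), 4)
  expect_gt(sum(u != 0), 0)
  expect_gt(pseudoMass(0.6), pseudoMass(0.3))
  expect_gt(pseudoMass(0.3), pseudoMass(0.1))
})

test_that("feature extraction tracks origins, skips bad records, and round-trips TSV", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(syntheticSpec(nPerClass = c(a = 2L, b = 2L),
                                      lengthRange = c(25L, 30L),
                                      signalStrength = 1, seed = 9),
                        dir = dir)
  seqs <- readProteinFasta(file.path(dir, "sequences.fasta"))
  unlink(file.path(dir, paste0(names(seqs)[4], ".pssm")))
  cfg <- featureConfig(lambda = 5)
  suppressMessages(X <- extractFeatures(seqs, dir, props9, cfg))
  expect_identical(dim(X), c(4L, 65L))
  expect_identical(attr(X, "origins"), c("pssm", "pssm", "pssm", "one_hot"))
  expect_identical(rownames(X), names(seqs))

  # identical input twice gives identical rows
  suppressMessages(X2 <- extractFeatures(seqs, dir, props9, cfg))
  expect_identical(X, X2)

  expect_error(extractFeatures(seqs[0], dir, props9, cfg))

  # a sequence shorter than lambda is skipped with a warning (or aborts in
  # strict mode), and the others survive
  tooShort <- c(seqs, Biostrings::AAStringSet(c(tiny = "ACD")))
  suppressMessages(expect_warning(
    X3 <- extractFeatures(tooShort, dir, props9, cfg), "tiny"))
  expect_identical(nrow(X3), 4L)
  expect_identical(attr(X3, "skipped"), "tiny")
  suppressMessages(expect_error(
    extractFeatures(tooShort, dir, props9, cfg, strict = TRUE), "tiny"))

  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureMatrix(X, path)
  expect_equal(readFeatureMatrix(path), X, ignore_attr = TRUE,
               tolerance = 1e-15)
  expect_identical(rownames(readFeatureMatrix(path)), rownames(X))
})
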
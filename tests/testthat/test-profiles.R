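fastaFile <- function(...) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

test_that("FASTA reading parses, upper-cases and validates records", {
  seqs <- readProteinFasta(fastaFile(">p1 some description", "ACDEF"))
  expect_identical(names(seqs), "p1")
  expect_identical(as.character(seqs[[1]]), "ACDEF")
  expect_identical(Biostrings::width(seqs), 5L)

  lower <- readProteinFasta(fastaFile(">p1", "acdef"))
  expect_identical(as.character(lower[[1]]), "ACDEF")

  expect_error(readProteinFasta(fastaFile(">p1", "AC3EF")), "p1")
  expect_error(readProteinFasta(fastaFile(">p1", "ACDEF", ">p1", "ACDEF")),
               "duplicate")
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readProteinFasta(empty))
})

test_that("the ascii PSSM parser recovers hand-written log-odds exactly", {
  path <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(rep(residueOrder(), 2), collapse = "  ")),
    "    1 A  -1   2  -3   4  -5   6  -7   8  -9  10   0   1   2   3   4   5   6   7   8   9    5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5  0.36 0.12",
    "    2 C   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0    5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5   5  0.00 0.00",
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1337     0.3114"), path)
  pssm <- parseAsciiPssm(path, expectedSequence = "AC")
  expect_identical(dim(pssm@E), c(2L, 20L))
  expect_identical(unname(pssm@E[1, ]),
                   c(-1, 2, -3, 4, -5, 6, -7, 8, -9, 10, 0:9))
  expect_identical(unname(pssm@E[2, ]), rep(0, 20))
  expect_identical(pssm@residues, c("A", "C"))
  # residue-column mismatch is located
  expect_error(parseAsciiPssm(path, expectedSequence = "AD"), "position")
  expect_error(parseAsciiPssm(path, expectedSequence = "ACD"), "residues")
})

test_that("truncated or non-integer PSSM rows are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("", "header",
               paste("    1 A ", paste(rep("1", 19), collapse = " "))), path)
  expect_error(parseAsciiPssm(path), "no PSSM score rows|truncated")
  path2 <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("", "header",
               paste("    1 A ", paste(c(rep("1", 19), "0.5"), collapse = " "),
                     paste(rep("5", 20), collapse = " "), "0.1 0.2")), path2)
  expect_error(parseAsciiPssm(path2), "line 3")
})

test_that("softmax standardization is uniform on constant rows and matches hand values", {
  mkPssm <- function(rows) {
    E <- do.call(rbind, rows); storage.mode(E) <- "integer"
    colnames(E) <- residueOrder()
    new("PSSMMatrix", identifier = "t", E = E,
        residues = rep("A", length(rows)))
  }
  p <- standardizePssm(mkPssm(list(rep(7L, 20))))
  expect_equal(unname(p@A[1, ]), rep(0.05, 20), tolerance = 1e-12)
  expect_identical(p@origin, "pssm")

  p2 <- standardizePssm(mkPssm(list(c(1L, rep(0L, 19)))))
  expect_equal(unname(p2@A[1, 1]), exp(1) / (exp(1) + 19), tolerance = 1e-12)
  expect_equal(unname(p2@A[1, 2]), 1 / (exp(1) + 19), tolerance = 1e-12)

  # numerical stability on scores whose naive softmax overflows
  big <- mkPssm(list(c(10000L, rep(0L, 19))))
  p3 <- standardizePssm(big)
  expect_true(all(is.finite(p3@A)))
  expect_equal(sum(p3@A[1, ]), 1, tolerance = 1e-12)
  expect_gt(p3@A[1, 1], 1 - 1e-12)
})

test_that("softmax rows sum to 1 and are shift invariant on random integer scores", {
  set.seed(42)
  for (rep in 1:20) {
    pssm <- randomPSSM(sample(5:30, 1), -1000L, 1000L)
    prof <- standardizePssm(pssm)
    expect_lt(max(abs(rowSums(prof@A) - 1)), 1e-10)
    # adding a constant to a row leaves its softmax unchanged
    shifted <- pssm@E
    shifted[1, ] <- shifted[1, ] + 137L
    prof2 <- standardizePssm(new("PSSMMatrix", identifier = "s", E = shifted,
                                 residues = pssm@residues))
    expect_lt(max(abs(prof2@A[1, ] - prof@A[1, ])), 1e-10)
    # agreement with the naive formula on rows that do not overflow
    small <- randomPSSM(3, -20L, 20L)
    profS <- standardizePssm(small)
    for (i in 1:3)
      expect_equal(unname(profS@A[i, ]), unname(naiveSoftmaxRow(small@E[i, ])),
                   tolerance = 1e-12)
  }
})

test_that("one-hot profiles encode standard residues exactly and degenerate ones uniformly", {
  p <- oneHotProfile("A", "x")
  expect_identical(dim(p@A), c(1L, 20L))
  expect_identical(unname(p@A[1, ]), c(1, rep(0, 19)))
  expect_identical(p@origin, "one_hot")

  px <- oneHotProfile("X", "x")
  expect_equal(unname(px@A[1, ]), rep(0.05, 20))

  set.seed(1)
  s <- randomSequence(40)
  prof <- oneHotProfile(s, "rt")
  expect_true(all(abs(rowSums(prof@A) - 1) < 1e-12))
  # row-argmax recovers the sequence
  expect_identical(paste(residueOrder()[apply(prof@A, 1, which.max)],
                         collapse = ""), s)
})

test_that("profile loading falls back to one-hot and validates PSSMs against sequences", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(syntheticSpec(
    nPerClass = c(a = 2L, b = 2L), lengthRange = c(20L, 25L),
    signalStrength = 1, seed = 3), dir = dir)
  seqs <- readProteinFasta(file.path(dir, "sequences.fasta"))
  # drop one PSSM to force a fallback
  unlink(file.path(dir, paste0(names(seqs)[1], ".pssm")))
  expect_message(profiles <- loadProfiles(seqs, dir), "1 of 4")
  expect_identical(attr(profiles, "origins"),
                   c("one_hot", "pssm", "pssm", "pssm"))
  expect_identical(unname(vapply(profiles, function(p) p@origin,
                                 character(1))),
                   c("one_hot", "pssm", "pssm", "pssm"))
})
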
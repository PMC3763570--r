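test_that("the default grid has the documented cardinalities and bounds", {
  g <- defaultGrid()
  expect_length(g@wValues, 20L)
  expect_length(g@lambdaValues, 19L)
  expect_identical(length(g@wValues) * length(g@lambdaValues), 380L)
  expect_equal(g@wValues, seq(0.05, 1, by = 0.05))
  expect_identical(g@lambdaValues, 2:20)
  expect_true(all(g@gammaValues > 0))
  expect_true(all(g@cValues > 0))
})

# small shared calibration study: 12 sequences, 3 classes, reduced grid
calFixture <- function() {
  props <- normalizeProperties(loadDefaultProperties())
  ds <- generateDataset(syntheticSpec(
    nPerClass = c(a = 4L, b = 4L, c = 4L), lengthRange = c(30L, 40L),
    signalStrength = 4, seed = 15))
  list(profiles = datasetProfiles(ds), labels = ds@labels, props = props)
}

test_that("calibration records every feasible combination and the winner is the argmax", {
  fx <- calFixture()
  grid <- calibrationGrid(wValues = c(0.1, 0.2), lambdaValues = c(2L, 4L),
                          gammaValues = c(2, 32), cValues = c(1, 8))
  res <- calibrate(fx$profiles, fx$labels, fx$props, grid)
  expect_identical(nrow(res@records), 4L)
  expect_true(all(res@winner$acc >= res@records$acc))
  expect_identical(nrow(res@infeasible), 0L)

  # the winner's accuracy is reproduced by an independent jackknife call
  w <- res@winner
  X <- do.call(rbind, lapply(fx$profiles, descriptorVector, props = fx$props,
                             config = featureConfig(w = w$w, lambda = w$lambda)))
  rownames(X) <- names(fx$profiles)
  cfg <- modelConfig(gamma = w$gamma, cost = w$C,
                     featureConfig = featureConfig(w = w$w, lambda = w$lambda),
                     classLabels = sort(unique(fx$labels)))
  expect_identical(jackknife(X, fx$labels, cfg)@acc, w$acc)

  # determinism
  res2 <- calibrate(fx$profiles, fx$labels, fx$props, grid)
  expect_identical(res@records, res2@records)
  expect_identical(res@winner, res2@winner)
})

test_that("ties are listed and broken toward the simplest model", {
  fx <- calFixture()
  # small w values keep every combination inside the descriptor's valid
  # domain (larger w can drive the normalizer Z nonpositive on this fixture)
  grid <- calibrationGrid(wValues = c(0.05, 0.1), lambdaValues = c(2L, 3L),
                          gammaValues = 32, cValues = 8)
  res <- calibrate(fx$profiles, fx$labels, fx$props, grid)
  top <- res@records[res@records$acc == res@winner$acc, ]
  expect_identical(nrow(res@ties), nrow(top))
  expect_identical(res@winner$lambda, min(top$lambda))
  sameLambda <- top[top$lambda == res@winner$lambda, ]
  expect_identical(res@winner$w, min(sameLambda$w))
})

test_that("infeasible lambda values are reported, and grid subsetting never improves the winner", {
  fx <- calFixture()  # shortest sequence has 30 residues
  grid <- calibrationGrid(wValues = 0.15, lambdaValues = c(2L, 35L),
                          gammaValues = 32, cValues = 8)
  expect_message(res <- calibrate(fx$profiles, fx$labels, fx$props, grid),
                 "infeasible")
  expect_identical(res@infeasible$lambda, 35L)
  expect_identical(nrow(res@records), 1L)

  full <- calibrate(fx$profiles, fx$labels, fx$props,
                    calibrationGrid(c(0.1, 0.2), c(2L, 4L), c(2, 32), c(1, 8)))
  sub <- calibrate(fx$profiles, fx$labels, fx$props,
                   calibrationGrid(full@winner$w, full@winner$lambda,
                                   full@winner$gamma, full@winner$C))
  expect_identical(sub@winner$acc, full@winner$acc)
  expect_lte(sub@winner$acc, full@winner$acc)

  shortGrid <- calibrationGrid(0.15, 40L, 32, 8)
  expect_error(calibrate(fx$profiles, fx$labels, fx$props, shortGrid),
               "no feasible lambda")
})

test_that("calibration results serialize to TSV plus a JSON winner block", {
  fx <- calFixture()
  res <- calibrate(fx$profiles, fx$labels, fx$props,
                   calibrationGrid(0.15, 2L, 32, 8))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeCalibration(res, tsv)
  tab <- read.table(tsv, sep = "\t", header = TRUE)
  expect_identical(nrow(tab), nrow(res@records))
  js <- jsonlite::read_json(paste0(tsv, ".winner.json"), simplifyVector = TRUE)
  expect_equal(js$winner$acc, res@winner$acc)
})
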
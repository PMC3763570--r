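#' Per-class confusion counts from truth/prediction vectors
#'
#' @param truth,predicted Parallel label vectors.
#' @param classLabels Class order; defaults to the sorted union of labels.
#' @return List with \code{confusion} (k x k table, rows truth) and
#'   \code{counts} (k x 4 matrix of TP, FN, FP, TN per class).
#' @export
confusionCounts <- function(truth, predicted,
                            classLabels = sort(unique(c(truth, predicted)))) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and prediction vectors differ in length")
  bad <- setdiff(unique(c(truth, predicted)), classLabels)
  if (length(bad)) stop("labels outside the class set: ",
                        paste(bad, collapse = ", "))
  conf <- table(factor(truth, levels = classLabels),
                factor(predicted, levels = classLabels))
  conf <- unclass(conf)
  N <- sum(conf)
  counts <- t(vapply(seq_along(classLabels), function(s) {
    TP <- conf[s, s]
    FN <- sum(conf[s, ]) - TP
    FP <- sum(conf[, s]) - TP
    TN <- N - TP - FN - FP
    c(TP = TP, FN = FN, FP = FP, TN = TN)
  }, numeric(4)))
  rownames(counts) <- classLabels
  list(confusion = conf, counts = counts)
}

# Matthews correlation with the 0-on-zero-denominator convention
.mcc <- function(TP, FN, FP, TN) {
  den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  if (den == 0) return(0)
  (TP * TN - FP * FN) / den
}

#' Per-class accuracy, MCC and overall accuracy from confusion counts
#'
#' Acc_s = TP_s / (TP_s + FN_s); MCC_s is the Matthews correlation
#' coefficient with the standard 0 convention when its denominator vanishes;
#' overall ACC = sum_s TP_s / sum_s (TP_s + FN_s).  A class with no true
#' members (TP_s + FN_s = 0) gets Acc_s = NA with a warning, never a silent 0.
#'
#' @param counts k x 4 TP/FN/FP/TN matrix as from \code{\link{confusionCounts}}.
#' @param confusion Optional k x k confusion table to store in the report.
#' @param protocol Protocol tag for the report.
#' @param details Optional list of protocol-specific extras.
#' @return An \code{\link{EvaluationReport}}.
#' @export
confusionMetrics <- function(counts, confusion = matrix(NA_real_, 0, 0),
                             protocol = "resubstitution", details = list()) {
  classLabels <- rownames(counts)
  acc <- counts[, "TP"] / (counts[, "TP"] + counts[, "FN"])
  noTruth <- (counts[, "TP"] + counts[, "FN"]) == 0
  if (any(noTruth)) {
    warning("class(es) with no true members; per-class accuracy undefined: ",
            paste(classLabels[noTruth], collapse = ", "))
    acc[noTruth] <- NA_real_
  }
  mcc <- vapply(seq_len(nrow(counts)), function(s)
    .mcc(counts[s, "TP"], counts[s, "FN"], counts[s, "FP"], counts[s, "TN"]),
    numeric(1))
  names(mcc) <- classLabels
  overall <- sum(counts[, "TP"]) / sum(counts[, "TP"] + counts[, "FN"])
  new("EvaluationReport", classLabels = classLabels, confusion = confusion,
      counts = counts, accPerClass = acc, mccPerClass = mcc, acc = overall,
      protocol = protocol, details = details)
}

#' Evaluate predictions against true labels
#'
#' @param truth,predicted Parallel label vectors.
#' @param classLabels Class order.
#' @param protocol Protocol tag.
#' @param details Extras to store in the report.
#' @return An \code{\link{EvaluationReport}}.
#' @export
evaluatePredictions <- function(truth, predicted,
                                classLabels = sort(unique(c(truth, predicted))),
                                protocol = "resubstitution",
                                details = list()) {
  cc <- confusionCounts(truth, predicted, classLabels)
  confusionMetrics(cc$counts, cc$confusion, protocol, details)
}

#' Jackknife (leave-one-out) evaluation
#'
#' For each of the N rows, trains on the remaining N-1 rows with the fixed
#' model configuration and predicts the held-out row; predictions are
#' aggregated into one confusion matrix.  Deterministic end to end.  The
#' jackknife is the reference protocol for this method's benchmark numbers.
#'
#' @param features Numeric matrix, one row per sequence.
#' @param labels Class labels, one per row; every class needs >= 2 members
#'   so no training fold loses a class entirely.
#' @param config A \code{\link{ModelConfig}}.
#' @param trainFun,predictFun Classifier hooks; default to the package SVM.
#'   Supplying e.g. a nearest-neighbour pair lets the protocol be tested
#'   independently of the SVM.
#' @return An \code{\link{EvaluationReport}} with protocol "jackknife".
#' @export
jackknife <- function(features, labels, config,
                      trainFun = trainModel, predictFun = predictLabels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  N <- nrow(features)
  if (N != length(labels)) stop("features and labels differ in length")
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least two classes")
  if (N < length(tab) + 1L) stop("too few samples for a jackknife")
  if (any(tab < 2L))
    stop("class(es) with a single member would vanish from a training fold: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  predicted <- character(N)
  for (i in seq_len(N)) {
    model <- trainFun(features[-i, , drop = FALSE], labels[-i], config)
    predicted[i] <- predictFun(model, features[i, , drop = FALSE])
  }
  evaluatePredictions(labels, predicted, config@classLabels,
                      protocol = "jackknife")
}

#' Repeated random hold-out (independent dataset) evaluation
#'
#' Each repeat draws round(trainFraction * N) rows uniformly at random
#' without stratification as its training set, trains, and evaluates on the
#' complement.  A repeat whose training set misses a class is redrawn with a
#' warning (bounded retries).  Reports the mean and the population standard
#' deviation of overall accuracy across repeats, fully reproducible from the
#' master seed (which spawns one sub-seed per repeat).
#'
#' @param features Numeric matrix.
#' @param labels Class labels.
#' @param config A \code{\link{ModelConfig}}.
#' @param trainFraction Fraction of rows used for training, in (0, 1).
#' @param repeats Number of random splits (>= 1).
#' @param seed Master integer seed.
#' @return List with \code{meanAcc}, \code{sdAcc} (population sd),
#'   \code{accs}, per-repeat \code{reports} and the spawned \code{seeds}.
#' @export
holdoutTest <- function(features, labels, config, trainFraction = 0.8,
                        repeats = 20L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  if (repeats < 1L) stop("repeats must be >= 1")
  N <- nrow(features)
  nTrain <- round(trainFraction * N)
  if (nTrain < 2L || nTrain >= N)
    stop("training fraction leaves no usable train/test split for N = ", N)
  set.seed(seed)
  repeatSeeds <- sample.int(.Machine$integer.max, repeats)
  reports <- vector("list", repeats)
  accs <- numeric(repeats)
  for (rep in seq_len(repeats)) {
    set.seed(repeatSeeds[rep])
    trainIdx <- NULL
    for (try in 1:100) {
      idx <- sample.int(N, nTrain)
      if (length(unique(labels[idx])) >= 2L &&
          length(unique(labels[-idx])) >= 1L) { trainIdx <- idx; break }
      warning("repeat ", rep, ": training draw missed a class; redrawing")
    }
    if (is.null(trainIdx))
      stop("could not draw a training set containing two classes")
    model <- trainModel(features[trainIdx, , drop = FALSE], labels[trainIdx],
                        config)
    pred <- predictLabels(model, features[-trainIdx, , drop = FALSE])
    reports[[rep]] <- evaluatePredictions(labels[-trainIdx], pred,
                                          config@classLabels,
                                          protocol = "holdout",
                                          details = list(seed = repeatSeeds[rep]))
    accs[rep] <- reports[[rep]]@acc
  }
  list(meanAcc = mean(accs),
       sdAcc = sqrt(mean((accs - mean(accs))^2)),  # population sd
       accs = accs, reports = reports, seeds = repeatSeeds,
       trainFraction = trainFraction, masterSeed = seed)
}

#' Tabulate an evaluation report
#'
#' One row per class plus an overall row, with accuracies as percentages to
#' two decimals (full precision stays in the report object).
#'
#' @param report An \code{\link{EvaluationReport}}.
#' @return A data.frame with columns class, ACC and MCC.
#' @export
reportTable <- function(report) {
  data.frame(
    class = c(report@classLabels, "overall"),
    ACC = sprintf("%.2f%%", 100 * c(report@accPerClass, report@acc)),
    MCC = c(sprintf("%.2f", report@mccPerClass), ""),
    stringsAsFactors = FALSE)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An \code{\link{EvaluationReport}}.
#' @param path Output path; when NULL the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
writeReport <- function(report, path = NULL) {
  x <- list(protocol = report@protocol,
            class_labels = report@classLabels,
            confusion = report@confusion,
            counts = report@counts,
            acc_per_class = as.list(report@accPerClass),
            mcc_per_class = as.list(report@mccPerClass),
            overall_acc = report@acc)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
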
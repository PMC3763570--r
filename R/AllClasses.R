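#' @import methods
#' @importFrom stats predict rnorm runif sd cor
#' @importFrom utils read.table write.table packageVersion
NULL

#' Canonical residue order
#'
#' The 20 standard amino acids in the column order of a PSI-BLAST ASCII PSSM
#' (A R N D C Q E G H I L K M F P S T W Y V).  This order indexes every
#' 20-wide object in the package: property scales, profile columns and the
#' composition block of descriptor vectors.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
#' @examples
#' residueOrder()
residueOrder <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# residues accepted in input sequences beyond the standard 20; they carry no
# property information and map to a uniform substitution row
DEGENERATE_RESIDUES <- c("X", "B", "Z", "U", "O", "J")

#' PropertyScale: one amino-acid physicochemical property scale
#'
#' Holds the raw (unnormalized) values H(r, j) of one AAindex-style scale,
#' one value per standard amino acid, named and ordered by
#' \code{\link{residueOrder}}.
#'
#' @slot accession AAindex accession string (e.g. "BULH740101").
#' @slot description Free-text description of the property.
#' @slot values Named numeric vector of 20 finite values.
#' @export
setClass("PropertyScale",
  representation(accession = "character",
                 description = "character",
                 values = "numeric"))

setValidity("PropertyScale", function(object) {
  msgs <- character(0)
  if (length(object@accession) != 1L || !nzchar(object@accession))
    msgs <- c(msgs, "accession must be a single non-empty string")
  if (length(object@values) != 20L)
    msgs <- c(msgs, "exactly 20 values required, one per standard amino acid")
  if (!all(is.finite(object@values)))
    msgs <- c(msgs, "all property values must be finite")
  if (!identical(names(object@values), residueOrder()))
    msgs <- c(msgs, "values must be named in canonical residue order")
  if (length(msgs)) msgs else TRUE
})

#' NormalizedPropertyTable: z-scored property scales
#'
#' An R x 20 matrix of normalized property values h(r, j), each row with mean
#' 0 and population standard deviation 1 over the 20 amino acids; columns in
#' canonical residue order, rows named by accession.
#'
#' @slot h Numeric R x 20 matrix of normalized values.
#' @slot accessions Ordered accession strings (rownames of h).
#' @slot descriptions Scale descriptions, parallel to accessions.
#' @export
setClass("NormalizedPropertyTable",
  representation(h = "matrix",
                 accessions = "character",
                 descriptions = "character"))

setValidity("NormalizedPropertyTable", function(object) {
  msgs <- character(0)
  h <- object@h
  if (ncol(h) != 20L || !identical(colnames(h), residueOrder()))
    msgs <- c(msgs, "h must have 20 columns in canonical residue order")
  if (nrow(h) != length(object@accessions))
    msgs <- c(msgs, "row count must equal number of accessions")
  if (nrow(h) > 0) {
    if (anyDuplicated(object@accessions))
      msgs <- c(msgs, "accessions must be unique")
    mu <- rowMeans(h)
    sp <- sqrt(rowMeans(sweep(h, 1, mu)^2))
    if (any(abs(mu) > 1e-9))
      msgs <- c(msgs, "every normalized scale must have mean 0 (tol 1e-9)")
    if (any(abs(sp - 1) > 1e-9))
      msgs <- c(msgs, "every normalized scale must have population sd 1 (tol 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})

#' PSSMMatrix: raw PSI-BLAST log-odds scores
#'
#' The L x 20 integer log-odds block of a PSI-BLAST ASCII PSSM, plus the
#' query residues as read from the file.
#'
#' @slot identifier Sequence identifier.
#' @slot E Integer-valued L x 20 matrix of log-odds scores (may be negative).
#' @slot residues The L query residues from the PSSM's residue column.
#' @export
setClass("PSSMMatrix",
  representation(identifier = "character",
                 E = "matrix",
                 residues = "character"))

setValidity("PSSMMatrix", function(object) {
  msgs <- character(0)
  if (ncol(object@E) != 20L)
    msgs <- c(msgs, "E must have exactly 20 score columns")
  if (nrow(object@E) != length(object@residues))
    msgs <- c(msgs, "row count of E must equal length of residue column")
  if (!all(is.finite(object@E)))
    msgs <- c(msgs, "all scores must be finite")
  if (any(object@E != round(object@E)))
    msgs <- c(msgs, "log-odds scores must be integers")
  if (length(msgs)) msgs else TRUE
})

#' StandardizedProfile: per-residue substitution probabilities
#'
#' An L x 20 row-stochastic matrix A where row i is the softmax-standardized
#' substitution distribution of residue i over the 20 amino acids.  Rows
#' come either from a PSSM (origin "pssm") or from the one-hot fallback
#' (origin "one_hot") used when no PSSM is available.
#'
#' @slot identifier Sequence identifier.
#' @slot A Numeric L x 20 matrix; entries in [0, 1]; rows sum to 1.
#' @slot origin Either "pssm" or "one_hot".
#' @export
setClass("StandardizedProfile",
  representation(identifier = "character",
                 A = "matrix",
                 origin = "character"))

setValidity("StandardizedProfile", function(object) {
  msgs <- character(0)
  A <- object@A
  if (ncol(A) != 20L || !identical(colnames(A), residueOrder()))
    msgs <- c(msgs, "A must have 20 columns in canonical residue order")
  if (nrow(A) < 1L)
    msgs <- c(msgs, "profile must have at least one row")
  if (any(A < 0 | A > 1))
    msgs <- c(msgs, "all entries must lie in [0, 1]")
  if (nrow(A) > 0 && any(abs(rowSums(A) - 1) > 1e-10))
    msgs <- c(msgs, "every row must sum to 1 (tol 1e-10)")
  if (!object@origin %in% c("pssm", "one_hot"))
    msgs <- c(msgs, "origin must be 'pssm' or 'one_hot'")
  if (length(msgs)) msgs else TRUE
})

#' FeatureConfig: descriptor parameters
#'
#' @slot w Weight of the sequence-order (pseudofactor) block; in (0, 1).
#' @slot lambda Number of correlation tiers; positive integer, must be
#'   smaller than every sequence length it is applied to.
#' @slot accessions Ordered accessions of the property scales used (defines R).
#' @export
setClass("FeatureConfig",
  representation(w = "numeric", lambda = "integer", accessions = "character"))

setValidity("FeatureConfig", function(object) {
  msgs <- character(0)
  if (length(object@w) != 1L || !is.finite(object@w) ||
      object@w <= 0 || object@w >= 1)
    msgs <- c(msgs, "w must be a single value in (0, 1)")
  if (length(object@lambda) != 1L || is.na(object@lambda) || object@lambda < 1L)
    msgs <- c(msgs, "lambda must be a positive integer")
  if (length(object@accessions) < 1L)
    msgs <- c(msgs, "at least one property scale is required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureConfig
#'
#' Defaults are the operating point recommended for the method on the
#' SML3-983 benchmark: w = 0.15, lambda = 11, with the nine bundled property
#' scales (descriptor length 20 + 11*9 = 119).
#'
#' @param w Pseudofactor weight in (0, 1).
#' @param lambda Number of sequence-order tiers (positive integer).
#' @param accessions Property accessions defining R; defaults to the nine
#'   bundled scales.
#' @return A \code{FeatureConfig} object.
#' @export
#' @examples
#' cfg <- featureConfig(w = 0.15, lambda = 11)
#' descriptorLength(cfg)  # 119
featureConfig <- function(w = 0.15, lambda = 11L,
                          accessions = defaultPropertyAccessions()) {
  new("FeatureConfig", w = as.numeric(w), lambda = as.integer(lambda),
      accessions = as.character(accessions))
}

#' Descriptor vector length for a configuration
#'
#' @param config A \code{FeatureConfig}.
#' @return Integer, 20 + lambda * R.
#' @export
descriptorLength <- function(config) {
  stopifnot(is(config, "FeatureConfig"))
  20L + config@lambda * length(config@accessions)
}

#' ModelConfig: SVM hyperparameters plus the feature configuration
#'
#' @slot gamma RBF kernel width parameter; positive.
#' @slot cost Soft-margin cost C; positive.
#' @slot featureConfig The \code{FeatureConfig} the features were built with.
#' @slot classLabels Ordered class label strings (at least two).
#' @export
setClass("ModelConfig",
  representation(gamma = "numeric", cost = "numeric",
                 featureConfig = "FeatureConfig", classLabels = "character"))

setValidity("ModelConfig", function(object) {
  msgs <- character(0)
  if (length(object@gamma) != 1L || !is.finite(object@gamma) || object@gamma <= 0)
    msgs <- c(msgs, "gamma must be a single positive value")
  if (length(object@cost) != 1L || !is.finite(object@cost) || object@cost <= 0)
    msgs <- c(msgs, "cost must be a single positive value")
  if (length(object@classLabels) < 2L || anyDuplicated(object@classLabels))
    msgs <- c(msgs, "at least two distinct class labels are required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ModelConfig
#'
#' Defaults are the calibrated optimum reported for the SML3-983 benchmark
#' (gamma = 0.125, C = 8) with the default three submitochondrial classes.
#'
#' @param gamma RBF kernel parameter (> 0).
#' @param cost SVM cost parameter (> 0).
#' @param featureConfig A \code{FeatureConfig}.
#' @param classLabels Ordered class labels.
#' @return A \code{ModelConfig} object.
#' @export
modelConfig <- function(gamma = 0.125, cost = 8,
                        featureConfig = PSPCPloc::featureConfig(),
                        classLabels = c("inner_membrane", "matrix",
                                        "outer_membrane")) {
  new("ModelConfig", gamma = as.numeric(gamma), cost = as.numeric(cost),
      featureConfig = featureConfig, classLabels = as.character(classLabels))
}

#' TrainedModel: a fitted one-vs-one RBF SVM
#'
#' @slot fit The fitted \code{e1071::svm} object.
#' @slot config The \code{ModelConfig} used for training.
#' @slot featureNames Column names of the training matrix.
#' @slot fingerprint md5 of the serialized training matrix and labels;
#'   stable across identical retrains.
#' @export
setClass("TrainedModel",
  representation(fit = "ANY", config = "ModelConfig",
                 featureNames = "character", fingerprint = "character"))

#' EvaluationReport: per-class and overall classification performance
#'
#' @slot classLabels Class order used throughout.
#' @slot confusion k x k contingency table (rows truth, columns prediction).
#' @slot counts k x 4 matrix of TP, FN, FP, TN per class.
#' @slot accPerClass Per-class accuracy Acc_s = TP_s / (TP_s + FN_s).
#' @slot mccPerClass Per-class Matthews correlation coefficient.
#' @slot acc Overall accuracy.
#' @slot protocol "jackknife", "holdout" or "resubstitution".
#' @slot details Protocol-specific extras (seeds, per-repeat reports, ...).
#' @export
setClass("EvaluationReport",
  representation(classLabels = "character", confusion = "matrix",
                 counts = "matrix", accPerClass = "numeric",
                 mccPerClass = "numeric", acc = "numeric",
                 protocol = "character", details = "list"))

#' CalibrationGrid: parameter grids for calibration
#'
#' @slot wValues Candidate pseudofactor weights.
#' @slot lambdaValues Candidate tier counts.
#' @slot gammaValues Candidate RBF gamma values.
#' @slot cValues Candidate SVM cost values.
#' @export
setClass("CalibrationGrid",
  representation(wValues = "numeric", lambdaValues = "integer",
                 gammaValues = "numeric", cValues = "numeric"))

setValidity("CalibrationGrid", function(object) {
  msgs <- character(0)
  if (!length(object@wValues) || any(!is.finite(object@wValues)) ||
      any(object@wValues <= 0) || any(object@wValues > 1))
    msgs <- c(msgs, "wValues must be nonempty, in (0, 1]")
  if (!length(object@lambdaValues) || any(object@lambdaValues < 1L))
    msgs <- c(msgs, "lambdaValues must be nonempty positive integers")
  if (!length(object@gammaValues) || any(object@gammaValues <= 0))
    msgs <- c(msgs, "gammaValues must be nonempty and positive")
  if (!length(object@cValues) || any(object@cValues <= 0))
    msgs <- c(msgs, "cValues must be nonempty and positive")
  if (length(msgs)) msgs else TRUE
})

#' CalibrationResult: outcome of a grid calibration
#'
#' @slot records One row per feasible (w, lambda) pair with the best
#'   (gamma, C) found for it and the corresponding jackknife accuracy.
#' @slot winner Single-row data.frame: the argmax combination.
#' @slot ties Rows whose accuracy equals the winner's.
#' @slot infeasible (w, lambda) pairs skipped (lambda >= shortest sequence).
#' @export
setClass("CalibrationResult",
  representation(records = "data.frame", winner = "data.frame",
                 ties = "data.frame", infeasible = "data.frame"))

#' SyntheticSpec: parameters of the synthetic dataset generator
#'
#' @slot nPerClass Sequences per class (each >= 2).
#' @slot lengthRange Integer [min, max] sequence length; min >= 3.
#' @slot signalStrength Nonnegative class-signal strength; 0 means
#'   exchangeable classes (a null model).
#' @slot mode "composition" (class-specific residue usage only), "order"
#'   (identical usage, class-specific periodic motif only) or "both".
#' @slot motifPeriods Per-class motif period; 0 disables the motif for that
#'   class.
#' @slot seed Integer seed; output is fully determined by it.
#' @export
setClass("SyntheticSpec",
  representation(nPerClass = "integer", lengthRange = "integer",
                 signalStrength = "numeric", mode = "character",
                 motifPeriods = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character(0)
  if (length(object@nPerClass) < 2L || any(object@nPerClass < 2L))
    msgs <- c(msgs, "need at least 2 classes with at least 2 sequences each")
  if (length(object@lengthRange) != 2L || object@lengthRange[1] < 3L ||
      object@lengthRange[2] < object@lengthRange[1])
    msgs <- c(msgs, "lengthRange must be [min, max] with min >= 3")
  if (object@signalStrength < 0)
    msgs <- c(msgs, "signalStrength must be nonnegative")
  if (!object@mode %in% c("composition", "order", "both"))
    msgs <- c(msgs, "mode must be 'composition', 'order' or 'both'")
  if (length(object@motifPeriods) != length(object@nPerClass) ||
      any(object@motifPeriods < 0L))
    msgs <- c(msgs, "motifPeriods must give one nonnegative period per class")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' LabeledDataset: sequences, labels and (optional) PSSMs
#'
#' @slot sequences An \code{AAStringSet}; names are identifiers.
#' @slot labels Character class labels, parallel to sequences.
#' @slot pssms Named list of \code{PSSMMatrix} (possibly empty).
#' @export
setClass("LabeledDataset",
  representation(sequences = "ANY", labels = "character", pssms = "list"))

setValidity("LabeledDataset", function(object) {
  msgs <- character(0)
  if (!is(object@sequences, "AAStringSet"))
    msgs <- c(msgs, "sequences must be an AAStringSet")
  else if (length(object@sequences) != length(object@labels))
    msgs <- c(msgs, "one label per sequence required")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StandardizedProfile", function(object) {
  cat(sprintf("StandardizedProfile '%s': %d positions x 20 residues (origin: %s)\n",
              object@identifier, nrow(object@A), object@origin))
})

setMethod("show", "NormalizedPropertyTable", function(object) {
  cat(sprintf("NormalizedPropertyTable: %d z-scored scales over 20 amino acids\n",
              nrow(object@h)))
  cat("  ", paste(object@accessions, collapse = ", "), "\n", sep = "")
})

setMethod("show", "FeatureConfig", function(object) {
  cat(sprintf("FeatureConfig: w = %g, lambda = %d, R = %d (length %d)\n",
              object@w, object@lambda, length(object@accessions),
              descriptorLength(object)))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: gamma = %g, C = %g, classes: %s\n",
              object@gamma, object@cost,
              paste(object@classLabels, collapse = ", ")))
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel (one-vs-one RBF SVM)\n")
  show(object@config)
  cat(sprintf("  features: %d, fingerprint: %s\n",
              length(object@featureNames), object@fingerprint))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%s)\n", object@protocol))
  print(reportTable(object))
})

setMethod("show", "LabeledDataset", function(object) {
  tab <- table(object@labels)
  cat(sprintf("LabeledDataset: %d sequences, %d PSSMs\n",
              length(object@sequences), length(object@pssms)))
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: %d (w, lambda) combinations evaluated\n",
              nrow(object@records)))
  cat("winner:\n")
  print(object@winner)
  if (nrow(object@ties) > 1L)
    cat(sprintf("(%d tied combinations; deterministic tie-break applied)\n",
                nrow(object@ties)))
})
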
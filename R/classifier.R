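#' RBF kernel between two descriptor vectors
#'
#' K(x, y) = exp(-gamma * |x - y|^2) with |.| the Euclidean norm.  Bounded in
#' (0, 1], equal to 1 exactly when x == y.  Implemented independently of the
#' SVM solver so the kernel contract is testable on its own.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Positive kernel width parameter.
#' @return The kernel value, a single number.
#' @export
#' @examples
#' rbfKernel(c(1, 0), c(0, 1), gamma = 0.125)  # exp(-0.25)
rbfKernel <- function(x, y, gamma) {
  if (length(x) != length(y))
    stop("kernel dimension mismatch: ", length(x), " vs ", length(y))
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((x - y)^2))
}

# md5 of the serialized training data; base R has no in-memory md5 so the
# bytes go through a temp file
.fingerprint <- function(features, labels) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(list(unname(features), as.character(labels)), con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Train a one-vs-one RBF-kernel SVM
#'
#' Fits a C-classification SVM with radial kernel via e1071 (LIBSVM), the
#' toolchain whose one-vs-one voting multiclass scheme this method assumes.
#' Descriptor vectors already sum to 1 by construction, so no additional
#' feature rescaling is applied (\code{scale = FALSE}).  Training is
#' deterministic for identical inputs; the returned model carries a
#' fingerprint of the training data.
#'
#' @param features Numeric matrix, one row per training sequence.
#' @param labels Class labels, one per row; at least two distinct classes.
#' @param config A \code{\link{ModelConfig}}; its \code{classLabels} fixes
#'   the class order (labels outside it are an error).
#' @return A \code{\link{TrainedModel}}.
#' @export
trainModel <- function(features, labels, config) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stop("row count (", nrow(features), ") does not match label count (",
         length(labels), ")")
  if (any(!is.finite(features)))
    stop("training features contain non-finite values")
  bad <- setdiff(unique(labels), config@classLabels)
  if (length(bad))
    stop("labels not in the configured class set: ",
         paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop("training data must contain at least two classes, found ",
         length(unique(labels)))
  y <- factor(labels, levels = config@classLabels)
  y <- droplevels(y)
  # fixed solver tie-break seed, restoring the caller's RNG stream afterwards
  rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(20130821L)
  fit <- e1071::svm(x = features, y = y, type = "C-classification",
                    kernel = "radial", gamma = config@gamma,
                    cost = config@cost, scale = FALSE)
  new("TrainedModel", fit = fit, config = config,
      featureNames = colnames(features) %||% character(0),
      fingerprint = .fingerprint(features, labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class labels for new descriptor vectors
#'
#' @param model A \code{\link{TrainedModel}}.
#' @param features Numeric matrix with the same column count (and order) as
#'   the training matrix.
#' @return Character vector of predicted labels, one per row (empty for an
#'   empty matrix).
#' @export
predictLabels <- function(model, features) {
  stopifnot(is(model, "TrainedModel"))
  features <- as.matrix(features)
  trainDim <- ncol(model@fit$SV)
  if (ncol(features) != trainDim)
    stop("feature dimension mismatch: model was trained on ", trainDim,
         " features, got ", ncol(features))
  if (nrow(features) == 0L) return(character(0))
  if (length(model@featureNames) && !is.null(colnames(features)) &&
      !identical(colnames(features), model@featureNames))
    stop("feature names/order differ from the training matrix")
  as.character(predict(model@fit, features))
}

#' Save a trained model with a JSON sidecar
#'
#' Writes the fitted state to \code{path} (RDS) and a human-readable JSON
#' sidecar \code{<path>.json} holding the model configuration, class labels,
#' feature names and training fingerprint.  \code{\link{loadModel}} verifies
#' the sidecar against the archive.
#'
#' @param model A \code{\link{TrainedModel}}.
#' @param path Output path for the model archive.
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  saveRDS(model, path)
  sidecar <- list(
    package = "PSPCPloc",
    version = as.character(packageVersion("PSPCPloc")),
    gamma = model@config@gamma,
    cost = model@config@cost,
    w = model@config@featureConfig@w,
    lambda = model@config@featureConfig@lambda,
    property_accessions = model@config@featureConfig@accessions,
    class_labels = model@config@classLabels,
    feature_names = model@featureNames,
    n_features = length(model@featureNames),
    training_fingerprint = model@fingerprint)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model archive, verifying its sidecar
#'
#' @param path Path passed to \code{\link{saveModel}}.
#' @return A \code{\link{TrainedModel}}.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  model <- readRDS(path)
  if (!is(model, "TrainedModel")) stop("not a model archive: ", path)
  sidecarPath <- paste0(path, ".json")
  if (file.exists(sidecarPath)) {
    sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
    if (!identical(sc$training_fingerprint, model@fingerprint))
      stop("model sidecar fingerprint does not match the archive")
    if (!isTRUE(all.equal(sc$gamma, model@config@gamma)) ||
        !isTRUE(all.equal(sc$cost, model@config@cost)) ||
        sc$lambda != model@config@featureConfig@lambda)
      stop("model sidecar configuration does not match the archive")
  }
  model
}
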
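#' Positional specific physicochemical properties (PSPCP)
#'
#' For each sequence position i and each normalized property r, the PSPCP is
#' the expectation of the z-scored property under the position's substitution
#' distribution: d[i, r] = sum_j A[i, j] * h[r, j].  For a one-hot profile
#' this collapses to the residue's own normalized property value; for a
#' uniform row it is 0 (the mean of a zero-mean scale).
#'
#' @param profile A \code{\link{StandardizedProfile}}.
#' @param props A \code{\link{NormalizedPropertyTable}}.
#' @return Numeric L x R matrix, columns named by accession.
#' @export
pspcp <- function(profile, props) {
  stopifnot(is(profile, "StandardizedProfile"),
            is(props, "NormalizedPropertyTable"))
  D <- profile@A %*% t(props@h)
  colnames(D) <- props@accessions
  D
}

#' Profile-based amino-acid composition
#'
#' The 20 composition descriptors are the column means of the standardized
#' profile, f_j = (1/L) sum_i A[i, j]; they replace the plain amino-acid
#' composition and always sum to 1.
#'
#' @param profile A \code{\link{StandardizedProfile}}.
#' @return Named numeric vector of 20 values summing to 1.
#' @export
composition <- function(profile) {
  stopifnot(is(profile, "StandardizedProfile"))
  colMeans(profile@A)
}

#' Sequence-order pseudofactors over PSPCP series
#'
#' The k-th tier pseudofactor for property r is the lag-k autocorrelation-type
#' average u[k, r] = (1/(L-k)) sum_{i=1}^{L-k} d[i, r] * d[i+k, r].  Because
#' PSPCP values are signed, pseudofactors may be negative.
#'
#' @param d L x R PSPCP matrix (from \code{\link{pspcp}}).
#' @param lambda Number of tiers; must be strictly less than L.
#' @param identifier Sequence name used in error messages.
#' @return lambda x R matrix of pseudofactors.
#' @export
pseudoFactors <- function(d, lambda, identifier = "") {
  lambda <- as.integer(lambda)
  L <- nrow(d)
  if (lambda < 1L) stop("lambda must be a positive integer")
  if (L <= lambda)
    stop("sequence ", if (nzchar(identifier)) paste0("'", identifier, "' "),
         "of length ", L, " is too short for lambda = ", lambda,
         " (need length > lambda)")
  u <- matrix(0, nrow = lambda, ncol = ncol(d),
              dimnames = list(NULL, colnames(d)))
  for (k in seq_len(lambda)) {
    idx <- seq_len(L - k)
    u[k, ] <- colSums(d[idx, , drop = FALSE] *
                      d[idx + k, , drop = FALSE]) / (L - k)
  }
  u
}

# feature names: composition block then property-major, tier-minor pseudo block
.featureNames <- function(accessions, lambda) {
  c(paste0("f_", residueOrder()),
    as.vector(vapply(accessions,
                     function(a) paste0("u_", a, "_k", seq_len(lambda)),
                     character(lambda))))
}

# assemble the normalized descriptor from precomputed parts; used both by
# descriptorVector() and by the calibration cache (w enters only here)
.descriptorFromParts <- function(f, u, w, accessions) {
  lambda <- nrow(u)
  Z <- sum(f) + w * sum(u)
  if (!is.finite(Z) || Z <= 0)
    stop("degenerate descriptor normalizer (Z = ", Z, ")")
  q <- c(f, w * as.vector(u)) / Z   # as.vector(u) is tier-minor within property
  names(q) <- .featureNames(accessions, lambda)
  q
}

#' Full pseudo-amino-acid descriptor vector for one profile
#'
#' Builds the 20 + lambda*R descriptor: the 20 profile compositions f_j and
#' the lambda*R pseudofactors u[k, r] weighted by w, all divided by the
#' common normalizer Z = sum_j f_j + w * sum_{r,k} u[k, r], so the vector
#' always sums to 1.  The pseudo block is laid out property-major,
#' tier-minor: entry 20 + (r-1)*lambda + k holds w*u[k, r]/Z.  Pseudofactors
#' (and hence some entries) can be negative; set \code{diagnostics = TRUE} to
#' error on negative entries instead.
#'
#' @param profile A \code{\link{StandardizedProfile}}.
#' @param props A \code{\link{NormalizedPropertyTable}}; its scales must
#'   match \code{config@accessions}.
#' @param config A \code{\link{FeatureConfig}}.
#' @param diagnostics If TRUE, enforce nonnegativity of all entries.
#' @return Named numeric vector of length 20 + lambda*R summing to 1.
#' @export
#' @examples
#' props <- normalizeProperties(loadDefaultProperties())
#' prof <- oneHotProfile(strrep("ACDEFGHIKLMN", 3), "demo")
#' q <- descriptorVector(prof, props, featureConfig(w = 0.15, lambda = 11))
#' length(q)  # 119
#' sum(q)     # 1
descriptorVector <- function(profile, props, config, diagnostics = FALSE) {
  stopifnot(is(config, "FeatureConfig"))
  if (!identical(config@accessions, props@accessions))
    stop("property table accessions do not match the feature configuration")
  f <- composition(profile)
  d <- pspcp(profile, props)
  u <- pseudoFactors(d, config@lambda, profile@identifier)
  q <- .descriptorFromParts(f, u, config@w, config@accessions)
  if (diagnostics && any(q < 0))
    stop("descriptor for '", profile@identifier,
         "' has negative entries (signed pseudofactors); ",
         sum(q < 0), " of ", length(q))
  q
}

#' Extract a feature matrix for a set of sequences
#'
#' Runs the full representation pipeline: per-sequence profile (PSSM when
#' available in \code{pssmDir}, one-hot fallback otherwise), PSPCP,
#' pseudofactors and the normalized descriptor vector.
#'
#' @param sequences An \code{AAStringSet} (names are identifiers) or a
#'   \code{\link{LabeledDataset}}.
#' @param pssmDir Directory with per-sequence \code{<id>.pssm} files, or NULL.
#' @param props A \code{\link{NormalizedPropertyTable}}.
#' @param config A \code{\link{FeatureConfig}}.
#' @param strict If TRUE, abort on the first per-sequence error; otherwise
#'   failing sequences are skipped and reported in a warning.
#' @return Numeric matrix, one named row per (successful) sequence, with
#'   attributes \code{origins} (per-row profile origin) and \code{skipped}
#'   (identifiers of skipped sequences).
#' @export
extractFeatures <- function(sequences, pssmDir = NULL, props, config,
                            strict = FALSE) {
  if (is(sequences, "LabeledDataset")) sequences <- sequences@sequences
  stopifnot(is(sequences, "AAStringSet"))
  if (!length(sequences)) stop("no sequences supplied")
  profiles <- loadProfiles(sequences, pssmDir)
  origins <- attr(profiles, "origins")
  rows <- vector("list", length(profiles))
  ok <- logical(length(profiles))
  errs <- character(0)
  for (i in seq_along(profiles)) {
    res <- tryCatch(descriptorVector(profiles[[i]], props, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (strict)
        stop("feature extraction failed for '", names(profiles)[i], "': ",
             conditionMessage(res))
      errs <- c(errs, paste0(names(profiles)[i], ": ", conditionMessage(res)))
    } else {
      rows[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("feature extraction failed for every sequence:\n",
                     paste(errs, collapse = "\n"))
  if (length(errs))
    warning(length(errs), " sequence(s) skipped:\n",
            paste(errs, collapse = "\n"))
  X <- do.call(rbind, rows[ok])
  rownames(X) <- names(profiles)[ok]
  attr(X, "origins") <- origins[ok]
  attr(X, "skipped") <- names(profiles)[!ok]
  X
}

#' Write a feature matrix as TSV
#'
#' First column is the sequence identifier; the header names every feature
#' (f_A..f_V, then u_<accession>_k<tier>).  Values are written with 17
#' significant digits so the matrix round-trips losslessly.
#'
#' @param X Feature matrix with row and column names.
#' @param path Output path.
#' @export
writeFeatureMatrix <- function(X, path) {
  df <- data.frame(identifier = rownames(X),
                   apply(X, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by \code{\link{writeFeatureMatrix}}
#'
#' @param path Input TSV path.
#' @return Numeric matrix with identifiers as rownames.
#' @export
readFeatureMatrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df[[1]]
  X
}
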
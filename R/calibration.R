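#' Default calibration grid
#'
#' The descriptor grid enumerates w from 0.05 to 1.00 in steps of 0.05 (20
#' values; 1.00 is included because the published enumeration range includes
#' it, even though user-supplied \code{FeatureConfig}s enforce the stricter
#' open interval (0, 1)) and lambda from 2 to 20 (19 values): 380 (w, lambda)
#' combinations.  The kernel grid uses the canonical LIBSVM grid-search
#' ranges, gamma in 2^-15..2^3 and C in 2^-5..2^15.
#'
#' @return A \code{\link{CalibrationGrid}}.
#' @export
#' @examples
#' g <- defaultGrid()
#' length(g@wValues) * length(g@lambdaValues)  # 380
defaultGrid <- function() {
  new("CalibrationGrid",
      wValues = seq(0.05, 1.00, by = 0.05),
      lambdaValues = 2:20,
      gammaValues = 2^seq(-15L, 3L),
      cValues = 2^seq(-5L, 15L))
}

#' Construct a (restricted) calibration grid
#'
#' @param wValues,lambdaValues,gammaValues,cValues Grid axes.
#' @return A \code{\link{CalibrationGrid}}.
#' @export
calibrationGrid <- function(wValues, lambdaValues, gammaValues, cValues) {
  new("CalibrationGrid", wValues = as.numeric(wValues),
      lambdaValues = as.integer(lambdaValues),
      gammaValues = as.numeric(gammaValues), cValues = as.numeric(cValues))
}

# clamp a grid w into FeatureConfig's open interval; w = 1 is evaluated as
# the limit value 1 - 1e-12 internally but reported as printed
.configForW <- function(w, lambda, accessions) {
  new("FeatureConfig", w = min(w, 1 - 1e-12), lambda = as.integer(lambda),
      accessions = accessions)
}

#' Grid calibration of descriptor and kernel parameters
#'
#' For every (w, lambda) pair, features are assembled once per lambda (the
#' composition and pseudofactor parts do not depend on w, so w is applied
#' cheaply from a cache) and jackknife overall accuracy is computed for
#' every (gamma, C) pair; the best kernel pair per combination is recorded
#' and the global winner is the accuracy argmax.  Ties are broken
#' deterministically: smallest lambda, then smallest w, then smallest C,
#' then smallest gamma.  Lambda values not strictly below the shortest
#' sequence length are reported as infeasible, never silently dropped.
#'
#' @param profiles Named list of \code{\link{StandardizedProfile}} objects
#'   (e.g. from \code{\link{loadProfiles}}).
#' @param labels Class labels parallel to \code{profiles}.
#' @param props A \code{\link{NormalizedPropertyTable}}.
#' @param grid A \code{\link{CalibrationGrid}}; default is the full grid
#'   (expensive — restrict it for small studies).
#' @param classLabels Class order for the models.
#' @return A \code{\link{CalibrationResult}}.
#' @export
calibrate <- function(profiles, labels, props, grid = defaultGrid(),
                      classLabels = sort(unique(labels))) {
  stopifnot(is(grid, "CalibrationGrid"))
  validObject(grid)
  labels <- as.character(labels)
  if (length(profiles) != length(labels))
    stop("profiles and labels differ in length")
  minLen <- min(vapply(profiles, function(p) nrow(p@A), integer(1)))
  feasible <- grid@lambdaValues < minLen
  infeasible <- data.frame(
    lambda = grid@lambdaValues[!feasible],
    reason = rep(sprintf("lambda >= shortest sequence length (%d)", minLen),
                 sum(!feasible)))
  if (!any(feasible)) stop("no feasible lambda values: shortest sequence has ",
                           minLen, " residues")
  if (nrow(infeasible))
    message("skipping ", nrow(infeasible),
            " infeasible lambda value(s): shortest sequence has ",
            minLen, " residues")
  # per-profile parts that do not depend on w: composition f and, per lambda,
  # the pseudofactor matrix u
  f <- lapply(profiles, composition)
  D <- lapply(profiles, pspcp, props = props)
  records <- list()
  for (lambda in grid@lambdaValues[feasible]) {
    u <- lapply(seq_along(D), function(i)
      pseudoFactors(D[[i]], lambda, profiles[[i]]@identifier))
    for (w in grid@wValues) {
      X <- do.call(rbind, lapply(seq_along(f), function(i)
        .descriptorFromParts(f[[i]], u[[i]], w, props@accessions)))
      rownames(X) <- names(profiles)
      best <- NULL
      for (gamma in sort(grid@gammaValues)) {
        for (C in sort(grid@cValues)) {
          cfg <- modelConfig(gamma = gamma, cost = C,
                             featureConfig = .configForW(w, lambda,
                                                         props@accessions),
                             classLabels = classLabels)
          acc <- jackknife(X, labels, cfg)@acc
          if (is.null(best) || acc > best$acc ||
              (acc == best$acc && (C < best$C ||
                                   (C == best$C && gamma < best$gamma))))
            best <- list(acc = acc, gamma = gamma, C = C)
        }
      }
      records[[length(records) + 1L]] <-
        data.frame(w = w, lambda = lambda, gamma = best$gamma, C = best$C,
                   acc = best$acc)
    }
  }
  records <- do.call(rbind, records)
  # deterministic winner: max acc, then smallest lambda, w, C, gamma
  ord <- order(-records$acc, records$lambda, records$w, records$C,
               records$gamma)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  ties <- records[records$acc == records$acc[1], , drop = FALSE]
  new("CalibrationResult", records = records,
      winner = records[1, , drop = FALSE], ties = ties,
      infeasible = infeasible)
}

#' Write calibration results as TSV plus a JSON winner block
#'
#' @param result A \code{\link{CalibrationResult}}.
#' @param tsvPath Path for the per-combination table.
#' @param jsonPath Path for the winner JSON; defaults to
#'   \code{<tsvPath>.winner.json}.
#' @export
writeCalibration <- function(result, tsvPath,
                             jsonPath = paste0(tsvPath, ".winner.json")) {
  write.table(result@records, tsvPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(winner = as.list(result@winner),
                            n_combinations = nrow(result@records),
                            n_ties = nrow(result@ties),
                            infeasible_lambda = result@infeasible$lambda),
                       jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tsvPath)
}
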
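# Bundled amino-acid property scales.
#
# Values are the AAindex1 entries for the nine accessions used by the method,
# embedded as constants so no network access is ever needed.  Each vector is
# in the canonical residue order A R N D C Q E G H I L K M F P S T W Y V
# (see residueOrder()), which coincides with AAindex's own Ala..Val row order.
.BUNDLED_PROPERTIES <- list(
  BULH740101 = list(
    description = "Transfer free energy to surface (Bull-Breese, 1974)",
    values = c(-0.20, -0.12, 0.08, -0.20, -0.45, 0.16, -0.30, 0.00, -0.12,
               -2.26, -2.46, -0.35, -1.47, -2.33, -0.98, -0.39, -0.52,
               -2.01, -2.24, -1.56)),
  EISD840101 = list(
    description = "Consensus normalized hydrophobicity scale (Eisenberg, 1984)",
    values = c(0.25, -1.76, -0.64, -0.72, 0.04, -0.69, -0.62, 0.16, -0.40,
               0.73, 0.53, -1.10, 0.26, 0.61, -0.07, -0.26, -0.18, 0.37,
               0.02, 0.54)),
  HOPT810101 = list(
    description = "Hydrophilicity value (Hopp-Woods, 1981)",
    values = c(-0.5, 3.0, 0.2, 3.0, -1.0, 0.2, 3.0, 0.0, -0.5, -1.8, -1.8,
               3.0, -1.3, -2.5, 0.0, 0.3, -0.4, -3.4, -2.3, -1.5)),
  RADA880108 = list(
    description = "Mean polarity (Radzicka-Wolfenden, 1988)",
    values = c(-0.06, -0.84, -0.48, -0.80, 1.36, -0.73, -0.77, -0.41, 0.49,
               1.31, 1.21, -1.18, 1.27, 1.27, 0.00, -0.50, -0.27, 0.88,
               0.33, 1.09)),
  ZIMJ680104 = list(
    description = "Isoelectric point (Zimmerman et al., 1968)",
    values = c(6.00, 10.76, 5.41, 2.77, 5.05, 5.65, 3.22, 5.97, 7.59, 6.02,
               5.98, 9.74, 5.74, 5.48, 6.30, 5.68, 5.66, 5.89, 5.66, 5.96)),
  MCMT640101 = list(
    description = "Refractivity (McMeekin et al., 1964)",
    values = c(4.34, 26.66, 13.28, 12.00, 35.77, 17.56, 17.26, 0.00, 21.81,
               19.06, 18.78, 21.29, 21.64, 29.40, 10.93, 6.35, 11.01, 42.53,
               31.53, 13.92)),
  BHAR880101 = list(
    description = "Average flexibility indices (Bhaskaran-Ponnuswamy, 1988)",
    values = c(0.357, 0.529, 0.463, 0.511, 0.346, 0.493, 0.497, 0.544, 0.323,
               0.462, 0.365, 0.466, 0.295, 0.314, 0.509, 0.507, 0.444, 0.305,
               0.420, 0.386)),
  CHOC750101 = list(
    description = "Average volume of buried residue (Chothia, 1975)",
    values = c(91.5, 202.0, 135.2, 124.5, 117.7, 161.1, 155.1, 66.4, 167.3,
               168.8, 167.9, 171.3, 170.8, 203.4, 129.3, 99.1, 122.1, 237.6,
               203.6, 141.7)),
  COSI940101 = list(
    description = "Electron-ion interaction potential values (Cosic, 1994)",
    values = c(0.0373, 0.0959, 0.0036, 0.1263, 0.0829, 0.0761, 0.0058,
               0.0050, 0.0242, 0.0000, 0.0000, 0.0371, 0.0823, 0.0946,
               0.0198, 0.0829, 0.0941, 0.0548, 0.0516, 0.0057))
)

#' Accessions of the bundled default property scales
#'
#' @return Character vector of the nine AAindex accessions used by default.
#' @export
defaultPropertyAccessions <- function() names(.BUNDLED_PROPERTIES)

#' Construct a PropertyScale
#'
#' @param accession AAindex-style accession string.
#' @param values Numeric vector of 20 values in canonical residue order
#'   (names, if present, are checked against \code{\link{residueOrder}}).
#' @param description Optional free-text description.
#' @return A \code{\link{PropertyScale}} object.
#' @export
propertyScale <- function(accession, values, description = "") {
  values <- as.numeric(values)
  if (length(values) != 20L)
    stop("property scale '", accession, "' must have exactly 20 values, got ",
         length(values))
  names(values) <- residueOrder()
  new("PropertyScale", accession = as.character(accession),
      description = as.character(description), values = values)
}

#' Load the nine bundled physicochemical property scales
#'
#' Returns the raw (unnormalized) amino-acid property scales used by the
#' method: transfer free energy to surface, consensus hydrophobicity,
#' hydrophilicity, mean polarity, isoelectric point, refractivity, average
#' flexibility, average buried volume and electron-ion interaction potential.
#' Values are AAindex1 entries embedded in the package.
#'
#' @return A named list of nine \code{\link{PropertyScale}} objects, in the
#'   fixed order of \code{\link{defaultPropertyAccessions}}.
#' @export
#' @examples
#' scales <- loadDefaultProperties()
#' length(scales)           # 9
#' scales[[1]]@accession    # "BULH740101"
loadDefaultProperties <- function() {
  out <- lapply(names(.BUNDLED_PROPERTIES), function(acc) {
    entry <- .BUNDLED_PROPERTIES[[acc]]
    if (is.null(entry$values) || length(entry$values) != 20L ||
        !all(is.finite(entry$values)))
      stop("bundled property data for '", acc, "' is missing or corrupt")
    propertyScale(acc, entry$values, entry$description)
  })
  names(out) <- names(.BUNDLED_PROPERTIES)
  out
}

#' Z-normalize property scales
#'
#' Converts raw scales H(r, j) to normalized values
#' h(r, j) = (H(r, j) - m(r)) / s(r), where m(r) is the mean and s(r) the
#' population standard deviation (divisor 20) over the 20 amino acids.  A
#' constant scale has s(r) = 0 and cannot be normalized.
#'
#' @param scales A list of \code{\link{PropertyScale}} objects (order kept).
#' @return A \code{\link{NormalizedPropertyTable}}.
#' @export
#' @examples
#' props <- normalizeProperties(loadDefaultProperties())
#' rowMeans(props@h)  # all ~0
normalizeProperties <- function(scales) {
  if (is(scales, "PropertyScale")) scales <- list(scales)
  if (is(scales, "NormalizedPropertyTable")) scales <- asPropertyScales(scales)
  if (!length(scales)) stop("at least one property scale is required")
  H <- do.call(rbind, lapply(scales, function(s) {
    stopifnot(is(s, "PropertyScale"))
    validObject(s)
    s@values
  }))
  accs <- unname(vapply(scales, function(s) s@accession, character(1)))
  descs <- unname(vapply(scales, function(s) s@description, character(1)))
  m <- rowMeans(H)
  s <- sqrt(rowMeans(sweep(H, 1, m)^2))
  if (any(s == 0))
    stop("property scale(s) with zero spread cannot be normalized: ",
         paste(accs[s == 0], collapse = ", "))
  h <- sweep(sweep(H, 1, m), 1, s, "/")
  dimnames(h) <- list(accs, residueOrder())
  new("NormalizedPropertyTable", h = h, accessions = accs,
      descriptions = descs)
}

#' Convert a NormalizedPropertyTable back to a list of scales
#'
#' Useful for re-normalizing (a fixed point: z-scoring is idempotent) or for
#' writing the normalized values out.
#'
#' @param table A \code{\link{NormalizedPropertyTable}}.
#' @return A list of \code{\link{PropertyScale}} objects.
#' @export
asPropertyScales <- function(table) {
  stopifnot(is(table, "NormalizedPropertyTable"))
  lapply(seq_along(table@accessions), function(r)
    propertyScale(table@accessions[r], table@h[r, ], table@descriptions[r]))
}

#' Read a custom property table from a TSV file
#'
#' Expected format: a header row \code{accession<TAB>A<TAB>R<TAB>...<TAB>V}
#' naming the 20 residues in canonical order, then one row per scale with
#' the accession followed by 20 numeric values.
#'
#' @param path Path to the tab-separated file.
#' @return A list of \code{\link{PropertyScale}} objects.
#' @export
readPropertyTable <- function(path) {
  if (!file.exists(path)) stop("property table not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) != 21L)
    stop("property table must have 21 columns (accession + 20 residues), got ",
         ncol(tab))
  if (!identical(colnames(tab)[-1], residueOrder()))
    stop("property table header must name the residues in canonical order: ",
         paste(residueOrder(), collapse = " "))
  if (anyDuplicated(tab[[1]]))
    stop("duplicate accessions in property table: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    vals <- as.numeric(tab[i, -1])
    if (!all(is.finite(vals)))
      stop("non-finite value in property table row '", tab[i, 1], "'")
    propertyScale(tab[i, 1], vals)
  })
}
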
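#' Construct a SyntheticSpec
#'
#' The generator emulates the two signal channels the descriptor is built to
#' capture: class-specific residue usage (the composition channel) and a
#' class-specific periodic motif (the sequence-order channel).  Per class c,
#' a usage distribution p_c = softmax(signalStrength * z_c) is drawn around
#' a fixed class direction z_c, and residues at positions i > T_c copy the
#' residue at i - T_c with probability signalStrength / (1 + signalStrength)
#' (T_c the class's motif period; 0 disables copying).  At
#' \code{signalStrength = 0} both channels vanish and the classes are
#' exchangeable — a null model.  Each sequence also gets a synthetic PSSM
#' whose integer log-odds rows softmax-concentrate on the position's
#' generating distribution, with Gaussian noise whose sd shrinks as the
#' signal grows, rounded and clipped to [-10, 10].
#'
#' Default class sizes follow the 661:177:145 inner-membrane/matrix/
#' outer-membrane imbalance of the 983-protein benchmark, scaled down, so
#' imbalanced-metric code paths are exercised.
#'
#' @param nPerClass Integer sequences per class; names become class labels
#'   (default: the three submitochondrial locations at benchmark proportions).
#' @param lengthRange [min, max] sequence length.
#' @param signalStrength Nonnegative signal strength; 0 = null model.
#' @param mode "composition", "order" or "both" (which channels are active).
#' @param motifPeriods Per-class motif period (0 = none); default 0 for
#'   class 1 and 3, 4, ... for the rest.
#' @param seed Integer seed; all output is a deterministic function of it.
#' @param preset "easy" overrides the defaults with a balanced, strongly
#'   separable 3 x 20 configuration; "null" sets signalStrength to 0.
#' @return A \code{\link{SyntheticSpec}}.
#' @export
#' @examples
#' spec <- syntheticSpec(preset = "easy", seed = 7)
syntheticSpec <- function(nPerClass = c(inner_membrane = 40L, matrix = 11L,
                                        outer_membrane = 9L),
                          lengthRange = c(60L, 100L),
                          signalStrength = 2,
                          mode = "both",
                          motifPeriods = NULL,
                          seed = 1L,
                          preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("easy", "null"))
    if (preset == "easy") {
      nPerClass <- c(inner_membrane = 20L, matrix = 20L, outer_membrane = 20L)
      signalStrength <- 4
      mode <- "both"
    } else {
      signalStrength <- 0
    }
  }
  if (is.null(names(nPerClass)))
    names(nPerClass) <- paste0("class", seq_along(nPerClass))
  if (is.null(motifPeriods))
    motifPeriods <- c(0L, seq(3L, length.out = length(nPerClass) - 1L))
  nPerClass <- stats::setNames(as.integer(nPerClass), names(nPerClass))
  new("SyntheticSpec", nPerClass = nPerClass,
      lengthRange = as.integer(lengthRange),
      signalStrength = as.numeric(signalStrength),
      mode = as.character(mode),
      motifPeriods = as.integer(motifPeriods),
      seed = as.integer(seed))
}

# class usage distributions: softmax(signal * z_c) over the 20 residues,
# z_c a fixed unit direction per class drawn from the seeded stream
.classDistributions <- function(nClasses, signal, mode) {
  t(vapply(seq_len(nClasses), function(c) {
    z <- rnorm(20)
    z <- z / sqrt(mean(z^2))
    if (mode == "order" || signal == 0) rep(0.05, 20)
    else { e <- exp(signal * z); e / sum(e) }
  }, numeric(20)))
}

# write one PSSM in the psiblast -out_ascii_pssm ASCII dialect
.writeAsciiPssm <- function(E, residues, path) {
  ord <- residueOrder()
  header <- c("",
              "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
              paste0("           ",
                     paste(sprintf("%3s", c(ord, ord)), collapse = "")))
  pct <- round(100 * exp(E - apply(E, 1, max)) /
                 rowSums(exp(E - apply(E, 1, max))))
  rows <- vapply(seq_len(nrow(E)), function(i)
    paste0(sprintf("%5d %s ", i, residues[i]),
           paste(sprintf("%4d", E[i, ]), collapse = ""), " ",
           paste(sprintf("%4d", pct[i, ]), collapse = ""),
           sprintf("  %4.2f %8.2f", 0.5, 1.0)),
    character(1))
  footer <- c("", "                      K         Lambda",
              "Standard Ungapped    0.1337     0.3114",
              "Standard Gapped      0.0410     0.2670",
              "PSI Ungapped         0.1337     0.3114",
              "PSI Gapped           0.0410     0.2670")
  writeLines(c(header, rows, footer), path)
}

#' Generate a labeled synthetic dataset with matching PSSM files
#'
#' Samples sequences and synthetic PSSMs under the generative model of
#' \code{\link{syntheticSpec}}.  When \code{dir} is given, writes
#' \code{sequences.fasta}, one \code{<id>.pssm} per sequence (in the
#' psiblast ASCII dialect, so they round-trip through
#' \code{\link{parseAsciiPssm}}) and \code{labels.tsv}; the same seed always
#' produces byte-identical files.
#'
#' @param spec A \code{\link{SyntheticSpec}}.
#' @param dir Output directory (created if needed), or NULL for in-memory
#'   only.
#' @return A \code{\link{LabeledDataset}} holding the sequences, labels and
#'   parsed-equivalent \code{\link{PSSMMatrix}} objects.
#' @export
generateDataset <- function(spec, dir = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  ord <- residueOrder()
  nClasses <- length(spec@nPerClass)
  classNames <- names(spec@nPerClass) %||% paste0("class", seq_len(nClasses))
  p <- .classDistributions(nClasses, spec@signalStrength, spec@mode)
  # motif strength: probability that a position keeps its periodic tiling
  # (the complement is resampled iid); 0 at zero signal, so the null model is
  # pure iid for every class
  keepProb <- if (spec@mode == "composition") 0 else
    spec@signalStrength / (1 + spec@signalStrength)
  noiseSd <- 2 / (1 + spec@signalStrength)
  maxPeriod <- max(spec@motifPeriods)
  seqs <- character(0); labels <- character(0); ids <- character(0)
  pssms <- list()
  for (c in seq_len(nClasses)) {
    Tc <- spec@motifPeriods[c]
    # in order mode a no-motif class is generated by the same lag-T copy
    # process and then randomly permuted: the exact residue multiset (hence
    # composition) is preserved while the order signal is destroyed, so the
    # classes differ in sequence order only
    scramble <- spec@mode == "order" && Tc == 0L && maxPeriod > 0L
    lag <- if (scramble) maxPeriod else Tc
    for (n in seq_len(spec@nPerClass[c])) {
      L <- sample(spec@lengthRange[1]:spec@lengthRange[2], 1L)
      if (lag > 0L && keepProb > 0) {
        # position i copies position i - lag with probability keepProb,
        # otherwise draws fresh from the class usage distribution
        res <- integer(L)
        for (i in seq_len(L)) {
          res[i] <- if (i > lag && runif(1) < keepProb) res[i - lag]
                    else sample.int(20L, 1L, prob = p[c, ])
        }
        if (scramble) res <- res[sample.int(L)]
      } else {
        res <- sample.int(20L, L, replace = TRUE, prob = p[c, ])
      }
      id <- sprintf("%s_%03d", classNames[c], n)
      # generating distribution per position: the sampled residue mixed with
      # the class usage, so the PSSM carries both channels
      Q <- matrix(rep(p[c, ], each = L), nrow = L)
      Q <- 0.3 * Q
      Q[cbind(seq_len(L), res)] <- Q[cbind(seq_len(L), res)] + 0.7
      E <- round(2 * log(Q / 0.05) + rnorm(L * 20L, sd = noiseSd))
      E <- pmin(pmax(E, -10), 10)
      storage.mode(E) <- "integer"
      colnames(E) <- ord
      pssms[[id]] <- new("PSSMMatrix", identifier = id, E = E,
                         residues = ord[res])
      seqs <- c(seqs, paste(ord[res], collapse = ""))
      ids <- c(ids, id)
      labels <- c(labels, classNames[c])
    }
  }
  sequences <- Biostrings::AAStringSet(seqs)
  names(sequences) <- ids
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(sequences, file.path(dir, "sequences.fasta"))
    for (id in ids)
      .writeAsciiPssm(pssms[[id]]@E, pssms[[id]]@residues,
                      file.path(dir, paste0(id, ".pssm")))
    write.table(data.frame(identifier = ids, class = labels),
                file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  new("LabeledDataset", sequences = sequences, labels = labels, pssms = pssms)
}

#' Standardized profiles of a labeled dataset
#'
#' @param dataset A \code{\link{LabeledDataset}} from
#'   \code{\link{generateDataset}}.
#' @return Named list of \code{\link{StandardizedProfile}} objects.
#' @export
datasetProfiles <- function(dataset) {
  stopifnot(is(dataset, "LabeledDataset"))
  ids <- names(dataset@sequences)
  profiles <- lapply(ids, function(id) {
    if (!is.null(dataset@pssms[[id]])) standardizePssm(dataset@pssms[[id]])
    else oneHotProfile(as.character(dataset@sequences[[id]]), id)
  })
  names(profiles) <- ids
  profiles
}

#' Feature matrix of a labeled dataset
#'
#' @param dataset A \code{\link{LabeledDataset}}.
#' @param props A \code{\link{NormalizedPropertyTable}}.
#' @param config A \code{\link{FeatureConfig}}.
#' @return Feature matrix, one row per sequence.
#' @export
datasetFeatures <- function(dataset, props, config) {
  profiles <- datasetProfiles(dataset)
  X <- do.call(rbind, lapply(profiles, descriptorVector, props = props,
                             config = config))
  rownames(X) <- names(profiles)
  X
}
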
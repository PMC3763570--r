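# Independent oracle implementations, written straight from the defining
# equations with explicit loops.  They deliberately share no code with the
# package internals they check.

# population z-score of one raw scale (20 values, canonical order)
naiveZScore <- function(H) {
  m <- sum(H) / 20
  s <- sqrt(sum((H - m)^2) / 20)
  (H - m) / s
}

# naive softmax of one score row, no stability tricks
naiveSoftmaxRow <- function(e) exp(e) / sum(exp(e))

# full descriptor from a raw integer score matrix and raw property scales:
# softmax -> PSPCP -> composition -> pseudofactors -> normalized vector,
# all as explicit loops
naiveDescriptorFromE <- function(E, rawScales, w, lambda) {
  L <- nrow(E)
  R <- length(rawScales)
  A <- matrix(0, L, 20)
  for (i in seq_len(L)) A[i, ] <- naiveSoftmaxRow(E[i, ])
  h <- lapply(rawScales, naiveZScore)
  d <- matrix(0, L, R)
  for (i in seq_len(L)) for (r in seq_len(R))
    d[i, r] <- sum(A[i, ] * h[[r]])
  f <- numeric(20)
  for (j in 1:20) f[j] <- sum(A[, j]) / L
  u <- matrix(0, lambda, R)
  for (k in seq_len(lambda)) for (r in seq_len(R)) {
    acc <- 0
    for (i in seq_len(L - k)) acc <- acc + d[i, r] * d[i + k, r]
    u[k, r] <- acc / (L - k)
  }
  Z <- sum(f) + w * sum(u)
  q <- numeric(20 + lambda * R)
  for (n in 1:20) q[n] <- f[n] / Z
  for (r in seq_len(R)) for (k in seq_len(lambda))
    q[20 + (r - 1) * lambda + k] <- w * u[k, r] / Z
  attr(q, "Z") <- Z
  q
}

# independent plain-sequence amphiphilic pseudo-amino-acid composition:
# composition = residue counts / L, correlation factors over the residues'
# own z-scored property values
naiveAmPseAAC <- function(sequence, rawScales, w, lambda) {
  ord <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  res <- match(strsplit(sequence, "")[[1]], ord)
  stopifnot(!anyNA(res))
  L <- length(res)
  R <- length(rawScales)
  h <- lapply(rawScales, naiveZScore)
  f <- numeric(20)
  for (j in 1:20) f[j] <- sum(res == j) / L
  d <- matrix(0, L, R)
  for (i in seq_len(L)) for (r in seq_len(R)) d[i, r] <- h[[r]][res[i]]
  u <- matrix(0, lambda, R)
  for (k in seq_len(lambda)) for (r in seq_len(R)) {
    acc <- 0
    for (i in seq_len(L - k)) acc <- acc + d[i, r] * d[i + k, r]
    u[k, r] <- acc / (L - k)
  }
  Z <- sum(f) + w * sum(u)
  q <- numeric(20 + lambda * R)
  for (n in 1:20) q[n] <- f[n] / Z
  for (r in seq_len(R)) for (k in seq_len(lambda))
    q[20 + (r - 1) * lambda + k] <- w * u[k, r] / Z
  attr(q, "Z") <- Z
  q
}

# Matthews correlation via its correlation definition: Pearson correlation of
# the per-sample class-s indicator vectors
pearsonMCC <- function(truth, predicted, class) {
  a <- as.numeric(truth == class)
  b <- as.numeric(predicted == class)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# raw (unnormalized) values of the bundled scales, for feeding the oracles
rawScaleValues <- function(accessions = defaultPropertyAccessions()) {
  scales <- loadDefaultProperties()[accessions]
  lapply(scales, function(s) unname(s@values))
}

# random valid profile: iid positive entries, rows normalized
randomProfile <- function(L, identifier = "rnd") {
  A <- matrix(stats::runif(L * 20, 0.01, 1), L, 20)
  A <- A / rowSums(A)
  colnames(A) <- residueOrder()
  new("StandardizedProfile", identifier = identifier, A = A, origin = "pssm")
}

# random integer PSSM built from residueOrder() letters
randomPSSM <- function(L, lo = -10L, hi = 10L, identifier = "rnd") {
  E <- matrix(sample(lo:hi, L * 20, replace = TRUE), L, 20)
  storage.mode(E) <- "integer"
  colnames(E) <- residueOrder()
  new("PSSMMatrix", identifier = identifier, E = E,
      residues = sample(residueOrder(), L, replace = TRUE))
}

randomSequence <- function(L) {
  paste(sample(residueOrder(), L, replace = TRUE), collapse = "")
}

# 1-nearest-neighbour stand-in classifier matching the trainModel/
# predictLabels contract, for testing evaluation protocols without the SVM
nn1Train <- function(features, labels, config) {
  list(X = as.matrix(features), y = as.character(labels))
}
nn1Predict <- function(model, features) {
  features <- as.matrix(features)
  apply(features, 1, function(x) {
    d2 <- rowSums(sweep(model$X, 2, x)^2)
    model$y[which.min(d2)]
  })
}

# small separable 3-class dataset via the easy generator preset
easyFeatures <- function(seed = 7, lambda = 11L, w = 0.15) {
  props <- normalizeProperties(loadDefaultProperties())
  ds <- generateDataset(syntheticSpec(preset = "easy", seed = seed))
  list(X = datasetFeatures(ds, props, featureConfig(w = w, lambda = lambda)),
       labels = ds@labels)
}

# model configuration used for synthetic-data studies: the kernel width
# follows the median heuristic for descriptor-scale distances (median
# squared distance ~ 0.03, gamma ~ 2^5), cost 8
syntheticModelConfig <- function(classLabels, lambda = 11L, w = 0.15) {
  modelConfig(gamma = 32, cost = 8,
              featureConfig = featureConfig(w = w, lambda = lambda),
              classLabels = classLabels)
}
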
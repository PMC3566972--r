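## One-hot encoding, categorical Naive Bayes, and the one-hidden-layer
## perceptron baseline.

#' One-hot encode hexapeptides
#'
#' Each peptide maps to 120 binary indicators (6 position blocks of 20
#' residues, residues in [AA_ALPHABET] order); exactly one indicator is set
#' per block.
#'
#' @param x character vector of hexapeptides or a [HexDataset-class].
#' @return numeric 0/1 matrix, n x 120, columns named `p<j>.<residue>`.
#' @export
encodePeptides <- function(x) {
  pep <- if (is(x, "HexDataset")) peptides(x) else as.character(x)
  n <- length(pep)
  if (n == 0) stop("no peptides to encode")
  if (any(nchar(pep) != 6L)) stop("peptides must have exactly 6 residues")
  m <- matrix(unlist(strsplit(pep, "", fixed = TRUE), use.names = FALSE),
              ncol = 6L, byrow = TRUE)
  E <- matrix(0, n, 120L,
              dimnames = list(NULL, paste0("p", rep(1:6, each = 20L), ".",
                                           rep(AA_ALPHABET, 6L))))
  for (j in 1:6) {
    idx <- match(m[, j], AA_ALPHABET)
    if (anyNA(idx)) stop("peptides contain symbols outside the 20-letter alphabet")
    E[cbind(seq_len(n), (j - 1L) * 20L + idx)] <- 1
  }
  E
}

#' Decode one-hot encoded instances back to sequences
#'
#' Inverse of [encodePeptides()].
#'
#' @param E numeric 0/1 matrix, n x 120.
#' @return character vector of hexapeptides.
#' @export
decodePeptides <- function(E) {
  stopifnot(is.matrix(E), ncol(E) == 120L)
  vapply(seq_len(nrow(E)), function(i) {
    paste(vapply(1:6, function(j) {
      block <- E[i, (j - 1L) * 20L + 1:20]
      if (sum(block != 0) != 1L) stop("not a valid one-hot row")
      AA_ALPHABET[which(block != 0)]
    }, ""), collapse = "")
  }, "")
}

## index representation: n x 6 matrix of active column indices (1..120)
peptideColumnIndex <- function(pep) {
  m <- matrix(unlist(strsplit(pep, "", fixed = TRUE), use.names = FALSE),
              ncol = 6L, byrow = TRUE)
  idx <- matrix(0L, nrow(m), 6L)
  for (j in 1:6) idx[, j] <- (j - 1L) * 20L + match(m[, j], AA_ALPHABET)
  idx
}

## ---------------------------------------------------------------------------
## Naive Bayes

#' Train a categorical naive Bayes classifier
#'
#' Per-position conditional tables
#' `P(residue | position, class) = (count + alpha) / (class count + 20 alpha)`
#' with Laplace pseudo-count `alpha`, and priors equal to class fractions.
#'
#' @param train [HexDataset-class] containing both classes.
#' @param alpha Laplace pseudo-count (default 1).
#' @return a [NaiveBayesModel-class].
#' @export
trainNaiveBayes <- function(train, alpha = 1) {
  stopifnot(is(train, "HexDataset"), alpha >= 0)
  lab <- isAmyloid(train)
  if (all(lab) || all(!lab)) stop("training data must contain both classes")
  classes <- c("non-amyloidogenic", "amyloidogenic")
  counts <- c(sum(!lab), sum(lab))
  tables <- array(0, dim = c(20L, 6L, 2L),
                  dimnames = list(residue = AA_ALPHABET, position = 1:6,
                                  class = classes))
  for (ci in 1:2) {
    freq <- positionFrequencies(train[lab == (ci == 2L)]) * counts[ci]
    tables[, , ci] <- (freq + alpha) / (counts[ci] + 20 * alpha)
  }
  new("NaiveBayesModel",
      priors = setNames(counts / sum(counts), classes),
      tables = tables, alpha = alpha, classCounts = as.integer(counts))
}

#' Predict with a naive Bayes model
#'
#' Posterior probability of the amyloidogenic class under per-position
#' independence, accumulated in log space; the posteriors over the two
#' classes sum to 1.
#'
#' @param object a [NaiveBayesModel-class].
#' @param newdata [HexDataset-class] or character vector of hexapeptides.
#' @param type `"prob"` (default; posterior of amyloidogenic), `"score"`
#'   (log posterior ratio), or `"class"`.
#' @param ... ignored.
#' @return numeric or logical vector.
#' @export
setMethod("predict", "NaiveBayesModel",
          function(object, newdata, type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  pep <- if (is(newdata, "HexDataset")) peptides(newdata) else sanitizeSequence(newdata)
  idx <- peptideColumnIndex(pep)          # 1..120; residue rank = (idx-1) %% 20 + 1
  res <- ((idx - 1L) %% 20L) + 1L
  logRatio <- log(object@priors[2]) - log(object@priors[1])
  for (j in 1:6)
    logRatio <- logRatio + log(object@tables[res[, j], j, 2L]) -
      log(object@tables[res[, j], j, 1L])
  logRatio <- unname(logRatio)
  switch(type,
         score = logRatio,
         prob = 1 / (1 + exp(-logRatio)),
         class = logRatio > 0)
})

## ---------------------------------------------------------------------------
## Multilayer perceptron

#' Train a one-hidden-layer perceptron
#'
#' Architecture 120 -> `hidden` -> 1 with logistic activations throughout,
#' trained by per-instance stochastic gradient descent with momentum on
#' squared error (the classical neural-net recipe this baseline mirrors),
#' for a fixed number of epochs. Weights and biases initialize uniformly in
#' [-0.5, 0.5]; the instance order is reshuffled once per epoch. All
#' randomness flows through `seed`, so identical calls produce identical
#' weight trajectories.
#'
#' @param train [HexDataset-class] containing both classes.
#' @param hidden hidden-layer width (default 60).
#' @param learningRate SGD learning rate (default 0.1).
#' @param momentum momentum coefficient (default 0.2).
#' @param epochs training epochs (default 500).
#' @param seed RNG seed (default 0).
#' @return an [MLPModel-class].
#' @export
trainMLP <- function(train, hidden = 60L, learningRate = 0.1, momentum = 0.2,
                     epochs = 500L, seed = 0L) {
  stopifnot(is(train, "HexDataset"), hidden >= 1, epochs >= 0,
            learningRate > 0, momentum >= 0, momentum < 1)
  lab <- isAmyloid(train)
  if (all(lab) || all(!lab)) stop("training data must contain both classes")
  idx <- peptideColumnIndex(peptides(train))
  y <- as.numeric(lab)
  set.seed(as.integer(seed))
  W1 <- matrix(runif(120L * hidden, -0.5, 0.5), 120L, hidden)
  b1 <- runif(hidden, -0.5, 0.5)
  W2 <- runif(hidden, -0.5, 0.5)
  b2 <- runif(1L, -0.5, 0.5)
  fit <- mlp_train_cpp(idx - 1L, y, W1, b1, W2, b2,
                       learningRate, momentum, as.integer(epochs))
  new("MLPModel", W1 = fit$W1, b1 = as.numeric(fit$b1),
      W2 = as.numeric(fit$W2), b2 = as.numeric(fit$b2),
      hyper = list(hidden = as.integer(hidden), learningRate = learningRate,
                   momentum = momentum, epochs = as.integer(epochs),
                   seed = as.integer(seed)),
      lossTrace = as.numeric(fit$lossTrace))
}

#' Predict with a multilayer perceptron
#'
#' Forward pass; the output is a probability strictly inside (0, 1), used
#' directly as the ROC ranking score. Class is positive iff the output
#' exceeds 0.5.
#'
#' @param object an [MLPModel-class].
#' @param newdata [HexDataset-class] or character vector of hexapeptides.
#' @param type `"prob"` (default), `"score"` (alias of prob), or `"class"`.
#' @param ... ignored.
#' @return numeric or logical vector.
#' @export
setMethod("predict", "MLPModel",
          function(object, newdata, type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  pep <- if (is(newdata, "HexDataset")) peptides(newdata) else sanitizeSequence(newdata)
  E <- encodePeptides(pep)
  H <- 1 / (1 + exp(-sweep(E %*% object@W1, 2L, object@b1, "+")))
  o <- as.numeric(1 / (1 + exp(-(H %*% object@W2 + object@b2))))
  switch(type, prob = o, score = o, class = o > 0.5)
})
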
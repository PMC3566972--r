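## Alternating decision tree learner over position-residue equality
## predicates, trained by weight boosting with exhaustive Z-score split
## selection.

## condition index <-> (position, residue): column (pos-1)*20 + rank(residue)
conditionIndex <- function(position, residue)
  (position - 1L) * 20L + match(residue, AA_ALPHABET)

conditionFromIndex <- function(idx) {
  list(position = ((idx - 1L) %/% 20L) + 1L,
       residue = AA_ALPHABET[((idx - 1L) %% 20L) + 1L])
}

#' Train an alternating decision tree
#'
#' Boosted learner over the 120 base conditions `AA[j] == residue`
#' (6 positions x 20 residues). Instances start with unit weights; the root
#' prediction value is `0.5 * log((W+ + eps) / (W- + eps))` over the initial
#' weights. Each iteration searches every existing prediction node (the
#' precondition path) crossed with every base condition and adds, at the
#' pair minimizing the split score
#' `Z = 2 * (sqrt(W+(c1 & c2) W-(c1 & c2)) + sqrt(W+(c1 & !c2) W-(c1 & !c2))) + W(!c1)`,
#' a splitter whose two prediction values are half-log-ratios on their
#' weight subsets; weights are then multiplied by `exp(-y * r(x))` where `r`
#' is the new contribution. Ties in Z break deterministically: lowest
#' position, then alphabetical residue, then earliest-created precondition
#' node, so two trainings on identical input yield identical models.
#'
#' @param train a [HexDataset-class] containing both classes.
#' @param iterations number of boosting iterations (splitters); the
#'   operating points studied here are 250 and 50.
#' @param smoothing value `eps` added to numerator and denominator of every
#'   half-log-ratio (default 1), keeping prediction values finite on pure
#'   weight subsets.
#' @return an [ADTreeModel-class].
#' @examples
#' hd <- HexDataset(c("AAAIAA", "NNQINY", "GGGIGG", "NNQQNY"),
#'                  c(TRUE, TRUE, TRUE, FALSE))
#' m <- trainADTree(hd, iterations = 1)
#' exportRules(m)
#' @export
trainADTree <- function(train, iterations = 50L, smoothing = 1) {
  stopifnot(is(train, "HexDataset"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0) stop("iterations must be >= 0")
  if (smoothing < 0) stop("smoothing must be >= 0")
  y <- ifelse(isAmyloid(train), 1, -1)
  if (all(y > 0) || all(y < 0))
    stop("training data must contain both classes")
  n <- length(y)
  X <- encodePeptides(peptides(train))        # n x 120, 0/1
  eps <- smoothing

  w <- rep(1, n)
  rootValue <- 0.5 * log((sum(w[y > 0]) + eps) / (sum(w[y < 0]) + eps))
  w <- w * exp(-y * rootValue)
  lossTrace <- sum(w)

  ## membership matrix over prediction nodes, columns in creation order:
  ## column j holds node id j-1 (root = 0; splitter k creates ids 2k-1, 2k)
  M <- matrix(1, n, 1L)
  sp <- data.frame(order = integer(0), parent = integer(0),
                   position = integer(0), residue = character(0),
                   trueValue = numeric(0), falseValue = numeric(0),
                   z = numeric(0), stringsAsFactors = FALSE)

  for (k in seq_len(iterations)) {
    wp <- w * (y > 0); wn <- w * (y < 0)
    Wtot <- sum(w)
    A <- crossprod(M * wp, X)                 # W+(c1 & c2), nodes x 120
    B <- crossprod(M * wn, X)                 # W-(c1 & c2)
    P <- colSums(M * wp); N <- colSums(M * wn)
    Arest <- pmax(P - A, 0); Brest <- pmax(N - B, 0)
    Z <- 2 * (sqrt(A * B) + sqrt(Arest * Brest)) + (Wtot - (P + N))
    zmin <- min(Z)
    cand <- which(Z == zmin, arr.ind = TRUE)
    ## tie key: condition index (position-major, residues alphabetical),
    ## then node creation order
    pick <- cand[order(cand[, 2L], cand[, 1L])[1L], , drop = TRUE]
    nd <- pick[[1L]]; cj <- pick[[2L]]
    cond <- conditionFromIndex(cj)
    a <- 0.5 * log((A[nd, cj] + eps) / (B[nd, cj] + eps))
    b <- 0.5 * log((Arest[nd, cj] + eps) / (Brest[nd, cj] + eps))
    mT <- M[, nd] * X[, cj]
    mF <- M[, nd] * (1 - X[, cj])
    w <- w * exp(-y * (a * mT + b * mF))
    M <- cbind(M, mT, mF)
    sp <- rbind(sp, data.frame(order = k, parent = nd - 1L,
                               position = cond$position, residue = cond$residue,
                               trueValue = a, falseValue = b, z = zmin,
                               stringsAsFactors = FALSE))
    lossTrace <- c(lossTrace, sum(w))
  }

  new("ADTreeModel", rootValue = rootValue, splitters = sp,
      iterations = iterations, smoothing = smoothing, lossTrace = lossTrace)
}

## core traversal: summed prediction values along all satisfied paths
adtreeScores <- function(model, pep) {
  X <- encodePeptides(pep)
  n <- nrow(X)
  s <- rep(model@rootValue, n)
  sp <- model@splitters
  if (nrow(sp)) {
    members <- vector("list", 2L * nrow(sp) + 1L)
    members[[1L]] <- rep(TRUE, n)
    for (k in seq_len(nrow(sp))) {
      mp <- members[[sp$parent[k] + 1L]]
      cnd <- X[, conditionIndex(sp$position[k], sp$residue[k])] > 0
      mT <- mp & cnd
      mF <- mp & !cnd
      s <- s + sp$trueValue[k] * mT + sp$falseValue[k] * mF
      members[[2L * k]] <- mT        # id 2k-1 -> slot 2k
      members[[2L * k + 1L]] <- mF   # id 2k   -> slot 2k+1
    }
  }
  as.numeric(s)
}

#' Predict with an alternating decision tree
#'
#' The score of a peptide is the root value plus the value of every
#' prediction node on satisfied paths. Class is amyloidogenic iff the score
#' is positive; for ROC ranking a calibrated probability
#' `1 / (1 + exp(-2 * score))` (logistic of twice the boosting margin) is
#' exposed.
#'
#' @param object an [ADTreeModel-class].
#' @param newdata [HexDataset-class] or character vector of hexapeptides.
#' @param type `"score"` (default), `"prob"`, or `"class"` (logical,
#'   TRUE = amyloidogenic).
#' @param ... ignored.
#' @return numeric or logical vector.
#' @export
setMethod("predict", "ADTreeModel",
          function(object, newdata, type = c("score", "prob", "class"), ...) {
  type <- match.arg(type)
  pep <- if (is(newdata, "HexDataset")) peptides(newdata) else sanitizeSequence(newdata)
  s <- adtreeScores(object, pep)
  switch(type,
         score = s,
         prob = 1 / (1 + exp(-2 * s)),
         class = s > 0)
})

setGeneric("exportRules", function(model, ...) standardGeneric("exportRules"))

#' Export the rules of an alternating decision tree
#'
#' One entry per splitter, numbered by boosting iteration (the order of
#' decreasing significance). The formatted notation is
#' `n: AAj | X a | !X b`: rule number, position, the residue's value when
#' present and (marked `!`) when absent, values printed to 3 decimals.
#'
#' @param model a trained [ADTreeModel-class].
#' @param ... ignored.
#' @return data.frame with columns `rule`, `position`, `residue`,
#'   `condition`, `trueValue`, `falseValue`, `parent`, and attribute
#'   `"formatted"` holding the printed lines (also from [formatRules()]).
#' @aliases exportRules
#' @export
setMethod("exportRules", "ADTreeModel", function(model, ...) {
  sp <- model@splitters
  out <- data.frame(rule = sp$order, position = sp$position,
                    residue = sp$residue,
                    condition = sprintf("AA%d=%s", sp$position, sp$residue),
                    trueValue = sp$trueValue, falseValue = sp$falseValue,
                    parent = sp$parent, stringsAsFactors = FALSE)
  attr(out, "formatted") <- formatRules(model)
  out
})

#' Format ADTree rules as printable lines
#'
#' @param model a trained [ADTreeModel-class].
#' @return character vector, one line per rule, e.g.
#'   `"1: AA4 | I 0.900 | !I -0.200"`.
#' @export
formatRules <- function(model) {
  sp <- model@splitters
  sprintf("%d: AA%d | %s %.3f | !%s %.3f",
          sp$order, sp$position, sp$residue, sp$trueValue,
          sp$residue, sp$falseValue)
}
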
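## Confusion metrics, ROC/AUC, the 10-run 66/34 resampling protocol,
## corrected resampled paired t-test, and win/draw/loss tabulation.

#' Confusion counts and derived metrics
#'
#' `TPR = TP / (TP + FN)`, `TNR = TN / (TN + FP)`,
#' `Acc = (TP + TN) / (TP + TN + FP + FN)`, with amyloidogenic as the
#' positive class.
#'
#' @param truth,predicted logical vectors of equal length (TRUE =
#'   amyloidogenic).
#' @return list with `counts` (named TP/FP/FN/TN) and `metrics` (named
#'   TPR/TNR/Acc). A class absent from `truth` makes the corresponding rate
#'   `NaN` with a warning.
#' @export
confusionMetrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  TP <- sum(truth & predicted); FP <- sum(!truth & predicted)
  FN <- sum(truth & !predicted); TN <- sum(!truth & !predicted)
  if (TP + FN == 0) warning("no positive instances: TPR is undefined")
  if (TN + FP == 0) warning("no negative instances: TNR is undefined")
  list(counts = c(TP = TP, FP = FP, FN = FN, TN = TN),
       metrics = c(TPR = TP / (TP + FN), TNR = TN / (TN + FP),
                   Acc = (TP + TN) / length(truth)))
}

#' ROC curve and AUC
#'
#' Curve from descending-score thresholds with tied scores grouped; AUC by
#' the trapezoid rule, which under this construction equals the
#' Mann-Whitney probability that a random positive outranks a random
#' negative with ties counted one half. 0.5 corresponds to random guessing,
#' 1.0 to perfect separation.
#'
#' @param truth logical vector (TRUE = amyloidogenic); both classes must be
#'   present.
#' @param scores numeric ranking scores, higher = more amyloidogenic.
#' @return list: `points` (data.frame `threshold`, `fpr`, `tpr`, starting
#'   at (0,0) and ending at (1,1)) and `auc`.
#' @export
rocCurve <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), all(is.finite(scores)))
  truth <- as.logical(truth)
  P <- sum(truth); N <- sum(!truth)
  if (P == 0 || N == 0) stop("ROC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  cumTP <- cumsum(t)[last]; cumFP <- cumsum(!t)[last]
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, cumFP / N),
                    tpr = c(0, cumTP / P))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Area under the ROC curve
#'
#' @inheritParams rocCurve
#' @return numeric AUC in [0, 1].
#' @export
rocAUC <- function(truth, scores) rocCurve(truth, scores)$auc

#' Table-1-style evaluation of a model on a test set
#'
#' @param truth logical labels of the test set.
#' @param scores numeric ranking scores.
#' @param predicted logical predictions (default: the model's own decision
#'   rule should be supplied; falls back to `scores > cutoff`).
#' @param cutoff decision cutoff applied to `scores` when `predicted` is
#'   missing.
#' @return named numeric: TPR, TNR, Acc, AUC.
#' @export
evaluateScores <- function(truth, scores, predicted = NULL, cutoff = 0.5) {
  if (is.null(predicted)) predicted <- scores > cutoff
  cm <- confusionMetrics(truth, predicted)
  c(cm$metrics, AUC = rocAUC(truth, scores))
}

## ---------------------------------------------------------------------------
## classifier factories: a uniform train/score interface for the protocol

#' Classifier factories for the evaluation protocol
#'
#' Each factory returns a lightweight specification (label, `fit(dataset)`,
#' `scoreFun(model, peptides)`) consumed by [resamplingExperiment()] and the
#' command-line `eval`/`compare` tools. The ranking score is the ADTree
#' margin probability, the naive Bayes posterior, and the perceptron output
#' respectively.
#'
#' @param iterations,smoothing ADTree hyperparameters.
#' @param alpha naive Bayes Laplace pseudo-count.
#' @param hidden,learningRate,momentum,epochs,seed perceptron
#'   hyperparameters.
#' @return an object of class `"hexClassifier"`.
#' @name classifier-factories
NULL

#' @rdname classifier-factories
#' @export
adtreeClassifier <- function(iterations = 50L, smoothing = 1) {
  structure(list(
    label = sprintf("ADTree %d", iterations),
    fit = function(train) trainADTree(train, iterations, smoothing),
    scoreFun = function(model, newdata) predict(model, newdata, type = "prob"),
    classFun = function(model, newdata) predict(model, newdata, type = "class")),
    class = "hexClassifier")
}

#' @rdname classifier-factories
#' @export
naiveBayesClassifier <- function(alpha = 1) {
  structure(list(
    label = "Naive Bayes",
    fit = function(train) trainNaiveBayes(train, alpha),
    scoreFun = function(model, newdata) predict(model, newdata, type = "prob"),
    classFun = function(model, newdata) predict(model, newdata, type = "class")),
    class = "hexClassifier")
}

#' @rdname classifier-factories
#' @export
mlpClassifier <- function(hidden = 60L, learningRate = 0.1, momentum = 0.2,
                          epochs = 500L, seed = 0L) {
  structure(list(
    label = "MLP",
    fit = function(train) trainMLP(train, hidden, learningRate, momentum,
                                   epochs, seed),
    scoreFun = function(model, newdata) predict(model, newdata, type = "prob"),
    classFun = function(model, newdata) predict(model, newdata, type = "class")),
    class = "hexClassifier")
}

#' @export
print.hexClassifier <- function(x, ...) {
  cat("hexClassifier:", x$label, "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------

#' Repeated random-split resampling experiment
#'
#' `k` train/test runs: each run draws a seeded shuffle of the dataset,
#' takes the first `trainFrac` as training data and the rest as test data
#' (unstratified by default), trains every method on the identical split,
#' and records its test AUC. A split that leaves either part single-class
#' is re-drawn with an incremented seed (logged).
#'
#' @param classifiers list of `"hexClassifier"` objects (see
#'   [adtreeClassifier()] and friends).
#' @param data a [HexDataset-class].
#' @param k number of runs (default 10).
#' @param trainFrac training fraction (default 0.66).
#' @param seeds integer vector of length `k` (default `0:(k-1)`).
#' @param stratified sample the split within each class (default FALSE).
#' @return object of class `"resamplingResult"`: list with `auc` (k x
#'   methods matrix), `nTrain`, `nTest`, `seeds`.
#' @export
resamplingExperiment <- function(classifiers, data, k = 10L, trainFrac = 0.66,
                                 seeds = seq_len(k) - 1L, stratified = FALSE) {
  stopifnot(is(data, "HexDataset"), length(seeds) == k, k >= 1,
            trainFrac > 0, trainFrac < 1)
  stopifnot(all(vapply(classifiers, inherits, TRUE, "hexClassifier")))
  n <- length(data)
  nTrain <- floor(trainFrac * n); nTest <- n - nTrain
  lab <- isAmyloid(data)
  methodNames <- vapply(classifiers, `[[`, "", "label")
  auc <- matrix(NA_real_, k, length(classifiers),
                dimnames = list(run = NULL, method = methodNames))
  for (r in seq_len(k)) {
    seed <- as.integer(seeds[r])
    repeat {
      set.seed(seed)
      perm <- if (stratified) {
        c(sample(which(lab)), sample(which(!lab)))[order(runif(n))]
      } else sample.int(n)
      trIdx <- perm[seq_len(nTrain)]; teIdx <- perm[-seq_len(nTrain)]
      if (length(unique(lab[trIdx])) == 2L && length(unique(lab[teIdx])) == 2L) break
      message(sprintf("run %d: split with seed %d lacks a class; re-drawing", r, seed))
      seed <- seed + 1000003L
    }
    tr <- data[trIdx]; te <- data[teIdx]
    for (m in seq_along(classifiers)) {
      cl <- classifiers[[m]]
      fitObj <- cl$fit(tr)
      auc[r, m] <- rocAUC(isAmyloid(te), cl$scoreFun(fitObj, te))
    }
  }
  structure(list(auc = auc, nTrain = nTrain, nTest = nTest,
                 seeds = as.integer(seeds)),
            class = "resamplingResult")
}

#' @export
print.resamplingResult <- function(x, ...) {
  cat(sprintf("resamplingResult: %d run(s), train %d / test %d\n",
              nrow(x$auc), x$nTrain, x$nTest))
  print(round(colMeans(x$auc), 4))
  invisible(x)
}

#' Corrected resampled paired t-test
#'
#' For per-run differences `d` of a metric between two methods evaluated on
#' `k` overlapping random splits,
#' `t = mean(d) / sqrt((1/k + nTest/nTrain) * var(d))` with unbiased
#' variance and `k - 1` degrees of freedom. The variance inflation term
#' `nTest/nTrain` corrects for the dependence between runs that share
#' training instances; with the ratio set to 0 the statistic reduces to the
#' classical paired t.
#'
#' @param d numeric vector of per-run differences (length `k >= 2`).
#' @param nTrain,nTest split sizes.
#' @param alpha two-sided significance level (default 0.05).
#' @return list: `statistic`, `p.value`, `df`, `meanDiff`, `decision`
#'   (`"win"`/`"draw"`/`"loss"` from the first method's viewpoint),
#'   `zeroVariance` flag (var(d) = 0 with nonzero mean reports p = 0).
#' @export
correctedPairedTTest <- function(d, nTrain, nTest, alpha = 0.05) {
  k <- length(d)
  stopifnot(k >= 2, nTrain > 0, nTest >= 0)
  m <- mean(d); v <- var(d)
  if (v == 0) {
    if (m == 0)
      return(list(statistic = 0, p.value = 1, df = k - 1, meanDiff = 0,
                  decision = "draw", zeroVariance = TRUE))
    return(list(statistic = sign(m) * Inf, p.value = 0, df = k - 1,
                meanDiff = m, decision = if (m > 0) "win" else "loss",
                zeroVariance = TRUE))
  }
  t <- m / sqrt((1 / k + nTest / nTrain) * v)
  p <- 2 * pt(-abs(t), df = k - 1)
  list(statistic = t, p.value = p, df = k - 1, meanDiff = m,
       decision = if (p < alpha) { if (m > 0) "win" else "loss" } else "draw",
       zeroVariance = FALSE)
}

#' Pairwise win/draw/loss comparison of methods
#'
#' Every method is compared with every other method for AUC using the
#' corrected resampled paired t-test; a win is a significantly higher mean
#' AUC at level `alpha`, a loss significantly lower, a draw otherwise.
#'
#' @param result a `"resamplingResult"` from [resamplingExperiment()].
#' @param alpha significance level (default 0.05).
#' @return list: `table` (data.frame method/wins/draws/losses, ordered by
#'   wins) and `p.values` (methods x methods matrix).
#' @export
winsDrawsLosses <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "resamplingResult"))
  auc <- result$auc
  m <- ncol(auc)
  if (m < 2) stop("need at least two methods to compare")
  nm <- colnames(auc)
  wins <- draws <- losses <- setNames(integer(m), nm)
  pmat <- matrix(NA_real_, m, m, dimnames = list(nm, nm))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    tt <- correctedPairedTTest(auc[, i] - auc[, j], result$nTrain,
                               result$nTest, alpha)
    pmat[i, j] <- tt$p.value
    switch(tt$decision,
           win = { wins[i] <- wins[i] + 1L },
           loss = { losses[i] <- losses[i] + 1L },
           draw = { draws[i] <- draws[i] + 1L })
  }
  tab <- data.frame(method = nm, wins = wins, draws = draws, losses = losses,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$wins, tab$losses), ]
  rownames(tab) <- NULL
  list(table = tab, p.values = pmat)
}
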
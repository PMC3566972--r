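## Fixtures and independent oracles shared across the test files.
## Everything is generated in code; no stored data.

## sanitized alphabet (the 20 letters minus cysteine)
ALPHA19 <- setdiff(AA_ALPHABET, "C")

randomPeptides <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  apply(matrix(sample(ALPHA19, n * 6, replace = TRUE), n, 6), 1, paste,
        collapse = "")
}

## a small dataset in which AA4=I perfectly separates the classes and no
## other position-residue condition does (negatives share no residue at any
## position)
toySeparableDataset <- function() {
  HexDataset(c("AAAIAA", "NNQINY", "GGGIGG", "TTTITT",
               "NNQQNY", "GAGAGA", "TSTSTS", "PEPEPE"),
             c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
             source = "toy")
}

## ---------------------------------------------------------------------------
## Independent ADTree oracle: replays a trained model's trajectory with
## scalar-loop arithmetic, recomputing at every iteration the exhaustive
## minimum of Z over (existing prediction node x 120 base conditions) and
## the prediction values, independent of the learner's vectorized path.

oracleConditionTruth <- function(pep, position, residue) {
  substring(pep, position, position) == residue
}

## path predicate (logical mask over peptides) of prediction node `id`
## given the first k-1 splitters
oraclePathMask <- function(pep, splitters, id) {
  mask <- rep(TRUE, length(pep))
  while (id != 0) {
    k <- ceiling(id / 2)
    branch <- id %% 2 == 1            # odd id = true child of splitter k
    cnd <- oracleConditionTruth(pep, splitters$position[k], splitters$residue[k])
    mask <- mask & (if (branch) cnd else !cnd)
    id <- splitters$parent[k]
  }
  mask
}

## exhaustive replay; returns per-iteration choice of the oracle and the
## model, each as list(parent, position, residue, z, trueValue, falseValue,
## runnerUpGap)
adtreeOracleReplay <- function(model, dataset) {
  pep <- peptides(dataset)
  y <- ifelse(isAmyloid(dataset), 1, -1)
  eps <- model@smoothing
  w <- rep(1, length(y))
  rootOracle <- 0.5 * log((sum(w[y > 0]) + eps) / (sum(w[y < 0]) + eps))
  w <- w * exp(-y * rootOracle)
  sp <- model@splitters
  out <- list(rootValue = rootOracle, iterations = list())
  nodeIds <- 0L
  ## precompute the 120 base-condition truth vectors once
  condTruth <- list()
  for (pos in 1:6) for (res in AA_ALPHABET)
    condTruth[[(pos - 1) * 20 + match(res, AA_ALPHABET)]] <-
      oracleConditionTruth(pep, pos, res)
  posTruth <- y > 0
  for (k in seq_len(nrow(sp))) {
    ## exhaustive Z over every existing prediction node x 120 conditions;
    ## weight sums accumulated by subsetted sums, not matrix products
    best <- NULL
    zAll <- c()
    Wtot <- sum(w)
    for (id in nodeIds) {
      mask <- oraclePathMask(pep, sp[seq_len(k - 1), , drop = FALSE], id)
      Wout <- Wtot - sum(w[mask])
      for (pos in 1:6) for (res in AA_ALPHABET) {
        cnd <- condTruth[[(pos - 1) * 20 + match(res, AA_ALPHABET)]]
        wTP <- sum(w[mask & cnd & posTruth])
        wTN <- sum(w[mask & cnd & !posTruth])
        wFP <- sum(w[mask & !cnd & posTruth])
        wFN <- sum(w[mask & !cnd & !posTruth])
        z <- 2 * (sqrt(wTP * wTN) + sqrt(wFP * wFN)) + Wout
        zAll <- c(zAll, z)
        ## tie key: position, then residue rank, then node creation order
        key <- c(z, pos, match(res, AA_ALPHABET), match(id, nodeIds))
        if (is.null(best) || keyLess(key, best$key)) {
          best <- list(key = key, parent = id, position = pos, residue = res,
                       z = z,
                       trueValue = 0.5 * log((wTP + eps) / (wTN + eps)),
                       falseValue = 0.5 * log((wFP + eps) / (wFN + eps)))
        }
      }
    }
    zSorted <- sort(zAll)
    best$runnerUpGap <- if (length(zSorted) > 1) zSorted[2] - zSorted[1] else Inf
    out$iterations[[k]] <- best
    ## apply the MODEL's k-th splitter (so later iterations stay comparable
    ## even if a near-tie made a different choice), using oracle arithmetic
    parentMask <- oraclePathMask(pep, sp[seq_len(k - 1), , drop = FALSE],
                                 sp$parent[k])
    cnd <- oracleConditionTruth(pep, sp$position[k], sp$residue[k])
    r <- ifelse(parentMask & cnd, sp$trueValue[k],
                ifelse(parentMask & !cnd, sp$falseValue[k], 0))
    w <- w * exp(-y * r)
    nodeIds <- c(nodeIds, 2L * k - 1L, 2L * k)
  }
  out
}

keyLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

## brute-force score oracle: evaluates every prediction node's full path
## predicate independently, then sums values of satisfied nodes
adtreeScoreOracle <- function(model, pep) {
  sp <- model@splitters
  vapply(pep, function(p) {
    s <- model@rootValue
    for (k in seq_len(nrow(sp))) {
      for (branch in c(TRUE, FALSE)) {
        id <- if (branch) 2L * k - 1L else 2L * k
        if (oraclePathMask(p, sp, id)) {
          s <- s + if (branch) sp$trueValue[k] else sp$falseValue[k]
        }
      }
    }
    s
  }, numeric(1), USE.NAMES = FALSE)
}

## Mann-Whitney pair-counting AUC oracle, O(P*N)
aucPairOracle <- function(truth, scores) {
  sp <- scores[truth]; sn <- scores[!truth]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

## random small labeled dataset guaranteed to contain both classes
randomSmallDataset <- function(n, seed) {
  set.seed(seed)
  repeat {
    lab <- runif(n) < runif(1, 0.2, 0.8)
    if (any(lab) && any(!lab)) break
  }
  ## mix signal and noise so splits are non-trivial
  pep <- randomPeptides(n)
  idx <- which(lab & runif(n) < 0.5)
  if (length(idx)) {
    tmp <- pep[idx]
    substr(tmp, 4, 4) <- "I"
    pep[idx] <- tmp
  }
  HexDataset(pep, lab, source = "sim")
}
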
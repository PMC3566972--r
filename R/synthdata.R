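## Seeded synthetic generators: hexapeptide datasets drawn from
## position-specific frequency matrices with a plantable discriminating
## motif, and paired energy tables with a controllable between-source
## difference distribution.

#' Position frequency matrix with uniform background
#'
#' A 6-column PFM whose columns all equal the supplied background residue
#' distribution.
#'
#' @param background named numeric over [AA_ALPHABET] summing to 1 (default
#'   [backgroundFrequencies()]).
#' @return 20 x 6 matrix.
#' @export
backgroundPFM <- function(background = backgroundFrequencies()) {
  stopifnot(length(background) == 20L,
            isTRUE(all.equal(sum(background), 1, tolerance = 1e-9)))
  m <- matrix(background, 20L, 6L,
              dimnames = list(residue = AA_ALPHABET, position = 1:6))
  m
}

#' Plant a position-residue motif signal into a PFM
#'
#' Sets the frequency of `residue` at `position` to `weight` and rescales
#' the remaining residues of that column to sum to `1 - weight`.
#'
#' @param pfm 20 x 6 PFM.
#' @param position 1..6.
#' @param residue one of the 20 letters.
#' @param weight target frequency of the planted residue (default 0.9).
#' @return modified PFM.
#' @export
plantMotif <- function(pfm, position = 4L, residue = "I", weight = 0.9) {
  stopifnot(position %in% 1:6, residue %in% AA_ALPHABET,
            weight > 0, weight < 1)
  col2 <- pfm[, position]
  col2[residue] <- 0
  if (sum(col2) <= 0) stop("cannot rescale: all remaining frequencies are zero")
  col2 <- col2 / sum(col2) * (1 - weight)
  col2[residue] <- weight
  pfm[, position] <- col2
  pfm
}

#' Configuration for the synthetic hexapeptide generator
#'
#' Defaults emulate the modeled study conditions: 4481 peptides with an
#' 825/4481 amyloidogenic prior, a background-composition negative class,
#' and a positive class carrying a planted AA4=I signal of weight 0.9.
#'
#' @param positivePFM,negativePFM 20 x 6 PFMs (columns sum to 1).
#' @param prior amyloidogenic class prior, in (0, 1).
#' @param n number of peptides.
#' @param seed RNG seed.
#' @return a list of class `"seqGenConfig"`.
#' @export
sequenceGeneratorConfig <- function(positivePFM = plantMotif(backgroundPFM()),
                                    negativePFM = backgroundPFM(),
                                    prior = 825 / 4481, n = 4481L,
                                    seed = 1L) {
  checkPFM <- function(p, what) {
    if (!is.matrix(p) || !all(dim(p) == c(20L, 6L)))
      stop(what, " must be a 20 x 6 matrix")
    if (any(p < 0)) stop(what, " has negative frequencies")
    if (!isTRUE(all.equal(unname(colSums(p)), rep(1, 6), tolerance = 1e-9)))
      stop(what, " columns must sum to 1")
  }
  checkPFM(positivePFM, "positivePFM"); checkPFM(negativePFM, "negativePFM")
  stopifnot(prior > 0, prior < 1, n >= 1)
  structure(list(positivePFM = positivePFM, negativePFM = negativePFM,
                 prior = prior, n = as.integer(n), seed = as.integer(seed)),
            class = "seqGenConfig")
}

#' Sample a synthetic hexapeptide dataset
#'
#' Labels are drawn from the class prior; residues are drawn independently
#' per position from the class PFM. Fully determined by the config seed.
#'
#' @param config a [sequenceGeneratorConfig()].
#' @return a [HexDataset-class] with source `"synthetic"`.
#' @export
samplePeptides <- function(config) {
  stopifnot(inherits(config, "seqGenConfig"))
  set.seed(config$seed)
  n <- config$n
  lab <- runif(n) < config$prior
  chars <- matrix("", n, 6L)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(lab == cls)
    if (!length(idx)) next
    pfm <- if (cls) config$positivePFM else config$negativePFM
    for (j in 1:6)
      chars[idx, j] <- sample(AA_ALPHABET, length(idx), replace = TRUE,
                              prob = pfm[, j])
  }
  pep <- do.call(paste0, asplit(chars, 2L))
  HexDataset(pep, lab, source = "synthetic", sanitize = TRUE)
}

#' Exact AUC of the Bayes-optimal classifier for a generator config
#'
#' AUC of the exact likelihood-ratio classifier, computed by enumerating
#' the discrete distribution of the summed per-position log-likelihood
#' ratios under each class (convolution over positions, aggregating equal
#' values). Residues with zero probability under both classes are skipped;
#' a residue possible under only one class contributes an infinite ratio,
#' handled exactly. Ties count one half, matching the Mann-Whitney
#' convention of [rocAUC()].
#'
#' @param config a [sequenceGeneratorConfig()].
#' @param maxSupport guard on the enumerated support size (default 2e6).
#' @return numeric AUC in [0, 1].
#' @export
bayesOptimalAuc <- function(config, maxSupport = 2e6) {
  stopifnot(inherits(config, "seqGenConfig"))
  pp <- config$positivePFM; pn <- config$negativePFM
  distFor <- function(classPFM) {
    v <- 0; p <- 1
    for (j in 1:6) {
      fp <- pp[, j]; fn <- pn[, j]; fc <- classPFM[, j]
      keep <- fc > 0
      llr <- log(fp[keep]) - log(fn[keep])   # +Inf / -Inf allowed
      grid <- outer(v, llr, "+")
      prob <- outer(p, fc[keep])
      key <- round(as.vector(grid), 9)
      agg <- rowsum(as.vector(prob), group = key)
      v <- as.numeric(rownames(agg)); p <- as.vector(agg)
      if (length(v) > maxSupport)
        stop("LLR support exceeds maxSupport; PFMs have too many distinct values")
    }
    o <- order(v)
    list(v = v[o], p = p[o])
  }
  dp <- distFor(pp); dn <- distFor(pn)
  ## P(S+ > S-) + 0.5 P(S+ = S-), exact over the discrete supports
  cumBelowOrEq <- cumsum(dn$p)
  idx <- findInterval(dp$v, dn$v)            # count of dn$v <= each dp$v
  eqIdx <- match(dp$v, dn$v)
  eqP <- ifelse(is.na(eqIdx), 0, dn$p[ifelse(is.na(eqIdx), 1L, eqIdx)])
  below <- ifelse(idx == 0, 0, cumBelowOrEq[pmax(idx, 1L)]) - eqP
  sum(dp$p * (below + 0.5 * eqP))
}

#' Configuration for the synthetic paired energy-table generator
#'
#' Defaults emulate the modeled energy comparison: base energies normal
#' with sd 3 kcal/mol and mean chosen so that 18.41% of segments fall at or
#' below the -23 kcal/mol threshold; the reference column differs by a
#' signed Laplace draw with mean absolute difference 1 kcal/mol.
#'
#' @param mean,sd base energy distribution, kcal/mol.
#' @param meanAbsDiff target mean absolute energy difference between the
#'   two sources, kcal/mol.
#' @param shape difference distribution: `"laplace"` (default) or
#'   `"normal"`.
#' @param threshold classification threshold, kcal/mol.
#' @param n number of records.
#' @param seed RNG seed.
#' @return a list of class `"energyGenConfig"`.
#' @export
energyGeneratorConfig <- function(mean = -23 - 3 * qnorm(825 / 4481), sd = 3,
                                  meanAbsDiff = 1,
                                  shape = c("laplace", "normal"),
                                  threshold = -23, n = 4481L, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(sd > 0, meanAbsDiff >= 0, n >= 1)
  structure(list(mean = mean, sd = sd, meanAbsDiff = meanAbsDiff,
                 shape = shape, threshold = threshold, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "energyGenConfig")
}

#' Sample a synthetic paired energy table
#'
#' Energies are drawn from the base normal; the reference energy adds a
#' signed difference drawn to hit the configured mean absolute difference
#' (Laplace: scale = meanAbsDiff; normal: sd = meanAbsDiff * sqrt(pi/2)).
#' Sequences are drawn from the background composition. Fully determined
#' by the config seed.
#'
#' @param config an [energyGeneratorConfig()].
#' @return data.frame with columns `sequence`, `energy`,
#'   `reference_energy`.
#' @export
sampleEnergyTable <- function(config) {
  stopifnot(inherits(config, "energyGenConfig"))
  set.seed(config$seed)
  n <- config$n
  chars <- matrix(sample(AA_ALPHABET, n * 6L, replace = TRUE,
                         prob = backgroundFrequencies()), n, 6L)
  pep <- do.call(paste0, asplit(chars, 2L))
  energy <- rnorm(n, config$mean, config$sd)
  d <- if (config$meanAbsDiff == 0) {
    rep(0, n)
  } else if (config$shape == "laplace") {
    rexp(n, rate = 1 / config$meanAbsDiff) * sample(c(-1, 1), n, replace = TRUE)
  } else {
    rnorm(n, 0, config$meanAbsDiff * sqrt(pi / 2))
  }
  data.frame(sequence = pep, energy = energy, reference_energy = energy + d,
             stringsAsFactors = FALSE)
}
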
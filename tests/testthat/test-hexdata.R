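test_that("sanitizeSequence uppercases, rewrites cysteine, and is idempotent", {
  expect_equal(sanitizeSequence("nnqqny"), "NNQQNY")
  expect_equal(sanitizeSequence("ACACAC"), "ASASAS")
  expect_error(sanitizeSequence(""), "non-empty")
  expect_error(sanitizeSequence(character(0)), "no sequence")
  set.seed(11)
  raw <- replicate(50, paste(sample(c(letters, LETTERS, "X", "*", "-"),
                                    sample(3:30, 1), replace = TRUE),
                             collapse = ""))
  once <- sanitizeSequence(raw)
  expect_identical(sanitizeSequence(once), once)   # idempotent
  expect_false(any(grepl("C", once, fixed = TRUE)))  # alphabet-closed on C
})

test_that("chunkSequence bounds chunk length and concatenates to the input", {
  s80 <- strrep("A", 80)
  expect_equal(chunkSequence(s80), s80)
  expect_equal(nchar(chunkSequence(paste0(s80, "K"))), c(80, 1))
  set.seed(21)
  for (L in c(1, 79, 80, 81, 200, 517)) {
    s <- paste(sample(ALPHA19, L, replace = TRUE), collapse = "")
    ch <- chunkSequence(s)
    expect_true(all(nchar(ch) <= 80))
    expect_equal(paste(ch, collapse = ""), s)
    expect_length(ch, ceiling(L / 80))
  }
})

test_that("extractWindows yields L - 5 hexapeptides and drops non-standard windows", {
  expect_length(extractWindows(strrep("A", 80)), 75)
  expect_equal(as.character(extractWindows("NNQQNY")), "NNQQNY")
  expect_length(extractWindows("NNQQN"), 0)  # shorter than the window

  ## brute-force enumeration oracle for sequences with non-standard symbols
  set.seed(31)
  for (rep in 1:20) {
    L <- sample(6:60, 1)
    chars <- sample(c(ALPHA19, "X", "B", "Z", "*"), L, replace = TRUE,
                    prob = c(rep(1, 19), 0.3, 0.2, 0.2, 0.1))
    s <- paste(chars, collapse = "")
    keepOracle <- character(0)
    for (i in seq_len(L - 5)) {                 # exhaustive window scan
      win <- substring(s, i, i + 5)
      if (!grepl("[XBZUOJ*-]", win)) keepOracle <- c(keepOracle, win)
    }
    got <- suppressMessages(extractWindows(s))
    expect_equal(as.character(got), keepOracle)
    expect_equal(attr(got, "dropped"), (L - 5) - length(keepOracle))
  }

  ## window-count identity on clean sequences
  for (L in c(6, 7, 23, 100)) {
    s <- paste(sample(ALPHA19, L, replace = TRUE), collapse = "")
    expect_length(extractWindows(s), max(0, L - 5))
  }
})

test_that("labelByEnergy uses an inclusive boundary and matches direct counting", {
  recs <- data.frame(sequence = c("NNQQNY", "AAAAAA", "IIIIII"),
                     energy = c(-23.0, -22.99, -30))
  ds <- labelByEnergy(recs)
  expect_equal(isAmyloid(ds), c(TRUE, FALSE, TRUE))   # -23.0 itself positive

  set.seed(41)
  tab <- data.frame(sequence = randomPeptides(1000),
                    energy = rnorm(1000, -20, 3))
  ds <- labelByEnergy(tab, threshold = -23)
  expect_equal(sum(isAmyloid(ds)), sum(tab$energy <= -23))  # counting oracle

  ## monotone in the threshold: lowering never increases positives
  ths <- sort(runif(8, -28, -16), decreasing = TRUE)
  pos <- vapply(ths, function(t) sum(isAmyloid(labelByEnergy(tab, t))),
                numeric(1))
  expect_true(all(diff(pos) <= 0))

  expect_warning(labelByEnergy(data.frame(sequence = c("AAAAAA", "KKKKKK"),
                                          energy = c(NA, -30))),
                 "non-finite")
  expect_error(suppressWarnings(
    labelByEnergy(data.frame(sequence = "AAAAAA", energy = NaN))))
})

test_that("positionFrequencies matches exact counts and Biostrings, and is duplication-invariant", {
  pf <- positionFrequencies(HexDataset("NNQQNY", TRUE))
  expect_equal(unname(pf["N", c(1, 2, 5)]), rep(1, 3))
  expect_equal(unname(pf["Q", c(3, 4)]), rep(1, 2))
  expect_equal(unname(pf["Y", 6]), 1)
  expect_equal(sum(pf), 6)  # each column sums to 1

  pep <- randomPeptides(500, seed = 51)
  pf <- positionFrequencies(pep)
  expect_equal(unname(colSums(pf)), rep(1, 6), tolerance = 1e-12)
  ## independent oracle: Biostrings consensus matrix
  cm <- Biostrings::consensusMatrix(Biostrings::AAStringSet(pep),
                                    as.prob = TRUE)
  expect_equal(unname(pf[rownames(cm)[rownames(cm) %in% AA_ALPHABET], ]),
               unname(cm[rownames(cm) %in% AA_ALPHABET, ]),
               tolerance = 1e-12)
  ## duplication invariance
  ds <- HexDataset(pep, rep(c(TRUE, FALSE), length.out = 500))
  expect_equal(positionFrequencies(c(ds, ds)), positionFrequencies(ds))

  ## law of large numbers: uniform residues -> frequencies near 1/19
  unif <- randomPeptides(50000, seed = 52)
  pfU <- positionFrequencies(unif)
  expect_lt(max(abs(pfU[ALPHA19, ] - 1 / 19)), 0.01)
  expect_equal(unname(pfU["C", ]), rep(0, 6))
})

test_that("classificationOverlap reports identity, negation, symmetry and breakdowns", {
  a <- setNames(c(TRUE, TRUE, FALSE, FALSE), randomPeptides(4, seed = 61))
  expect_equal(classificationOverlap(a, a)$totalFraction, 1)
  expect_equal(classificationOverlap(a, !a)$totalFraction, 0)

  b <- a; b[2] <- FALSE
  ov <- classificationOverlap(a, b)
  expect_equal(ov$totalFraction, 0.75)
  expect_equal(ov$fractionAmongPositivesA, 0.5)
  expect_equal(ov$fractionAmongNegativesA, 1)
  expect_equal(ov$positivesA, 2)
  expect_equal(ov$positivesB, 1)
  ## total fraction is symmetric
  expect_equal(classificationOverlap(b, a)$totalFraction, ov$totalFraction)

  ## intersection semantics and error on empty overlap
  c2 <- setNames(TRUE, "GGGGGG")
  expect_error(classificationOverlap(a, c2), "share no peptides")
  d <- c(a[1:2], setNames(FALSE, "WWWWWW"))
  expect_equal(classificationOverlap(a, d)$nShared, 2)
})

test_that("energyAgreement computes mean and nearest-rank quantile of |difference|", {
  same <- data.frame(energy = c(-20, -25), reference_energy = c(-20, -25))
  ea <- energyAgreement(same)
  expect_equal(ea$meanAbsDiff, 0)
  expect_equal(ea$quantileAbsDiff, 0)

  four <- data.frame(energy = rep(0, 4), reference_energy = c(1, -1, 1, -1))
  expect_equal(energyAgreement(four)$meanAbsDiff, 1)

  ## nearest-rank convention: ceiling(0.9 * 10) = 9th sorted value
  ten <- data.frame(energy = rep(0, 10), reference_energy = 1:10)
  expect_equal(energyAgreement(ten)$quantileAbsDiff, 9)

  ## half-normal mean, closed form: E|N(0, 0.8)| = 0.8 * sqrt(2/pi)
  set.seed(71)
  d <- rnorm(1e4, 0, 0.8)
  hn <- data.frame(energy = d, reference_energy = 0)
  se <- 0.8 * sqrt(1 - 2 / pi) / sqrt(1e4)
  expect_lt(abs(energyAgreement(hn)$meanAbsDiff - 0.8 * sqrt(2 / pi)), 3 * se)

  expect_error(energyAgreement(data.frame(energy = NA_real_,
                                          reference_energy = 1)),
               "no records")
})

test_that("dedupHexDataset keeps first occurrences and tags label conflicts", {
  ds <- HexDataset(c("AAAAAA", "AAAAAA", "KKKKKK", "KKKKKK", "NNQQNY"),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE),
                   source = c("a", "b", "a", "b", "a"))
  dd <- suppressMessages(dedupHexDataset(ds))
  expect_equal(attr(dd, "conflicts"), 1)
  expect_equal(sum(peptides(dd) == "AAAAAA"), 1)       # consistent dup collapsed
  expect_equal(sum(peptides(dd) == "KKKKKK"), 2)       # conflict kept, tagged
  expect_true(all(grepl("label-conflict",
                        peptideSource(dd)[peptides(dd) == "KKKKKK"])))
})

test_that("HexDataset validates its invariants", {
  expect_error(HexDataset("AAAAA", TRUE), "6-residue")
  expect_error(HexDataset("AAAXAA", TRUE), "6-residue")
  expect_error(HexDataset("AAACAA", TRUE, sanitize = FALSE), "6-residue")
  ## sanitize folds C into S instead
  expect_equal(peptides(HexDataset("AAACAA", TRUE)), "AAASAA")
  expect_error(HexDataset(c("AAAAAA", "KKKKKK"), TRUE, source = ""))
  ds <- HexDataset(c("AAAAAA", "KKKKKK"), c(TRUE, FALSE))
  expect_equal(length(ds[1]), 1L)
  expect_equal(as.data.frame(ds)$label,
               c("amyloidogenic", "non-amyloidogenic"))
})
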
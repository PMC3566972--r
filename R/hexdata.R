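## Sequence ingestion, hexapeptide extraction, energy-threshold labeling and
## dataset statistics.

#' Sanitize a protein sequence
#'
#' Uppercases the sequence and rewrites every cysteine (C) to serine (S) so
#' that threaded structures cannot form disulfide bridges. Symbols outside
#' the 20-letter alphabet (X, B, Z, U, O, J, *, -) are left in place here;
#' [extractWindows()] drops windows containing them. Idempotent.
#'
#' @param raw character vector of non-empty sequences.
#' @return character vector of the same length.
#' @examples
#' sanitizeSequence("nnqqny")  # "NNQQNY"
#' sanitizeSequence("ACACAC")  # "ASASAS"
#' @export
sanitizeSequence <- function(raw) {
  if (length(raw) == 0) stop("no sequence given")
  raw <- as.character(raw)
  if (anyNA(raw) || any(!nzchar(raw))) stop("sequences must be non-empty")
  chartr("C", "S", toupper(raw))
}

#' Split a sequence into chunks of bounded length
#'
#' Non-overlapping cut into strings not exceeding `maxLen` residues; the
#' concatenation of the chunks equals the input. Hexapeptide windows
#' spanning a chunk boundary are not recovered (chunking exists to bound
#' segment length ahead of redundancy reduction, which is out of scope);
#' pass the sequence straight to [extractWindows()] to skip chunking.
#'
#' @param seq a single sequence string.
#' @param maxLen maximum chunk length (default 80).
#' @return character vector of chunks.
#' @export
chunkSequence <- function(seq, maxLen = 80L) {
  stopifnot(length(seq) == 1L, nzchar(seq), maxLen >= 1)
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = maxLen)
  substring(seq, starts, pmin(starts + maxLen - 1L, n))
}

#' Extract sliding hexapeptide windows
#'
#' Cuts a sequence into `width`-residue windows shifted by `step` positions.
#' Windows containing a non-standard symbol (X, B, Z, U, O, J, *, -) are
#' dropped (the 20-letter model space has no representation for them); the
#' number dropped is reported via `message()` and attached as attribute
#' `"dropped"`.
#'
#' @param seq a single sequence string (sanitize first).
#' @param width window width (default 6).
#' @param step shift between windows (default 1).
#' @return character vector of windows (empty if the sequence is shorter
#'   than `width`), with attribute `dropped`.
#' @examples
#' length(extractWindows(strrep("A", 80)))  # 75
#' @export
extractWindows <- function(seq, width = 6L, step = 1L) {
  stopifnot(length(seq) == 1L, width >= 1, step >= 1)
  n <- nchar(seq)
  if (n < width) {
    out <- character(0)
    attr(out, "dropped") <- 0L
    return(out)
  }
  starts <- seq.int(1L, n - width + 1L, by = step)
  win <- substring(seq, starts, starts + width - 1L)
  bad <- grepl("[-XBZUOJ*]", win)
  if (any(bad))
    message(sprintf("extractWindows: dropped %d window(s) containing non-standard symbols", sum(bad)))
  out <- win[!bad]
  attr(out, "dropped") <- sum(bad)
  out
}

#' Label hexapeptides by their minimal zipper energy
#'
#' A segment is amyloidogenic iff its energy is not greater than the
#' threshold (boundary inclusive: energy <= threshold is positive). The
#' default threshold of -23 kcal/mol is the steric-zipper classification
#' threshold.
#'
#' @param records data.frame with columns `sequence` and `energy`
#'   (kcal/mol); e.g. from [readHexTable()] or [sampleEnergyTable()].
#' @param threshold classification threshold in kcal/mol (default -23).
#' @param source provenance tag for the resulting dataset.
#' @return A [HexDataset-class]; records with non-finite energy are rejected
#'   with a warning and counted in attribute `"rejected"`.
#' @export
labelByEnergy <- function(records, threshold = -23, source = "energy") {
  stopifnot(is.data.frame(records), all(c("sequence", "energy") %in% names(records)))
  if (nrow(records) == 0) stop("no energy records given")
  ok <- is.finite(records$energy)
  if (!all(ok))
    warning(sprintf("labelByEnergy: rejected %d record(s) with non-finite energy", sum(!ok)))
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0) stop("all energy records were non-finite")
  out <- HexDataset(records$sequence, records$energy <= threshold, source = source)
  attr(out, "rejected") <- sum(!ok)
  out
}

#' Position-specific residue frequencies
#'
#' Frequency of each of the 20 residues at each of the 6 positions. Columns
#' sum to 1.
#'
#' @param dataset a [HexDataset-class] or character vector of hexapeptides.
#' @return 20 x 6 numeric matrix, rows named by [AA_ALPHABET], columns 1..6.
#' @export
positionFrequencies <- function(dataset) {
  pep <- if (is(dataset, "HexDataset")) peptides(dataset) else as.character(dataset)
  if (length(pep) == 0) stop("empty dataset")
  m <- matrix(unlist(strsplit(pep, "", fixed = TRUE), use.names = FALSE),
              ncol = 6L, byrow = TRUE)
  freq <- vapply(1:6, function(j)
    tabulate(match(m[, j], AA_ALPHABET), nbins = 20L), numeric(20L))
  freq <- freq / length(pep)
  dimnames(freq) <- list(residue = AA_ALPHABET, position = 1:6)
  freq
}

#' Agreement between two binary classifications of the same peptides
#'
#' Compares two peptide -> label maps on their shared peptides and reports
#' the fraction identically classified, overall and stratified by the first
#' map's label.
#'
#' @param a,b named logical vectors (names = peptide sequences, value TRUE =
#'   amyloidogenic), or [HexDataset-class] objects.
#' @return list: `nShared`, `totalFraction`, `fractionAmongPositivesA`,
#'   `fractionAmongNegativesA`, `positivesA`, `positivesB`.
#' @export
classificationOverlap <- function(a, b) {
  asLabelMap <- function(x) {
    if (is(x, "HexDataset")) setNames(isAmyloid(x), peptides(x)) else x
  }
  a <- asLabelMap(a); b <- asLabelMap(b)
  stopifnot(is.logical(a), is.logical(b), !is.null(names(a)), !is.null(names(b)))
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop("the two classifications share no peptides")
  la <- a[shared]; lb <- b[shared]
  same <- la == lb
  list(nShared = length(shared),
       totalFraction = mean(same),
       fractionAmongPositivesA = if (any(la)) mean(same[la]) else NA_real_,
       fractionAmongNegativesA = if (any(!la)) mean(same[!la]) else NA_real_,
       positivesA = sum(la),
       positivesB = sum(lb))
}

#' Agreement between paired energy columns
#'
#' Mean absolute difference between an energy column and a reference energy
#' column, plus a high quantile of the absolute difference by the
#' nearest-rank convention (the `ceiling(prob * n)`-th sorted value).
#'
#' @param records data.frame with columns `energy` and `reference_energy`
#'   (kcal/mol).
#' @param prob quantile level (default 0.9).
#' @return list: `meanAbsDiff`, `quantileAbsDiff`, `prob`, `n`.
#' @export
energyAgreement <- function(records, prob = 0.9) {
  stopifnot(is.data.frame(records),
            all(c("energy", "reference_energy") %in% names(records)),
            prob > 0, prob <= 1)
  d <- abs(records$energy - records$reference_energy)
  d <- d[is.finite(d)]
  if (length(d) == 0) stop("no records with both energies present")
  ds <- sort(d)
  list(meanAbsDiff = mean(d),
       quantileAbsDiff = ds[ceiling(prob * length(ds))],
       prob = prob,
       n = length(d))
}

#' Remove duplicate hexapeptides from a dataset
#'
#' Optional pass for merging window-derived sets with experimentally studied
#' hexapeptides. Duplicates with consistent labels are collapsed to the
#' first occurrence. Sequences carrying conflicting labels are all kept,
#' with `"|label-conflict"` appended to their source tags, and their count
#' is reported.
#'
#' @param dataset a [HexDataset-class].
#' @return deduplicated [HexDataset-class] with attribute `"conflicts"`.
#' @export
dedupHexDataset <- function(dataset) {
  stopifnot(is(dataset, "HexDataset"))
  pep <- peptides(dataset); lab <- isAmyloid(dataset)
  conflictSeq <- unique(pep[pep %in% pep[lab] & pep %in% pep[!lab]])
  isConflict <- pep %in% conflictSeq
  keep <- isConflict | !duplicated(pep)
  out <- new("HexDataset",
             peptides = pep[keep],
             amyloid = lab[keep],
             source = ifelse(isConflict[keep],
                             paste0(dataset@source[keep], "|label-conflict"),
                             dataset@source[keep]))
  if (length(conflictSeq))
    message(sprintf("dedupHexDataset: %d sequence(s) carry conflicting labels; kept all occurrences tagged",
                    length(conflictSeq)))
  attr(out, "conflicts") <- length(conflictSeq)
  out
}

#' Extract all hexapeptides from protein sequences
#'
#' Pipeline convenience: sanitize each sequence, optionally cut it into
#' chunks of at most `maxLen` residues, then extract 6-residue windows
#' shifted by one position.
#'
#' @param sequences named character vector of protein sequences (e.g. from
#'   [readProteinFasta()]).
#' @param maxLen chunk length bound (default 80); `Inf` or `chunk = FALSE`
#'   skips chunking.
#' @param chunk logical; cut into chunks first (default TRUE).
#' @return data.frame with columns `sequence` (hexapeptide) and `source`
#'   (record name), attribute `"dropped"` = windows lost to non-standard
#'   symbols.
#' @export
hexapeptidesFromSequences <- function(sequences, maxLen = 80L, chunk = TRUE) {
  stopifnot(length(sequences) > 0)
  nm <- if (is.null(names(sequences))) sprintf("seq%d", seq_along(sequences)) else names(sequences)
  dropped <- 0L
  res <- lapply(seq_along(sequences), function(i) {
    s <- sanitizeSequence(sequences[[i]])
    pieces <- if (chunk && is.finite(maxLen)) chunkSequence(s, maxLen) else s
    wins <- lapply(pieces, extractWindows)
    dropped <<- dropped + sum(vapply(wins, function(w) attr(w, "dropped"), integer(1)))
    w <- unlist(wins, use.names = FALSE)
    if (length(w)) data.frame(sequence = w, source = nm[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(sequence = character(0), source = character(0))
  attr(out, "dropped") <- dropped
  out
}
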
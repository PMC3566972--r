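## S4 classes for the hexapeptide classification stack.

#' HexDataset: a labeled collection of sanitized hexapeptides
#'
#' The atomic training/evaluation container: six-residue sequences over the
#' 20-letter alphabet (cysteine-free after sanitization), a binary
#' amyloidogenicity label, and a free-text provenance tag per peptide.
#' Duplicate sequences are allowed (the same hexapeptide can occur in many
#' proteins).
#'
#' @slot peptides character vector of 6-letter sequences.
#' @slot amyloid logical; `TRUE` = amyloidogenic (the positive class).
#' @slot source character provenance tags (non-empty).
#' @export
setClass("HexDataset",
         representation(peptides = "character",
                        amyloid  = "logical",
                        source   = "character"))

setValidity("HexDataset", function(object) {
  n <- length(object@peptides)
  if (length(object@amyloid) != n || length(object@source) != n)
    return("peptides, amyloid and source must have equal length")
  if (anyNA(object@amyloid)) return("labels must be TRUE/FALSE, not NA")
  if (any(!nzchar(object@source))) return("source tags must be non-empty")
  ## sanitized alphabet: the 20 letters minus C (cysteine maps to serine)
  bad <- !grepl("^[ADEFGHIKLMNPQRSTVWY]{6}$", object@peptides)
  if (any(bad))
    return(sprintf(
      "%d peptide(s) are not 6-residue strings over the sanitized alphabet (first offender: '%s')",
      sum(bad), object@peptides[which(bad)[1]]))
  TRUE
})

#' Construct a HexDataset
#'
#' @param peptides character vector of 6-letter peptides.
#' @param amyloid labels: logical, 0/1, or `"amyloidogenic"` /
#'   `"non-amyloidogenic"` strings.
#' @param source provenance tag(s), recycled.
#' @param sanitize uppercase and rewrite cysteine to serine before
#'   validation (default `TRUE`).
#' @return A [HexDataset-class] object.
#' @examples
#' hd <- HexDataset(c("NNQQNY", "AAAAAA"), c(TRUE, FALSE), source = "demo")
#' @export
HexDataset <- function(peptides, amyloid, source = "unspecified",
                       sanitize = TRUE) {
  peptides <- as.character(peptides)
  if (sanitize && length(peptides)) peptides <- sanitizeSequence(peptides)
  if (is.character(amyloid) || is.factor(amyloid)) {
    amyloid <- as.character(amyloid)
    ok <- amyloid %in% c("amyloidogenic", "non-amyloidogenic")
    if (!all(ok)) stop("character labels must be 'amyloidogenic' or 'non-amyloidogenic'")
    amyloid <- amyloid == "amyloidogenic"
  } else if (is.numeric(amyloid)) {
    if (!all(amyloid %in% c(0, 1))) stop("numeric labels must be 0/1")
    amyloid <- amyloid == 1
  }
  new("HexDataset", peptides = peptides, amyloid = as.logical(amyloid),
      source = rep_len(as.character(source), length(peptides)))
}

#' @describeIn HexDataset-class number of peptides
#' @param x a `HexDataset`.
#' @export
setMethod("length", "HexDataset", function(x) length(x@peptides))

#' @export
setMethod("show", "HexDataset", function(object) {
  n <- length(object)
  cat(sprintf("HexDataset with %d hexapeptide(s): %d amyloidogenic, %d non-amyloidogenic\n",
              n, sum(object@amyloid), sum(!object@amyloid)))
  if (n) {
    k <- min(n, 4L)
    cat(sprintf("  %s%s\n",
                paste(sprintf("%s(%s)", object@peptides[seq_len(k)],
                              ifelse(object@amyloid[seq_len(k)], "+", "-")),
                      collapse = " "),
                if (n > k) " ..." else ""))
  }
})

#' @rdname HexDataset-class
#' @param i index vector.
#' @export
setMethod("[", "HexDataset", function(x, i) {
  new("HexDataset", peptides = x@peptides[i], amyloid = x@amyloid[i],
      source = x@source[i])
})

setGeneric("peptides", function(x) standardGeneric("peptides"))
setGeneric("isAmyloid", function(x) standardGeneric("isAmyloid"))
setGeneric("peptideSource", function(x) standardGeneric("peptideSource"))

#' Accessors for HexDataset
#'
#' `peptides()` returns the 6-letter sequences, `isAmyloid()` the logical
#' labels (TRUE = amyloidogenic), `peptideSource()` the provenance tags.
#'
#' @param x a [HexDataset-class].
#' @return character / logical / character vector respectively.
#' @aliases peptides isAmyloid peptideSource
#' @export peptides isAmyloid peptideSource
#' @name HexDataset-accessors
NULL

#' @rdname HexDataset-accessors
setMethod("peptides", "HexDataset", function(x) x@peptides)
#' @rdname HexDataset-accessors
setMethod("isAmyloid", "HexDataset", function(x) x@amyloid)
#' @rdname HexDataset-accessors
setMethod("peptideSource", "HexDataset", function(x) x@source)

#' @describeIn HexDataset-class coerce to a data.frame with columns
#'   `sequence`, `label`, `source`
#' @param row.names,optional,... passed for generic compatibility, ignored.
#' @export
setMethod("as.data.frame", "HexDataset",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(sequence = x@peptides,
             label = ifelse(x@amyloid, "amyloidogenic", "non-amyloidogenic"),
             source = x@source, stringsAsFactors = FALSE)
})

#' Concatenate HexDatasets
#'
#' @param x,... `HexDataset` objects.
#' @return the combined [HexDataset-class].
#' @export
setMethod("c", "HexDataset", function(x, ...) {
  rest <- list(...)
  for (y in rest) {
    stopifnot(is(y, "HexDataset"))
    x <- new("HexDataset",
             peptides = c(x@peptides, y@peptides),
             amyloid  = c(x@amyloid, y@amyloid),
             source   = c(x@source, y@source))
  }
  x
})

## ---------------------------------------------------------------------------

#' ADTreeModel: an alternating decision tree over position-residue predicates
#'
#' The tree alternates prediction nodes (additive real contributions) and
#' splitter (decision) nodes testing `AA[position] == residue`. An instance's
#' score is the root value plus the value of every prediction node whose full
#' path predicate it satisfies. Prediction nodes are numbered 0 (root), then
#' 2k-1 / 2k for the true/false children of the k-th splitter.
#'
#' @slot rootValue numeric root prediction value.
#' @slot splitters data.frame, one row per boosting iteration: `order`,
#'   `parent` (prediction-node id the splitter hangs from), `position`,
#'   `residue`, `trueValue`, `falseValue`, `z` (the minimized split score).
#' @slot iterations integer number of boosting iterations.
#' @slot smoothing numeric value added to numerator and denominator of every
#'   half-log-ratio.
#' @slot lossTrace numeric; total exponential loss after the root and after
#'   each iteration.
#' @export
setClass("ADTreeModel",
         representation(rootValue = "numeric", splitters = "data.frame",
                        iterations = "integer", smoothing = "numeric",
                        lossTrace = "numeric"))

setValidity("ADTreeModel", function(object) {
  sp <- object@splitters
  if (nrow(sp) != object@iterations)
    return("number of splitters must equal iterations")
  if (nrow(sp)) {
    if (!all(sp$order == seq_len(nrow(sp)))) return("splitter order must be 1..iterations")
    ## acyclicity/reachability: parent of splitter k must be a node created
    ## before k (root 0 or a child of an earlier splitter)
    if (!all(sp$parent >= 0 & sp$parent <= 2 * (sp$order - 1)))
      return("each splitter's parent must be an already-existing prediction node")
    if (!all(sp$position %in% 1:6)) return("positions must be 1..6")
    if (!all(sp$residue %in% AA_ALPHABET)) return("residues must be in the 20-letter alphabet")
    if (!all(is.finite(sp$trueValue)) || !all(is.finite(sp$falseValue)))
      return("prediction values must be finite")
  }
  if (!is.finite(object@rootValue)) return("root value must be finite")
  if (object@smoothing < 0) return("smoothing must be >= 0")
  TRUE
})

#' @export
setMethod("show", "ADTreeModel", function(object) {
  cat(sprintf("ADTreeModel: %d boosting iteration(s), smoothing %g, root %.3f\n",
              object@iterations, object@smoothing, object@rootValue))
  if (object@iterations > 0) {
    k <- min(object@iterations, 3L)
    cat(paste0("  ", formatRules(object)[seq_len(k)], collapse = "\n"), "\n")
    if (object@iterations > k) cat(sprintf("  ... %d more rule(s)\n", object@iterations - k))
  }
})

## ---------------------------------------------------------------------------

#' NaiveBayesModel: categorical naive Bayes over hexapeptide positions
#'
#' @slot priors named numeric (negative, positive), summing to 1.
#' @slot tables numeric array 20 x 6 x 2: P(residue | position, class),
#'   Laplace-smoothed; class slices sum to 1 per position.
#' @slot alpha Laplace pseudo-count.
#' @slot classCounts integer class counts in the training data.
#' @export
setClass("NaiveBayesModel",
         representation(priors = "numeric", tables = "array",
                        alpha = "numeric", classCounts = "integer"))

setValidity("NaiveBayesModel", function(object) {
  if (!isTRUE(all.equal(sum(object@priors), 1))) return("priors must sum to 1")
  if (!all(dim(object@tables) == c(20L, 6L, 2L))) return("tables must be 20 x 6 x 2")
  cs <- apply(object@tables, c(2, 3), sum)
  if (!isTRUE(all.equal(as.vector(cs), rep(1, 12), tolerance = 1e-9)))
    return("each (position, class) conditional table must sum to 1")
  TRUE
})

#' @export
setMethod("show", "NaiveBayesModel", function(object) {
  cat(sprintf("NaiveBayesModel: priors %.3f (non-amyloid) / %.3f (amyloid), alpha = %g\n",
              object@priors[1], object@priors[2], object@alpha))
})

## ---------------------------------------------------------------------------

#' MLPModel: one-hidden-layer perceptron over one-hot encoded hexapeptides
#'
#' Architecture 120 -> hidden -> 1 with logistic activations throughout,
#' trained by per-instance stochastic gradient descent with momentum on
#' squared error.
#'
#' @slot W1 input-to-hidden weights (120 x hidden).
#' @slot b1 hidden biases.
#' @slot W2 hidden-to-output weights.
#' @slot b2 output bias (length 1).
#' @slot hyper list: hidden, learningRate, momentum, epochs, seed.
#' @slot lossTrace per-epoch mean squared error (running estimate).
#' @export
setClass("MLPModel",
         representation(W1 = "matrix", b1 = "numeric", W2 = "numeric",
                        b2 = "numeric", hyper = "list", lossTrace = "numeric"))

setValidity("MLPModel", function(object) {
  if (nrow(object@W1) != 120L) return("W1 must have 120 rows (6 positions x 20 residues)")
  h <- ncol(object@W1)
  if (length(object@b1) != h || length(object@W2) != h || length(object@b2) != 1L)
    return("weight dimensions are inconsistent")
  if (!all(is.finite(object@W1)) || !all(is.finite(object@b1)) ||
      !all(is.finite(object@W2)) || !all(is.finite(object@b2)))
    return("weights must be finite")
  TRUE
})

#' @export
setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel: 120-%d-1 logistic, lr %g, momentum %g, %d epoch(s), seed %d\n",
              ncol(object@W1), object@hyper$learningRate, object@hyper$momentum,
              object@hyper$epochs, object@hyper$seed))
})

## ---------------------------------------------------------------------------

#' ZipperScaffold: backbone of a two-sheet steric-zipper reference structure
#'
#' Backbone (N, CA, C, O) coordinates for two beta-sheets of five 6-residue
#' strands each. Sheet 2 of the canonical scaffold sits at the native sheet
#' separation; templates are produced by rigid translations of sheet 2.
#'
#' @slot atoms data.frame: `sheet` (1/2), `strand` (1..5), `chain` (A..J),
#'   `resno` (1..6), `atom` (N/CA/C/O), `x`, `y`, `z`.
#' @slot sequence the scaffold's own hexapeptide sequence.
#' @slot nativeSeparation numeric, Angstrom.
#' @export
setClass("ZipperScaffold",
         representation(atoms = "data.frame", sequence = "character",
                        nativeSeparation = "numeric"))

setValidity("ZipperScaffold", function(object) {
  a <- object@atoms
  need <- c("sheet", "strand", "chain", "resno", "atom", "x", "y", "z")
  if (!all(need %in% names(a))) return("atoms must have sheet/strand/chain/resno/atom/x/y/z")
  if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
    return("coordinates must be finite")
  if (!setequal(unique(a$sheet), 1:2)) return("scaffold must contain sheets 1 and 2")
  for (s in 1:2) {
    ss <- a[a$sheet == s, ]
    if (length(unique(ss$strand)) != 5L) return("each sheet must have 5 strands")
    if (!all(sort(unique(ss$resno)) == 1:6)) return("each strand must have residues 1..6")
  }
  if (nchar(object@sequence) != 6L) return("scaffold sequence must have 6 residues")
  TRUE
})

#' @export
setMethod("show", "ZipperScaffold", function(object) {
  cat(sprintf("ZipperScaffold '%s': 2 sheets x 5 strands x 6 residues (%d atoms), native separation %.2f A\n",
              object@sequence, nrow(object@atoms), object@nativeSeparation))
})

#' ZipperTemplate: one rigid-body pose of the two-sheet zipper
#'
#' @slot shift numeric, Angstrom along the chain axis.
#' @slot separation numeric, Angstrom across the sheets.
#' @slot atoms data.frame as in [ZipperScaffold-class].
#' @export
setClass("ZipperTemplate",
         representation(shift = "numeric", separation = "numeric",
                        atoms = "data.frame"))

#' @export
setMethod("show", "ZipperTemplate", function(object) {
  cat(sprintf("ZipperTemplate: shift %.1f A along chains, separation %.1f A across sheets\n",
              object@shift, object@separation))
})

#' ThreadedZipper: a hexapeptide threaded onto a zipper template
#'
#' All ten chains carry the peptide's residue identities on the template
#' backbone; side-chain placement is left to the energy adapter.
#'
#' @slot template the [ZipperTemplate-class] used.
#' @slot peptide the threaded 6-letter sequence.
#' @slot atoms data.frame with an additional `resid` column (3-letter codes).
#' @export
setClass("ThreadedZipper",
         representation(template = "ZipperTemplate", peptide = "character",
                        atoms = "data.frame"))

#' @export
setMethod("show", "ThreadedZipper", function(object) {
  cat(sprintf("ThreadedZipper: '%s' on template (shift %.1f, separation %.1f), 10 chains\n",
              object@peptide, object@template@shift, object@template@separation))
})
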
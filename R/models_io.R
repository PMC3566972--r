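## Structured plain-text model serialization. Numbers are written with
## %.17g so save/load round-trips doubles exactly.

MODEL_FORMAT_VERSION <- 1L

fmtNum <- function(x) sprintf("%.17g", x)

setGeneric("saveModel", function(model, path) standardGeneric("saveModel"))

#' Save a trained classifier to a text file
#'
#' Machine-readable structured text (tagged sections, tab-separated
#' numbers, full double precision); [loadModel()] restores an identical
#' model. ADTree files additionally embed the human-readable rule listing
#' as comments.
#'
#' @param model an [ADTreeModel-class], [NaiveBayesModel-class] or
#'   [MLPModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @aliases saveModel
#' @export
setMethod("saveModel", "ADTreeModel", function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("AmyloHexModel\tadtree\t%d", MODEL_FORMAT_VERSION),
               paste(c("# rules:", formatRules(model)), collapse = "\n# "),
               paste("rootValue", fmtNum(model@rootValue), sep = "\t"),
               paste("iterations", model@iterations, sep = "\t"),
               paste("smoothing", fmtNum(model@smoothing), sep = "\t"),
               paste("lossTrace", paste(fmtNum(model@lossTrace), collapse = "\t"), sep = "\t"),
               "splitters\torder\tparent\tposition\tresidue\ttrueValue\tfalseValue\tz"),
             con)
  sp <- model@splitters
  if (nrow(sp))
    writeLines(sprintf("s\t%d\t%d\t%d\t%s\t%s\t%s\t%s", sp$order, sp$parent,
                       sp$position, sp$residue, fmtNum(sp$trueValue),
                       fmtNum(sp$falseValue), fmtNum(sp$z)), con)
  invisible(path)
})

#' @rdname saveModel-ADTreeModel-method
#' @export
setMethod("saveModel", "NaiveBayesModel", function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("AmyloHexModel\tnaivebayes\t%d", MODEL_FORMAT_VERSION),
               paste("priors", paste(fmtNum(model@priors), collapse = "\t"), sep = "\t"),
               paste("alpha", fmtNum(model@alpha), sep = "\t"),
               paste("classCounts", paste(model@classCounts, collapse = "\t"), sep = "\t")),
             con)
  for (ci in 1:2)
    writeLines(sprintf("table\t%d\t%d\t%s", ci, 1:6,
                       apply(model@tables[, , ci], 2L, function(col)
                         paste(fmtNum(col), collapse = "\t"))), con)
  invisible(path)
})

#' @rdname saveModel-ADTreeModel-method
#' @export
setMethod("saveModel", "MLPModel", function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  h <- model@hyper
  writeLines(c(sprintf("AmyloHexModel\tmlp\t%d", MODEL_FORMAT_VERSION),
               sprintf("hyper\t%d\t%s\t%s\t%d\t%d", h$hidden,
                       fmtNum(h$learningRate), fmtNum(h$momentum),
                       h$epochs, h$seed),
               paste("b1", paste(fmtNum(model@b1), collapse = "\t"), sep = "\t"),
               paste("W2", paste(fmtNum(model@W2), collapse = "\t"), sep = "\t"),
               paste("b2", fmtNum(model@b2), sep = "\t"),
               paste("lossTrace", paste(fmtNum(model@lossTrace), collapse = "\t"), sep = "\t")),
             con)
  writeLines(sprintf("W1\t%s", apply(model@W1, 2L, function(col)
    paste(fmtNum(col), collapse = "\t"))), con)
  invisible(path)
})

#' Load a classifier saved by [saveModel()]
#'
#' @param path model file.
#' @return the restored model object.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2 || hdr[1] != "AmyloHexModel")
    stop("not an AmyloHex model file: ", path)
  type <- hdr[2]
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  tagOf <- vapply(fields, `[[`, "", 1L)
  get1 <- function(tag) fields[[match(tag, tagOf)]][-1]
  switch(type,
    adtree = {
      spRows <- fields[tagOf == "s"]
      sp <- if (length(spRows)) {
        data.frame(order = as.integer(vapply(spRows, `[[`, "", 2L)),
                   parent = as.integer(vapply(spRows, `[[`, "", 3L)),
                   position = as.integer(vapply(spRows, `[[`, "", 4L)),
                   residue = vapply(spRows, `[[`, "", 5L),
                   trueValue = as.numeric(vapply(spRows, `[[`, "", 6L)),
                   falseValue = as.numeric(vapply(spRows, `[[`, "", 7L)),
                   z = as.numeric(vapply(spRows, `[[`, "", 8L)),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(order = integer(0), parent = integer(0),
                   position = integer(0), residue = character(0),
                   trueValue = numeric(0), falseValue = numeric(0),
                   z = numeric(0), stringsAsFactors = FALSE)
      }
      new("ADTreeModel", rootValue = as.numeric(get1("rootValue")),
          splitters = sp, iterations = as.integer(get1("iterations")),
          smoothing = as.numeric(get1("smoothing")),
          lossTrace = as.numeric(get1("lossTrace")))
    },
    naivebayes = {
      tabRows <- fields[tagOf == "table"]
      tables <- array(0, dim = c(20L, 6L, 2L),
                      dimnames = list(residue = AA_ALPHABET, position = 1:6,
                                      class = c("non-amyloidogenic", "amyloidogenic")))
      for (row in tabRows) {
        ci <- as.integer(row[2]); j <- as.integer(row[3])
        tables[, j, ci] <- as.numeric(row[-(1:3)])
      }
      new("NaiveBayesModel",
          priors = setNames(as.numeric(get1("priors")),
                            c("non-amyloidogenic", "amyloidogenic")),
          tables = tables, alpha = as.numeric(get1("alpha")),
          classCounts = as.integer(get1("classCounts")))
    },
    mlp = {
      hy <- get1("hyper")
      W1cols <- fields[tagOf == "W1"]
      W1 <- vapply(W1cols, function(r) as.numeric(r[-1]), numeric(120L))
      new("MLPModel", W1 = unname(W1), b1 = as.numeric(get1("b1")),
          W2 = as.numeric(get1("W2")), b2 = as.numeric(get1("b2")),
          hyper = list(hidden = as.integer(hy[1]),
                       learningRate = as.numeric(hy[2]),
                       momentum = as.numeric(hy[3]),
                       epochs = as.integer(hy[4]),
                       seed = as.integer(hy[5])),
          lossTrace = as.numeric(get1("lossTrace")))
    },
    stop("unknown model type: ", type))
}
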
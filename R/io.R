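## Readers and writers: FASTA, tab-separated hexapeptide/energy tables, and
## a minimal ARFF importer.

#' Read protein sequences from a FASTA file
#'
#' Multi-record, wrapped lines; full '>' headers are preserved as names.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("FASTA file contains no records: ", path)
  setNames(as.character(aa), names(aa))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

## canonical column set of the tab-separated hexapeptide dialect
HEXTABLE_COLUMNS <- c("sequence", "energy", "reference_energy", "label", "source")

#' Read a tab-separated hexapeptide table
#'
#' UTF-8, tab-separated, header line; any subset of the columns `sequence`
#' (required), `energy`, `reference_energy` (kcal/mol), `label`
#' (`amyloidogenic` / `non-amyloidogenic`), `source`. This is the dialect
#' the supplementary energy sheets (trainset(+), trainset(-), testset(+),
#' testset(-)) re-export to, and the one [writeHexTable()] emits.
#'
#' @param path input file.
#' @return data.frame with typed columns.
#' @export
readHexTable <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (!"sequence" %in% names(df))
    stop("hexapeptide table must have a 'sequence' column: ", path)
  df$sequence <- as.character(df$sequence)
  for (col in c("energy", "reference_energy"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a tab-separated hexapeptide table
#'
#' @param df data.frame (or [HexDataset-class], coerced via
#'   `as.data.frame`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHexTable <- function(df, path) {
  if (is(df, "HexDataset")) df <- as.data.frame(df)
  stopifnot(is.data.frame(df), "sequence" %in% names(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a hexapeptide table to a HexDataset
#'
#' @param df data.frame with `sequence` and `label` columns (plus optional
#'   `source`).
#' @param source fallback provenance tag when the table has no `source`.
#' @return [HexDataset-class].
#' @export
hexDatasetFromTable <- function(df, source = "table") {
  stopifnot(is.data.frame(df), all(c("sequence", "label") %in% names(df)))
  HexDataset(df$sequence, df$label,
             source = if ("source" %in% names(df)) df$source else source)
}

#' Minimal ARFF importer
#'
#' Reads nominal/numeric attributes and comma-separated data rows; enough to
#' ingest simple attribute-relation files of hexapeptide features. No
#' support for sparse rows, strings with escaped quotes, or date types.
#'
#' @param path ARFF file.
#' @return data.frame; nominal attributes as character, numeric as numeric.
#' @export
readARFF <- function(path) {
  if (!file.exists(path)) stop("ARFF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  lower <- tolower(lines)
  attrIdx <- grep("^@attribute", lower)
  dataIdx <- match(TRUE, lower == "@data")
  if (length(attrIdx) == 0 || is.na(dataIdx)) stop("not a parseable ARFF file: ", path)
  attrs <- lapply(lines[attrIdx], function(l) {
    m <- regmatches(l, regexec("^@\\w+\\s+('[^']+'|\\S+)\\s+(.*)$", l, ignore.case = TRUE))[[1]]
    list(name = gsub("^'|'$", "", m[2]),
         numeric = tolower(trimws(m[3])) %in% c("numeric", "real", "integer"))
  })
  rows <- lines[-seq_len(dataIdx)]
  rows <- rows[!startsWith(tolower(rows), "@")]
  parts <- strsplit(rows, ",", fixed = TRUE)
  if (any(lengths(parts) != length(attrs)))
    stop("ARFF data rows do not match the attribute count")
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- vapply(attrs, `[[`, "", "name")
  for (j in seq_along(attrs)) {
    out[[j]] <- gsub("^\\s+|\\s+$", "", out[[j]])
    out[[j]] <- gsub("^'|'$", "", out[[j]])
    if (attrs[[j]]$numeric) out[[j]] <- as.numeric(out[[j]])
  }
  out
}
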
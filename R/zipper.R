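## Simplified steric-zipper template enumeration, threading, and
## minimum-energy classification.

## backbone offsets of one idealized extended residue, relative to its CA
## (strand along +x, sheet in the xy-plane); the alternating y-offset gives
## the in-plane zig-zag of an extended chain
idealResidueOffsets <- function(flip) {
  s <- if (flip) -1 else 1
  rbind(N  = c(-1.23, s * 0.30, 0),
        CA = c( 0.00, s * -0.25, 0),
        C  = c( 1.23, s * 0.30, 0),
        O  = c( 1.25, s * 1.52, 0))
}

#' Build the idealized two-sheet zipper scaffold
#'
#' A synthetic, idealized stand-in for the fibril-forming NNQQNY
#' cross-beta arrangement: two flat parallel sheets of five extended
#' 6-residue strands (backbone N, CA, C, O only), 4.8 Angstrom strand
#' spacing within a sheet, sheet 2 a rigid copy of sheet 1 displaced along
#' the sheet normal by the native separation. It is a geometric scaffold
#' for template enumeration, not an experimentally determined structure.
#'
#' @param sequence the scaffold's own hexapeptide (default `"NNQQNY"`).
#' @param strandSpacing Angstrom between strands within a sheet (default
#'   4.8).
#' @param nativeSeparation Angstrom between the two sheets (default 8.5, a
#'   typical dry steric-zipper inter-sheet distance).
#' @param caSpacing Angstrom between consecutive CA atoms along a strand
#'   (default 3.5, extended conformation).
#' @return a [ZipperScaffold-class].
#' @export
buildIdealScaffold <- function(sequence = "NNQQNY", strandSpacing = 4.8,
                               nativeSeparation = 8.5, caSpacing = 3.5) {
  sequence <- sanitizeSequence(sequence)
  stopifnot(nchar(sequence) == 6L)
  rows <- list()
  for (sheet in 1:2) for (strand in 1:5) for (res in 1:6) {
    off <- idealResidueOffsets(res %% 2 == 0)
    xyz <- sweep(off, 2L, c((res - 1) * caSpacing, (strand - 1) * strandSpacing,
                            if (sheet == 2) nativeSeparation else 0), "+")
    rows[[length(rows) + 1L]] <- data.frame(
      sheet = sheet, strand = strand,
      chain = LETTERS[(sheet - 1) * 5 + strand],
      resno = res, atom = rownames(off),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  new("ZipperScaffold", atoms = atoms, sequence = sequence,
      nativeSeparation = nativeSeparation)
}

## orthonormal frame of a scaffold, recomputed from coordinates:
## chain axis = mean CA(i) -> CA(i+1) direction of sheet 1,
## inter-strand axis = mean direction between consecutive strand centroids,
## sheet normal = unit cross product, oriented toward sheet 2
scaffoldFrame <- function(scaffold) {
  a <- scaffold@atoms
  ca <- a[a$atom == "CA" & a$sheet == 1, ]
  ca <- ca[order(ca$strand, ca$resno), ]
  diffs <- do.call(rbind, lapply(split(ca, ca$strand), function(s) {
    xyz <- as.matrix(s[order(s$resno), c("x", "y", "z")])
    diff(xyz)
  }))
  axis <- colMeans(diffs)
  nax <- sqrt(sum(axis^2))
  if (nax < 1e-8) stop("degenerate scaffold: chain axis undefined")
  axis <- axis / nax
  cent <- do.call(rbind, lapply(split(ca, ca$strand), function(s)
    colMeans(as.matrix(s[, c("x", "y", "z")]))))
  inter <- colMeans(diff(cent))
  nin <- sqrt(sum(inter^2))
  if (nin < 1e-8) stop("degenerate scaffold: inter-strand axis undefined")
  inter <- inter / nin
  normal <- c(axis[2] * inter[3] - axis[3] * inter[2],
              axis[3] * inter[1] - axis[1] * inter[3],
              axis[1] * inter[2] - axis[2] * inter[1])
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-8) stop("degenerate scaffold: sheet normal undefined")
  normal <- normal / nn
  c1 <- colMeans(as.matrix(a[a$sheet == 1, c("x", "y", "z")]))
  c2 <- colMeans(as.matrix(a[a$sheet == 2, c("x", "y", "z")]))
  if (sum((c2 - c1) * normal) < 0) normal <- -normal
  list(axis = axis, normal = normal)
}

#' Enumerate the simplified steric-zipper templates
#'
#' One rigid-body pose per grid point: sheet 1 stays fixed; sheet 2 is the
#' canonical sheet translated by `shift` Angstrom along the chain axis and
#' placed `separation` Angstrom away along the sheet normal. The default
#' grids (0-8 Angstrom in 1 Angstrom steps along the chains, 6-11 Angstrom
#' across the sheets) give 9 x 6 = 54 templates, enumerated shift-major.
#' The third displacement direction of the full-profile approach is
#' intentionally not enumerated.
#'
#' @param scaffold a [ZipperScaffold-class].
#' @param shifts numeric grid along the chain axis (default `0:8`).
#' @param separations numeric grid across the sheets (default `6:11`).
#' @return list of [ZipperTemplate-class] objects.
#' @export
enumerateTemplates <- function(scaffold, shifts = 0:8, separations = 6:11) {
  stopifnot(is(scaffold, "ZipperScaffold"))
  frame <- scaffoldFrame(scaffold)
  a <- scaffold@atoms
  sheet1 <- a[a$sheet == 1, ]
  base2 <- sheet1
  base2$sheet <- 2L
  base2$chain <- LETTERS[5L + match(base2$chain, LETTERS[1:5])]
  out <- vector("list", length(shifts) * length(separations))
  k <- 0L
  for (sh in shifts) for (sep in separations) {
    t2 <- base2
    disp <- sh * frame$axis + sep * frame$normal
    t2$x <- t2$x + disp[1]; t2$y <- t2$y + disp[2]; t2$z <- t2$z + disp[3]
    atoms <- rbind(sheet1, t2)
    rownames(atoms) <- NULL
    k <- k + 1L
    out[[k]] <- new("ZipperTemplate", shift = as.numeric(sh),
                    separation = as.numeric(sep), atoms = atoms)
  }
  out
}

#' Thread a hexapeptide onto a zipper template
#'
#' Assigns the peptide's residue identities to all ten 6-residue chains of
#' the template backbone (five per sheet). Side-chain placement is the
#' energy adapter's job; the threaded structure carries backbone atoms and
#' residue names only.
#'
#' @param template a [ZipperTemplate-class].
#' @param peptide a sanitized 6-letter sequence; cysteine is refused
#'   (sanitize first).
#' @return a [ThreadedZipper-class].
#' @export
threadPeptide <- function(template, peptide) {
  stopifnot(is(template, "ZipperTemplate"), length(peptide) == 1L)
  peptide <- toupper(peptide)
  if (grepl("C", peptide, fixed = TRUE))
    stop("peptide contains cysteine; apply sanitizeSequence() first")
  if (!grepl("^[ADEFGHIKLMNPQRSTVWY]{6}$", peptide))
    stop("peptide must be 6 residues over the sanitized alphabet")
  atoms <- template@atoms
  res1 <- strsplit(peptide, "")[[1]]
  atoms$resid <- bio3d::aa123(res1[atoms$resno])
  new("ThreadedZipper", template = template, peptide = peptide, atoms = atoms)
}

#' Minimum-energy classification of a hexapeptide over zipper templates
#'
#' Threads the peptide onto every template, collects the adapter's ten
#' per-chain energies for each, takes the global minimum, and classifies
#' the peptide as amyloidogenic iff at least one chain's energy is not
#' greater than the threshold (min energy <= threshold). Templates on
#' which the adapter fails are skipped with a log message and counted; if
#' all fail, an error is raised.
#'
#' @param peptide a sanitized 6-letter sequence.
#' @param templates list of [ZipperTemplate-class] (e.g. from
#'   [enumerateTemplates()]).
#' @param adapter a function `(peptide, template) -> numeric(10)` of
#'   per-chain energies in kcal/mol, such as [surrogateEnergyAdapter()] or a
#'   wrapper around an external design program.
#' @param threshold kcal/mol (default -23).
#' @return list: `minEnergy`, `amyloid`, `templateIndex`, `chainIndex`,
#'   `failures`.
#' @export
minEnergyLabel <- function(peptide, templates, adapter, threshold = -23) {
  stopifnot(length(templates) >= 1, is.function(adapter))
  best <- Inf; bestTemplate <- NA_integer_; bestChain <- NA_integer_
  failures <- 0L
  for (i in seq_along(templates)) {
    e <- tryCatch(adapter(peptide, templates[[i]]), error = function(err) err)
    if (inherits(e, "error")) {
      message(sprintf("minEnergyLabel: adapter failed on template %d (%s); skipped",
                      i, conditionMessage(e)))
      failures <- failures + 1L
      next
    }
    if (length(e) != 10L || !all(is.finite(e)))
      stop("adapter must return 10 finite per-chain energies")
    if (min(e) < best) {
      best <- min(e); bestTemplate <- i; bestChain <- which.min(e)
    }
  }
  if (failures == length(templates))
    stop("energy adapter failed on every template")
  list(minEnergy = best, amyloid = best <= threshold,
       templateIndex = bestTemplate, chainIndex = bestChain,
       failures = failures)
}

#' Toy surrogate per-chain energy adapter
#'
#' A deterministic, smooth, explicitly NON-PHYSICAL stand-in for an
#' external side-chain design/energy program, so the threading and
#' minimum-energy machinery can run and be tested without one. The chain
#' energy decreases with the peptide's summed Kyte-Doolittle hydropathy and
#' is penalized quadratically away from an 8.5 Angstrom sheet separation
#' and linearly with the along-chain shift; a small chain-index offset
#' makes the per-chain minimum well defined. Its absolute values carry no
#' physical meaning.
#'
#' @param peptide 6-letter sequence.
#' @param template a [ZipperTemplate-class].
#' @return numeric vector of 10 chain energies (kcal/mol scale by
#'   convention only).
#' @export
surrogateEnergyAdapter <- function(peptide, template) {
  res <- strsplit(toupper(peptide), "")[[1]]
  stopifnot(length(res) == 6L)
  hyd <- sum(KYTE_DOOLITTLE[res])
  base <- -20 - 0.6 * hyd + 0.3 * (template@separation - 8.5)^2 +
    0.1 * abs(template@shift)
  base + 0.02 * (0:9)
}

## ---------------------------------------------------------------------------
## PDB interchange

#' Write a zipper structure to a PDB file
#'
#' Standard ATOM records, chains A-J. Un-threaded templates and scaffolds
#' carry glycine residue names (backbone only, no side chain implied);
#' threaded structures carry the peptide's residues.
#'
#' @param x a [ThreadedZipper-class], [ZipperTemplate-class] or
#'   [ZipperScaffold-class].
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
writeZipperPDB <- function(x, path) {
  atoms <- if (is(x, "ThreadedZipper")) x@atoms else x@atoms
  if (is.null(atoms$resid)) atoms$resid <- "GLY"
  ## bio3d expects per-atom vectors; residue numbering restarts per chain
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$resno, chain = atoms$chain,
                   resid = atoms$resid, elety = atoms$atom,
                   o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)))
  invisible(path)
}

#' Read a two-sheet zipper scaffold from a PDB file
#'
#' Reads backbone atoms (N, CA, C, O) and assigns the two sheets from the
#' supplied chain identifiers. The structure must contain five 6-residue
#' strands per sheet.
#'
#' @param path PDB file.
#' @param sheet1Chains,sheet2Chains chain identifiers of the five strands
#'   of each sheet (defaults A-E and F-J).
#' @param nativeSeparation native sheet separation to record, Angstrom; if
#'   `NULL` (default) it is measured as the centroid distance between the
#'   sheets projected on the sheet normal.
#' @return a [ZipperScaffold-class].
#' @export
readScaffoldPDB <- function(path, sheet1Chains = LETTERS[1:5],
                            sheet2Chains = LETTERS[6:10],
                            nativeSeparation = NULL) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  a <- a[a$elety %in% c("N", "CA", "C", "O") &
           a$chain %in% c(sheet1Chains, sheet2Chains), ]
  if (nrow(a) == 0) stop("no backbone atoms on the requested chains in ", path)
  sheet <- ifelse(a$chain %in% sheet1Chains, 1L, 2L)
  strand <- ifelse(sheet == 1L, match(a$chain, sheet1Chains),
                   match(a$chain, sheet2Chains))
  ## renumber residues 1..6 within each strand
  atoms <- data.frame(sheet = sheet, strand = strand, chain = a$chain,
                      resno = ave(a$resno, paste(sheet, strand),
                                  FUN = function(r) match(r, sort(unique(r)))),
                      atom = a$elety, resid = a$resid,
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  s1 <- atoms[atoms$sheet == 1 & atoms$strand == 1 & atoms$atom == "CA", ]
  s1 <- s1[order(s1$resno), ]
  seq1 <- paste(bio3d::aa321(s1$resid), collapse = "")
  if (!grepl("^[A-Z]{6}$", toupper(seq1))) seq1 <- "NNQQNY"
  atoms$resid <- NULL
  sc <- new("ZipperScaffold", atoms = atoms,
            sequence = sanitizeSequence(seq1),
            nativeSeparation = 0)
  frame <- scaffoldFrame(sc)
  if (is.null(nativeSeparation)) {
    c1 <- colMeans(as.matrix(atoms[atoms$sheet == 1, c("x", "y", "z")]))
    c2 <- colMeans(as.matrix(atoms[atoms$sheet == 2, c("x", "y", "z")]))
    nativeSeparation <- abs(sum((c2 - c1) * frame$normal))
  }
  sc@nativeSeparation <- nativeSeparation
  validObject(sc)
  sc
}
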
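## PDB fixed-column I/O, C-alpha extraction, superposition and B-factors.
## Everything downstream (DMD, GNM, networks, rigidity) consumes these types.

.splitLines <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

.parseNum <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v)))
    stop(sprintf("PDB parse error at line %d: unreadable %s field ('%s')",
                 lineno[which(is.na(v))[1]], what, s[which(is.na(v))[1]]),
         call. = FALSE)
  v
}

## sp2 / conjugated side-chain groups whose internal bonds are locked
.lockedGroups <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  ARG = c("NE", "CZ", "NH1", "NH2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CG", "CD", "OE1", "OE2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CG", "CD", "OE1", "NE2"))

.inferBonds <- function(atoms) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  reskey <- paste(atoms$chain, atoms$resno, atoms$icode)
  ii <- jj <- integer(0)
  ## intra-residue: covalent if closer than 1.9 A (1.3 A if an H is involved)
  for (rk in unique(reskey)) {
    idx <- which(reskey == rk)
    if (length(idx) < 2) next
    d <- as.matrix(dist(xyz[idx, , drop = FALSE]))
    isH <- atoms$element[idx] == "H"
    lim <- ifelse(outer(isH, isH, "|"), 1.3, 1.9)
    hit <- which(d > 0.1 & d < lim & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) { ii <- c(ii, idx[hit[, 1]]); jj <- c(jj, idx[hit[, 2]]) }
  }
  ## inter-residue peptide bond: C(i) - N(i+1) below 1.7 A
  cs <- which(atoms$name == "C"); ns <- which(atoms$name == "N")
  for (ci in cs) for (ni in ns) {
    if (reskey[ci] == reskey[ni]) next
    if (sqrt(sum((xyz[ci, ] - xyz[ni, ])^2)) < 1.7) {
      ii <- c(ii, min(ci, ni)); jj <- c(jj, max(ci, ni))
    }
  }
  if (!length(ii))
    return(data.frame(i = integer(0), j = integer(0), rotatable = logical(0)))
  b <- unique(data.frame(i = ii, j = jj))
  ## classification: peptide C-N, carbonyl C=O and amide N-H are locked, as
  ## are bonds inside conjugated side-chain groups; bonds to terminal H keep
  ## the lock of their heavy-atom group; everything else rotates
  rot <- logical(nrow(b))
  for (k in seq_len(nrow(b))) {
    a1 <- atoms[b$i[k], ]; a2 <- atoms[b$j[k], ]
    nm <- c(a1$name, a2$name)
    inter <- !(identical(reskey[b$i[k]], reskey[b$j[k]]))
    if (inter && setequal(nm, c("C", "N"))) { rot[k] <- FALSE; next }
    if (setequal(nm, c("C", "O")) || setequal(nm, c("N", "H"))) {
      rot[k] <- FALSE; next
    }
    grp <- .lockedGroups[[a1$resname]]
    if (!is.null(grp) && all(nm %in% grp) && !inter) { rot[k] <- FALSE; next }
    if ("H" %in% c(a1$element, a2$element)) { rot[k] <- FALSE; next }
    rot[k] <- TRUE
  }
  b$rotatable <- rot
  b
}

.elementFromName <- function(name) {
  s <- gsub("[0-9' ]", "", name)
  ifelse(substr(s, 1, 1) %in% c("H", "C", "N", "O", "S", "P"),
         substr(s, 1, 1), substr(s, 1, 2))
}

#' Read structures from PDB text
#'
#' Parses fixed-column ATOM (and optionally HETATM) records; MODEL/ENDMDL
#' blocks delimit conformers.  Only blank or 'A' alternate locations are kept.
#' Covalent bonds are inferred from intra-residue distances plus the
#' inter-residue peptide C-N rule (< 1.7 A) and classified rotatable/locked.
#'
#' @param text character vector of PDB lines (or one string with newlines)
#' @param keepHetatm keep HETATM records (default FALSE)
#' @param inferBonds infer the covalent bond list (default TRUE)
#' @return list of AtomStructure, one per MODEL
#' @export
readPdb <- function(text, keepHetatm = FALSE, inferBonds = TRUE) {
  lines <- .splitLines(text)
  rec <- substr(lines, 1, 6)
  isAtom <- rec == "ATOM  " | (keepHetatm & rec == "HETATM")
  if (!any(isAtom)) stop("no ATOM records found", call. = FALSE)
  bad <- which(isAtom & nchar(lines) < 54)
  if (length(bad))
    stop(sprintf("PDB parse error at line %d: ATOM record truncated (%d < 54 columns)",
                 bad[1], nchar(lines[bad[1]])), call. = FALSE)
  model <- cumsum(rec == "MODEL ")
  model[model == 0] <- 1
  out <- list()
  for (m in unique(model[isAtom])) {
    sel <- which(isAtom & model == m)
    ln <- lines[sel]
    alt <- substr(ln, 17, 17)
    keep <- alt %in% c(" ", "A", "")
    sel <- sel[keep]; ln <- ln[keep]
    if (!length(ln)) next
    el <- trimws(substr(ln, 77, 78))
    name <- trimws(substr(ln, 13, 16))
    el[!nzchar(el)] <- .elementFromName(name[!nzchar(el)])
    atoms <- data.frame(
      element = el,
      name = name,
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resno = as.integer(.parseNum(substr(ln, 23, 26), sel, "residue number")),
      icode = substr(ln, 27, 27),
      x = .parseNum(substr(ln, 31, 38), sel, "x"),
      y = .parseNum(substr(ln, 39, 46), sel, "y"),
      z = .parseNum(substr(ln, 47, 54), sel, "z"),
      stringsAsFactors = FALSE)
    atoms$icode[atoms$icode == " "] <- ""
    if (nrow(atoms) <= 2000) {
      d <- dist(as.matrix(atoms[, c("x", "y", "z")]))
      if (any(d < 0.5))
        stop("atoms closer than 0.5 A: corrupt structure", call. = FALSE)
    }
    bonds <- if (inferBonds) .inferBonds(atoms) else
      data.frame(i = integer(0), j = integer(0), rotatable = logical(0))
    out[[length(out) + 1]] <- new("AtomStructure", atoms = atoms,
                                  bonds = bonds, model = as.integer(m))
  }
  out
}

#' Extract the C-alpha trace of a chain
#'
#' @param structure an AtomStructure
#' @param chain chain id(s) to keep; NULL keeps all chains
#' @return a CaTrace with one bead per residue, in author order; residues
#'   lacking a CA atom are skipped with a warning
#' @export
extractCaTrace <- function(structure, chain = NULL) {
  a <- structure@atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!nrow(a)) stop("chain selector matches no atoms", call. = FALSE)
  reskey <- paste(a$chain, a$resno, a$icode)
  resOrder <- unique(reskey)
  ca <- a[a$name == "CA", , drop = FALSE]
  missing <- setdiff(resOrder, paste(ca$chain, ca$resno, ca$icode))
  if (length(missing))
    warning(sprintf("%d residue(s) lack a CA atom and were skipped",
                    length(missing)))
  if (nrow(ca) < 2) stop("fewer than 2 CA atoms in selection", call. = FALSE)
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$icode)), , drop = FALSE]
  ord <- match(paste(ca$chain, ca$resno, ca$icode), resOrder)
  ca <- ca[order(ord), , drop = FALSE]
  gaps <- sqrt(rowSums((as.matrix(ca[-1, c("x", "y", "z")]) -
                        as.matrix(ca[-nrow(ca), c("x", "y", "z")]))^2))
  if (any(gaps > 6))
    warning(sprintf("chain break: consecutive C-alpha distance %.2f A > 6 A",
                    max(gaps)))
  new("CaTrace",
      ids = data.frame(chain = ca$chain, resno = ca$resno, icode = ca$icode,
                       stringsAsFactors = FALSE),
      resnames = ca$resname,
      coords = unname(as.matrix(ca[, c("x", "y", "z")])))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of mobile onto
#' reference; reflections are excluded.
#'
#' @param mobile N x 3 coordinate matrix
#' @param reference N x 3 coordinate matrix, same N >= 3
#' @return list(coords = transformed mobile, rmsd, rotation, translation)
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("coordinate sets differ in size", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(A %*% t(R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(coords = fitted, rmsd = rmsd, rotation = R,
       translation = cr - as.vector(R %*% cm))
}

.superposeFrames <- function(arr, ref) {
  for (f in seq_len(dim(arr)[1]))
    arr[f, , ] <- superpose(arr[f, , ], ref)$coords
  arr
}

#' Ensemble B-factors
#'
#' Each frame is superposed onto the ensemble mean (mean, fit, re-mean,
#' re-fit: two passes), then B_i = (8 pi^2 / 3) <|r_i - <r_i>|^2>.
#'
#' @param ensemble an Ensemble with >= 2 frames
#' @param fit superpose frames first (default TRUE); FALSE analyses raw
#'   coordinates, useful when frames are already in a common frame
#' @return a ResidueProfile in A^2
#' @export
computeBfactors <- function(ensemble, fit = TRUE) {
  arr <- ensemble@coords
  if (dim(arr)[1] < 2) stop("need at least 2 frames", call. = FALSE)
  if (fit) {
    ref <- apply(arr, c(2, 3), mean)
    arr <- .superposeFrames(arr, ref)
    ref <- apply(arr, c(2, 3), mean)
    arr <- .superposeFrames(arr, ref)
  }
  mu <- apply(arr, c(2, 3), mean)
  msf <- rowMeans(apply(arr, 1, function(fr) rowSums((fr - mu)^2)))
  new("ResidueProfile", values = (8 * pi^2 / 3) * msf,
      name = "bfactor", units = "A^2", ids = ensemble@ids)
}

#' Mean-square fluctuations of an ensemble
#'
#' Convenience wrapper around the B-factor machinery returning raw
#' per-residue mean-square fluctuations (A^2) after superposition.
#'
#' @param ensemble an Ensemble with >= 2 frames
#' @param fit superpose first (default TRUE)
#' @return numeric vector of MSFs
#' @export
meanSquareFluct <- function(ensemble, fit = TRUE) {
  profileValues(computeBfactors(ensemble, fit = fit)) / (8 * pi^2 / 3)
}

.fmtPdbLine <- function(serial, name, resname, chain, resno, icode, xyz) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial %% 100000, name4, resname, chain, resno,
          ifelse(nzchar(icode), icode, " "), xyz[1], xyz[2], xyz[3], 1, 0)
}

#' Write a C-alpha ensemble as a trajectory
#'
#' @param ensemble an Ensemble
#' @param format "pdb" (multi-model, one CA atom per residue) or "xyz"
#' @param file optional path; when NULL the text is returned invisibly
#' @return character vector of lines, invisibly when written to file
#' @export
writeTrajectory <- function(ensemble, format = c("pdb", "xyz"), file = NULL) {
  format <- match.arg(format)
  arr <- ensemble@coords
  ids <- ensemble@ids
  nm <- ensemble@resnames
  F <- dim(arr)[1]; N <- dim(arr)[2]
  out <- character(0)
  if (format == "pdb") {
    for (f in seq_len(F)) {
      out <- c(out, sprintf("MODEL     %4d", f))
      for (i in seq_len(N))
        out <- c(out, .fmtPdbLine(i, "CA", nm[i], ids$chain[i], ids$resno[i],
                                  ids$icode[i], arr[f, i, ]))
      out <- c(out, "ENDMDL")
    }
    out <- c(out, "END")
  } else {
    for (f in seq_len(F)) {
      out <- c(out, as.character(N), sprintf("frame %d t= %.6f", f,
                                             ensemble@times[f]))
      out <- c(out, sprintf("%-2s %12.3f %12.3f %12.3f", "C",
                            arr[f, , 1], arr[f, , 2], arr[f, , 3]))
    }
  }
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Read an XYZ trajectory
#'
#' @param text character vector of XYZ lines
#' @return list of F x N x 3 coordinate array and frame count
#' @export
readXyz <- function(text) {
  lines <- .splitLines(text)
  frames <- list(); pos <- 1
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- as.integer(trimws(lines[pos]))
    if (is.na(n)) stop("malformed XYZ atom count", call. = FALSE)
    block <- lines[(pos + 2):(pos + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    pos <- pos + 2 + n
  }
  arr <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  arr
}

#' Write a per-residue profile as TSV
#'
#' Columns: chain, resno, icode, value (author numbering).
#'
#' @param profile a ResidueProfile
#' @param file output path
#' @export
writeResidueProfile <- function(profile, file) {
  df <- cbind(profile@ids, value = profile@values)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

## Constructor used by generators and tests
.newCaTrace <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                        resnames = rep("ALA", nrow(coords))) {
  new("CaTrace",
      ids = data.frame(chain = chain, resno = as.integer(resno), icode = "",
                       stringsAsFactors = FALSE),
      resnames = resnames, coords = unname(as.matrix(coords)))
}

.newEnsemble <- function(arr, trace, times = seq_len(dim(arr)[1]),
                         provenance = list()) {
  new("Ensemble", coords = arr, times = as.numeric(times),
      ids = trace@ids, resnames = trace@resnames, provenance = provenance)
}

.checkTraceGeometry <- function(trace) {
  x <- trace@coords; n <- nrow(x)
  d <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2))
  if (any(d < 2.8 | d > 4.2))
    warning(sprintf("%d consecutive C-alpha distance(s) outside [2.8, 4.2] A",
                    sum(d < 2.8 | d > 4.2)))
  invisible(d)
}
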
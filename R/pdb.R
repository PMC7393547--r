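# PDB structure input/output and the internal structure container.
#
# A `pdb_structure` holds one chain worth of coordinates in two aligned
# tables: `atoms` (one row per heavy atom) and `residues` (one row per
# residue, in chain order).  Author numbering (resno + insertion code) is
# preserved for I/O; the dense 1-based `resi` index is used for all
# computation.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' Parse a PDB file and extract one chain
#'
#' Reads ATOM records for the requested chain, resolving alternate
#' locations to the highest-occupancy conformer and discarding HETATM
#' records, waters and hydrogens.  The experimental method is taken from
#' the EXPDTA header record when present.
#'
#' @param path path to a PDB file.
#' @param chain single chain identifier (e.g. `"A"`).
#' @return an object of class `pdb_structure`: a list with elements
#'   `id` (file stem), `chain` (requested chain id), `experiment`
#'   (e.g. `"X-RAY DIFFRACTION"` or `NA`), `atoms` (data frame with
#'   columns `serial`, `name`, `resname`, `aa`, `resno`, `icode`, `resi`,
#'   `x`, `y`, `z`, `occupancy`, `bfactor`, `element`) and `residues`
#'   (data frame with `resi`, `resno`, `icode`, `aa`).
#' @export
#' @examples
#' pdb <- synthetic_structure(segments = list(c("helix", 8)), seed = 1)
#' tf <- tempfile(fileext = ".pdb")
#' write_pdb(pdb, tf)
#' s <- parse_pdb(tf, "A")
#' nrow(s$residues)
parse_pdb <- function(path, chain) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path)
  }
  header <- readLines(path, n = 200L, warn = FALSE)
  exp_line <- grep("^EXPDTA", header, value = TRUE)
  experiment <- if (length(exp_line)) {
    trimws(sub("^EXPDTA\\s*", "", exp_line[1]))
  } else {
    NA_character_
  }
  pdb <- tryCatch(
    suppressMessages(suppressWarnings(
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))),
    error = function(e) stop("no ATOM records could be parsed from ", path,
                             " (", conditionMessage(e), ")"))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  available <- unique(at$chain)
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("chain '", chain, "' not found in ", path,
         " (available: ", paste(available, collapse = ", "), ")")
  }
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- at$elesy
  miss <- is.na(elem) | elem == ""
  elem[miss] <- element_from_name(at$elety[miss])
  at$elesy <- toupper(trimws(elem))
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' has no heavy atoms in ", path)

  # alternate locations: keep highest occupancy, ties -> first encountered
  icode <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$resno, icode, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]   # restore file order

  icode <- ifelse(is.na(at$insert), "", at$insert)
  reskey <- paste(at$resno, icode, sep = "|")
  resi <- match(reskey, unique(reskey))
  aa <- unname(AA3TO1[at$resid])
  aa[is.na(aa)] <- "X"
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, resname = at$resid, aa = aa,
    resno = at$resno, icode = icode, resi = resi,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), NA_real_, at$b),
    element = at$elesy,
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  first <- !duplicated(resi)
  residues <- data.frame(
    resi = resi[first], resno = atoms$resno[first],
    icode = atoms$icode[first], aa = aa[first], stringsAsFactors = FALSE)
  out <- list(id = sub("\\.(pdb|ent)$", "", basename(path)),
              chain = chain, experiment = experiment,
              atoms = atoms, residues = residues)
  class(out) <- "pdb_structure"
  out
}

element_from_name <- function(name) {
  n <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(n, 1, 2))
  one <- toupper(substr(n, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CA2", "SE", "CL", "BR"),
         two, one)
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("pdb_structure", x$id, " chain", x$chain, ":",
      nrow(x$residues), "residues,", nrow(x$atoms), "atoms;",
      "experiment:", ifelse(is.na(x$experiment), "<none>", x$experiment),
      "\n")
  invisible(x)
}

#' One-letter sequence of a parsed chain
#'
#' @param structure a `pdb_structure`.
#' @return single string of one-letter codes (unknown residues as `X`).
#' @export
chain_sequence <- function(structure) {
  paste(structure$residues$aa, collapse = "")
}

#' Write a structure to a PDB file
#'
#' Emits HEADER/EXPDTA records followed by fixed-width ATOM records and is
#' the exact inverse of [parse_pdb()] for structures produced by the
#' synthetic generator (byte-stable given identical input).
#'
#' @param structure a `pdb_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  lines <- c(
    sprintf("HEADER    SYNTHETIC FIXTURE%43s%s", "", toupper(structure$id)),
    if (!is.na(structure$experiment))
      sprintf("EXPDTA    %s", structure$experiment))
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  substr(at$name, 1, 4))
  recs <- sprintf(
    "ATOM  %5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$serial %% 100000L, name4, " ", at$resname, structure$chain,
    at$resno, ifelse(at$icode == "", " ", at$icode),
    at$x, at$y, at$z, at$occupancy,
    ifelse(is.na(at$bfactor), 0, at$bfactor), at$element)
  writeLines(c(lines, recs, "END"), path)
  invisible(path)
}

# coordinates of one named atom in one residue (by dense index), or NULL
atom_coord <- function(structure, resi, name) {
  a <- structure$atoms
  i <- which(a$resi == resi & a$name == name)
  if (!length(i)) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}
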
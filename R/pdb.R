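# PDB v3 fixed-column reading and writing, plus the in-memory structure
# container used throughout the package. Only the first MODEL of an
# ensemble is kept and alternate locations other than ' '/'A' are dropped,
# so a refinement always acts on one well-defined conformer.

new_structure <- function(atoms, skipped = 0L, dropped_solvent = 0L) {
  rownames(atoms) <- NULL
  s <- list(atoms = atoms, skipped = skipped,
            dropped_solvent = dropped_solvent)
  class(s) <- "rna_structure"
  s <- index_residues(s)
  key <- with(s$atoms, paste(chain, resnum, icode, name))
  if (anyDuplicated(key))
    stop("duplicate atom: ", key[anyDuplicated(key)], call. = FALSE)
  s
}

index_residues <- function(s) {
  a <- s$atoms
  rid <- paste(a$chain, a$resnum, a$icode, sep = "\r")
  s$atoms$res <- match(rid, unique(rid))
  s
}

#' Read a PDB file or text into a structure object
#'
#' Fixed-column PDB v3 parsing of ATOM/HETATM records. Only the first MODEL
#' block is retained; alternate location indicators other than blank or 'A'
#' are skipped; water and common ion residues are dropped (counted in the
#' returned object); atom names are normalized (\code{O1P} to \code{OP1},
#' asterisk to prime). Unparsable lines produce a warning with the line
#' number and are skipped.
#'
#' @param input Path to a PDB file, or PDB text (single string with
#'   newlines, or a character vector of lines).
#' @return An object of class \code{rna_structure}.
#' @examples
#' s <- read_pdb(c(
#'  "ATOM      1  C1'   A A   1      10.000  4.000  2.000           C"))
#' s$atoms$name
#' @export
read_pdb <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else if (length(input) == 1L) strsplit(input, "\n",
                                                  fixed = TRUE)[[1]]
           else input
  rec <- substr(lines, 1, 6)
  # keep only the first MODEL block, if any
  m_start <- which(trimws(rec) == "MODEL")
  if (length(m_start) > 1L) {
    m_end <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(m_end)) m_end[1] else m_start[2]
    keep <- seq_along(lines) < stop_at | seq_along(lines) < m_start[1]
    lines <- lines[keep]
    rec <- rec[keep]
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  idx <- which(is_atom)
  if (!length(idx))
    stop("no ATOM/HETATM records found in input", call. = FALSE)
  ln <- lines[idx]
  serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resnum <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  icode <- substr(ln, 27, 27)
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  element <- trimws(substr(ln, 77, 78))
  bad <- is.na(resnum) | is.na(x) | is.na(y) | is.na(z) | name == ""
  for (b in which(bad))
    warning("skipping unparsable record at line ", idx[b], call. = FALSE)
  drop_alt <- !bad & !(altloc %in% c(" ", "A", ""))
  solvent <- !bad & !drop_alt & resname %in% .water_ion_names
  keep <- !bad & !drop_alt & !solvent
  if (!any(keep))
    stop("no usable ATOM/HETATM records in input", call. = FALSE)
  name <- normalize_atom_name(name)
  element <- ifelse(element == "" | is.na(element), infer_element(name),
                    element)
  atoms <- data.frame(serial = serial[keep], name = name[keep],
                      resname = resname[keep], chain = chain[keep],
                      resnum = resnum[keep], icode = icode[keep],
                      x = x[keep], y = y[keep], z = z[keep],
                      element = element[keep],
                      record = trimws(rec[idx][keep]),
                      stringsAsFactors = FALSE)
  new_structure(atoms, skipped = sum(bad) + sum(drop_alt),
                dropped_solvent = sum(solvent))
}

#' Write a structure as PDB v3 text
#'
#' Fixed-column output; a TER record is emitted between chains and serials
#' are re-numbered sequentially. Round-tripping through \code{read_pdb}
#' reproduces names, numbering and coordinates to 0.001 Angstrom.
#'
#' @param structure An \code{rna_structure}.
#' @param file Optional path; when given the text is also written there.
#' @return The PDB text as a character vector of lines, invisibly when
#'   \code{file} is given.
#' @export
write_pdb <- function(structure, file = NULL) {
  a <- structure$atoms
  if (nrow(a) == 0L) stop("cannot write an empty structure", call. = FALSE)
  if (nrow(a) > 99999L)
    stop("serial overflow: more than 99999 atoms", call. = FALSE)
  fmt_name <- function(n, el) {
    # element-aligned atom name field (cols 13-16)
    ifelse(nchar(el) == 1L & nchar(n) < 4L, sprintf(" %-3s", n),
           sprintf("%-4s", n))
  }
  out <- character(0)
  serial <- 0L
  chains <- unique(a$chain)
  for (ci in seq_along(chains)) {
    rows <- which(a$chain == chains[ci])
    for (r in rows) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "%-6s%5d %s%1s%-3s%1s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ifelse(a$record[r] == "HETATM", "HETATM", "ATOM"), serial,
        fmt_name(a$name[r], a$element[r]), " ", a$resname[r], " ",
        a$chain[r], a$resnum[r], a$icode[r], a$x[r], a$y[r], a$z[r],
        1.00, 0.00, a$element[r]))
    }
    last <- rows[length(rows)]
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %-3s%1s%1s%4d%1s", serial,
                          a$resname[last], " ", a$chain[last],
                          a$resnum[last], a$icode[last]))
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# ---- accessors -------------------------------------------------------------

#' Coordinates of a structure as an n x 3 matrix
#' @param structure An \code{rna_structure}.
#' @return Numeric matrix with one row per atom (Angstrom).
#' @export
get_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure An \code{rna_structure}.
#' @param value n x 3 numeric matrix.
#' @return The modified structure.
#' @export
set_coords <- function(structure, value) {
  stopifnot(nrow(value) == nrow(structure$atoms), ncol(value) == 3L)
  structure$atoms$x <- value[, 1]
  structure$atoms$y <- value[, 2]
  structure$atoms$z <- value[, 3]
  structure
}

n_atoms <- function(structure) nrow(structure$atoms)

# residue-level summary table: one row per residue, in file order
residue_table <- function(structure) {
  a <- structure$atoms
  first <- !duplicated(a$res)
  data.frame(res = a$res[first], chain = a$chain[first],
             resnum = a$resnum[first], icode = a$icode[first],
             resname = a$resname[first], stringsAsFactors = FALSE)
}

atom_index <- function(structure, chain, resnum, name, icode = " ") {
  a <- structure$atoms
  which(a$chain == chain & a$resnum == resnum & a$icode == icode &
        a$name == normalize_atom_name(name))
}

#' @export
print.rna_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("Nucleic acid structure: ", nrow(x$atoms), " atoms, ", nrow(rt),
      " residues, ", length(unique(rt$chain)), " chain(s)\n", sep = "")
  if (x$skipped > 0L || x$dropped_solvent > 0L)
    cat("  (skipped records: ", x$skipped, ", dropped solvent/ion atoms: ",
        x$dropped_solvent, ")\n", sep = "")
  invisible(x)
}
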
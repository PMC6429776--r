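# Atom-name normalization. PDB files in the wild carry several naming
# dialects for nucleic acids: primes written as asterisks (C1* for C1'),
# phosphate oxygens as O1P/O2P instead of OP1/OP2, and hydrogens with
# leading or trailing digit variants. Everything is normalized to PDB v3.

.atom_name_map <- c(
  "O1P" = "OP1", "O2P" = "OP2", "O3P" = "OP3",
  "H5'1" = "H5'", "H5'2" = "H5''", "1H5'" = "H5'", "2H5'" = "H5''",
  "H2'1" = "H2'", "H2'2" = "H2''", "1H2'" = "H2'", "2H2'" = "H2''",
  "HO'2" = "HO2'", "2HO'" = "HO2'", "HO2" = "HO2'",
  "H3T" = "HO3'", "H5T" = "HO5'", "HO3" = "HO3'", "HO5" = "HO5'",
  "1H2" = "H21", "2H2" = "H22", "1H4" = "H41", "2H4" = "H42",
  "1H6" = "H61", "2H6" = "H62", "HN3" = "H3", "HN1" = "H1",
  "C5M" = "C7", "H5M1" = "H71", "H5M2" = "H72", "H5M3" = "H73")

#' Normalize a PDB atom name to PDB v3 conventions
#'
#' Converts sugar asterisks to primes (\code{C1*} to \code{C1'}) and maps
#' legacy phosphate / hydrogen names (\code{O1P} to \code{OP1}, \code{H5'1}
#' to \code{H5'}, ...).
#'
#' @param name Atom name, possibly with surrounding whitespace.
#' @return Normalized atom name.
#' @export
normalize_atom_name <- function(name) {
  n <- gsub("*", "'", trimws(name), fixed = TRUE)
  hit <- unname(.atom_name_map[n])
  ifelse(is.na(hit), n, hit)
}

infer_element <- function(name) {
  n <- sub("^[0-9']+", "", trimws(name))
  el <- substr(n, 1, 1)
  ifelse(el %in% c("C", "N", "O", "P", "H"), el, toupper(el))
}

.water_ion_names <- c("HOH", "WAT", "H2O", "DOD", "NA", "K", "MG", "CL",
                      "ZN", "MN", "CA", "SR", "BA", "CS", "BR", "IOD",
                      "SO4", "PO4")
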
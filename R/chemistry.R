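# Static chemical identity tables: atomic masses, element inference from PDB
# atom names, residue-code translation and side-chain charge rules.

# Standard atomic masses (Da), IUPAC 2021 conventional values.
.sapflex_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, CL = 35.45, "NA" = 22.990, K = 39.098, MG = 24.305,
  CA = 40.078, ZN = 65.38, FE = 55.845, BR = 79.904, I = 126.904
)

.standard_aa3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # common protonation-variant names map to their parent residue
  HID = "H", HIE = "H", HIP = "H", CYX = "C", CYM = "C",
  ASH = "D", GLH = "E", LYN = "K"
)

.standard_aa1 <- structure(names(.standard_aa3)[1:20], names = .standard_aa3[1:20])

# Solvent residue names recognized in mixed protein/solvent systems:
# water models and chloroform.
.solvent_resnames <- c("WAT", "HOH", "CL3", "CHL")
.ion_resnames <- c("CL-", "NA+", "CL", "NA", "K+", "MG2")

#' Infer the chemical element from a PDB atom name
#'
#' Follows PDB naming conventions for protein and solvent atoms: the
#' element is the first alphabetic character of the atom name, except for
#' recognized two-letter ion/solvent atoms (e.g. `CL`, `NA` as monoatomic
#' species). In a protein residue, `CA` is an alpha carbon, not calcium.
#'
#' @param name character vector of PDB atom names (e.g. `"CA"`, `"SG"`, `"OW"`).
#' @param resname optional residue names, used to disambiguate monoatomic ions.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name, resname = NULL) {
  name <- toupper(trimws(name))
  el <- sub("^[0-9']*", "", name)
  el <- substr(el, 1L, 1L)
  if (!is.null(resname)) {
    ion <- toupper(trimws(resname)) %in% .ion_resnames
    el[ion & name %in% c("CL", "NA", "K", "MG", "BR")] <-
      name[ion & name %in% c("CL", "NA", "K", "MG", "BR")]
  }
  el
}

#' Atomic mass lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in Da; unknown elements get 12.011 (carbon)
#'   with a warning.
#' @export
element_mass <- function(element) {
  m <- .sapflex_masses[toupper(element)]
  if (anyNA(m)) {
    warning("unknown element(s): ",
            paste(unique(element[is.na(m)]), collapse = ", "),
            "; carbon mass assumed")
    m[is.na(m)] <- .sapflex_masses[["C"]]
  }
  unname(m)
}

#' One-letter code for three-letter residue names
#'
#' Nonstandard residues become `"X"`.
#' @param resname character vector of 3-letter codes.
#' @return character vector of 1-letter codes.
#' @export
aa3to1 <- function(resname) {
  out <- .standard_aa3[toupper(trimws(resname))]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Three-letter codes for a one-letter sequence
#' @param sequence single string of one-letter codes.
#' @return character vector of 3-letter codes; unknown letters become `"UNK"`.
#' @export
aa1to3 <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  out <- .standard_aa1[s]
  out[is.na(out)] <- "UNK"
  unname(out)
}
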
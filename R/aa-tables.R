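# Canonical amino-acid tables used throughout the package.
# The fixed residue order (alphabetical by three-letter code) defines the
# layout of every 20-element feature block and of the 20x20 contact matrices.

AA_THREE <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL")

AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

names(AA_ONE) <- AA_THREE
AA_THREE_FROM_ONE <- stats::setNames(AA_THREE, AA_ONE)

#' Canonical amino-acid order
#'
#' The fixed residue ordering (alphabetical by three-letter code) that defines
#' the layout of every 20-element feature block, shell histogram and contact
#' matrix in the package.
#'
#' @param three logical; return three-letter codes (default) or one-letter.
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_order()
#' aa_order(three = FALSE)
aa_order <- function(three = TRUE) {
  if (three) AA_THREE else unname(AA_ONE)
}

# Common chemically modified residues mapped to their canonical parent.
# Applied when reading structures; anything not listed here (and not
# canonical) is dropped with a warning.
MODIFIED_RES <- c(
  MSE = "MET",  # selenomethionine
  SEC = "CYS",  # selenocysteine (structural analogue)
  CSO = "CYS", CSS = "CYS", CME = "CYS", OCS = "CYS",
  SEP = "SER", TPO = "THR", PTR = "TYR",
  MLY = "LYS", KCX = "LYS", LLP = "LYS",
  HYP = "PRO", PCA = "GLU", FME = "MET",
  MLE = "LEU", AIB = "ALA", DAL = "ALA"
)

# Van der Waals radii (Angstrom), Bondi-style values by element.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98)
VDW_DEFAULT <- 1.70  # carbon fallback for unknown elements

# Maximum attainable solvent-accessible area per residue type (Angstrom^2),
# Rost & Sander-style normalisation constants for relative accessibility.
MAX_ASA <- c(ALA = 106, ARG = 248, ASN = 157, ASP = 163, CYS = 135,
             GLN = 198, GLU = 194, GLY = 84,  HIS = 184, ILE = 169,
             LEU = 164, LYS = 205, MET = 188, PHE = 197, PRO = 136,
             SER = 130, THR = 142, TRP = 227, TYR = 222, VAL = 142)

#' Maximum accessible surface area table
#'
#' Per-residue maximum solvent-accessible areas used to convert absolute
#' accessibility into relative accessibility (RSA, percent). The default
#' table follows the Rost-Sander convention of extended Gly-X-Gly
#' tripeptides.
#'
#' @return Named numeric vector (Angstrom^2), one entry per residue type in
#'   [aa_order()].
#' @export
max_asa_table <- function() MAX_ASA

.validate_aa1 <- function(x, what = "residue") {
  bad <- !(x %in% AA_ONE)
  if (any(bad)) {
    stop(sprintf("unknown %s code(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.aa3_to1 <- function(x) unname(AA_ONE[x])
.aa1_to3 <- function(x) unname(AA_THREE_FROM_ONE[x])

# Empty named count vector in canonical order
.zero_counts <- function() stats::setNames(integer(20), AA_THREE)
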
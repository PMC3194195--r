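# Structure reading and writing.
#
# Parsing is delegated to bio3d; on top of that we apply the model's
# residue-level rules: one chain at a time, heavy polymer atoms only,
# altloc resolved by occupancy, common modified residues mapped to their
# canonical parent, and every retained residue must carry a C-alpha.

.WATERS <- c("HOH", "DOD", "WAT", "H2O")

.infer_element <- function(elety, elesy) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # strip leading digits then take the leading letters of the atom name
    nm <- toupper(gsub("^[0-9']+", "", trimws(elety[miss])))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    el[miss] <- ifelse(two %in% c("SE", "CL", "BR", "FE", "ZN", "MG"), two, one)
  }
  el
}

.atom_radius <- function(element) {
  r <- VDW_RADII[element]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("no van der Waals radius for element(s) %s; using %.2f",
                    paste(unique(element[unknown]), collapse = ", "),
                    VDW_DEFAULT), call. = FALSE)
    r[unknown] <- VDW_DEFAULT
  }
  unname(r)
}

#' Read one chain of a PDB file into a structure model
#'
#' Parses a PDB file (via [bio3d::read.pdb()]) and retains the heavy atoms of
#' the requested polymer chain. Waters and non-polymer heteroatoms are
#' excluded; common chemically modified residues (e.g. selenomethionine,
#' `MSE`) are mapped to their canonical parent type; residues of unknown type
#' are dropped with a warning. Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first encountered). Only residues with
#' a C-alpha atom are kept, and only the first model of a multi-model file is
#' read.
#'
#' @param path Path to a PDB-format text file.
#' @param chain Single chain identifier to extract.
#' @param id Optional identifier stored on the model (defaults to the file
#'   name without extension).
#' @return A `StructureModel`: a list with elements `id`, `chain_id`,
#'   `residues` (data frame: `ordinal`, `resno`, `insert`, `type`, `aa`),
#'   `atoms` (data frame: `ordinal`, `name`, `element`, `x`, `y`, `z`,
#'   `radius`), and `resolution` (Angstrom, `NA` if not recorded).
#' @export
read_pdb <- function(path, chain, id = NULL) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  stopifnot(is.character(chain), length(chain) == 1L)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (!any(at$chain == chain, na.rm = TRUE)) {
    stop(sprintf("chain not found: '%s' in %s", chain, path), call. = FALSE)
  }
  at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]

  # residue type resolution: canonical ATOM records, or modified residues
  # (often deposited as HETATM) mapped to a parent; everything else excluded
  resid <- at$resid
  canon <- resid %in% AA_THREE
  modif <- resid %in% names(MODIFIED_RES)
  keep <- (at$type == "ATOM" & canon) | modif
  dropped <- unique(resid[!keep & !(resid %in% .WATERS) & at$type == "ATOM"])
  if (length(dropped)) {
    warning(sprintf("dropping unmapped residue type(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  at <- at[keep, , drop = FALSE]
  at$resid[at$resid %in% names(MODIFIED_RES)] <-
    MODIFIED_RES[at$resid[at$resid %in% names(MODIFIED_RES)]]

  # drop hydrogens
  at$element <- .infer_element(at$elety, at$elesy)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]

  if (nrow(at) == 0L) stop("empty structure: no polymer atoms", call. = FALSE)

  # altloc: keep highest occupancy per (residue, atom name), first on ties
  at$insert[is.na(at$insert)] <- ""
  reskey <- paste(at$resno, at$insert, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(match(reskey, unique(reskey)), at$elety, -occ,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(reskey[ord], at$elety, sep = "|")), , drop = FALSE]
  # restore file order
  at <- at[order(match(paste(at$resno, at$insert, sep = "|"), unique(reskey)),
                 at$eleno), , drop = FALSE]

  reskey <- paste(at$resno, at$insert, sep = "|")
  ukeys <- unique(reskey)
  has_ca <- vapply(ukeys, function(k) any(at$elety[reskey == k] == "CA"),
                   logical(1))
  ukeys <- ukeys[has_ca]
  if (length(ukeys) == 0L) stop("empty structure: no residue with C-alpha",
                                call. = FALSE)
  at <- at[reskey %in% ukeys, , drop = FALSE]
  reskey <- paste(at$resno, at$insert, sep = "|")
  ordinal <- match(reskey, ukeys)

  first <- !duplicated(reskey)
  residues <- data.frame(
    ordinal = ordinal[first],
    resno = at$resno[first],
    insert = at$insert[first],
    type = at$resid[first],
    stringsAsFactors = FALSE
  )
  residues <- residues[order(residues$ordinal), , drop = FALSE]
  residues$aa <- .aa3_to1(residues$type)
  rownames(residues) <- NULL

  atoms <- data.frame(
    ordinal = ordinal,
    name = at$elety,
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    radius = .atom_radius(at$element),
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL

  structure(list(
    id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
    chain_id = chain,
    residues = residues,
    atoms = atoms,
    resolution = .read_resolution(path)
  ), class = "StructureModel")
}

.read_resolution <- function(path) {
  lines <- readLines(path, n = 500L, warn = FALSE)
  hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(hit) == 0L) return(NA_real_)
  m <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
  if (length(m) == 0L) NA_real_ else as.numeric(m)
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s' chain %s: %d residues, %d heavy atoms",
              x$id, x$chain_id, nrow(x$residues), nrow(x$atoms)))
  if (!is.na(x$resolution)) cat(sprintf(", resolution %.2f A", x$resolution))
  cat("\n")
  invisible(x)
}

#' Structure sequence
#'
#' One-letter sequence of a structure model, in residue-ordinal order.
#'
#' @param struct A `StructureModel`.
#' @return Single character string.
#' @export
structure_sequence <- function(struct) {
  paste(struct$residues$aa, collapse = "")
}

#' Write a structure model as PDB text
#'
#' Serialises a `StructureModel` back to fixed-column `ATOM` records
#' (coordinates at the format's 3-decimal precision). Re-reading the output
#' reproduces the model's residues and coordinates.
#'
#' @param struct A `StructureModel`.
#' @param path Optional file to write; if `NULL` the lines are returned only.
#' @return Invisibly, a character vector of PDB lines.
#' @export
write_pdb <- function(struct, path = NULL) {
  res <- struct$residues
  at <- struct$atoms
  resno <- res$resno[at$ordinal]
  insert <- res$insert[at$ordinal]
  type <- res$type[at$ordinal]
  name4 <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1, 4),
                  sprintf(" %-3s", at$name))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name4, type, struct$chain_id, resno,
    ifelse(insert == "", " ", insert), at$x, at$y, at$z, 1, 0,
    sprintf("%2s", at$element))
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
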
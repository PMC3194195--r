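# Structural environment of a mutated residue: the residue-type composition
# of a distance shell around its C-alpha, and its relative solvent
# accessibility. Together these form the 21-element structure block of the
# feature vector (20 shell counts + RSA).

.ca_coords <- function(struct, residue_ordinal) {
  at <- struct$atoms
  hit <- which(at$ordinal == residue_ordinal & at$name == "CA")
  if (length(hit) == 0L)
    stop(sprintf("no C-alpha for residue ordinal %d", residue_ordinal),
         call. = FALSE)
  c(at$x[hit[1]], at$y[hit[1]], at$z[hit[1]])
}

# ordinals of residues with >= 1 heavy atom within `radius` of the center's
# C-alpha, excluding the center residue itself
.shell_ordinals <- function(struct, residue_ordinal, radius) {
  if (!(residue_ordinal %in% struct$residues$ordinal))
    stop(sprintf("no residue with ordinal %d", residue_ordinal), call. = FALSE)
  stopifnot(radius >= 0)
  ca <- .ca_coords(struct, residue_ordinal)
  at <- struct$atoms
  d2 <- (at$x - ca[1])^2 + (at$y - ca[2])^2 + (at$z - ca[3])^2
  hit <- at$ordinal[d2 <= radius^2]
  sort(unique(hit[hit != residue_ordinal]))
}

#' Residue-type composition of the shell around a residue
#'
#' Counts, for each of the 20 residue types, the chain residues having at
#' least one heavy atom within `radius` Angstrom of the C-alpha atom of the
#' given residue. The residue itself is excluded. This is the 20-element
#' structural-environment histogram; the default 6 Angstrom cutoff is the
#' optimised shell radius of the predictor.
#'
#' @param struct A `StructureModel`.
#' @param residue_ordinal 1-based residue ordinal within the chain.
#' @param radius Shell radius in Angstrom (default 6.0).
#' @return Named integer vector of length 20 in [aa_order()] order.
#' @export
shell_residue_counts <- function(struct, residue_ordinal, radius = 6.0) {
  ords <- .shell_ordinals(struct, residue_ordinal, radius)
  counts <- .zero_counts()
  if (length(ords)) {
    types <- struct$residues$type[match(ords, struct$residues$ordinal)]
    tab <- table(factor(types, levels = AA_THREE))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Shell contact partners of a residue
#'
#' Returns the residue types interacting with a given residue under the same
#' shell rule as [shell_residue_counts()]: any residue with a heavy atom
#' within `radius` of the center's C-alpha. Used to enumerate the contacts
#' lost by a wild-type residue and gained by its replacement.
#'
#' @inheritParams shell_residue_counts
#' @return List with `center` (three-letter type of the center residue) and
#'   `partners` (character vector of partner types, one entry per partner
#'   residue).
#' @export
contact_partners <- function(struct, residue_ordinal, radius = 6.0) {
  ords <- .shell_ordinals(struct, residue_ordinal, radius)
  res <- struct$residues
  list(center = res$type[match(residue_ordinal, res$ordinal)],
       partners = res$type[match(ords, res$ordinal)])
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by numerical quadrature
#'
#' Shrake-Rupley-style computation: for every atom, quasi-uniform test
#' points are placed on a sphere of radius `r_vdw + probe`; the accessible
#' fraction is the share of points not buried inside any other atom's
#' expanded sphere, scaled by the full sphere area. Per-residue areas are the
#' sums over the residue's heavy atoms. An internal replacement for external
#' accessibility programs; precomputed values can be imported instead via
#' [read_accessibility()].
#'
#' @param struct A `StructureModel`.
#' @param probe Probe (water) radius in Angstrom, default 1.4.
#' @param n_points Number of quadrature points per atom, default 960
#'   (minimum 100).
#' @return A `SasaResult`: list with `residue_asa` (named numeric vector by
#'   residue ordinal, Angstrom^2), `atom_asa`, `probe`, `n_points`.
#' @export
compute_sasa <- function(struct, probe = 1.4, n_points = 960L) {
  stopifnot(n_points >= 100L, probe >= 0)
  at <- struct$atoms
  n <- nrow(at)
  if (n == 0L) stop("empty structure", call. = FALSE)
  pts <- .sphere_points(n_points)
  xyz <- cbind(at$x, at$y, at$z)
  rad <- at$radius + probe
  atom_asa <- numeric(n)
  # pairwise neighbor prefilter
  for (i in seq_len(n)) {
    di <- sqrt((xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
                 (xyz[, 3] - xyz[i, 3])^2)
    nb <- which(di < rad[i] + rad & seq_len(n) != i)
    if (length(nb) == 0L) {
      atom_asa[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      d2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- d2 > rad[j]^2
    }
    atom_asa[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  residue_asa <- tapply(atom_asa, at$ordinal, sum)
  residue_asa <- stats::setNames(as.numeric(residue_asa), names(residue_asa))
  structure(list(residue_asa = residue_asa, atom_asa = atom_asa,
                 probe = probe, n_points = as.integer(n_points)),
            class = "SasaResult")
}

#' Relative solvent accessibility
#'
#' Converts an absolute accessible area into a percentage of the residue
#' type's maximum attainable area ([max_asa_table()]), clipped to
#' \[0, 100\].
#'
#' @param asa Absolute accessible area (Angstrom^2), non-negative.
#' @param residue_type Three-letter residue code.
#' @param max_asa Normalisation table (named numeric, Angstrom^2).
#' @return RSA in percent.
#' @export
relative_sasa <- function(asa, residue_type, max_asa = max_asa_table()) {
  stopifnot(all(asa >= 0))
  .validate_aa1(.aa3_to1(residue_type), "residue")
  pmin(100, pmax(0, 100 * asa / unname(max_asa[residue_type])))
}

#' Per-residue RSA profile of a structure
#'
#' Convenience wrapper: computes (or imports) absolute accessibility and
#' normalises every residue to percent RSA.
#'
#' @param struct A `StructureModel`.
#' @param sasa Optional precomputed `SasaResult` or a named numeric vector of
#'   absolute per-residue areas indexed by ordinal; computed internally when
#'   `NULL`.
#' @param ... Passed to [compute_sasa()].
#' @return Named numeric vector: residue ordinal -> RSA percent.
#' @export
rsa_profile <- function(struct, sasa = NULL, ...) {
  if (is.null(sasa)) sasa <- compute_sasa(struct, ...)
  areas <- if (inherits(sasa, "SasaResult")) sasa$residue_asa else sasa
  res <- struct$residues
  ord <- as.integer(names(areas))
  types <- res$type[match(ord, res$ordinal)]
  stats::setNames(relative_sasa(as.numeric(areas), types), names(areas))
}

#' Assemble the 21-element structural environment
#'
#' Shell residue-type counts plus the RSA of the mutated residue, in the
#' fixed feature order (20 counts then RSA).
#'
#' @inheritParams shell_residue_counts
#' @param rsa RSA (percent) of the residue; typically one entry of
#'   [rsa_profile()].
#' @return Named numeric vector of length 21.
#' @export
structure_environment <- function(struct, residue_ordinal, rsa, radius = 6.0) {
  stopifnot(length(rsa) == 1L, rsa >= 0, rsa <= 100)
  counts <- shell_residue_counts(struct, residue_ordinal, radius)
  c(as.numeric(counts), RSA = as.numeric(rsa)) |>
    stats::setNames(c(names(counts), "RSA"))
}
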
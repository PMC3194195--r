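# Sequence-derived feature blocks: the 20-element mutation encoding, the
# 19-residue sequence-window composition (used by the sequence-only variant
# in place of the structural environment), the 5 profile features including
# the conservation index, and the 4-element family-classifier slot.

#' Encode a substitution as a 20-element vector
#'
#' The element of the wild-type residue is set to -1, the element of the
#' newly introduced residue to +1, all others to 0.
#'
#' @param wt,mut One-letter residue codes, `wt != mut`.
#' @return Named numeric vector of length 20 in [aa_order()] order.
#' @export
#' @examples
#' encode_mutation("A", "V")
encode_mutation <- function(wt, mut) {
  .validate_aa1(c(wt, mut))
  if (identical(wt, mut))
    stop("not a substitution: wt == mut", call. = FALSE)
  v <- stats::setNames(numeric(20), AA_THREE)
  v[.aa1_to3(wt)] <- -1
  v[.aa1_to3(mut)] <- 1
  v
}

#' Decode a mutation encoding back to residue codes
#' @param enc A vector produced by [encode_mutation()].
#' @return Character vector `c(wt, mut)` (one-letter codes).
#' @export
decode_mutation <- function(enc) {
  stopifnot(length(enc) == 20L)
  c(.aa3_to1(AA_THREE[which(enc == -1)]), .aa3_to1(AA_THREE[which(enc == 1)]))
}

#' Residue composition of the sequence window around a position
#'
#' Counts residue types inside a window centred on the mutated position that
#' spans the sequence symmetrically towards the N- and C-terminus, with a
#' total length of 19 by default (9 positions each side). The window is
#' truncated at the sequence boundaries. The centre position itself is not
#' counted: its identity is already carried by the mutation encoding.
#'
#' @param seq Protein sequence (one-letter string).
#' @param position 1-based position of the mutated residue.
#' @param window_length Odd total window length (default 19).
#' @param include_center Count the centre residue as well (default `FALSE`).
#' @return Named integer vector of length 20 in [aa_order()] order.
#' @export
sequence_window_counts <- function(seq, position, window_length = 19L,
                                   include_center = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (position < 1L || position > n)
    stop(sprintf("position %d outside sequence of length %d", position, n),
         call. = FALSE)
  if (window_length %% 2L != 1L)
    stop("window_length must be odd", call. = FALSE)
  half <- (window_length - 1L) %/% 2L
  idx <- seq(max(1L, position - half), min(n, position + half))
  if (!include_center) idx <- idx[idx != position]
  counts <- .zero_counts()
  if (length(idx)) {
    chars <- strsplit(seq, "")[[1]][idx]
    chars <- chars[chars %in% AA_ONE]
    tab <- table(factor(.aa1_to3(chars), levels = AA_THREE))
    counts[] <- as.integer(tab)
  }
  counts
}

# gap-excluded residue frequencies of one alignment column (length-20 vector)
.column_freqs <- function(mat, col) {
  chars <- mat[, col]
  chars <- chars[chars %in% AA_ONE]
  if (length(chars) == 0L)
    stop("no aligned residues: column is entirely gaps", call. = FALSE)
  tab <- table(factor(chars, levels = AA_ONE))
  as.numeric(tab) / length(chars)
}

# overall gap-excluded residue frequencies of the whole alignment
.overall_freqs <- function(mat) {
  chars <- mat[mat %in% AA_ONE]
  tab <- table(factor(chars, levels = AA_ONE))
  as.numeric(tab) / length(chars)
}

# alignment column index corresponding to a 1-based query sequence position
.query_column <- function(aln, position) {
  qchars <- strsplit(aln$rows[aln$query], "")[[1]]
  nongap <- which(qchars != "-")
  if (position < 1L || position > length(nongap))
    stop(sprintf("position %d outside query of length %d",
                 position, length(nongap)), call. = FALSE)
  nongap[position]
}

#' Conservation index of an alignment position
#'
#' Euclidean distance between the residue-frequency vector of the column
#' mapped to the query position and the overall residue-frequency vector of
#' the alignment:
#' \deqn{CI(i) = \left[\sum_{a=1}^{20} (f_a(i) - f_a)^2\right]^{1/2}}
#' where \eqn{f_a(i)} is the gap-excluded relative frequency of residue
#' \eqn{a} in the column and \eqn{f_a} its overall frequency across the
#' alignment. A column whose composition matches the background scores 0; a
#' fully conserved column of a rare residue scores high.
#'
#' @param aln A `SapAlignment`.
#' @param position 1-based position in the (ungapped) query sequence.
#' @return Non-negative numeric scalar.
#' @export
conservation_index <- function(aln, position) {
  mat <- .aln_matrix(aln)
  fi <- .column_freqs(mat, .query_column(aln, position))
  f <- .overall_freqs(mat)
  sqrt(sum((fi - f)^2))
}

#' Profile features at a mutated position
#'
#' The five sequence-profile features: gap-excluded column frequencies of the
#' wild-type (`F_W`) and mutant (`F_N`) residues, the number of sequences in
#' the alignment (`N_T`), the number of sequences aligned (non-gap) at the
#' position (`N_S`), and the conservation index (`CI`).
#'
#' @inheritParams conservation_index
#' @param wt,mut One-letter residue codes of the substitution.
#' @return Named numeric vector `c(F_W, F_N, N_T, N_S, CI)`.
#' @export
profile_features <- function(aln, position, wt, mut) {
  .validate_aa1(c(wt, mut))
  mat <- .aln_matrix(aln)
  col <- .query_column(aln, position)
  fi <- .column_freqs(mat, col)
  names(fi) <- AA_ONE
  f <- .overall_freqs(mat)
  chars <- mat[, col]
  c(F_W = unname(fi[wt]), F_N = unname(fi[mut]),
    N_T = nrow(mat), N_S = sum(chars != "-"),
    CI = sqrt(sum((fi - f)^2)))
}

.PANTHER_DEFAULT <- c(P_D = 0.5, P_W = 0, P_N = 0, N_IC = 0)

#' Family-classifier features for a substitution
#'
#' Looks up precomputed family scores (see [read_panther_table()]) for one
#' substitution. When the substitution is absent — or no table is supplied —
#' the documented defaults are returned: deleterious probability 0.5 and the
#' remaining values 0, i.e. an uninformative prior.
#'
#' @param record One-row mutation data frame (columns `protein_id`,
#'   `position`, `wt`, `mut`).
#' @param table Optional data frame from [read_panther_table()].
#' @return Named numeric vector `c(P_D, P_W, P_N, N_IC)`.
#' @export
panther_features <- function(record, table = NULL) {
  if (is.null(table) || nrow(table) == 0L) return(.PANTHER_DEFAULT)
  hit <- which(table$protein_id == record$protein_id &
                 table$position == record$position &
                 table$wt == record$wt & table$mut == record$mut)
  if (length(hit) == 0L) return(.PANTHER_DEFAULT)
  i <- hit[1]
  c(P_D = table$P_D[i], P_W = table$P_W[i], P_N = table$P_N[i],
    N_IC = table$N_IC[i])
}
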
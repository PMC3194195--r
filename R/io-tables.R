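# Tabular and sequence I/O: mutation tables, aligned FASTA, a minimal OBO
# subset, GO annotation tables, accessibility and family-score imports, and
# the sequence -> structure position mapping with its acceptance filters.

.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a labeled (or unlabeled) mutation table
#'
#' Reads a tab-delimited table of single amino acid substitutions with header
#' columns `protein_id`, `chain_id`, `position`, `wt`, `mut` and optionally
#' `label`. Residues are one-letter codes; positions are 1-based sequence
#' positions; labels are `disease` or `neutral`. Every malformed row is
#' reported with its row number and the whole read fails if any row is
#' invalid.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the validated columns (integer `position`,
#'   `label` present only if the file has it).
#' @export
read_mutation_table <- function(path) {
  df <- .read_tsv(path, c("protein_id", "chain_id", "position", "wt", "mut"))
  has_label <- "label" %in% names(df)
  out <- data.frame(
    protein_id = df$protein_id,
    chain_id = df$chain_id,
    position = suppressWarnings(as.integer(df$position)),
    wt = toupper(df$wt),
    mut = toupper(df$mut),
    stringsAsFactors = FALSE
  )
  if (has_label) out$label <- df$label
  validate_mutations(out, context = path)
}

#' Validate a mutation data frame
#'
#' Checks the invariants of a mutation set: canonical one-letter residue
#' codes, `wt != mut`, positive integer positions, and (when present) labels
#' in `{disease, neutral}`. Used by [read_mutation_table()] and by the
#' fixture generator.
#'
#' @param df Data frame with columns `protein_id`, `chain_id`, `position`,
#'   `wt`, `mut` and optionally `label`.
#' @param context String used to prefix error messages.
#' @return The validated data frame, invisibly classed.
#' @export
validate_mutations <- function(df, context = "mutation table") {
  n <- nrow(df)
  if (n == 0L) return(df)
  errs <- character(0)
  row_err <- function(i, msg) sprintf("row %d: %s", i, msg)
  for (i in seq_len(n)) {
    if (is.na(df$position[i]) || df$position[i] < 1L)
      errs <- c(errs, row_err(i, "position must be a positive integer"))
    if (!(df$wt[i] %in% AA_ONE))
      errs <- c(errs, row_err(i, sprintf("unknown wt residue '%s'", df$wt[i])))
    if (!(df$mut[i] %in% AA_ONE))
      errs <- c(errs, row_err(i, sprintf("unknown mut residue '%s'", df$mut[i])))
    if (identical(df$wt[i], df$mut[i]))
      errs <- c(errs, row_err(i, "wt and mut are identical (not a substitution)"))
    if ("label" %in% names(df) && !(df$label[i] %in% c("disease", "neutral")))
      errs <- c(errs, row_err(i, sprintf("label '%s' not in {disease, neutral}",
                                         df$label[i])))
  }
  if (length(errs)) {
    stop(sprintf("%s: %d invalid row(s)\n%s", context, length(errs),
                 paste(errs, collapse = "\n")), call. = FALSE)
  }
  df
}

#' Write a mutation table
#' @param df Mutation data frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_mutation_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- alignments -------------------------------------------------------------

.ALN_ALPHABET <- c(AA_ONE, "-", "X")

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in aligned-FASTA format. All rows must
#' have equal length; the query row (by default the first) may contain only
#' the 20 canonical residues, `X`, and the gap character `-` (`.` is
#' normalised to `-`).
#'
#' @param path Path to the aligned FASTA file.
#' @param query Index of the query row (default 1).
#' @return A `SapAlignment`: list with `ids`, `rows` (character vector of
#'   equal-length gapped sequences) and `query`.
#' @export
read_alignment <- function(path, query = 1L) {
  set <- Biostrings::readAAStringSet(path)
  rows <- toupper(chartr(".", "-", as.character(set)))
  new_alignment(rows, ids = names(set), query = query)
}

#' Construct an alignment object from gapped rows
#'
#' @param rows Character vector of equal-length gapped sequences.
#' @param ids Row identifiers (defaults to `seq1`, `seq2`, ...).
#' @param query Index of the query row.
#' @return A `SapAlignment`.
#' @export
new_alignment <- function(rows, ids = NULL, query = 1L) {
  if (length(rows) < 1L) stop("alignment has no rows", call. = FALSE)
  w <- nchar(rows)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: rows differ in length", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  query <- as.integer(query)
  stopifnot(query >= 1L, query <= length(rows))
  qchars <- strsplit(rows[query], "")[[1]]
  bad <- setdiff(unique(qchars), .ALN_ALPHABET)
  if (length(bad))
    stop(sprintf("query row contains characters outside the alphabet: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(ids = unname(ids), rows = unname(rows), query = query),
            class = "SapAlignment")
}

#' @export
print.SapAlignment <- function(x, ...) {
  cat(sprintf("SapAlignment: %d rows x %d columns (query row %d)\n",
              length(x$rows), nchar(x$rows[1]), x$query))
  invisible(x)
}

# character matrix view (rows x columns)
.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, ""))
}

#' Write an alignment as aligned FASTA
#' @param aln A `SapAlignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::AAStringSet(aln$rows)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- ontology ---------------------------------------------------------------

#' Read a minimal OBO ontology
#'
#' Parses the OBO 1.2 subset used for GO feature computation: `[Term]`
#' stanzas with `id`, `name`, `namespace` and `is_a` fields. Only `is_a`
#' edges are kept. The result must be acyclic and every edge endpoint must be
#' a declared term.
#'
#' @param path Path to the OBO file.
#' @return An `OntologyDag`: list with `terms`, `name`, `namespace`,
#'   `parents` (term -> character vector) and `children`.
#' @export
read_obo_lite <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  in_term <- FALSE
  terms <- character(0); nm <- character(0); ns <- character(0)
  edges_child <- character(0); edges_parent <- character(0)
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.na(cur$id)) {
      terms <<- c(terms, cur$id)
      nm <<- c(nm, cur$name)
      ns <<- c(ns, cur$namespace)
      if (length(cur$isa)) {
        edges_child <<- c(edges_child, rep(cur$id, length(cur$isa)))
        edges_parent <<- c(edges_parent, cur$isa)
      }
    }
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush()
      cur <- list(id = NA_character_, name = NA_character_,
                  namespace = NA_character_, isa = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^namespace:", ln)) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      cur$isa <- c(cur$isa, trimws(sub("^is_a:", "", ln)))
    }
  }
  flush()
  if (anyDuplicated(terms))
    stop("duplicate term id(s) in ontology", call. = FALSE)
  undeclared <- setdiff(edges_parent, terms)
  if (length(undeclared))
    stop(sprintf("is_a edge to undeclared term(s): %s",
                 paste(undeclared, collapse = ", ")), call. = FALSE)
  new_ontology(terms, edges_child, edges_parent, name = nm, namespace = ns)
}

#' Construct an ontology DAG from term and edge vectors
#'
#' @param terms Character vector of term identifiers.
#' @param child,parent Parallel character vectors: one `is_a` edge per entry,
#'   `child[i] -> parent[i]`.
#' @param name,namespace Optional per-term metadata.
#' @return An `OntologyDag`.
#' @export
new_ontology <- function(terms, child = character(0), parent = character(0),
                         name = NULL, namespace = NULL) {
  stopifnot(length(child) == length(parent))
  bad <- setdiff(c(child, parent), terms)
  if (length(bad))
    stop(sprintf("edge endpoint(s) not declared: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (length(child)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = child, to = parent), directed = TRUE,
      vertices = data.frame(name = terms))
    if (!igraph::is_dag(g)) stop("ontology contains a cycle", call. = FALSE)
  }
  parents <- split(parent, factor(child, levels = terms))
  children <- split(child, factor(parent, levels = terms))
  structure(list(
    terms = terms,
    name = if (is.null(name)) rep(NA_character_, length(terms)) else name,
    namespace = if (is.null(namespace)) rep(NA_character_, length(terms)) else namespace,
    parents = lapply(parents, unname),
    children = lapply(children, unname)
  ), class = "OntologyDag")
}

#' @export
print.OntologyDag <- function(x, ...) {
  cat(sprintf("OntologyDag: %d terms, %d is_a edges\n",
              length(x$terms), sum(lengths(x$parents))))
  invisible(x)
}

#' Read a protein -> GO term annotation table
#'
#' Two-column TSV (`protein_id`, `term`) of direct annotations. Every term
#' must exist in the supplied ontology.
#'
#' @param path Path to the TSV file.
#' @param ontology An `OntologyDag`.
#' @return Named list: `protein_id` -> character vector of directly annotated
#'   terms (deduplicated).
#' @export
read_annotations <- function(path, ontology) {
  df <- .read_tsv(path, c("protein_id", "term"))
  unknown <- setdiff(df$term, ontology$terms)
  if (length(unknown))
    stop(sprintf("annotation references unknown term(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  lapply(split(df$term, df$protein_id), unique)
}

#' Write an annotation table
#' @param annotations Named list protein -> terms.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    protein_id = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read precomputed per-residue accessibility
#'
#' Import path for per-residue absolute solvent-accessible areas computed
#' externally (e.g. by DSSP). TSV with columns `chain`, `ordinal`, `asa`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with `chain`, integer `ordinal` and numeric `asa`
#'   (Angstrom^2, all non-negative).
#' @export
read_accessibility <- function(path) {
  df <- .read_tsv(path, c("chain", "ordinal", "asa"))
  out <- data.frame(chain = df$chain,
                    ordinal = as.integer(df$ordinal),
                    asa = as.numeric(df$asa),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$asa)) || any(out$asa < 0))
    stop("accessibility values must be non-negative numbers", call. = FALSE)
  out
}

#' Read a precomputed family-classifier feature table
#'
#' PANTHER-style per-substitution scores: `protein_id`, `position`, `wt`,
#' `mut`, `P_D` (deleterious probability), `P_W`, `P_N` (family-alignment
#' frequencies of the wild-type and new residue) and `N_IC` (independent
#' counts). Substitutions absent from the table receive documented defaults
#' at feature-assembly time (see [panther_features()]).
#'
#' @param path Path to the TSV file.
#' @return Data frame keyed by (`protein_id`, `position`, `wt`, `mut`).
#' @export
read_panther_table <- function(path) {
  df <- .read_tsv(path, c("protein_id", "position", "wt", "mut",
                          "P_D", "P_W", "P_N", "N_IC"))
  out <- data.frame(
    protein_id = df$protein_id,
    position = as.integer(df$position),
    wt = toupper(df$wt),
    mut = toupper(df$mut),
    P_D = as.numeric(df$P_D),
    P_W = as.numeric(df$P_W),
    P_N = as.numeric(df$P_N),
    N_IC = as.numeric(df$N_IC),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$P_D)) || any(out$P_D < 0) || any(out$P_D > 1))
    stop("P_D must lie in [0, 1]", call. = FALSE)
  if (any(is.na(out$position)) || any(is.na(out$P_W)) ||
      any(is.na(out$P_N)) || any(is.na(out$N_IC)))
    stop("malformed family-feature row(s): non-numeric fields", call. = FALSE)
  out
}

# ---- sequence -> structure mapping ------------------------------------------

.SUBMAT <- local({
  alpha <- c(AA_ONE, "X")
  m <- matrix(-3, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(m) <- 2
  m["X", "X"] <- -3  # X never counts as identical
  m
})

#' Map sequence positions onto structure residues
#'
#' Finds the best local correspondence between a query protein sequence and
#' the residue sequence of a structure chain, then applies the acceptance
#' filters used when pairing database sequences with deposited structures:
#' the aligned block must be gapless, 100% identical, and at least
#' `min_length` residues long. On success the mapping from 1-based sequence
#' positions to structure residue ordinals is returned; otherwise the mapping
#' is rejected with the first failed criterion (`gap`, `identity`, or
#' `length`).
#'
#' @param seq Query protein sequence (one-letter string).
#' @param struct A `StructureModel`.
#' @param min_length Minimum accepted block length (residues).
#' @return A `SeqStructMapping`: list with `protein_id`, `chain_id`, `map`
#'   (named integer vector, sequence position -> residue ordinal), `length`
#'   and `identity`; or an error of class `sap_unmappable` whose `reason`
#'   field names the failed criterion.
#' @export
map_sequence_to_structure <- function(seq, struct, min_length = 40L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  sseq <- structure_sequence(struct)
  if (nchar(sseq) == 0L) stop("empty structure", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = seq, subject = sseq, type = "local",
    substitutionMatrix = .SUBMAT, gapOpening = 4, gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  reject <- function(reason) {
    cond <- structure(
      class = c("sap_unmappable", "error", "condition"),
      list(message = sprintf("unmappable: rejected by %s filter", reason),
           call = NULL, reason = reason))
    stop(cond)
  }
  if (grepl("-", pat, fixed = TRUE) || grepl("-", sub, fixed = TRUE))
    reject("gap")
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(sub, "")[[1]]
  if (!all(pc == sc)) reject("identity")
  width <- length(pc)
  if (width < min_length) reject("length")
  qstart <- Biostrings::start(Biostrings::pattern(aln))
  sstart <- Biostrings::start(Biostrings::subject(aln))
  map <- stats::setNames(seq(sstart, length.out = width),
                         seq(qstart, length.out = width))
  structure(list(protein_id = struct$id, chain_id = struct$chain_id,
                 map = map, length = width, identity = 1),
            class = "SeqStructMapping")
}

#' Look up a structure residue ordinal for a sequence position
#' @param mapping A `SeqStructMapping`.
#' @param position 1-based sequence position.
#' @return Integer residue ordinal, or error if outside the mapped block.
#' @export
mapped_ordinal <- function(mapping, position) {
  key <- as.character(position)
  if (!key %in% names(mapping$map))
    stop(sprintf("position %d outside the mapped block", position),
         call. = FALSE)
  unname(mapping$map[key])
}
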
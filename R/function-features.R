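# Gene Ontology features: annotation propagation to ancestors, per-term
# class counts over a training set (leakage-free by construction: counts are
# a pure function of the records passed in), and the log-odds score
#   LGO = sum_GO log2[ f_GO(D) / f_GO(N) ],  f_GO(X) = (c_X + 1)/(T_X + 1)
# with one pseudo-count per class, summed over a protein's propagated terms.

.closure <- function(edges, start) {
  # transitive closure over a named list term -> adjacent terms
  out <- character(0)
  frontier <- start
  while (length(frontier)) {
    out <- c(out, frontier)
    nxt <- unique(unlist(edges[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, out)
  }
  unique(out)
}

#' Propagate terms to all ancestors
#'
#' Returns the union of a set of directly annotated terms with every
#' ancestor reachable via `is_a` edges, each term counted once.
#'
#' @param ontology An `OntologyDag`.
#' @param direct Character vector of term ids.
#' @return Character vector of terms (direct plus ancestors, deduplicated).
#' @export
propagate <- function(ontology, direct) {
  unknown <- setdiff(direct, ontology$terms)
  if (length(unknown))
    stop(sprintf("unknown term(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  .closure(ontology$parents, unique(direct))
}

#' Propagate a whole annotation set
#'
#' @param ontology An `OntologyDag`.
#' @param annotations Named list protein -> direct terms (as returned by
#'   [read_annotations()]).
#' @return Named list protein -> propagated term set.
#' @export
propagate_annotations <- function(ontology, annotations) {
  lapply(annotations, function(terms) propagate(ontology, terms))
}

#' All descendants of a term
#' @param ontology An `OntologyDag`.
#' @param term Term id.
#' @return Character vector: the term plus every descendant.
#' @export
term_subtree <- function(ontology, term) {
  if (!term %in% ontology$terms)
    stop(sprintf("unknown term: %s", term), call. = FALSE)
  .closure(ontology$children, term)
}

#' Remove a term and its descendants from every protein's annotation
#'
#' Used by the function-holdout protocol: when testing on proteins selected
#' by a functional term, that term's whole subtree is blanked out of the
#' annotations used to score the test set, so the selection criterion cannot
#' leak into the GO features.
#'
#' @param annotations Named list protein -> (propagated) term set.
#' @param ontology An `OntologyDag`.
#' @param term Term id whose subtree is removed.
#' @return The filtered annotation list.
#' @export
exclude_term_subtree <- function(annotations, ontology, term) {
  sub <- term_subtree(ontology, term)
  lapply(annotations, function(terms) setdiff(terms, sub))
}

#' Per-term class counts over a training set
#'
#' For every GO term, counts the disease-labeled and neutral-labeled
#' training mutations whose protein carries the term (after propagation).
#' The counting unit is the mutation: a protein with several training
#' mutations contributes once per mutation (set `per_protein = TRUE` to
#' count each protein once per class instead). Totals `T_D` and `T_N` are
#' the training mutations (or proteins) per class. Counts are a function of
#' the supplied records only, which is what makes per-fold fitting
#' leakage-free.
#'
#' @param training Labeled mutation data frame (column `label`).
#' @param annotations Named list protein -> propagated term set.
#' @param per_protein Count proteins instead of mutations (default `FALSE`).
#' @return A `GoClassCounts`: list with `c_D`, `c_N` (named numeric vectors
#'   by term) and totals `T_D`, `T_N`.
#' @export
fit_go_counts <- function(training, annotations, per_protein = FALSE) {
  stopifnot("label" %in% names(training))
  if (per_protein) {
    keep <- !duplicated(training[, c("protein_id", "label")])
    training <- training[keep, , drop = FALSE]
  }
  unannotated <- setdiff(unique(training$protein_id), names(annotations))
  if (length(unannotated))
    message(sprintf("%d protein(s) without annotations contribute no GO counts",
                    length(unannotated)))
  count_class <- function(lab) {
    recs <- training[training$label == lab, , drop = FALSE]
    # one increment per (mutation, term) pair
    terms <- unlist(lapply(recs$protein_id, function(p) annotations[[p]]),
                    use.names = FALSE)
    if (is.null(terms)) terms <- character(0)
    table(terms)
  }
  tab_d <- count_class("disease")
  tab_n <- count_class("neutral")
  all_terms <- union(names(tab_d), names(tab_n))
  c_D <- stats::setNames(numeric(length(all_terms)), all_terms)
  c_N <- c_D
  c_D[names(tab_d)] <- as.numeric(tab_d)
  c_N[names(tab_n)] <- as.numeric(tab_n)
  structure(list(c_D = c_D, c_N = c_N,
                 T_D = sum(training$label == "disease"),
                 T_N = sum(training$label == "neutral"),
                 per_protein = per_protein),
            class = "GoClassCounts")
}

#' GO log-odds score of a term set
#'
#' Sums, over the given terms, the log2 ratio of the term's pseudo-counted
#' frequency among disease-labeled versus neutral-labeled training
#' mutations: `f_GO(X) = (c_X + 1)/(T_X + 1)`. Terms never seen in training
#' contribute `log2((1/(T_D+1))/(1/(T_N+1)))`, which is 0 for balanced
#' totals. The empty set scores 0.
#'
#' @param terms Character vector of (propagated) term ids.
#' @param counts A `GoClassCounts`.
#' @return Numeric scalar.
#' @export
lgo_score <- function(terms, counts) {
  if (length(terms) == 0L) return(0)
  terms <- unique(terms)
  cd <- ifelse(terms %in% names(counts$c_D), counts$c_D[terms], 0)
  cn <- ifelse(terms %in% names(counts$c_N), counts$c_N[terms], 0)
  fd <- (cd + 1) / (counts$T_D + 1)
  fn <- (cn + 1) / (counts$T_N + 1)
  sum(log2(fd / fn))
}

#' The 2-element GO feature block
#'
#' Number of (propagated) GO terms carried by the protein, and its LGO
#' score under the supplied training counts. A protein without annotations
#' gets `(0, 0)`.
#'
#' @param protein_id Protein identifier.
#' @param annotations Named list protein -> propagated term set.
#' @param counts A `GoClassCounts`.
#' @return Named numeric vector `c(N_GO, LGO)`.
#' @export
go_feature_pair <- function(protein_id, annotations, counts) {
  terms <- annotations[[protein_id]]
  if (is.null(terms) || length(terms) == 0L) return(c(N_GO = 0, LGO = 0))
  c(N_GO = length(unique(terms)), LGO = lgo_score(terms, counts))
}
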
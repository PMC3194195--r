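# Residue-interaction analysis. A substitution removes the wild-type
# residue's contacts ("lost") and, under the approximation that the C-alpha
# position does not move, creates the same contacts for the new residue
# ("gained"). Pooling these events over a labeled mutation set gives two
# symmetric 20x20 log-odds matrices:
#   LC(i,j) = log2[ f(c(i,j), D) / f(c(i,j), N) ]
# with f(c, X) = (count_X(c) + 1) / (total_X + 1); the pseudo-count keeps
# every entry finite and is declared in the output headers.

.contact_events <- function(struct, mapping, record, kind, radius) {
  ordinal <- mapped_ordinal(mapping, record$position)
  cp <- contact_partners(struct, ordinal, radius)
  wt3 <- .aa1_to3(record$wt)
  if (!identical(cp$center, wt3))
    stop(sprintf(
      "structure/sequence disagreement at position %d: structure has %s, record wt is %s",
      record$position, cp$center, wt3), call. = FALSE)
  center <- if (kind == "lost") wt3 else .aa1_to3(record$mut)
  if (length(cp$partners) == 0L) {
    return(data.frame(kind = character(0), a = character(0), b = character(0),
                      protein_id = character(0), position = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  # unordered pairs, stored in canonical order
  a <- pmin(match(center, AA_THREE), match(cp$partners, AA_THREE))
  b <- pmax(match(center, AA_THREE), match(cp$partners, AA_THREE))
  data.frame(kind = kind, a = AA_THREE[a], b = AA_THREE[b],
             protein_id = record$protein_id, position = record$position,
             label = if ("label" %in% names(record)) record$label else NA_character_,
             stringsAsFactors = FALSE)
}

#' Contacts lost by the wild-type residue
#'
#' One event per shell partner (6 Angstrom C-alpha shell by default),
#' pairing the wild-type residue type with the partner's type. The
#' structure residue addressed through the mapping must match the record's
#' wild-type residue.
#'
#' @param struct A `StructureModel`.
#' @param mapping A `SeqStructMapping` for the record's protein.
#' @param record One-row mutation data frame.
#' @param radius Shell radius (Angstrom).
#' @return Data frame of events: `kind`, `a`, `b` (unordered pair in
#'   canonical order), `protein_id`, `position`, `label`.
#' @export
lost_contacts <- function(struct, mapping, record, radius = 6.0) {
  .contact_events(struct, mapping, record, "lost", radius)
}

#' Contacts gained by the mutant residue
#'
#' Same shell partners as [lost_contacts()], paired with the mutant residue
#' type: the new residue is assumed to inherit the wild-type's C-alpha
#' position and hence its interaction partners.
#'
#' @inheritParams lost_contacts
#' @return Data frame of events (see [lost_contacts()]).
#' @export
gained_contacts <- function(struct, mapping, record, radius = 6.0) {
  .contact_events(struct, mapping, record, "gained", radius)
}

#' Fit the lost/gained contact log-odds matrices
#'
#' Pools labeled contact events and computes, separately for lost and gained
#' contacts, the symmetric 20x20 matrix of log2 ratios of pseudo-counted
#' pair frequencies among disease-labeled versus neutral-labeled events.
#' Positive entries mark contact changes enriched among disease mutations.
#'
#' @param events Data frame of events with columns `kind`, `a`, `b`,
#'   `label` (rows from [lost_contacts()] / [gained_contacts()]).
#' @return An `InteractionLogOdds`: list with matrices `lost` and `gained`
#'   (20x20, canonical order), per-kind/class `totals`, and `pseudo_count`.
#' @export
fit_interaction_log_odds <- function(events) {
  if (nrow(events) == 0L) {
    warning("no contact events: returning all-zero matrices", call. = FALSE)
    z <- matrix(0, 20, 20, dimnames = list(AA_THREE, AA_THREE))
    return(structure(list(lost = z, gained = z,
                          totals = c(lost_D = 0, lost_N = 0,
                                     gained_D = 0, gained_N = 0),
                          pseudo_count = 1),
                     class = "InteractionLogOdds"))
  }
  stopifnot(all(events$label %in% c("disease", "neutral")))
  one_kind <- function(kind) {
    ev <- events[events$kind == kind, , drop = FALSE]
    count_mat <- function(lab) {
      m <- matrix(0, 20, 20, dimnames = list(AA_THREE, AA_THREE))
      sel <- ev[ev$label == lab, , drop = FALSE]
      if (nrow(sel)) {
        tab <- table(factor(sel$a, AA_THREE), factor(sel$b, AA_THREE))
        m <- m + unclass(tab)
        m <- m + t(m) - diag(diag(m))  # mirror into symmetric counts
      }
      m
    }
    cd <- count_mat("disease")
    cn <- count_mat("neutral")
    td <- sum(ev$label == "disease")
    tn <- sum(ev$label == "neutral")
    lc <- log2(((cd + 1) / (td + 1)) / ((cn + 1) / (tn + 1)))
    list(lc = lc, td = td, tn = tn)
  }
  lost <- one_kind("lost")
  gained <- one_kind("gained")
  structure(list(lost = lost$lc, gained = gained$lc,
                 totals = c(lost_D = lost$td, lost_N = lost$tn,
                            gained_D = gained$td, gained_N = gained$tn),
                 pseudo_count = 1),
            class = "InteractionLogOdds")
}

#' Enumerate contact events for a whole mutation set
#'
#' @param mutations Labeled mutation data frame.
#' @param structures Named list of `StructureModel`s by `protein_id`.
#' @param mappings Named list of `SeqStructMapping`s by `protein_id`.
#' @param radius Shell radius (Angstrom).
#' @return Data frame of pooled lost and gained events.
#' @export
contact_events <- function(mutations, structures, mappings, radius = 6.0) {
  out <- vector("list", 2L * nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    rec <- mutations[i, , drop = FALSE]
    st <- structures[[rec$protein_id]]
    mp <- mappings[[rec$protein_id]]
    if (is.null(st) || is.null(mp))
      stop(sprintf("no structure/mapping for protein %s", rec$protein_id),
           call. = FALSE)
    out[[2L * i - 1L]] <- lost_contacts(st, mp, rec, radius)
    out[[2L * i]] <- gained_contacts(st, mp, rec, radius)
  }
  do.call(rbind, out)
}

#' Write a contact log-odds matrix as TSV
#'
#' 20x20 matrix with a residue-order header row/column; a comment line
#' records the pseudo-count rule.
#'
#' @param lc An `InteractionLogOdds`.
#' @param kind `"lost"` or `"gained"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lc_matrix <- function(lc, kind = c("lost", "gained"), path) {
  kind <- match.arg(kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# %s-contact log2 odds; pseudo-count %g per pair per class; totals D=%d N=%d",
    kind, lc$pseudo_count, lc$totals[paste0(kind, "_D")],
    lc$totals[paste0(kind, "_N")]), con)
  m <- lc[[kind]]
  writeLines(paste(c("residue", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 10)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
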
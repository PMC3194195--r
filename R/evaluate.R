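# Evaluation protocol: reverse-mutation balancing, sequence-identity
# clustering, homology-aware k-fold plans, the statistical indexes
# (accuracy, per-class Matthews correlation / sensitivity / predictive
# value, AUC, TPR at fixed FPR), reliability filtering, the
# function-holdout split, and RSA-stratified scoring.

#' Balance a labeled set by reverse mutations
#'
#' For every neutral record `wt -> mut`, appends the reverse substitution
#' `mut -> wt` on the same protein and position, also labeled neutral.
#' Disease records are untouched. This doubles the neutral class, bringing
#' a disease-skewed set close to balance. Appended rows carry
#' `reversed = TRUE`.
#'
#' @param mutations Labeled mutation data frame.
#' @return The augmented data frame.
#' @export
balance_with_reverse <- function(mutations) {
  if (nrow(mutations) == 0L) {
    mutations$reversed <- logical(0)
    return(mutations)
  }
  stopifnot("label" %in% names(mutations))
  mutations$reversed <- FALSE
  neutral <- mutations[mutations$label == "neutral", , drop = FALSE]
  if (nrow(neutral)) {
    rev <- neutral
    rev$wt <- neutral$mut
    rev$mut <- neutral$wt
    rev$reversed <- TRUE
    mutations <- rbind(mutations, rev)
  }
  rownames(mutations) <- NULL
  mutations
}

# ---- homology clustering ----------------------------------------------------

#' Cluster proteins by pairwise sequence identity
#'
#' Single-linkage clustering in which two proteins are joined when their
#' local alignment reaches at least `identity` percent identical positions
#' over at least `coverage` of the shorter sequence's length (defaults 30%
#' and 0.9, the conventional thresholds for homology-aware evaluation).
#' Alignments are computed with [Biostrings::pairwiseAlignment()]
#' (BLOSUM62, local).
#'
#' @param sequences Named character vector of protein sequences.
#' @param identity Identity threshold in percent.
#' @param coverage Minimum aligned fraction of the shorter sequence.
#' @return Named integer vector: protein id -> cluster id (1-based, in order
#'   of first appearance).
#' @export
cluster_proteins <- function(sequences, identity = 30, coverage = 0.9) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  n <- length(sequences)
  ids <- names(sequences)
  if (n == 1L) return(stats::setNames(1L, ids))
  submat <- .blosum62()
  set <- Biostrings::AAStringSet(sequences)
  edges_from <- integer(0); edges_to <- integer(0)
  for (i in seq_len(n - 1L)) {
    pats <- set[(i + 1L):n]
    aln <- Biostrings::pairwiseAlignment(
      pats, set[[i]], type = "local", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 0.5)
    pid <- Biostrings::pid(aln, type = "PID1")
    pr <- Biostrings::pattern(aln)
    sr <- Biostrings::subject(aln)
    shorter <- pmin(nchar(sequences[(i + 1L):n]), nchar(sequences[i]))
    cover_p <- (Biostrings::end(pr) - Biostrings::start(pr) + 1L)
    cover_s <- (Biostrings::end(sr) - Biostrings::start(sr) + 1L)
    cov <- pmin(cover_p, cover_s) / shorter
    hit <- which(pid >= identity & cov >= coverage)
    if (length(hit)) {
      edges_from <- c(edges_from, rep(i, length(hit)))
      edges_to <- c(edges_to, i + hit)
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[edges_from], to = ids[edges_to]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp[ids]), ids)
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Pairwise percent identity between two sequence sets
#'
#' Maximum local-alignment identity of each query against any target,
#' subject to the same coverage rule as [cluster_proteins()]. Used by the
#' function-holdout protocol to purge training proteins similar to test
#' proteins.
#'
#' @param queries,targets Named character vectors of sequences.
#' @param coverage Minimum aligned fraction of the shorter sequence.
#' @return Numeric vector (one max-identity percent per query).
#' @export
max_identity_to <- function(queries, targets, coverage = 0.9) {
  submat <- .blosum62()
  tgt <- Biostrings::AAStringSet(targets)
  vapply(queries, function(q) {
    aln <- Biostrings::pairwiseAlignment(
      tgt, q, type = "local", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 0.5)
    pid <- Biostrings::pid(aln, type = "PID1")
    pr <- Biostrings::pattern(aln)
    sr <- Biostrings::subject(aln)
    shorter <- pmin(nchar(targets), nchar(q))
    cov <- pmin(Biostrings::end(pr) - Biostrings::start(pr) + 1L,
                Biostrings::end(sr) - Biostrings::start(sr) + 1L) / shorter
    ok <- cov >= coverage
    if (any(ok)) max(pid[ok]) else 0
  }, numeric(1))
}

# ---- fold plans -------------------------------------------------------------

#' Build a homology-aware k-fold plan
#'
#' Assigns whole homology clusters to folds so that no cluster (hence no
#' pair of similar proteins, and no protein) ever spans training and test.
#' Clusters are placed greedily, largest first (ties shuffled by `seed`),
#' each into the fold minimising a combined size/class-ratio objective, so
#' folds end up close in size and in disease fraction.
#'
#' @param mutations Labeled mutation data frame.
#' @param clusters Named integer vector protein id -> cluster id
#'   ([cluster_proteins()]).
#' @param k Number of folds (must not exceed the number of clusters).
#' @param seed Integer seed for tie-breaking.
#' @return A `FoldPlan`: list with `folds` (list of row-index vectors),
#'   `clusters`, `k`, `seed`.
#' @export
make_folds <- function(mutations, clusters, k = 20L, seed = 1L) {
  n <- nrow(mutations)
  stopifnot(n >= 1L, "label" %in% names(mutations))
  miss <- setdiff(unique(mutations$protein_id), names(clusters))
  if (length(miss))
    stop(sprintf("protein(s) missing from cluster map: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  cl_of_row <- clusters[mutations$protein_id]
  ucl <- unique(cl_of_row)
  if (k > length(ucl))
    stop(sprintf("k = %d exceeds the number of clusters (%d)",
                 k, length(ucl)), call. = FALSE)
  sizes <- vapply(ucl, function(cl) sum(cl_of_row == cl), numeric(1))
  dis <- vapply(ucl, function(cl)
    sum(cl_of_row == cl & mutations$label == "disease"), numeric(1))
  set.seed(seed)
  ord <- order(-sizes, sample.int(length(ucl)))
  ratio <- sum(mutations$label == "disease") / n
  fold_n <- numeric(k); fold_d <- numeric(k)
  assign_cl <- integer(length(ucl))
  for (idx in ord) {
    n_after <- fold_n + sizes[idx]
    d_after <- fold_d + dis[idx]
    score <- n_after + 2 * abs(d_after - ratio * n_after)
    f <- which.min(score)
    assign_cl[idx] <- f
    fold_n[f] <- n_after[f]
    fold_d[f] <- d_after[f]
  }
  fold_of_row <- assign_cl[match(cl_of_row, ucl)]
  folds <- lapply(seq_len(k), function(f) which(fold_of_row == f))
  plan <- structure(list(folds = folds, clusters = clusters,
                         k = as.integer(k), seed = as.integer(seed)),
                    class = "FoldPlan")
  .check_fold_plan(plan, n)
  plan
}

.check_fold_plan <- function(plan, n) {
  all_idx <- sort(unlist(plan$folds))
  if (!identical(all_idx, seq_len(n)))
    stop("fold plan does not partition the dataset", call. = FALSE)
  invisible(plan)
}

# ---- statistical indexes ----------------------------------------------------

.confusion <- function(pred_class, labels, s) {
  other <- setdiff(c("disease", "neutral"), s)
  c(p = as.numeric(sum(pred_class == s & labels == s)),
    n = as.numeric(sum(pred_class == other & labels == other)),
    u = as.numeric(sum(pred_class == other & labels == s)),
    o = as.numeric(sum(pred_class == s & labels == other)))
}

.mcc_from_confusion <- function(cc) {
  W2 <- (cc["p"] + cc["u"]) * (cc["p"] + cc["o"]) *
    (cc["n"] + cc["u"]) * (cc["n"] + cc["o"])
  if (W2 == 0) return(structure(0, degenerate = TRUE))
  unname((cc["p"] * cc["n"] - cc["u"] * cc["o"]) / sqrt(W2))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic on the
#' disease probabilities (midranks for ties).
#'
#' @param o_d Disease probabilities.
#' @param labels Labels in `{disease, neutral}`.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(o_d, labels) {
  pos <- labels == "disease"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(structure(0, degenerate = TRUE))
  r <- rank(o_d)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC points
#'
#' False-positive and true-positive rates at every decision threshold over
#' the score, from the all-neutral corner (0,0) to (1,1).
#'
#' @inheritParams auc_rank
#' @return Data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(o_d, labels) {
  pos <- labels == "disease"
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(o_d, decreasing = TRUE)
  thr <- unique(o_d[ord])
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last <- cumsum(rle(o_d[ord])$lengths)  # last index at each threshold
  data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1),
             threshold = c(Inf, thr))
}

#' Statistical indexes of a prediction set
#'
#' Computes the full panel: overall accuracy `Q2 = P/T`; the per-class
#' Matthews correlation `C(s) = [p n - u o]/W` with
#' `W = [(p+u)(p+o)(n+u)(n+o)]^{1/2}`; per-class sensitivity
#' `S(s) = p/(p+u)`; per-class positive predictive value `P(s) = p/(p+o)`;
#' rank-statistic AUC; and the true-positive rate at 10% false-positive
#' rate. Degenerate denominators are reported as 0 and flagged in
#' `degenerate`. Two FPR conventions are returned: the standard ROC rate
#' (`tpr_at_fpr10`, primary) and the rate based on one minus precision
#' (`tpr_at_fdr10`).
#'
#' @param o_d Disease probabilities.
#' @param labels Labels in `{disease, neutral}`.
#' @param pred_class Optional predicted classes; derived from `o_d >= 0.5`
#'   when omitted.
#' @return A `MetricsReport` list.
#' @export
compute_metrics <- function(o_d, labels, pred_class = NULL) {
  stopifnot(length(o_d) >= 1L, length(o_d) == length(labels))
  if (is.null(pred_class))
    pred_class <- ifelse(o_d >= 0.5, "disease", "neutral")
  cd <- .confusion(pred_class, labels, "disease")
  cn <- .confusion(pred_class, labels, "neutral")
  degenerate <- character(0)
  safe_ratio <- function(num, den, what) {
    if (den == 0) { degenerate <<- c(degenerate, what); return(0) }
    unname(num / den)
  }
  mcc_d <- .mcc_from_confusion(cd)
  if (isTRUE(attr(mcc_d, "degenerate"))) degenerate <- c(degenerate, "C")
  roc <- roc_points(o_d, labels)
  tpr_at <- function(fpr_vals, tpr_vals, cut) {
    ok <- fpr_vals <= cut
    if (!any(ok)) 0 else max(tpr_vals[ok])
  }
  # precision-based alternative FPR convention: scan thresholds
  ordx <- order(o_d, decreasing = TRUE)
  tp <- cumsum(labels[ordx] == "disease")
  fp <- cumsum(labels[ordx] == "neutral")
  prec <- tp / (tp + fp)
  tprs <- tp / sum(labels == "disease")
  tpr_fdr <- { ok <- (1 - prec) <= 0.10; if (any(ok)) max(tprs[ok]) else 0 }
  structure(list(
    q2 = mean(pred_class == labels),
    mcc = as.numeric(mcc_d),
    s_d = safe_ratio(cd["p"], cd["p"] + cd["u"], "S(D)"),
    s_n = safe_ratio(cn["p"], cn["p"] + cn["u"], "S(N)"),
    p_d = safe_ratio(cd["p"], cd["p"] + cd["o"], "P(D)"),
    p_n = safe_ratio(cn["p"], cn["p"] + cn["o"], "P(N)"),
    auc = as.numeric(auc_rank(o_d, labels)),
    tpr_at_fpr10 = tpr_at(roc$fpr, roc$tpr, 0.10),
    tpr_at_fdr10 = tpr_fdr,
    confusion = list(disease = cd, neutral = cn),
    n = length(labels),
    degenerate = unique(degenerate)
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "n=%d  Q2=%.3f  C=%.3f  S(D)=%.3f  P(D)=%.3f  S(N)=%.3f  P(N)=%.3f  AUC=%.3f\n",
    x$n, x$q2, x$mcc, x$s_d, x$p_d, x$s_n, x$p_n, x$auc))
  if (length(x$degenerate))
    cat("degenerate:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Metrics as a function of the reliability-index threshold
#'
#' For thresholds 0..9, restricts to predictions with `RI > threshold` and
#' reports the retained fraction, accuracy and Matthews correlation —
#' higher-confidence subsets trade coverage for accuracy.
#'
#' @param predictions Data frame from [predict_sap()] (columns `o_d`,
#'   `class`, `ri`).
#' @param labels True labels.
#' @return Data frame: `threshold`, `coverage`, `n`, `q2`, `mcc`.
#' @export
reliability_curve <- function(predictions, labels) {
  out <- lapply(0:9, function(t) {
    keep <- predictions$ri > t
    if (!any(keep))
      return(data.frame(threshold = t, coverage = 0, n = 0L,
                        q2 = NA_real_, mcc = NA_real_))
    m <- compute_metrics(predictions$o_d[keep], labels[keep],
                         predictions$class[keep])
    data.frame(threshold = t, coverage = mean(keep), n = sum(keep),
               q2 = m$q2, mcc = m$mcc)
  })
  do.call(rbind, out)
}

#' RSA-stratified metrics
#'
#' Splits predictions into equal-width relative-accessibility bins
#' (multiples of `100/n_bins` percent; the last bin closed at 100) and
#' scores each bin separately — buried and exposed mutations behave
#' differently under a structure-aware model.
#'
#' @param predictions Data frame with `o_d` and `class`.
#' @param labels True labels.
#' @param rsa RSA percent per prediction.
#' @param n_bins Number of bins on \[0, 100\].
#' @return Data frame: `bin`, `rsa_lo`, `rsa_hi`, `n`, `n_disease`,
#'   `n_neutral`, `q2`, `mcc`.
#' @export
stratify_by_rsa <- function(predictions, labels, rsa, n_bins = 10L) {
  edges <- seq(0, 100, length.out = n_bins + 1L)
  bin <- pmin(findInterval(rsa, edges, rightmost.closed = TRUE), n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    keep <- bin == b
    if (!any(keep))
      return(data.frame(bin = b, rsa_lo = edges[b], rsa_hi = edges[b + 1L],
                        n = 0L, n_disease = 0L, n_neutral = 0L,
                        q2 = NA_real_, mcc = NA_real_))
    m <- compute_metrics(predictions$o_d[keep], labels[keep],
                         predictions$class[keep])
    data.frame(bin = b, rsa_lo = edges[b], rsa_hi = edges[b + 1L],
               n = sum(keep),
               n_disease = sum(labels[keep] == "disease"),
               n_neutral = sum(labels[keep] == "neutral"),
               q2 = m$q2, mcc = m$mcc)
  })
  do.call(rbind, out)
}

#' Function-holdout split
#'
#' Builds the stringent evaluation split used to bound the contribution of
#' structural features: the test set holds every mutation on proteins
#' annotated (after propagation) with `term` or one of its descendants; the
#' training set is the remainder, minus mutations on proteins whose
#' sequence identity to any test protein exceeds `identity_cutoff`. The
#' annotations returned for scoring the test set have the term's whole
#' subtree removed, so the selection criterion cannot leak into the GO
#' features.
#'
#' @param mutations Labeled mutation data frame.
#' @param annotations Named list protein -> direct terms.
#' @param ontology An `OntologyDag`.
#' @param term The functional term defining the test set.
#' @param sequences Named character vector of protein sequences (for the
#'   identity purge); `NULL` skips the purge.
#' @param identity_cutoff Percent identity above which a training protein is
#'   removed.
#' @return List with `train`, `test` (mutation data frames),
#'   `annotations_test` (subtree-excluded, propagated),
#'   `annotations_train` (propagated), `removed_proteins`.
#' @export
holdout_by_function <- function(mutations, annotations, ontology, term,
                                sequences = NULL, identity_cutoff = 30) {
  prop <- propagate_annotations(ontology, annotations)
  test_prot <- names(prop)[vapply(prop, function(t) term %in% t, logical(1))]
  is_test <- mutations$protein_id %in% test_prot
  test <- mutations[is_test, , drop = FALSE]
  train <- mutations[!is_test, , drop = FALSE]
  removed <- character(0)
  if (!is.null(sequences) && nrow(test) > 0L && nrow(train) > 0L) {
    train_prot <- unique(train$protein_id)
    ident <- max_identity_to(sequences[train_prot],
                             sequences[intersect(test_prot, names(sequences))])
    removed <- train_prot[ident > identity_cutoff]
    train <- train[!(train$protein_id %in% removed), , drop = FALSE]
  }
  list(train = train, test = test,
       annotations_test = exclude_term_subtree(prop, ontology, term),
       annotations_train = prop,
       removed_proteins = removed)
}
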
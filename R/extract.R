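# Dataset-level feature extraction and the homology-aware cross-validation
# driver. Extraction is split in two: everything except the GO block is a
# fixed property of a mutation and is computed once; the 2-element GO block
# depends on class counts fitted on a training set, so it is appended
# per-fold (leakage-free) or from explicit counts.

#' Extract per-mutation features (all blocks except GO)
#'
#' Computes, for every mutation, the mutation encoding, the environment
#' block (structural shell + RSA for the `"3d"` variant, sequence window
#' for `"seq"`), the profile features and the family-score block. Per
#' protein, the sequence -> structure mapping and the RSA profile are
#' computed once and reused; precomputed accessibility can be supplied
#' instead of running the internal SASA quadrature.
#'
#' @param mutations Mutation data frame ([read_mutation_table()]).
#' @param sequences Named character vector of protein sequences.
#' @param alignments Named list of `SapAlignment`s by protein id.
#' @param structures Named list of `StructureModel`s by protein id
#'   (required for `variant = "3d"`).
#' @param panther Optional family-score table ([read_panther_table()]).
#' @param variant `"3d"` or `"seq"`.
#' @param radius Shell radius in Angstrom.
#' @param window_length Sequence-window length (odd).
#' @param sasa Optional named list protein id -> per-residue absolute ASA
#'   (named by ordinal), e.g. from [read_accessibility()] or a cached
#'   [compute_sasa()].
#' @param n_points SASA quadrature points when computed internally.
#' @param mappings Optional named list of `SeqStructMapping`s; computed via
#'   [map_sequence_to_structure()] when missing.
#' @return A `SapFeatures`: list with `X_base` (numeric matrix), `records`,
#'   `variant`, `rsa` (per-mutation RSA, `NA` for `"seq"`), `mappings`,
#'   `params`.
#' @export
extract_features <- function(mutations, sequences, alignments,
                             structures = NULL, panther = NULL,
                             variant = c("3d", "seq"), radius = 6.0,
                             window_length = 19L, sasa = NULL,
                             n_points = 960L, mappings = NULL) {
  variant <- match.arg(variant)
  n <- nrow(mutations)
  stopifnot(n >= 1L)
  prots <- unique(mutations$protein_id)
  miss_seq <- setdiff(prots, names(sequences))
  if (length(miss_seq))
    stop(sprintf("no sequence for protein(s): %s",
                 paste(miss_seq, collapse = ", ")), call. = FALSE)

  if (variant == "3d") {
    miss_st <- setdiff(prots, names(structures))
    if (length(miss_st))
      stop(sprintf("no structure for protein(s): %s",
                   paste(miss_st, collapse = ", ")), call. = FALSE)
    if (is.null(mappings)) {
      mappings <- lapply(prots, function(p)
        map_sequence_to_structure(sequences[[p]], structures[[p]]))
      names(mappings) <- prots
    }
    rsa_by_prot <- lapply(prots, function(p) {
      if (!is.null(sasa) && !is.null(sasa[[p]]))
        rsa_profile(structures[[p]], sasa = sasa[[p]])
      else
        rsa_profile(structures[[p]], n_points = n_points)
    })
    names(rsa_by_prot) <- prots
  }

  p_base <- sum(FEATURE_BLOCKS[[variant]]) - 2L  # GO block appended later
  X <- matrix(NA_real_, n, p_base)
  rsa_vec <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rec <- mutations[i, , drop = FALSE]
    menc <- encode_mutation(rec$wt, rec$mut)
    if (variant == "3d") {
      mp <- mappings[[rec$protein_id]]
      ordinal <- mapped_ordinal(mp, rec$position)
      st <- structures[[rec$protein_id]]
      st_aa <- st$residues$aa[match(ordinal, st$residues$ordinal)]
      if (!identical(st_aa, rec$wt))
        stop(sprintf(
          "structure/sequence disagreement for %s position %d: %s vs %s",
          rec$protein_id, rec$position, st_aa, rec$wt), call. = FALSE)
      rsa_vec[i] <- unname(rsa_by_prot[[rec$protein_id]][as.character(ordinal)])
      env <- structure_environment(st, ordinal, rsa_vec[i], radius)
    } else {
      env <- sequence_window_counts(sequences[[rec$protein_id]], rec$position,
                                    window_length)
    }
    prof <- profile_features(alignments[[rec$protein_id]], rec$position,
                             rec$wt, rec$mut)
    pf <- panther_features(rec, panther)
    X[i, ] <- c(menc, as.numeric(env), prof, pf)
  }
  colnames(X) <- utils::head(feature_names(variant), p_base)
  structure(list(X_base = X, records = mutations, variant = variant,
                 rsa = rsa_vec, mappings = if (variant == "3d") mappings,
                 params = list(radius = radius, window_length = window_length,
                               n_points = n_points)),
            class = "SapFeatures")
}

#' Append the GO block under given training counts
#'
#' @param feats A `SapFeatures`.
#' @param counts A `GoClassCounts` (fitted on training records).
#' @param annotations Named list protein -> propagated term set (may be
#'   `NULL`: unannotated proteins score `(0, 0)`).
#' @return Full numeric feature matrix (52 or 51 columns).
#' @export
finalize_features <- function(feats, counts, annotations = NULL) {
  if (is.null(annotations)) annotations <- list()
  go <- t(vapply(feats$records$protein_id,
                 function(p) go_feature_pair(p, annotations, counts),
                 numeric(2)))
  X <- cbind(feats$X_base, go)
  colnames(X) <- feature_names(feats$variant)
  rownames(X) <- NULL
  X
}

#' Write / read a feature table
#'
#' TSV round-trip of an assembled feature matrix together with the record
#' columns, preserving full numeric precision.
#'
#' @param X Feature matrix with column names.
#' @param records Matching mutation data frame.
#' @param path Output path.
#' @return `write_feature_table`: invisibly `path`; `read_feature_table`:
#'   list with `X` and `records`.
#' @export
write_feature_table <- function(X, records, path) {
  df <- cbind(records, as.data.frame(X, check.names = FALSE))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param variant Feature variant of the stored table.
#' @export
read_feature_table <- function(path, variant = c("3d", "seq")) {
  variant <- match.arg(variant)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fn <- feature_names(variant)
  missing <- setdiff(fn, names(df))
  if (length(missing))
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  X <- as.matrix(df[fn])
  list(X = X, records = df[setdiff(names(df), fn)])
}

#' Homology-aware cross-validation
#'
#' Runs the full evaluation protocol: whole homology clusters are assigned
#' to `k` folds; for each fold the GO class counts, the feature rescaling
#' and the classifier are fitted on the other `k - 1` folds only, and the
#' held-out fold is predicted. Pooled predictions are scored with
#' [compute_metrics()]. Deterministic given `seed`.
#'
#' @param feats A `SapFeatures` for the (already balanced, if desired)
#'   dataset.
#' @param clusters Named integer vector protein -> cluster id.
#' @param annotations Named list protein -> propagated term set (`NULL` for
#'   no GO information).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param C,gamma Classifier hyperparameters.
#' @return List with `predictions` (data frame: record columns plus `o_d`,
#'   `class`, `ri`, `fold`), `metrics` (a `MetricsReport`), `plan` (the
#'   `FoldPlan`), and `params`.
#' @export
cross_validate <- function(feats, clusters, annotations = NULL, k = 20L,
                           seed = 1L, C = 8, gamma = 0.03125) {
  records <- feats$records
  n <- nrow(records)
  plan <- make_folds(records, clusters, k = k, seed = seed)
  o_d <- rep(NA_real_, n)
  fold_of <- rep(NA_integer_, n)
  for (f in seq_len(k)) {
    test_idx <- plan$folds[[f]]
    if (length(test_idx) == 0L) next
    train_idx <- setdiff(seq_len(n), test_idx)
    counts <- fit_go_counts(records[train_idx, , drop = FALSE],
                            if (is.null(annotations)) list() else annotations)
    X <- finalize_features(feats, counts, annotations)
    model <- train_sap_model(X[train_idx, , drop = FALSE],
                             records$label[train_idx], C = C, gamma = gamma,
                             variant = feats$variant, seed = seed + f)
    pred <- predict_sap(model, X[test_idx, , drop = FALSE])
    o_d[test_idx] <- pred$o_d
    fold_of[test_idx] <- f
  }
  predictions <- cbind(records,
                       data.frame(o_d = o_d,
                                  class = ifelse(o_d >= 0.5, "disease",
                                                 "neutral"),
                                  ri = reliability_index(o_d),
                                  fold = fold_of,
                                  stringsAsFactors = FALSE))
  metrics <- compute_metrics(o_d, records$label, predictions$class)
  list(predictions = predictions, metrics = metrics, plan = plan,
       params = list(k = as.integer(k), seed = as.integer(seed),
                     C = C, gamma = gamma, variant = feats$variant))
}
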
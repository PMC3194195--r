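# Feature-vector assembly and the RBF-kernel classifier.
#
# The structure variant ("3d") concatenates Mut(20) + StructureEnv(21) +
# Prof(5) + PANTHER(4) + GO(2) = 52 elements; the sequence variant ("seq")
# replaces the 21-element structural environment with the 20-element
# sequence-window composition, giving 51. Feature order is fixed and
# enforced.

FEATURE_BLOCKS <- list(
  `3d` = c(mut = 20L, env = 21L, prof = 5L, panther = 4L, go = 2L),
  seq = c(mut = 20L, env = 20L, prof = 5L, panther = 4L, go = 2L)
)

#' Assemble one feature vector
#'
#' Concatenates the feature blocks in the fixed order: mutation encoding,
#' environment (structural or sequence, by variant), profile, family
#' scores, GO pair.
#'
#' @param mut_enc 20-element mutation encoding ([encode_mutation()]).
#' @param env 21-element structural environment (`variant = "3d"`) or
#'   20-element sequence window ([sequence_window_counts()],
#'   `variant = "seq"`).
#' @param prof 5-element profile block ([profile_features()]).
#' @param panther 4-element family block ([panther_features()]).
#' @param go 2-element GO block ([go_feature_pair()]).
#' @param variant `"3d"` (52 elements) or `"seq"` (51 elements).
#' @return Numeric vector of length 52 (`3d`) or 51 (`seq`).
#' @export
assemble_vector <- function(mut_enc, env, prof, panther, go,
                            variant = c("3d", "seq")) {
  variant <- match.arg(variant)
  spec <- FEATURE_BLOCKS[[variant]]
  blocks <- list(mut = mut_enc, env = env, prof = prof,
                 panther = panther, go = go)
  for (nm in names(spec)) {
    if (length(blocks[[nm]]) != spec[[nm]])
      stop(sprintf("block '%s' has length %d, expected %d (variant %s)",
                   nm, length(blocks[[nm]]), spec[[nm]], variant),
           call. = FALSE)
  }
  v <- as.numeric(unlist(blocks, use.names = FALSE))
  if (any(!is.finite(v))) stop("non-finite feature value", call. = FALSE)
  names(v) <- feature_names(variant)
  v
}

#' Feature names of a variant
#' @param variant `"3d"` or `"seq"`.
#' @return Character vector of column names (length 52 or 51).
#' @export
feature_names <- function(variant = c("3d", "seq")) {
  variant <- match.arg(variant)
  env <- if (variant == "3d") c(paste0("env_", AA_THREE), "env_RSA")
         else paste0("win_", AA_THREE)
  c(paste0("mut_", AA_THREE), env,
    c("F_W", "F_N", "N_T", "N_S", "CI"),
    c("P_D", "P_W", "P_N", "N_IC"),
    c("N_GO", "LGO"))
}

# ---- feature rescaling ------------------------------------------------------

#' Fit per-feature linear rescaling to \[-1, 1\]
#'
#' Computes training min/max per column; [apply_scaling()] maps the training
#' minimum to -1 and maximum to +1 without clipping, so held-out values
#' outside the training range map outside \[-1, 1\]. Constant features map
#' to 0.
#'
#' @param X Numeric matrix (rows = mutations, columns = features).
#' @return A `FeatureScaling`: list with `min`, `max`.
#' @export
fit_scaling <- function(X) {
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "FeatureScaling")
}

#' Apply a fitted rescaling
#' @param scaling A `FeatureScaling`.
#' @param X Numeric matrix or vector with the same feature layout.
#' @return Rescaled matrix/vector.
#' @export
apply_scaling <- function(scaling, X) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1)
  rng <- scaling$max - scaling$min
  const <- rng == 0
  Xs <- sweep(sweep(X, 2, scaling$min), 2,
              ifelse(const, 1, rng / 2), "/") - 1
  Xs[, const] <- 0
  if (vec) Xs[1, ] else Xs
}

# ---- classifier -------------------------------------------------------------

MODEL_VERSION <- 1L

#' Train the RBF-kernel classifier
#'
#' Fits a soft-margin support vector machine with a radial basis function
#' kernel `K(x_i, x_j) = exp(-gamma ||x_i - x_j||^2)` and Platt-style
#' probability calibration (via libsvm through \pkg{e1071}). The defaults
#' `C = 8` and `gamma = 0.03125` are the grid-search optimum for rescaled
#' 52-element inputs. Feature rescaling is fitted here on the training data
#' only and stored with the model. Deterministic given `seed` (the
#' calibration's internal cross-validation is seeded).
#'
#' @param X Numeric feature matrix (unscaled).
#' @param labels Character/factor vector in `{disease, neutral}`.
#' @param C Soft-margin cost.
#' @param gamma RBF kernel width.
#' @param variant `"3d"` or `"seq"` (metadata and input-length contract).
#' @param seed Integer RNG seed.
#' @return A `TrainedModel`: list with the fitted svm, `scaling`, `variant`,
#'   `C`, `gamma`, `seed`, training class counts and `version`.
#' @export
train_sap_model <- function(X, labels, C = 8, gamma = 0.03125,
                            variant = c("3d", "seq"), seed = 1L) {
  variant <- match.arg(variant)
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("disease", "neutral")))
  if (length(unique(labels)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  if (ncol(X) != sum(FEATURE_BLOCKS[[variant]]))
    stop(sprintf("expected %d features for variant %s, got %d",
                 sum(FEATURE_BLOCKS[[variant]]), variant, ncol(X)),
         call. = FALSE)
  scaling <- fit_scaling(X)
  Xs <- apply_scaling(scaling, X)
  y <- factor(labels, levels = c("disease", "neutral"))
  set.seed(seed)
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = C, gamma = gamma,
                    probability = TRUE, scale = FALSE)
  structure(list(fit = fit, scaling = scaling, variant = variant,
                 C = C, gamma = gamma, seed = as.integer(seed),
                 n_train = c(disease = sum(y == "disease"),
                             neutral = sum(y == "neutral")),
                 version = MODEL_VERSION),
            class = "TrainedModel")
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf(
    "TrainedModel (variant %s): C=%g gamma=%g, trained on %d disease / %d neutral\n",
    x$variant, x$C, x$gamma, x$n_train["disease"], x$n_train["neutral"]))
  invisible(x)
}

#' Predict disease probability, class, and reliability index
#'
#' Applies the stored rescaling and the calibrated classifier. The
#' reliability index maps the disease probability `O_D` to a 0-10 scale:
#' `RI = 20 * |O_D - 0.5|`. The class is `disease` when `O_D >= 0.5` (ties
#' resolve to disease — the conservative call for a pathogenicity screen).
#'
#' @param model A `TrainedModel`.
#' @param X Feature matrix or single vector (unscaled, same layout as
#'   training).
#' @return Data frame with columns `o_d`, `class`, `ri`.
#' @export
predict_sap <- function(model, X) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1)
  want <- sum(FEATURE_BLOCKS[[model$variant]])
  if (ncol(X) != want)
    stop(sprintf("feature length %d does not match model variant %s (%d)",
                 ncol(X), model$variant, want), call. = FALSE)
  Xs <- apply_scaling(model$scaling, X)
  pr <- stats::predict(model$fit, Xs, probability = TRUE)
  o_d <- attr(pr, "probabilities")[, "disease"]
  data.frame(o_d = unname(o_d),
             class = ifelse(o_d >= 0.5, "disease", "neutral"),
             ri = reliability_index(o_d),
             stringsAsFactors = FALSE)
}

#' Reliability index of a disease probability
#'
#' `RI = 20 * |O_D - 0.5|`, ranging from 0 (maximally uncertain) to 10
#' (maximally confident).
#'
#' @param o_d Disease probability in \[0, 1\].
#' @return Numeric in \[0, 10\].
#' @export
reliability_index <- function(o_d) {
  stopifnot(all(o_d >= 0 & o_d <= 1))
  20 * abs(o_d - 0.5)
}

#' Save / load a trained model
#'
#' The archive is a versioned RDS file; loading refuses archives written by
#' an incompatible model version.
#'
#' @param model A `TrainedModel`.
#' @param path Archive path.
#' @return `save_sap_model`: invisibly, `path`. `load_sap_model`: the model.
#' @export
save_sap_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sap_model
#' @export
load_sap_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "TrainedModel") ||
      !identical(model$version, MODEL_VERSION))
    stop("incompatible or corrupt model archive", call. = FALSE)
  model
}
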
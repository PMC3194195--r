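test_that("assembled vectors have the contracted lengths and block order", {
  menc <- encode_mutation("A", "V")
  env3d <- c(rep(0, 20), 35)
  win <- rep(0, 20)
  prof <- c(F_W = 0.5, F_N = 0.1, N_T = 10, N_S = 9, CI = 0.3)
  pf <- c(P_D = 0.5, P_W = 0, P_N = 0, N_IC = 0)
  go <- c(N_GO = 3, LGO = -0.2)

  v3 <- assemble_vector(menc, env3d, prof, pf, go, "3d")
  expect_length(v3, 52L)
  vs <- assemble_vector(menc, win, prof, pf, go, "seq")
  expect_length(vs, 51L)

  # fixed block order: Mut, Environment, Prof, PANTHER, GO
  expect_equal(unname(v3[1:20]), unname(menc))
  expect_equal(unname(v3[21:41]), env3d)
  expect_equal(unname(v3[42:46]), unname(prof))
  expect_equal(unname(v3[47:50]), unname(pf))
  expect_equal(unname(v3[51:52]), unname(go))
  expect_equal(names(v3), feature_names("3d"))

  # zeroed blocks leave only the substitution's +-1 pair
  vz <- assemble_vector(menc, rep(0, 21), rep(0, 5), rep(0, 4), rep(0, 2),
                        "3d")
  expect_equal(sum(vz != 0), 2L)

  expect_error(assemble_vector(menc, rep(0, 20), prof, pf, go, "3d"),
               "block 'env'")
})

test_that("rescaling maps the training range onto [-1, 1] without clipping", {
  X <- cbind(a = c(0, 5, 10), b = c(-2, 0, 2), const = c(7, 7, 7))
  sc <- fit_scaling(X)
  Xs <- apply_scaling(sc, X)
  expect_equal(Xs[, "a"], c(-1, 0, 1))
  expect_equal(Xs[, "b"], c(-1, 0, 1))
  expect_equal(Xs[, "const"], c(0, 0, 0))
  held_out <- apply_scaling(sc, c(20, -4, 7))
  expect_equal(unname(held_out), c(3, -2, 0))
})

test_that("the classifier separates a separable toy problem and is seeded", {
  set.seed(10)
  n <- 40
  X <- matrix(rnorm(n * 52, sd = 0.2), n, 52)
  X[1:(n / 2), 1] <- X[1:(n / 2), 1] + 5  # wide margin on feature 1
  y <- rep(c("disease", "neutral"), each = n / 2)
  m <- train_sap_model(X, y, seed = 3)
  pred <- predict_sap(m, X)
  expect_equal(mean(pred$class == y), 1.0)

  m2 <- train_sap_model(X, y, seed = 3)
  expect_identical(predict_sap(m2, X)$o_d, pred$o_d)

  expect_error(train_sap_model(X, rep("disease", n)), "single class")
  expect_error(predict_sap(m, X[, 1:51]), "does not match")
})

test_that("reliability index follows RI = 20|O_D - 0.5|", {
  expect_equal(reliability_index(0.5), 0)
  expect_equal(reliability_index(1.0), 10)
  expect_equal(reliability_index(0.0), 10)
  expect_equal(reliability_index(0.8), 6.0)
})

test_that("model archives round-trip and refuse incompatible versions", {
  set.seed(11)
  X <- matrix(rnorm(20 * 51), 20, 51)
  y <- rep(c("disease", "neutral"), 10)
  m <- train_sap_model(X, y, variant = "seq", seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_sap_model(m, f)
  m2 <- load_sap_model(f)
  expect_identical(predict_sap(m2, X)$o_d, predict_sap(m, X)$o_d)
  bad <- m; bad$version <- 99L
  saveRDS(bad, f)
  expect_error(load_sap_model(f), "incompatible")
})

test_that("metrics reproduce the hand-evaluated confusion arithmetic", {
  # confusion for class disease: p=40, n=30, u=10, o=20
  labels <- c(rep("disease", 50), rep("neutral", 50))
  pred <- c(rep("disease", 40), rep("neutral", 10),
            rep("disease", 20), rep("neutral", 30))
  o_d <- ifelse(pred == "disease", 0.9, 0.1)
  m <- compute_metrics(o_d, labels, pred)
  expect_equal(m$q2, 0.70)
  expect_equal(m$mcc, 1000 / sqrt(50 * 60 * 40 * 50), tolerance = 1e-12)
  expect_equal(m$s_d, 40 / 50)
  expect_equal(m$p_d, 40 / 60)
  expect_equal(m$s_n, 30 / 50)
  expect_equal(m$p_n, 30 / 40)

  perfect <- compute_metrics(c(0.9, 0.9, 0.1), c("disease", "disease",
                                                 "neutral"))
  expect_equal(perfect$q2, 1); expect_equal(perfect$mcc, 1)
  expect_equal(perfect$auc, 1)

  onesided <- compute_metrics(rep(0.9, 4), c("disease", "disease",
                                             "neutral", "disease"))
  expect_equal(onesided$mcc, 0)
  expect_equal(onesided$s_d, 1)
  expect_true("C" %in% onesided$degenerate)
})

test_that("Matthews C equals the Pearson correlation of binary vectors", {
  set.seed(12)
  checked <- 0
  while (checked < 1000) {
    n <- sample(10:60, 1)
    labels <- sample(c("disease", "neutral"), n, replace = TRUE)
    pred <- sample(c("disease", "neutral"), n, replace = TRUE)
    r <- suppressWarnings(cor(as.numeric(labels == "disease"),
                              as.numeric(pred == "disease")))
    m <- compute_metrics(ifelse(pred == "disease", 0.9, 0.1), labels, pred)
    if (is.na(r)) {
      expect_equal(m$mcc, 0)
    } else {
      expect_equal(m$mcc, r, tolerance = 1e-12)
    }
    checked <- checked + 1
  }
})

test_that("rank-statistic AUC equals trapezoidal ROC integration", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(20:100, 1)
    labels <- sample(c("disease", "neutral"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    o_d <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    roc <- roc_points(o_d, labels)
    trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_equal(auc_rank(o_d, labels), trap, tolerance = 1e-9)
  }
})

test_that("reverse balancing doubles neutrals and preserves disease rows", {
  df <- data.frame(protein_id = c("P1", "P1", "P2"), chain_id = "A",
                   position = c(10L, 11L, 5L), wt = c("A", "C", "G"),
                   mut = c("V", "S", "R"),
                   label = c("neutral", "disease", "neutral"),
                   stringsAsFactors = FALSE)
  b <- balance_with_reverse(df)
  expect_equal(sum(b$label == "disease"), 1L)
  expect_equal(sum(b$label == "neutral"), 4L)
  rev1 <- b[b$reversed & b$position == 10L, ]
  expect_equal(rev1$wt, "V"); expect_equal(rev1$mut, "A")

  empty <- df[0, ]
  expect_equal(nrow(balance_with_reverse(empty)), 0L)

  fix <- small_fixture()
  b2 <- balance_with_reverse(fix$mutations)
  expect_equal(sum(b2$label == "neutral"),
               2L * sum(fix$mutations$label == "neutral"))
  expect_equal(sum(b2$label == "disease"),
               sum(fix$mutations$label == "disease"))
})

test_that("identity clustering is single-linkage at 30%/0.9 coverage", {
  set.seed(14)
  base <- paste(sample(aa_order(FALSE), 100, replace = TRUE), collapse = "")
  mutate_seq <- function(s, frac) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), round(frac * length(ch)))
    ch[idx] <- vapply(ch[idx], function(q)
      sample(setdiff(aa_order(FALSE), q), 1), character(1))
    paste(ch, collapse = "")
  }
  A <- base
  B <- mutate_seq(A, 0.55)           # ~45% identity to A
  C <- mutate_seq(B, 0.55)           # linked to B, distant from A
  D <- paste(sample(aa_order(FALSE), 100, replace = TRUE), collapse = "")

  cl <- cluster_proteins(c(A = A, B = B, C = C, D = D))
  expect_equal(cl[["A"]], cl[["B"]])
  expect_equal(cl[["B"]], cl[["C"]])
  expect_false(cl[["A"]] == cl[["D"]])

  two <- cluster_proteins(c(x = A, y = A))
  expect_equal(unname(two), c(1L, 1L))
})

test_that("fold plans partition the data and never split a cluster", {
  df <- data.frame(protein_id = rep(paste0("P", 1:8), each = 3),
                   label = rep(c("disease", "neutral"), 12),
                   stringsAsFactors = FALSE)
  clusters <- setNames(1:8, paste0("P", 1:8))

  # leave-one-protein-out when every protein is its own cluster and k = n
  plan <- make_folds(df, clusters, k = 8, seed = 1)
  expect_length(plan$folds, 8L)
  for (f in plan$folds)
    expect_length(unique(df$protein_id[f]), 1L)

  # partition property
  expect_setequal(unlist(plan$folds), seq_len(nrow(df)))

  # planted 2-cluster input with k = 2: each cluster wholly in one fold
  clusters2 <- setNames(c(1, 1, 1, 1, 2, 2, 2, 2), paste0("P", 1:8))
  plan2 <- make_folds(df, clusters2, k = 2, seed = 1)
  for (f in plan2$folds)
    expect_length(unique(clusters2[df$protein_id[f]]), 1L)

  expect_error(make_folds(df, clusters, k = 9), "exceeds")
})

test_that("no homology cluster spans train and test in any fold", {
  fix <- small_fixture()
  cl <- small_clusters()
  plan <- make_folds(fix$mutations, cl, k = 10, seed = 2)
  cl_of_row <- cl[fix$mutations$protein_id]
  for (f in seq_along(plan$folds)) {
    test_cl <- unique(cl_of_row[plan$folds[[f]]])
    train_cl <- unique(cl_of_row[-plan$folds[[f]]])
    expect_length(intersect(test_cl, train_cl), 0L)
  }
})

test_that("cross-validation is deterministic and leakage-free", {
  feats <- small_features("3d")
  fix <- small_fixture()
  cl <- small_clusters()
  prop <- propagate_annotations(fix$ontology, fix$annotations)

  cv1 <- cross_validate(feats, cl, prop, k = 5, seed = 7)
  cv2 <- cross_validate(feats, cl, prop, k = 5, seed = 7)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$metrics, cv2$metrics)

  # scaling fitted on training rows is invariant to test-fold content
  X <- finalize_features(feats, fit_go_counts(fix$mutations, prop), prop)
  tr <- cv1$plan$folds[[1]]
  sc1 <- fit_scaling(X[-tr, , drop = FALSE])
  Xperm <- X
  Xperm[tr, ] <- X[rev(tr), ]
  sc2 <- fit_scaling(Xperm[-tr, , drop = FALSE])
  expect_identical(sc1, sc2)
})

test_that("reliability filtering trades coverage for accuracy consistently", {
  set.seed(15)
  n <- 200
  o_d <- runif(n)
  labels <- ifelse(runif(n) < o_d, "disease", "neutral")
  pred <- data.frame(o_d = o_d,
                     class = ifelse(o_d >= 0.5, "disease", "neutral"),
                     ri = reliability_index(o_d))
  rc <- reliability_curve(pred, labels)
  expect_equal(nrow(rc), 10L)
  expect_equal(rc$coverage[1], mean(pred$ri > 0))
  expect_true(all(diff(rc$coverage) <= 0))
  # matches direct re-filtering at threshold 5
  keep <- pred$ri > 5
  direct <- compute_metrics(o_d[keep], labels[keep], pred$class[keep])
  expect_equal(rc$q2[rc$threshold == 5], direct$q2)
  expect_equal(rc$mcc[rc$threshold == 5], direct$mcc)
})

test_that("RSA stratification uses equal-width bins that cover the data", {
  set.seed(16)
  n <- 300
  rsa <- runif(n, 0, 100)
  labels <- ifelse(rsa < 30, "disease", "neutral")
  o_d <- ifelse(labels == "disease", 0.8, 0.3)
  pred <- data.frame(o_d = o_d,
                     class = ifelse(o_d >= 0.5, "disease", "neutral"))
  st <- stratify_by_rsa(pred, labels, rsa)
  expect_equal(nrow(st), 10L)
  expect_equal(st$rsa_lo, seq(0, 90, 10))
  expect_equal(sum(st$n), n)
  expect_equal(sum(st$n_disease) + sum(st$n_neutral), n)

  all_buried <- stratify_by_rsa(pred, labels, rep(0, n))
  expect_equal(all_buried$n[1], n)
  expect_true(all(all_buried$n[-1] == 0))
})

test_that("the function holdout is disjoint and purges near-identical homologs", {
  ont <- new_ontology(c("root", "kin", "kin_sub", "other"),
                      c("kin", "kin_sub", "other"),
                      c("root", "kin", "root"))
  seqs <- c(
    K1 = strrep("ACDEFGHIKL", 10),
    T1 = paste0(strrep("ACDEFGHIKL", 9), "ACDEFGHIKW", collapse = ""),
    U1 = paste(rep("WYWVRNDCQE", 10), collapse = "")
  )
  ann <- list(K1 = "kin_sub", T1 = "other", U1 = "other")
  mut <- data.frame(protein_id = c("K1", "T1", "U1"), chain_id = "A",
                    position = c(5L, 6L, 7L), wt = c("F", "G", "V"),
                    mut = c("L", "A", "I"),
                    label = c("disease", "neutral", "disease"),
                    stringsAsFactors = FALSE)
  # annotating with a descendant selects the protein via propagation
  ho <- holdout_by_function(mut, ann, ont, "kin", sequences = seqs)
  expect_equal(ho$test$protein_id, "K1")
  expect_false(any(ho$train$protein_id %in% ho$test$protein_id))
  # T1 is ~99% identical to K1 -> purged from training
  expect_true("T1" %in% ho$removed_proteins)
  expect_equal(ho$train$protein_id, "U1")
  # the selecting subtree is blanked from test-set annotations
  expect_false("kin" %in% ho$annotations_test$K1)
  expect_false("kin_sub" %in% ho$annotations_test$K1)

  none <- holdout_by_function(mut, ann, ont, "root", sequences = NULL)
  expect_equal(nrow(none$test), 3L)  # root is ancestral to everything

  # a term no protein carries (even after propagation) -> empty test set
  iso <- new_ontology(c("a", "b", "c"), "a", "b")
  ho2 <- holdout_by_function(mut, list(K1 = "a", T1 = "a", U1 = "a"),
                             iso, "c", sequences = NULL)
  expect_equal(nrow(ho2$test), 0L)
  expect_equal(nrow(ho2$train), 3L)
})
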
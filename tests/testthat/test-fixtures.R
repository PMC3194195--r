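test_that("synthetic structures are deterministic and geometrically sane", {
  h1 <- make_structure(20, "helix", seed = 4)
  h2 <- make_structure(20, "helix", seed = 4)
  expect_identical(write_pdb(h1), write_pdb(h2))

  ca <- h1$atoms[h1$atoms$name == "CA", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(abs(d - 3.8) < 0.1))

  expect_error(make_structure(0, "helix"), "n_residues")
})

test_that("a compact globule buries residues", {
  g <- make_structure(50, "globule", seed = 6)
  rsa <- rsa_profile(g, n_points = 480)
  expect_true(any(rsa < 20))
})

test_that("alignment generator respects per-column conservation", {
  q <- strrep("ACDEFGHIKL", 3)
  full <- make_alignment(q, 10, conservation = 1, seed = 5)
  expect_true(all(full$rows == q))

  # at conservation 0 every non-query row draws from the other 19 types
  mixed <- make_alignment(strrep("A", 40), 1000,
                          conservation = c(rep(0, 20), rep(1, 20)), seed = 5)
  mat <- do.call(rbind, strsplit(mixed$rows[-1], ""))
  expect_true(all(mat[, 21:40] == "A"))
  expect_true(all(mat[, 1:20] != "A"))
  # non-query residues appear uniformly (1/19 each) at free columns
  freq_v <- mean(mat[, 1:20] == "V")
  expect_lt(abs(freq_v - 1 / 19), 0.01)

  # conservation raises the conservation index
  set.seed(55)
  q <- paste(sample(aa_order(FALSE), 40, replace = TRUE), collapse = "")
  aln <- make_alignment(q, 50, conservation = c(rep(0, 20), rep(1, 20)),
                        seed = 5)
  expect_gt(conservation_index(aln, 30), conservation_index(aln, 10))
})

test_that("the GO world plants enrichment at the marked term", {
  prone <- rep(c(TRUE, FALSE), each = 100)
  null_w <- make_go_world(40, 200, enrichment_odds = 1,
                          disease_prone = prone, seed = 8)
  has_marked <- vapply(null_w$annotations, function(a)
    null_w$marked_term %in% a, logical(1))
  expect_lt(abs(mean(has_marked[prone]) - mean(has_marked[!prone])), 0.15)

  enr <- make_go_world(40, 200, enrichment_odds = 8,
                       disease_prone = prone, seed = 8)
  train <- data.frame(
    protein_id = names(enr$annotations),
    label = ifelse(prone, "disease", "neutral"),
    stringsAsFactors = FALSE)
  prop <- propagate_annotations(enr$ontology, enr$annotations)
  cts <- fit_go_counts(train, prop)
  expect_gt(lgo_score(enr$marked_term, cts), 0)
})

test_that("a null-effect dataset has no class RSA gap", {
  cfg <- fixture_config(seed = 31, n_proteins = 20L, n_residues = 40L,
                        n_mutations = 300L, delta_rsa = 0,
                        sasa_points = 240L)
  fix <- make_labeled_dataset(cfg)
  expect_lt(abs(fix$manifest$realized_rsa_gap), 3)
})

test_that("the planted RSA gap tracks the requested effect size", {
  cfg <- fixture_config(seed = 32, n_proteins = 40L, n_residues = 60L,
                        n_mutations = 600L, delta_rsa = 15,
                        sasa_points = 240L)
  fix <- make_labeled_dataset(cfg)
  expect_lt(abs(fix$manifest$realized_rsa_gap - 15), 3)
  # measured on the mutation table itself via the pipeline's RSA
  rsa_of <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i)
      fix$rsa[[rows$protein_id[i]]][[as.character(rows$position[i])]],
      numeric(1))
  }
  gap <- mean(rsa_of(fix$mutations[fix$mutations$label == "neutral", ])) -
    mean(rsa_of(fix$mutations[fix$mutations$label == "disease", ]))
  expect_lt(abs(gap - 15), 3)
})

test_that("regeneration from the same config is byte-identical", {
  cfg <- fixture_config(seed = 33, n_proteins = 8L, n_residues = 30L,
                        n_mutations = 40L, sasa_points = 240L)
  f1 <- make_labeled_dataset(cfg)
  f2 <- make_labeled_dataset(cfg)
  expect_identical(f1$mutations, f2$mutations)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(write_pdb(f1$structures[[1]]),
                   write_pdb(f2$structures[[1]]))
  expect_identical(f1$alignments[[3]]$rows, f2$alignments[[3]]$rows)
})

test_that("every generated artifact parses back through the readers", {
  cfg <- fixture_config(seed = 34, n_proteins = 6L, n_residues = 45L,
                        n_mutations = 30L, sasa_points = 240L)
  fix <- make_labeled_dataset(cfg)
  dir <- withr::local_tempdir()
  expect_no_warning(write_fixture_dir(fix, dir))

  mut <- read_mutation_table(file.path(dir, "mutations.tsv"))
  expect_equal(nrow(mut), 30L)
  st <- read_pdb(file.path(dir, "structures", "P1.pdb"), "A", id = "P1")
  expect_equal(structure_sequence(st), unname(fix$sequences["P1"]))
  aln <- read_alignment(file.path(dir, "alignments", "P2.fasta"))
  expect_identical(aln$rows, fix$alignments[["P2"]]$rows)
  ont <- read_obo_lite(file.path(dir, "ontology.obo"))
  expect_setequal(ont$terms, fix$ontology$terms)
  ann <- read_annotations(file.path(dir, "annotations.tsv"), ont)
  expect_setequal(ann$P1, fix$annotations$P1)
  acc <- read_accessibility(file.path(dir, "accessibility.tsv"))
  expect_true(all(acc$asa >= 0))

  # the manifest records the seed and effect sizes plus file checksums
  man <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("^seed = 34$", man)))
  expect_true(any(grepl("^delta_rsa = ", man)))
  expect_true(any(grepl("^md5 ", man)))
})

test_that("feature tables round-trip losslessly through TSV", {
  fix <- small_fixture()
  feats <- small_features("3d")
  prop <- propagate_annotations(fix$ontology, fix$annotations)
  cts <- fit_go_counts(fix$mutations, prop)
  X <- finalize_features(feats, cts, prop)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(X, fix$mutations, f)
  back <- read_feature_table(f, "3d")
  expect_equal(unname(back$X), unname(X), tolerance = 1e-15)
  expect_equal(back$records$protein_id, fix$mutations$protein_id)
})
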
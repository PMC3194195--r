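# Builders for small synthetic test objects and independent brute-force
# oracles. Everything here is generated in code; no stored fixtures.

# Build a StructureModel directly from per-residue atom lists.
# residues: list of list(type = "GLY", atoms = matrix(xyz, ncol = 3)),
# first atom of each residue is its C-alpha.
toy_structure <- function(residues, id = "toy", chain = "A") {
  n <- length(residues)
  res_df <- data.frame(
    ordinal = seq_len(n), resno = seq_len(n), insert = "",
    type = vapply(residues, `[[`, character(1), "type"),
    stringsAsFactors = FALSE
  )
  res_df$aa <- unname(setNames(aa_order(FALSE), aa_order())[res_df$type])
  atom_rows <- lapply(seq_len(n), function(i) {
    xyz <- residues[[i]]$atoms
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
    nm <- c("CA", paste0("C", seq_len(max(0, nrow(xyz) - 1L)) + 1L))
    data.frame(ordinal = i, name = nm[seq_len(nrow(xyz))], element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = 1.7,
               stringsAsFactors = FALSE)
  })
  structure(list(id = id, chain_id = chain, residues = res_df,
                 atoms = do.call(rbind, atom_rows), resolution = NA_real_),
            class = "StructureModel")
}

# random toy structure: n residues, 1-3 heavy atoms each, coords in a box
random_toy_structure <- function(n, seed, box = 15) {
  set.seed(seed)
  types <- sample(aa_order(), n, replace = TRUE)
  residues <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    list(type = types[i],
         atoms = matrix(runif(3 * k, 0, box), ncol = 3))
  })
  toy_structure(residues)
}

# brute-force shell histogram: O(n * m) all-pairs scan
brute_shell_counts <- function(struct, center, radius) {
  at <- struct$atoms
  ca <- at[at$ordinal == center & at$name == "CA", ]
  counts <- setNames(integer(20), aa_order())
  for (j in struct$residues$ordinal) {
    if (j == center) next
    aj <- at[at$ordinal == j, ]
    d <- sqrt((aj$x - ca$x)^2 + (aj$y - ca$y)^2 + (aj$z - ca$z)^2)
    if (any(d <= radius)) {
      ty <- struct$residues$type[struct$residues$ordinal == j]
      counts[ty] <- counts[ty] + 1L
    }
  }
  counts
}

# brute-force conservation index: explicit double loop over rows/columns
brute_ci <- function(aln, position) {
  rows <- strsplit(aln$rows, "")
  qc <- rows[[aln$query]]
  nongap <- which(qc != "-")
  col <- nongap[position]
  aa1 <- aa_order(FALSE)
  colchars <- vapply(rows, `[[`, character(1), col)
  colchars <- colchars[colchars %in% aa1]
  fi <- vapply(aa1, function(a) mean(colchars == a), numeric(1))
  allchars <- unlist(rows)
  allchars <- allchars[allchars %in% aa1]
  f <- vapply(aa1, function(a) mean(allchars == a), numeric(1))
  sqrt(sum((fi - f)^2))
}

# hand-written minimal PDB text (one string per line)
toy_pdb_lines <- function() {
  c(
    "HEADER    TOY PROTEIN",
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "TER",
    "END"
  )
}

# a small balanced labeled fixture shared across protocol tests (cached)
.small_fix_env <- new.env()
small_fixture <- function() {
  if (is.null(.small_fix_env$fix)) {
    cfg <- fixture_config(seed = 11, n_proteins = 30L, n_residues = 50L,
                          n_mutations = 160L, delta_rsa = 15,
                          sasa_points = 240L)
    .small_fix_env$fix <- make_labeled_dataset(cfg)
  }
  .small_fix_env$fix
}

small_features <- function(variant = "3d") {
  key <- paste0("feats_", variant)
  if (is.null(.small_fix_env[[key]])) {
    fix <- small_fixture()
    .small_fix_env[[key]] <- extract_features(
      fix$mutations, fix$sequences, fix$alignments,
      if (variant == "3d") fix$structures, variant = variant,
      sasa = fix$sasa)
  }
  .small_fix_env[[key]]
}

small_clusters <- function() {
  if (is.null(.small_fix_env$clusters)) {
    .small_fix_env$clusters <- cluster_proteins(small_fixture()$sequences)
  }
  .small_fix_env$clusters
}
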
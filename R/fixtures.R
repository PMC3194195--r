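# Synthetic fixture generation. Produces every input the pipeline consumes
# (structures, sequences, alignments, ontology, annotations, labeled
# mutation tables) with controllable planted contrasts: a burial (RSA) gap
# between disease and neutral mutations, a conservation gap, a GO enrichment
# odds, and a Cys-Cys contact-loss bias. All generators are pure functions
# of (config, seed).

#' Generate a synthetic structure
#'
#' Builds a chain of `n_residues` with C-alpha (and, except glycine,
#' C-beta) atoms in one of two geometries: an ideal alpha-helix (1.5
#' Angstrom rise, 100 degree twist, consecutive C-alpha separation ~3.8
#' Angstrom) or a compact globule (jittered space-filling cluster at
#' 3.8 Angstrom lattice spacing, filled from the core outwards so the chain
#' has genuinely buried and exposed residues).
#'
#' @param n_residues Number of residues (>= 1).
#' @param geometry `"helix"` or `"globule"`.
#' @param seed Integer seed.
#' @param sequence Optional one-letter sequence (random when `NULL`).
#' @param id,chain Identifiers stored on the model.
#' @return A `StructureModel`.
#' @export
make_structure <- function(n_residues, geometry = c("helix", "globule"),
                           seed = 1L, sequence = NULL, id = "synth",
                           chain = "A") {
  geometry <- match.arg(geometry)
  if (n_residues < 1L) stop("n_residues must be >= 1", call. = FALSE)
  set.seed(seed)
  if (is.null(sequence)) {
    sequence <- paste(sample(AA_ONE, n_residues, replace = TRUE),
                      collapse = "")
  }
  stopifnot(nchar(sequence) == n_residues)
  aa <- strsplit(sequence, "")[[1]]
  .validate_aa1(aa)

  if (geometry == "helix") {
    i <- seq_len(n_residues) - 1L
    theta <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    cb <- cbind(3.8 * cos(theta), 3.8 * sin(theta), 1.5 * i)
  } else {
    # cubic lattice filled from the centre outwards, then jittered
    a <- 3.8
    m <- ceiling((n_residues * 3 / 4)^(1 / 3)) + 2L
    g <- expand.grid(x = -m:m, y = -m:m, z = -m:m)
    g <- g[order(g$x^2 + g$y^2 + g$z^2), ]
    g <- g[seq_len(n_residues), ] * a
    ca <- as.matrix(g) + matrix(stats::rnorm(3 * n_residues, sd = 0.3),
                                ncol = 3)
    dimnames(ca) <- NULL
    # side-chain stub pointing away from the centroid
    cen <- colMeans(ca)
    dirs <- sweep(ca, 2, cen)
    nrm <- sqrt(rowSums(dirs^2)); nrm[nrm == 0] <- 1
    cb <- ca + 1.5 * dirs / nrm
  }

  has_cb <- aa != "G"
  n_atoms <- n_residues + sum(has_cb)
  ordinal <- c(seq_len(n_residues), which(has_cb))
  name <- c(rep("CA", n_residues), rep("CB", sum(has_cb)))
  xyz <- rbind(ca, cb[has_cb, , drop = FALSE])
  ord <- order(ordinal, match(name, c("CA", "CB")))
  atoms <- data.frame(ordinal = ordinal[ord], name = name[ord],
                      element = "C", x = xyz[ord, 1], y = xyz[ord, 2],
                      z = xyz[ord, 3], radius = unname(VDW_RADII["C"]),
                      stringsAsFactors = FALSE)
  residues <- data.frame(ordinal = seq_len(n_residues),
                         resno = seq_len(n_residues), insert = "",
                         type = .aa1_to3(aa), aa = aa,
                         stringsAsFactors = FALSE)
  structure(list(id = id, chain_id = chain, residues = residues,
                 atoms = atoms, resolution = NA_real_),
            class = "StructureModel")
}

#' Generate a synthetic alignment around a query
#'
#' Rows are sampled column-wise: with probability equal to the column's
#' conservation level the query residue is kept, otherwise a residue is
#' drawn uniformly from the other 19 types. The query is row 1; the
#' alignment is gapless.
#'
#' @param query Query sequence (one-letter string).
#' @param n_rows Total number of rows including the query.
#' @param conservation Scalar or per-column vector of conservation levels in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return A `SapAlignment`.
#' @export
make_alignment <- function(query, n_rows, conservation = 0.5, seed = 1L) {
  set.seed(seed)
  L <- nchar(query)
  qc <- strsplit(query, "")[[1]]
  cons <- rep_len(conservation, L)
  stopifnot(all(cons >= 0 & cons <= 1), n_rows >= 1L)
  rows <- character(n_rows)
  rows[1] <- query
  if (n_rows > 1L) {
    for (r in 2:n_rows) {
      keep <- stats::runif(L) < cons
      chars <- qc
      if (any(!keep)) {
        chars[!keep] <- vapply(qc[!keep], function(q)
          sample(setdiff(AA_ONE, q), 1L), character(1))
      }
      rows[r] <- paste(chars, collapse = "")
    }
  }
  new_alignment(rows, ids = c("query", paste0("hom", seq_len(n_rows - 1L))),
                query = 1L)
}

#' Generate a random ontology and class-linked annotations
#'
#' Builds a random tree ontology of `n_terms` terms (term 1 is the root)
#' and annotates proteins with a few random terms each. One mid-tree
#' "marked" term is associated with disease-prone proteins at the given
#' odds multiplier: proteins flagged disease-prone carry the marked term
#' with odds `enrichment_odds` times the baseline. At odds 1 the marked
#' term is label-independent.
#'
#' @param n_terms Number of terms.
#' @param n_proteins Number of proteins (named `P1`, `P2`, ... unless ids
#'   are given).
#' @param enrichment_odds Odds multiplier for the marked term among
#'   disease-prone proteins.
#' @param disease_prone Logical vector (length `n_proteins`) flagging the
#'   proteins linked to disease; default none.
#' @param protein_ids Optional protein identifiers.
#' @param base_prob Baseline probability of carrying the marked term.
#' @param seed Integer seed.
#' @return List with `ontology` (`OntologyDag`), `annotations` (named
#'   list), `marked_term`.
#' @export
make_go_world <- function(n_terms, n_proteins, enrichment_odds = 1,
                          disease_prone = rep(FALSE, n_proteins),
                          protein_ids = NULL, base_prob = 0.15, seed = 1L) {
  set.seed(seed)
  stopifnot(n_terms >= 2L, length(disease_prone) == n_proteins)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  parent_of <- c(NA_integer_,
                 vapply(2:n_terms, function(i) sample.int(i - 1L, 1L),
                        integer(1)))
  child <- terms[2:n_terms]
  parent <- terms[parent_of[2:n_terms]]
  ontology <- new_ontology(terms, child, parent)
  marked <- terms[min(n_terms, 2L + stats::rbinom(1, n_terms - 2L, 0.3))]
  if (is.null(protein_ids)) protein_ids <- paste0("P", seq_len(n_proteins))
  odds0 <- base_prob / (1 - base_prob)
  p_marked <- ifelse(disease_prone,
                     enrichment_odds * odds0 / (1 + enrichment_odds * odds0),
                     base_prob)
  annotations <- lapply(seq_len(n_proteins), function(i) {
    k <- sample(1:3, 1L)
    direct <- sample(setdiff(terms, marked), k)
    if (stats::runif(1) < p_marked[i]) direct <- c(direct, marked)
    direct
  })
  names(annotations) <- protein_ids
  list(ontology = ontology, annotations = annotations, marked_term = marked)
}

#' Fixture configuration
#'
#' Bundles the generator's parameters. Defaults define the standard
#' benchmark conditions: 200 globular proteins of 100 residues, 1,000
#' mutations split evenly between classes, a 20-percentage-point RSA gap
#' between classes, and all other feature channels label-independent.
#'
#' @param seed Integer seed (mandatory).
#' @param n_proteins,n_residues Protein count and chain length.
#' @param n_mutations Total mutations (half disease, half neutral).
#' @param delta_rsa Target gap (percentage points) between the neutral and
#'   disease class mean RSA.
#' @param conservation_gap Added conservation at disease-mutated alignment
#'   columns (0 = label-independent).
#' @param go_odds GO enrichment odds for disease-prone proteins (1 =
#'   label-independent).
#' @param contact_cys_bias Fraction of disease mutations rewritten into a
#'   Cys residue with a Cys shell partner (plants a Cys-Cys contact-loss
#'   signal).
#' @param n_aln_rows Rows per synthetic alignment.
#' @param homolog_frac Fraction of proteins generated as mutated copies of
#'   an earlier protein (creates non-trivial homology clusters).
#' @param homolog_identity Sequence identity of those copies.
#' @param sasa_points SASA quadrature points used by the generator.
#' @param geometry Structure geometry.
#' @return A `FixtureConfig` list.
#' @export
fixture_config <- function(seed, n_proteins = 200L, n_residues = 100L,
                           n_mutations = 1000L, delta_rsa = 20,
                           conservation_gap = 0, go_odds = 1,
                           contact_cys_bias = 0, n_aln_rows = 50L,
                           homolog_frac = 0.1, homolog_identity = 0.6,
                           sasa_points = 960L,
                           geometry = "globule") {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(delta_rsa >= 0, conservation_gap >= 0, go_odds > 0,
            contact_cys_bias >= 0, contact_cys_bias <= 1)
  structure(as.list(environment()), class = "FixtureConfig")
}

# Placement kernels: each class samples positions with Gaussian weights
# centred at class-specific RSA targets a half-gap either side of the pooled
# mean. The kernel width (sd, RSA points) is a generator constant: it fixes
# the within-class spread so that delta_rsa is the sole discriminability
# dial (at delta 0 both kernels coincide and placement is
# label-independent). The half-gap is calibrated by root-finding so the
# expected realized class mean gap equals delta_rsa.
RSA_KERNEL_SD <- 10

.kernel_weights <- function(rsa, center, sd = RSA_KERNEL_SD) {
  w <- stats::dnorm(rsa, mean = center, sd = sd)
  w + 1e-12  # keep every position reachable
}

.solve_half_gap <- function(rsa, delta, sd = RSA_KERNEL_SD) {
  if (delta == 0) return(0)
  m0 <- mean(rsa)
  gap <- function(h) {
    wn <- .kernel_weights(rsa, m0 + h, sd)
    wd <- .kernel_weights(rsa, m0 - h, sd)
    sum(rsa * wn) / sum(wn) - sum(rsa * wd) / sum(wd)
  }
  hi <- 80
  if (gap(hi) <= delta) return(hi)
  stats::uniroot(function(h) gap(h) - delta, c(0, hi), tol = 1e-6)$root
}

#' Generate a complete labeled benchmark dataset
#'
#' Produces mutations, structures, sequences, alignments, accessibility and
#' a GO world under the contrasts requested in the configuration. Disease
#' mutations are preferentially placed at buried positions and neutral ones
#' at exposed positions: each class samples positions with Gaussian weights
#' centred at class RSA targets a calibrated half-gap either side of the
#' pooled mean (kernel width 10 RSA points, fixed), so the expected class
#' mean-RSA gap equals `delta_rsa` and vanishing `delta_rsa` means
#' label-independent placement. Burial is measured with
#' the pipeline's own accessibility computation, so planted effects live in
#' the same units the classifier sees.
#'
#' @param config A `FixtureConfig`.
#' @return A `SapFixture`: list with `mutations`, `sequences`,
#'   `structures`, `alignments`, `sasa` (per-protein absolute per-residue
#'   areas), `rsa` (per-protein percent), `ontology`, `annotations`,
#'   `marked_term`, `manifest`.
#' @export
make_labeled_dataset <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  cfg <- config
  set.seed(cfg$seed)
  prot_ids <- paste0("P", seq_len(cfg$n_proteins))

  # sequences (with homolog copies), structures, accessibility
  sequences <- character(cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    if (i > 1L && stats::runif(1) < cfg$homolog_frac) {
      src <- strsplit(sequences[sample.int(i - 1L, 1L)], "")[[1]]
      flip <- stats::runif(length(src)) > cfg$homolog_identity
      src[flip] <- vapply(src[flip], function(q)
        sample(setdiff(AA_ONE, q), 1L), character(1))
      sequences[i] <- paste(src, collapse = "")
    } else {
      sequences[i] <- paste(sample(AA_ONE, cfg$n_residues, replace = TRUE),
                            collapse = "")
    }
  }
  names(sequences) <- prot_ids
  structures <- lapply(seq_len(cfg$n_proteins), function(i)
    make_structure(cfg$n_residues, cfg$geometry, seed = cfg$seed + i,
                   sequence = sequences[i], id = prot_ids[i]))
  names(structures) <- prot_ids
  set.seed(cfg$seed + 100003L)  # structure seeds consumed the stream

  sasa <- lapply(structures, function(st)
    compute_sasa(st, n_points = cfg$sasa_points)$residue_asa)
  rsa <- lapply(prot_ids, function(p)
    rsa_profile(structures[[p]], sasa = sasa[[p]]))
  names(rsa) <- prot_ids

  # position sampling with exponential tilt towards the target RSA gap
  pool <- data.frame(
    protein_id = rep(prot_ids, each = cfg$n_residues),
    position = rep(seq_len(cfg$n_residues), cfg$n_proteins),
    rsa = unlist(rsa, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  n_d <- cfg$n_mutations %/% 2L
  n_n <- cfg$n_mutations - n_d
  h <- .solve_half_gap(pool$rsa, cfg$delta_rsa)
  m0 <- mean(pool$rsa)
  idx_d <- sample.int(nrow(pool), n_d,
                      prob = .kernel_weights(pool$rsa, m0 - h))
  rest <- setdiff(seq_len(nrow(pool)), idx_d)
  idx_n <- rest[sample.int(length(rest), n_n,
                           prob = .kernel_weights(pool$rsa[rest], m0 + h))]

  mutations <- rbind(
    data.frame(pool[idx_d, c("protein_id", "position")],
               label = "disease", stringsAsFactors = FALSE),
    data.frame(pool[idx_n, c("protein_id", "position")],
               label = "neutral", stringsAsFactors = FALSE)
  )
  mutations$chain_id <- "A"

  # Cys-Cys contact-loss planting: a fraction of disease sites is rewritten
  # into a cysteine microcluster (the centre and every shell partner become
  # CYS), so the contacts lost by those mutations are Cys-Cys pairs
  if (cfg$contact_cys_bias > 0) {
    n_bias <- round(cfg$contact_cys_bias * n_d)
    mut_key <- paste(mutations$protein_id, mutations$position)
    for (j in seq_len(n_bias)) {
      p <- mutations$protein_id[j]
      pos <- mutations$position[j]
      st <- structures[[p]]
      partners <- .shell_ordinals(st, pos, 6.0)
      # never rewrite a position carrying another mutation record: the
      # planted signal must stay specific to the biased disease sites
      partners <- partners[!(paste(p, partners) %in% mut_key)]
      rewrite <- c(pos, partners)
      st$residues$aa[rewrite] <- "C"
      st$residues$type[rewrite] <- "CYS"
      for (q in rewrite) substr(sequences[p], q, q) <- "C"
      structures[[p]] <- st
    }
  }

  mutations$wt <- vapply(seq_len(nrow(mutations)), function(i)
    substr(sequences[mutations$protein_id[i]], mutations$position[i],
           mutations$position[i]), character(1))
  mutations$mut <- vapply(mutations$wt, function(w)
    sample(setdiff(AA_ONE, w), 1L), character(1))
  mutations <- mutations[, c("protein_id", "chain_id", "position",
                             "wt", "mut", "label")]
  rownames(mutations) <- NULL

  # alignments: per-column conservation, optionally raised at disease sites
  alignments <- vector("list", cfg$n_proteins)
  names(alignments) <- prot_ids
  for (i in seq_len(cfg$n_proteins)) {
    cons <- stats::runif(nchar(sequences[i]), 0.2, 0.9)
    if (cfg$conservation_gap > 0) {
      dsites <- mutations$position[mutations$protein_id == prot_ids[i] &
                                     mutations$label == "disease"]
      cons[dsites] <- pmin(1, cons[dsites] + cfg$conservation_gap)
    }
    alignments[[i]] <- make_alignment(sequences[i], cfg$n_aln_rows, cons,
                                      seed = cfg$seed + 200000L + i)
  }
  set.seed(cfg$seed + 300007L)

  disease_prone <- prot_ids %in%
    mutations$protein_id[mutations$label == "disease"]
  world <- make_go_world(n_terms = 60L, n_proteins = cfg$n_proteins,
                         enrichment_odds = cfg$go_odds,
                         disease_prone = disease_prone,
                         protein_ids = prot_ids,
                         seed = cfg$seed + 400009L)

  gap_real <- mean(pool$rsa[idx_n]) - mean(pool$rsa[idx_d])
  manifest <- c(unclass(cfg), list(
    realized_rsa_gap = gap_real,
    mean_rsa_disease = mean(pool$rsa[idx_d]),
    mean_rsa_neutral = mean(pool$rsa[idx_n]),
    fraction_buried = mean(pool$rsa < 20),
    marked_term = world$marked_term
  ))

  structure(list(mutations = mutations, sequences = sequences,
                 structures = structures, alignments = alignments,
                 sasa = sasa, rsa = rsa, ontology = world$ontology,
                 annotations = world$annotations,
                 marked_term = world$marked_term, manifest = manifest),
            class = "SapFixture")
}

#' Write an ontology as minimal OBO text
#' @param ontology An `OntologyDag`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_along(ontology$terms)) {
    writeLines(c("", "[Term]", paste0("id: ", ontology$terms[i])), con)
    if (!is.na(ontology$name[i]))
      writeLines(paste0("name: ", ontology$name[i]), con)
    if (!is.na(ontology$namespace[i]))
      writeLines(paste0("namespace: ", ontology$namespace[i]), con)
    for (p in ontology$parents[[ontology$terms[i]]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Materialise a fixture as files
#'
#' Writes every generated artifact in its external format (PDB, FASTA,
#' aligned FASTA, OBO, TSV) plus a structured-text manifest with the seed,
#' all effect sizes and per-file checksums.
#'
#' @param fix A `SapFixture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_fixture_dir <- function(fix, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  write_mutation_table(fix$mutations, file.path(dir, "mutations.tsv"))
  seqs <- Biostrings::AAStringSet(fix$sequences)
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
  for (p in names(fix$structures))
    write_pdb(fix$structures[[p]],
              file.path(dir, "structures", paste0(p, ".pdb")))
  for (p in names(fix$alignments))
    write_alignment(fix$alignments[[p]],
                    file.path(dir, "alignments", paste0(p, ".fasta")))
  write_obo(fix$ontology, file.path(dir, "ontology.obo"))
  write_annotations(fix$annotations, file.path(dir, "annotations.tsv"))
  acc <- do.call(rbind, lapply(names(fix$sasa), function(p)
    data.frame(chain = "A", ordinal = as.integer(names(fix$sasa[[p]])),
               asa = as.numeric(fix$sasa[[p]]), protein_id = p)))
  utils::write.table(acc, file.path(dir, "accessibility.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(dir, "manifest.txt"))
  sums <- tools::md5sum(files)
  man <- file.path(dir, "manifest.txt")
  con <- file(man, "w")
  scalars <- Filter(function(x) is.atomic(x) && length(x) == 1L,
                    fix$manifest)
  writeLines(sprintf("%s = %s", names(scalars),
                     vapply(scalars, as.character, character(1))), con)
  writeLines(sprintf("md5 %s %s", unname(sums),
                     substring(files, nchar(dir) + 2L)), con)
  close(con)
  invisible(man)
}
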
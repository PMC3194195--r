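# sap3d

Predicts whether a single amino acid polymorphism (SAP) — a one-residue
protein substitution arising from a nonsynonymous SNP — is **disease-related
or neutral**, and quantifies how much protein three-dimensional structure
contributes to that call. It is aimed at structural bioinformaticians and
variant-effect methodologists who want a complete, self-contained
implementation of a structure-aware SAP classifier together with the
homology-aware evaluation protocol needed to score one honestly.

## The model

A soft-margin SVM with an RBF kernel
K(x<sub>i</sub>, x<sub>j</sub>) = exp(−γ‖x<sub>i</sub> − x<sub>j</sub>‖²)
(defaults C = 8, γ = 0.03125, features rescaled to [−1, 1] on the training
data) classifies a 52-element feature vector:

* **Mut (20)** — the substitution: −1 at the wild-type residue, +1 at the
  new one;
* **Structure environment (21)** — counts of each residue type with a heavy
  atom within 6 Å of the mutated residue's Cα, plus its relative solvent
  accessibility (RSA, %) from an internal Shrake–Rupley computation;
* **Prof (5)** — wild-type/mutant column frequencies, alignment depth, local
  depth, and the conservation index
  CI(i) = [Σ<sub>a</sub> (f<sub>a</sub>(i) − f<sub>a</sub>)²]<sup>1/2</sup>;
* **PANTHER (4)** — family-classifier scores, with uninformative defaults
  (0.5, 0, 0, 0) when absent;
* **GO (2)** — the number of propagated GO terms and the log-odds score
  LGO = Σ<sub>GO</sub> log₂[f<sub>GO</sub>(D)/f<sub>GO</sub>(N)], with
  f<sub>GO</sub>(X) = (c<sub>X</sub>+1)/(T<sub>X</sub>+1) counted on training
  mutations only.

A sequence-only variant (51 elements) swaps the structural environment for a
19-residue window composition; running both under the same protocol isolates
the value of structure. Each prediction carries a reliability index
RI = 20·|O(D) − 0.5| ∈ [0, 10] from the calibrated disease probability O(D).
Evaluation uses 20-fold cross-validation in which proteins are single-linkage
clustered at ≥30% identity (≥0.9 coverage) and whole clusters stay within one
fold; the neutral class can be doubled by reverse mutations (`wt→mut` ⇒
`mut→wt`, neutral). A companion module scores residue contacts **lost** by
the wild type and **gained** by the mutant within the same 6 Å shell as
20×20 log₂ odds matrices (LC), separating disease-enriched contact changes
such as lost Cys–Cys pairs.

Because the original curated datasets (variant databases, mapped PDB
structures, uniref90 profiles, a frozen GO release) are not shippable, the
package includes a first-class synthetic-fixture generator that produces
structures, alignments, ontologies, annotations and labeled mutation tables
with *planted*, calibrated effect sizes — so the whole pipeline is testable
and benchmarkable offline.

## Worked example

```r
library(sap3d)

# a synthetic benchmark: 40 globular proteins, 200 labeled mutations,
# disease mutations planted 20 RSA points more buried than neutral ones
cfg <- fixture_config(seed = 1, n_proteins = 40L, n_residues = 60L,
                      n_mutations = 200L, delta_rsa = 20, sasa_points = 240L)
fix <- make_labeled_dataset(cfg)

feats <- extract_features(fix$mutations, fix$sequences, fix$alignments,
                          fix$structures, variant = "3d", sasa = fix$sasa)
clusters <- cluster_proteins(fix$sequences)
annotations <- propagate_annotations(fix$ontology, fix$annotations)

cv <- cross_validate(feats, clusters, annotations, k = 10, seed = 1)
cv$metrics
#> n=200  Q2=0.775  C=0.550  S(D)=0.780  P(D)=0.772  S(N)=0.770  P(N)=0.778  AUC=0.845

head(cv$predictions[, c("protein_id", "position", "wt", "mut",
                        "label", "o_d", "class", "ri")], 3)
#>   protein_id position wt mut   label       o_d   class       ri
#> 1        P39       30  Q   I disease 0.7297070 disease 4.594140
#> 2        P26       14  D   W disease 0.8861832 disease 7.723665
#> 3        P36       16  G   N disease 0.8176244 disease 6.352488
```

`Q2` is overall accuracy, `C` the per-class Matthews correlation, `S`/`P`
per-class sensitivity and positive predictive value, and `AUC` the
rank-statistic area under the ROC curve — here the classifier recovers the
planted burial signal well above chance on homology-clean folds. Each row of
`cv$predictions` gives the calibrated disease probability `o_d`, the class
call (threshold 0.5), and the reliability index `ri`. Filtering by
reliability trades coverage for accuracy:

```r
rc <- reliability_curve(cv$predictions, cv$predictions$label)
rc[rc$threshold %in% c(0, 5, 8), ]
#>   threshold coverage   n        q2       mcc
#> 1         0    1.000 200 0.7750000 0.5500275
#> 6         5    0.635 127 0.8661417 0.7323909
#> 9         8    0.305  61 0.8852459 0.7738258
```

At `RI > 5` the model keeps 63.5% of predictions and is 86.6% accurate.
A command-line front end over the same functions is installed at
`inst/cli/sap3d.R` (subcommands `simulate`, `features`, `crossval`,
`contacts`, `predict`).

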
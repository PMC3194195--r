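---
title: "Methods: structure-aware classification of amino acid substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-aware classification of amino acid substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

A single amino acid polymorphism (SAP) replaces one residue of a protein
with another. Some substitutions are tolerated; others destabilise the fold,
break a functional site, or disrupt an interaction and cause disease. `sap3d`
frames the question as binary classification — *disease* versus *neutral* —
and answers it with a soft-margin support vector machine over features that
describe the substitution, its three-dimensional context, its evolutionary
context, and the protein's function.

## The feature vector

The structure-based variant (`"3d"`) uses 52 features in a fixed order:

| block | length | content |
|---|---|---|
| Mut | 20 | substitution encoding: −1 at the wild-type residue, +1 at the new residue |
| Structure environment | 21 | counts of each residue type with a heavy atom within 6 Å of the mutated residue's Cα, plus the residue's relative solvent accessibility (RSA, percent) |
| Prof | 5 | wild-type and mutant column frequencies `F_W`, `F_N`; alignment row count `N_T`; rows aligned at the column `N_S`; conservation index `CI` |
| PANTHER | 4 | family-classifier scores `P_D`, `P_W`, `P_N`, `N_IC` (defaults `0.5, 0, 0, 0` when unavailable) |
| GO | 2 | number of propagated GO terms and the log-odds score `LGO` |

The sequence-only variant (`"seq"`, 51 features) replaces the 21-element
structural environment with the residue composition of a 19-position
sequence window centred on the mutation. Comparing the two variants under
identical protocols isolates the contribution of structure.

Two scores are worth spelling out. The conservation index of a query
position $i$ is the Euclidean distance between the column's residue
frequency vector and the alignment's overall composition,
$CI(i) = [\sum_{a=1}^{20}(f_a(i)-f_a)^2]^{1/2}$, computed with gaps excluded
from all denominators. The GO score of a protein is
$LGO = \sum_{GO} \log_2 [f_{GO}(D)/f_{GO}(N)]$ over its propagated terms,
with $f_{GO}(X) = (c_X + 1)/(T_X + 1)$: $c_X$ counts the *training*
mutations of class $X$ whose protein carries the term, $T_X$ is the class
total, and the added pseudo-count keeps every term finite. Because the
counts are a pure function of the training records, refitting them inside
each cross-validation fold makes the feature leakage-free by construction.

### Choices the formulas leave open

* **Window centre.** Whether the 19-residue window counts the mutated
  position is ambiguous; the centre is excluded by default (its identity is
  already fully encoded in the Mut block, and counting it twice would
  double-encode the wild type). `include_center = TRUE` restores the other
  convention.
* **`N_T` versus `N_S`.** Interpreted as the number of alignment rows
  versus the number of rows with a residue (not a gap) at the column.
* **LGO denominator.** The pseudo-count rule fixes numerator and
  denominator as `(c+1)/(T+1)` with mutations (not proteins) as the
  counting unit, since the score labels mutations; `per_protein = TRUE`
  switches the unit.
* **Ontology traversal.** Only `is_a` edges are followed and the three GO
  namespaces are merged into one term set; each term counts once no matter
  how many paths reach it.

## Structure handling

Structures are read from PDB files (via `bio3d`), one chain at a time.
Heavy atoms of polymer residues are kept; waters, ligands and hydrogens are
excluded; alternate locations resolve to the highest-occupancy conformer
(first on ties); common modified residues (MSE → MET, SEC → CYS, …) map to
their canonical parent and anything unmapped is dropped with a warning.
Every retained residue must have a Cα. Only the first model of a
multi-model file is used, and only intra-chain contacts are ever computed.

Database sequences are matched to structure chains by a local alignment
that must be **gapless**, **100% identical** and **at least 40 residues
long** — the same filters used when pairing sequence databases with
deposited structures; failures report which filter rejected them.

Solvent accessibility is computed internally by Shrake–Rupley quadrature:
for each atom, 960 quasi-uniform points (a golden-spiral lattice, so the
computation is deterministic) are placed on the sphere of radius
$r_{vdw} + 1.4$ Å and the accessible fraction is scaled by the sphere area.
Bondi-style van der Waals radii are used, with the carbon radius as the
fallback for unknown elements (with a warning). Per-residue areas are
normalised to percent RSA with the Rost–Sander maximum-area table; the
choice of table is a documented convention, not a derived fact, and
precomputed accessibilities (e.g. from DSSP) can be imported with
`read_accessibility()` instead. Quadrature precision: doubling the point
count moves well-exposed residues by well under 2% on average; residues
with almost no exposed surface can only converge in absolute terms, since
a single grid point represents ≈0.13 Å².

## Classifier

The kernel is a radial basis function
$K(x_i, x_j) = \exp(-\gamma\|x_i - x_j\|^2)$ with $C = 8$ and
$\gamma = 0.03125$, the grid-search optimum for rescaled inputs of this
layout; they are defaults, not constants. Before training, each feature is
linearly mapped to $[-1, 1]$ using the *training* minimum and maximum
(held-out values may fall outside the interval; constant features map to
0). Probability estimates come from libsvm's Platt-style calibration (via
`e1071`); its internal cross-validation is seeded, so training is
deterministic given a seed. A prediction is *disease* when the calibrated
probability $O_D \ge 0.5$ — the tie at exactly 0.5 resolves to disease,
the conservative call for a pathogenicity screen — and its reliability
index is $RI = 20\,|O_D - 0.5| \in [0, 10]$.

## Evaluation protocol

Performance is measured by 20-fold cross-validation with two safeguards.
First, proteins are clustered by single-linkage at ≥30% local-alignment
identity over ≥90% of the shorter sequence (BLOSUM62 scoring), and whole
clusters — hence all mutations of all similar proteins — are assigned to a
single fold, so homologs never straddle train and test. Second, everything
fitted — feature scaling, GO counts, the classifier — is refitted on the
training folds only. Fold assignment is greedy, largest cluster first with
seed-shuffled tie-breaking, minimising a combined size/class-ratio
objective so folds stay near the global disease fraction.

Class imbalance is addressed by reverse-mutation balancing: every neutral
substitution `wt→mut` contributes a second neutral record `mut→wt` at the
same position. Structure-derived features of a reverse mutation are
computed on the same wild-type structure — only the substitution encoding
and the substitution-dependent profile/family lookups flip — and such rows
are flagged `reversed` in the output.

Reported indexes: overall accuracy $Q2$; per-class Matthews correlation
(numerically identical to the Pearson correlation of the binary vectors,
which the tests assert); per-class sensitivity and positive predictive
value; rank-statistic AUC (equal to trapezoidal ROC integration); and the
true-positive rate at 10% false-positive rate. Two FPR conventions exist
in the literature — the standard ROC rate and one minus precision — so
both are computed (`tpr_at_fpr10`, `tpr_at_fdr10`) with the standard one
primary. Degenerate denominators report 0 and are flagged rather than
propagating `NaN`.

The *function holdout* (`holdout_by_function()`) builds a harsher split:
all mutations on proteins annotated with a chosen GO term (after
propagation) form the test set; training excludes them plus any protein
above a pairwise-identity cutoff to a test protein; and the term's whole
subtree is blanked from the annotations used to score the test set, so the
selection criterion cannot leak into the GO features. RSA-stratified
scoring (`stratify_by_rsa()`, ten equal-width bins) shows where structure
helps: typically most for buried residues, where the wild-type-structure
approximation is best.

## Contact scores

Within the same 6 Å Cα shell, a substitution *loses* the contacts of the
wild-type residue and — under the approximation that the backbone does not
move — *gains* the same partners for the new residue. Pooling events over
a labeled dataset gives two symmetric 20×20 log-odds matrices,
$LC = \log_2[f(c(i,j), D)/f(c(i,j), N)]$, computed per kind (lost/gained)
with one pseudo-count per pair per class; the pseudo-count is a deviation
required for finiteness and is declared in the output headers. Pairs are
unordered and every partner contributes one event. Positive entries mark
contact changes enriched among disease mutations — the classic examples
being lost disulfide partners (Cys–Cys) and gained aromatic crowding
(Trp–Trp).

## The synthetic benchmark generator

Real benchmarks for this task require curated variant databases, mapped
structures, large sequence searches and a frozen ontology release. The
fixture module instead generates every input with controlled statistical
structure, so the full pipeline can be built, tested and benchmarked
offline:

* **Structures** are ideal helices (1.5 Å rise, 100° twist; consecutive
  Cα ≈ 3.8 Å) or compact globules — jittered cubic lattices at 3.8 Å
  spacing filled from the core outwards — with Cα and (except glycine) a
  Cβ stub pointing away from the centroid. Globules genuinely bury
  residues, which is what the RSA signal needs.
* **Alignments** keep the query residue with per-column probability equal
  to the column's conservation level, otherwise drawing uniformly from the
  other 19 types.
* **The GO world** is a random tree ontology; a marked term is attached to
  disease-prone proteins at a configurable odds multiplier (odds 1 =
  label-independent).
* **Mutation placement** drives the planted structural signal. Positions
  are sampled with Gaussian weights on the pooled RSA distribution, the
  two class kernels centred a calibrated half-gap either side of the
  pooled mean so the expected class mean-RSA gap equals `delta_rsa`
  exactly (root-finding on the empirical distribution). The kernel width
  is fixed at 10 RSA points: the mean gap alone does not determine how
  discriminable the classes are, so the generator pins the within-class
  spread as a constant, making `delta_rsa` the single effect-size dial —
  zero gap means identically distributed classes, and discriminability
  grows monotonically with the gap. Burial is measured with the package's
  own accessibility computation, so planted effects live in the units the
  classifier consumes.
* **Contact bias** rewrites a fraction of disease sites into cysteine
  microclusters (the site and its shell partners become CYS), planting
  Cys–Cys losses among disease mutations; positions carrying other
  mutation records are never rewritten, keeping the plant specific to the
  biased sites.
* A fraction of proteins are mutated copies of earlier ones (default 10%
  at 60% identity), so homology clustering has real work to do.

What the generator does **not** emulate: real packing and secondary
structure, correlated substitution patterns within alignment columns,
biased amino-acid composition, shared domains between otherwise unrelated
proteins, and curation noise in labels. Passing the recovery benchmarks
therefore shows that the pipeline *faithfully extracts planted signals
under its own protocol* — not that it reaches any particular accuracy on
real variant data.

## Benchmark conditions and problem sizes

The standard benchmark uses 200 globular proteins of 100 residues and
1,000 mutations (half per class) with a 20-point RSA gap and all other
channels label-independent; the null condition sets the gap to zero. At
this scale the structure variant's cross-validated AUC sits near 0.9 while
the sequence variant stays near 0.5, and both fall to ≈0.5 under the null.
The contact benchmark uses 50 proteins, 400 mutations and a bias fraction
of 0.6. Smaller configurations (tens of proteins, a few hundred mutations)
are used for protocol and determinism checks; these sizes were chosen so
the planted effects dominate sampling noise while the whole suite stays
comfortably runnable on a single CPU.

## Numerical and degenerate-input conventions

1-based positions and closed intervals throughout, matching mutation
nomenclature (`C163S`). Shell radius 0 yields empty shells; a mutation
whose mapped structure residue disagrees with the stated wild type is an
error, not a silent skip. Empty contact-event sets produce zero matrices
with a warning. Model archives are versioned and refuse to load across
incompatible versions. All stochastic steps — generation, fold assignment,
calibration — are pure functions of their seeds; identical seeds give
byte-identical outputs end to end.

## Known limitations

Only intra-chain, wild-type-structure context is modelled: effects through
quaternary contacts, large rearrangements, or mutant-specific structure
are outside the model, and accuracy for highly exposed residues is
correspondingly weaker. The internal accessibility quadrature approximates
(rather than reproduces) DSSP values; users wanting exact parity should
import DSSP output. The CI/LGO conventions above are reasonable defaults
where the underlying definitions are ambiguous, and are exposed as
configuration rather than hard-coded.
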
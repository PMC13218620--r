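---
title: "ligscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ligscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ligscreen` implements a ligand-based virtual-screening workflow against a
single protein target: normalize a compound activity table, featurize the
molecules three ways, learn (a) a pIC50 regressor and (b) a pairwise
similarity model that fuses the three representations through attention,
then use both to reduce, score and rank an external candidate library, and
finally characterize the hits by clustering, structure–activity
correlations and maximum common substructures. This vignette documents the
models, the parameters that matter, and the design decisions taken where
more than one reasonable choice existed.

## Activity conventions

All activities are handled as pIC50 = −log10(IC50 in molar), so 100 nM
corresponds to pIC50 = 7. Units are never guessed: `load_ligand_table()`
requires an explicit unit (`nM` default, the ChEMBL convention). Rows with
unparsable SMILES or missing/non-positive IC50, or IC50 outside a
configurable plausibility window (10^-3^–10^12^ nM), are rejected and
counted; exact duplicates by canonical SMILES are collapsed to the median
IC50 (robust to outliers, since activity databases frequently carry
repeated measurements spanning orders of magnitude). The accounting
identity `rejected + deduplicated + kept = raw rows` always holds and is
part of the test contract.

Activity classes use the conventional medicinal-chemistry thresholds: low
(pIC50 < 5), medium (5 ≤ pIC50 ≤ 7, both boundaries inclusive), high
(pIC50 > 7, i.e. IC50 below 100 nM). A separate binary discretization
(high = pIC50 > 7) feeds the classification metrics of the regression
suite. Drug-likeness uses Lipinski's four strict inequalities (LogP < 5,
MW < 500 Da, HBD < 5, HBA < 10), evaluated on the average molecular
weight, which is the rule's conventional basis.

## Molecular representations

**Canonicalization.** All structure handling goes through OpenBabel
canonical SMILES. OpenBabel is lenient with some malformed strings, so a
syntactic pre-check (balanced brackets, paired ring-closure digits,
character whitelist) enforces rejection of truncated input before parsing.
Multi-fragment (salt) inputs keep the largest organic fragment.

**Circular fingerprints.** `morgan_fingerprint()` implements ECFP-style
iterated neighborhood hashing on the heavy-atom graph: seed invariants are
(element, heavy degree, hydrogen count, formal charge, ring membership);
each iteration hashes the previous invariant together with the sorted
(bond order, neighbor invariant) pairs; environments whose bond set
duplicates an already-emitted environment are removed, as in standard ECFP
generation; feature identifiers are folded modulo `nbits`. Defaults are
radius 2 (ECFP4-equivalent; the radius is configurable) and 1024 bits.
Because the graph is built from the canonical atom order, any SMILES
spelling of a molecule yields the same bits — a property-tested contract.
A single heavy atom yields exactly one bit (one radius-0 environment and
nothing larger).

**Descriptors.** The fixed six-descriptor vector is
[MolLogP, MolWt, NumRotatableBonds, TPSA, NumHAcceptors, NumHDonors].
LogP, molecular weight and TPSA come from OpenBabel's property engine
(LogP is a computed group-contribution estimate; note that OpenBabel's
TPSA variant includes polar sulfur/phosphorus contributions). The counted
descriptors are SMARTS-based rules chosen to reproduce the conventional
donor/acceptor counts for reference drugs: donors are N/O/S atoms bearing
at least one hydrogen; acceptors are all oxygens plus hydrogen-free
nitrogens. These reproduce glutathione (6 HBD / 6 HBA), estrone (1 / 2),
melatonin (2 HBD) and methotrexate (5 / 10) exactly. Rotatable bonds use
the classic Daylight definition (acyclic single bonds between
non-terminal heavy atoms); amide C–N bonds are counted, which some
toolkits exclude — the definition is applied consistently throughout.

**SELFIES-style token vectors.** Molecules are tokenized as SELFIES-type
strings (atom tokens with bond-order prefixes, `[BranchN]`/`[RingN]`
tokens with index symbols) produced by a deterministic depth-first walk of
the kekulized canonical graph. The model consumes a *bag of tokens*: a
count vector over a vocabulary built from the training set, with a final
unknown-token bin so screening never fails on unseen chemistry. Counts
were chosen over padded sequences because they are order-insensitive,
fixed-dimension, and need no padding or truncation policy; the tokenizer
itself remains a faithful structural encoding (ethanol is
`[C][C][O]`, benzene `[C][C][=C][C][=C][C][=Ring1][=Branch1]`).

## The pIC50 regression suite

`train_and_evaluate()` splits 80/20, fits column standardization
(z-scores; constant columns set to zero and flagged) on the training split
only, and runs grid search inside 5-fold cross-validation on the training
split; the held-out split is scored exactly once per model, a contract
enforced in the tests through an instrumentation hook that records the row
indices of every engine fit and score call.

The six mandatory model families and their default (final, tuned)
hyperparameters: ridge (alpha 1.0), linear SVR (C 0.1, epsilon 0.01),
extremely randomized trees (200 trees, sqrt feature sampling), leaf-wise
gradient boosting (learning rate 0.05, 300 rounds, depth 7, 31 leaves),
xgboost (learning rate 0.1, 200 rounds, depth 6, subsample 0.8) and
random forest (150 trees). Engines are glmnet, e1071, ranger and xgboost;
the leaf-wise booster uses xgboost's lossguide histogram grower, which is
the same algorithmic family as LightGBM. Because the defaults are already
the tuned configurations, the default grid per hyperparameter is the
single default value; callers supply richer grids when they want a
search. CNN/GNN entries exist as flag-gated specifications and are
reported as explicit skips rather than silently dropped, so a requested
model never vanishes from a report.

Classification metrics (accuracy, precision, recall, F1; precision and
recall on the high class) are computed on the discretized predictions —
per fold, then averaged, for the cross-validation numbers; this
per-fold-then-average convention is recorded in the report metadata.
Degenerate cases (no predicted or no true positives) are flagged
undefined instead of propagating NaN.

**Perturbation robustness** adds zero-mean Gaussian noise with standard
deviation `intensity × column-sd` to the evaluation features; robustness
analyses of this kind admit many perturbation operators, and additive
Gaussian noise on standardized features is the simplest one with a
controllable scale. At intensity 0 the curve equals the baseline
metrics exactly (no noise is drawn at all). **Taylor statistics** use
population (1/n) moments so the identity
cRMSE² = sd_p² + sd_o² − 2·sd_p·sd_o·r holds to machine precision.

## The fusion similarity model

The pairwise similarity model uses three per-molecule encoders into a
shared hidden space (default 128): a linear map for the SELFIES count
vector, and linear → ReLU → dropout → batch-normalization blocks for the
fingerprint and descriptor vectors. A multi-head attention block (4
heads) uses the SELFIES embedding as the query over a two-token
key/value sequence — the fingerprint embedding and the descriptor
embedding — so the topological context decides how much weight each of
the other modalities receives. The attended output is concatenated with
the fingerprint and descriptor embeddings into a 3×128 molecule
embedding.

Pairs are scored with shared (siamese) encoder weights through the
symmetric combination [|e_a − e_b|, e_a ⊙ e_b] followed by an MLP
(128 → 32 → 1) and a sigmoid, so `score(a,b) = score(b,a)` holds by
construction and scores live strictly inside (0, 1). The output layer is
zero-initialized, so an untrained model scores exactly 0.5.

Training minimizes MSE against {0,1} pair labels with Adam (learning rate
10^-3^, batch 64, up to 50 epochs): positives are high×high pairs,
negatives any pair containing a low-activity member, medium-activity
molecules excluded, classes balanced. The learning rate halves when the
validation loss (15% held-out pairs, never used for gradients) fails to
improve for 5 epochs; training stops after 10 such epochs and the
best-validation weights are restored. The network and its
backpropagation are implemented directly on base-R matrices; the analytic
gradients are verified against central differences in the test suite, and
an epoch-scoped private RNG makes training bit-reproducible under a seed.
Non-finite loss aborts with a diagnostic rather than returning a broken
model.

The Tanimoto coefficient over fingerprint bits (|A∩B|/|A∪B|; defined as 1
for two empty fingerprints) is the classical baseline; `compare_similarity_metrics()`
merges both scores into one per-pair record set with their Pearson
correlation, and `enrichment_at_k()` quantifies practical utility as the
fraction (and fold over base rate) of actives among the top-ranked
candidates.

## Library reduction and screening

`diversity_reduce()` embeds candidate fingerprints into two dimensions and
overlays a square grid whose resolution is tuned (by bisection) until the
number of occupied cells approximates the target count; the member nearest
each occupied cell centroid is kept. The embedding is classical
multidimensional scaling (principal coordinates) of Jaccard/Tanimoto
distances: a deterministic, dependency-light embedding whose pairwise
distance preservation is exactly what the occupied-grid policy needs.
Axes carrying only numerical noise are flattened so duplicate-heavy
libraries collapse cleanly. The selection is idempotent: re-reducing a
reduced set with the same target returns the same set.

`screen_library()` scores every candidate against every ligand anchor (an
anchor subsample is configurable and recorded in the result metadata),
keeps the best-scoring anchor with its Tanimoto similarity, predicts
pIC50 with the trained extremely-randomized-trees regressor (the suite's
strongest model) and converts it to IC50 in nM, annotates Lipinski
violations, and flags hits above a similarity threshold of 0.8. Results
are ranked by best fusion score with ties broken by candidate id, making
the output a stable total order.

## Cluster / SAR / MCS analytics

K-means runs on fingerprint bits plus a z-scored pIC50 column (mean 0, sd
1, so activity contributes on the same scale as one bit). For each k the
best of 20 seeded restarts is kept; the SSE (elbow) curve and the mean
silhouette curve are both reported, and the chosen k is the silhouette
argmax — when the two criteria disagree the silhouette wins, because it is
a direct quality score rather than an inflection heuristic. PCA
projections report explained-variance fractions with a deterministic sign
convention. Bit-frequency profiles give, per cluster, the fraction of
members with each bit set. Per-cluster SAR tables report the Pearson
correlation of each descriptor with pIC50, with small clusters (< 3) and
zero-variance descriptors flagged rather than NaN.

The maximum common substructure search is a backtracking maximum common
connected subgraph over the heavy-atom graphs: atoms match by element;
acyclic and triple bonds match by exact order; ring bonds of order 1/2
share a single match class. The ring-bond class exists because kekulized
double-bond positions inside an aromatic ring are an artifact of
canonicalization — two substituted pyrimidines can carry their formal
double bonds on different ring bonds — and because rings should match
rings. The search is an anytime algorithm under a wall-clock timeout
(default 10 s per cluster): a timeout returns the best pattern found so
far with a `timed_out` flag, distinct from the empty-pattern outcome.
Multi-member clusters are folded pairwise, smallest molecules first; with
`min_fraction` below 1 a member whose inclusion would collapse the
pattern may be skipped, up to the allowed fraction — the analogue of the
threshold parameter in standard MCS tools, and the recommended setting
(0.9) for clusters produced by k-means, which are rarely 100% pure.

## The synthetic structure–activity generator

The generator provides planted ground truth for every stage. Molecules
are scaffold + two substituents: four ligand scaffolds (benzene, indole,
piperidine, pyrimidine, each with two substitution points), a fragment
alphabet of 15 plain substituents plus six hydroxyl-bearing
"activity-boosting" variants, and linkers of 0–3 methylenes. The boost
fragments all place their hydroxyl oxygen exactly two bonds from the
scaffold attachment point and always attach without a linker, so every
boosted molecule shares a fixed attachment–CH–OH motif: this is what
makes "the high-activity cluster's MCS contains a hydroxyl" a
well-defined planted truth rather than a coincidence. (With variable
linkers the hydroxyl would sit at varying graph depth and *no* common
substructure could retain it.)

Activities follow
pIC50 = β0 + β1·boost + β2·(TPSA/100) + β3·rotors + ε, ε ~ N(0, σ),
with defaults β = (4.8, 2.6, 0.6, 0.05), σ = 0.4 and a boost probability
of 0.4; a nonlinear mode adds a boost × TPSA interaction (coefficient
1.0) for experiments that need a tree-favoring signal. The defaults were
chosen once, against the analytic class-boundary arithmetic, to give
roughly balanced low/medium/high classes with high anchored near the
boost rate; at n = 2000 the realized balance is ≈ 22/45/33
(low/medium/high) — the uniqueness constraint caps the number of distinct
boosted structures, so the boosted fraction saturates below 0.4 at that
scale while small sets (n ≤ 400) sit near 40% high. The planted
coefficients, per-molecule design matrix and seeds are returned as a
ground-truth sidecar; regressing the generated activities on the true
design matrix recovers β within 3 standard errors, which is tested before
the generator is trusted to validate anything else.

Candidate libraries contain an `analog_fraction` of analog-series edits
of ligand molecules — the parent's site-A (pharmacophore) substituent is
preserved and the peripheral site re-drawn, as in a real SAR series — and
decoys built on four disjoint scaffolds (naphthalene, thiophene, furan,
cyclohexane) from the non-boost alphabet only: a decoy carrying the full
planted pharmacophore would not be a decoy, matching how screening
benchmarks define inactive background.

What the generator does *not* emulate: realistic medicinal-chemistry
property distributions, activity cliffs, assay noise structure,
stereochemistry, or the scale of real aggregated corpora. Tests passing
on this benchmark demonstrate that the pipeline recovers signal it is
supposed to recover; they do not certify performance on real screening
data.

## Problem sizes and numerical choices

The default benchmark scales, chosen as desk-scale study conditions:
n = 2000 ligands for the regression suite and coefficient recovery;
n = 300 ligands / 150 candidates (30% analogs) for the fusion, screening
and cluster stages; 1000 balanced training pairs; k ∈ 2..8 for cluster
selection. Seeds are single integers fanned out deterministically to
every random component (splits, fold assignment, engines, pair sampling,
initialization, dropout, noise draws).

Numerical conventions worth knowing: standardization uses training-set
statistics only, with constant columns zeroed and flagged; batch
normalization uses population (1/n) batch moments with running statistics
for inference; k-means falls back from Hartigan–Wong to Lloyd when k
approaches n; silhouette is undefined (NA) for all-singleton clusterings;
PCA and PCoA fix reflection signs deterministically; ties in screening
rankings break by candidate id; the both-empty-fingerprint Tanimoto is
defined as 1.

## Known limitations

OpenBabel's LogP and TPSA variants differ in detail from other toolkits
(printed literature LogP values are therefore not used as test oracles).
The HBA rule is a deliberately simple approximation calibrated to
reference drugs; it counts some weak acceptors (e.g. N-alkyl amide
nitrogens are excluded, but ester oxygens are counted). The MCS search is
exponential in the worst case and relies on its timeout for adversarial
inputs. The fusion model is a desk-scale network trained on planted
labels; transferring it across targets or to absolute affinity
prediction is out of scope.
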
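# ligscreen

Ligand-based virtual screening in R, for computational chemists who have a
compound activity table for a protein target (SMILES + IC50/pIC50) and an
external candidate library, and want a tested, reproducible path from raw
tables to ranked, annotated screening hits.

The package implements the full workflow:

1. **Ingestion** — validated SMILES canonicalization, explicit IC50 unit
   handling, pIC50 = −log10(IC50 [M]) conversion, duplicate collapsing,
   exact row accounting (`load_ligand_table()`).
2. **Featurization** — Morgan/ECFP-style circular fingerprints (1024 bits,
   radius 2), the six-descriptor vector [MolLogP, MolWt,
   NumRotatableBonds, TPSA, NumHAcceptors, NumHDonors], and SELFIES-style
   token-count vectors over a training vocabulary.
3. **Activity modelling** — a suite of pIC50 regressors (ridge, linear
   SVR, extremely randomized trees, leaf-wise gradient boosting, xgboost,
   random forest) with 5-fold cross-validated grid search, discretized
   classification metrics (high = pIC50 > 7), perturbation-robustness
   curves and Taylor-diagram statistics (`train_and_evaluate()`).
4. **Similarity learning** — a trainable pairwise similarity model that
   encodes the three representations into a shared hidden space and fuses
   them with multi-head attention (SELFIES embedding as the query over
   fingerprint/descriptor embeddings as keys and values). Siamese
   encoders and a symmetric pair combination `[|e_a − e_b|, e_a ⊙ e_b]`
   give a score in (0,1) trained with MSE on high×high (positive) vs
   low-containing (negative) activity pairs; the Tanimoto coefficient is
   the built-in baseline (`train_fusion()`, `pair_score()`, `tanimoto()`).
5. **Screening** — diversity reduction of the candidate library
   (2-D principal-coordinates embedding of Jaccard distances + an
   occupied-grid keep rule), all-vs-anchors similarity scoring, predicted
   pIC50/IC50 per candidate, Lipinski annotation, hit flags above a 0.8
   similarity threshold, ranked export for downstream docking
   (`diversity_reduce()`, `screen_library()`, `export_top_candidates()`).
6. **Hit analytics** — K-means over fingerprints + standardized pIC50 with
   elbow/silhouette selection, PCA projection, fingerprint-bit frequency
   heatmap inputs, per-cluster descriptor↔activity Pearson correlations,
   and per-cluster maximum common substructures (`kmeans_select()`,
   `mcs_for_cluster()`).
7. **A synthetic benchmark** — a structure–activity generator that plants
   a known activity model (a hydroxyl-bearing boost fragment plus TPSA
   and rotor effects: pIC50 = β0 + β1·boost + β2·TPSA/100 + β3·rotors + ε)
   so every stage above can be validated against ground truth
   (`generate_ligand_set()`, `generate_candidate_library()`).

Chemistry primitives (SMILES parsing, canonicalization, properties, SDF)
are backed by OpenBabel via ChemmineOB/ChemmineR.

## Worked example

Entirely self-contained (synthetic data, fixed seeds):

```r
library(ligscreen)

spec  <- synthetic_spec(n_ligands = 120, seed = 7)
lig   <- generate_ligand_set(spec)
lig$table
#> <ligand_table> 120 compounds (rejected 0, deduplicated 0)
#>          id                       smiles      ic50_nM    pic50    source
#> 1 syn_00001 NCc1[nH]c2c(c1C(O)(C)C)cccc2    14.300955 7.844635 synthetic
#> 2 syn_00002      CCOCCCC1CCN(CC1)CCN(C)C 17622.135081 4.753941 synthetic
#> ...  114  more rows

fe    <- featurize_table(lig$table)
lab   <- classify_activity(lig$table$pic50)
pairs <- build_pair_dataset(lig$table, lab, max_pairs = 400, seed = 7)
model <- train_fusion(chemfusion_init(fe, fusion_config(seed = 7)), fe, pairs)
model
#> <chemfusion> hidden_dim=128 heads=4 mlp=[128,32] trained
#>   epochs: 33  best val MSE: 1.59e-05

X    <- build_feature_matrix(lig$table, features = fe)
rep_ <- train_and_evaluate(X, lig$table$pic50,
                           list(model_spec("extra_trees"), model_spec("ridge")),
                           seed = 7)
rep_
#> <eval_report> n =120 (5-fold CV, 20% test)
#>         model status train_mae test_mae train_r2 test_r2 cv_accuracy  cv_f1
#> 1 extra_trees     ok  0.123941   0.4858   0.9847  0.7887      0.8747 0.7378
#> 2       ridge     ok  0.003275   0.6415   1.0000  0.6119      0.8637 0.7056

cand <- generate_candidate_library(spec, lig, n_candidates = 80,
                                   analog_fraction = 0.3)
cfe  <- featurize_table(cand$table, vocab = fe$vocab)
res  <- screen_library(model, rep_$models$extra_trees$fit,
                       rep_$standardization, lig$table, cand$table,
                       ligand_features = fe, candidate_features = cfe)
res
#> <screen_result> 80 candidates, 41 hits (threshold 0.8)
#>           id best_fusion_score predicted_pic50  hit
#> 1 cand_00002         0.9999841        7.783810 TRUE
#> 2 cand_00024         0.9999828        7.281179 TRUE
#> ...
```

Reading the output: the extremely randomized trees model explains ~79% of
held-out activity variance on this 120-molecule planted benchmark; the
trained similarity model assigns near-1 scores to candidates that are
analog-series edits of active ligands, and those dominate the top of the
ranking — `res$hit` marks candidates whose best score against any ligand
anchor exceeds 0.8, and `predicted_pic50` > 7 marks predicted
sub-100 nM potency.

A command-line wrapper over the same functions ships in
`inst/cli/ligscreen.R` with subcommands `simulate | prepare | featurize |
train-regressors | train-fusion | reduce-library | screen | cluster |
report` and global `--config/--seed/--out` flags.

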
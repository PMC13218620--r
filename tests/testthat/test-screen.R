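candidate_fixture <- function() fixture("candidate_fixture", function() {
  s <- small_set()
  cand <- generate_candidate_library(s$spec, s$lig, n_candidates = 60L,
                                     analog_fraction = 0.3)
  cfe <- featurize_table(cand$table, vocab = s$fe$vocab)
  list(cand = cand, cfe = cfe)
})

screen_fixture <- function() fixture("screen_fixture", function() {
  s <- small_set(); sf <- small_fusion(); cf <- candidate_fixture()
  rep_ <- train_and_evaluate(
    s$X, s$lig$table$pic50,
    list(model_spec("extra_trees", list(n_estimators = 100))), seed = 1)
  res <- screen_library(sf$model, rep_$models$extra_trees$fit,
                        rep_$standardization, s$lig$table, cf$cand$table,
                        ligand_features = s$fe, candidate_features = cf$cfe)
  list(res = res, rep_ = rep_)
})

test_that("diversity reduction keeps ~target molecules, one per grid cell", {
  cf <- candidate_fixture()
  sel <- diversity_reduce(cf$cand$table, 20L, features = cf$cfe, seed = 1)
  expect_s3_class(sel, "diversity_selection")
  expect_true(all(sel$kept_ids %in% cf$cand$table$id))
  # within +-30% of the target at this small scale
  expect_gte(length(sel$kept_idx), 14L)
  expect_lte(length(sel$kept_idx), 26L)
  expect_equal(dim(sel$embedding), c(nrow(cf$cand$table), 2L))
  # deterministic
  sel2 <- diversity_reduce(cf$cand$table, 20L, features = cf$cfe, seed = 1)
  expect_identical(sel$kept_ids, sel2$kept_ids)
  expect_error(diversity_reduce(cf$cand$table, 10000L, features = cf$cfe),
               "target_count")
})

test_that("total redundancy collapses to a single kept candidate", {
  dup <- new_ligand_table(data.frame(
    id = sprintf("d%02d", 1:30), smiles = rep(canonicalize_smiles("CCO"), 30),
    ic50_nM = NA_real_, pic50 = NA_real_, source = "x"))
  sel <- diversity_reduce(dup, 1L, seed = 1)
  expect_length(sel$kept_idx, 1L)
})

test_that("structurally disjoint families are both represented at target 2", {
  fam <- new_ligand_table(data.frame(
    id = sprintf("f%02d", 1:10),
    smiles = c(rep(canonicalize_smiles("c1ccccc1CCN"), 5),
               rep(canonicalize_smiles("C1CCCCC1OP(=O)(O)O"), 5)),
    ic50_nM = NA_real_, pic50 = NA_real_, source = "x"))
  # duplicates within families; distinct across
  sel <- diversity_reduce(fam, 2L, seed = 1)
  kept_smiles <- fam$smiles[sel$kept_idx]
  expect_length(unique(kept_smiles), 2L)
})

test_that("diversity reduction is idempotent on its own output", {
  cf <- candidate_fixture()
  sel <- diversity_reduce(cf$cand$table, 20L, features = cf$cfe, seed = 1)
  reduced <- new_ligand_table(as.data.frame(cf$cand$table)[sel$kept_idx, ])
  sel2 <- diversity_reduce(reduced, length(sel$kept_idx), seed = 1)
  expect_setequal(sel2$kept_ids, sel$kept_ids)
})

test_that("screening returns a ranked, internally consistent hit table", {
  sc <- screen_fixture()
  res <- sc$res
  expect_s3_class(res, "screen_result")
  # ranked by best fusion score, ties by id
  expect_true(all(diff(res$best_fusion_score) <= 0))
  # hit flag definition
  expect_equal(res$hit, res$best_fusion_score > 0.8)
  # predicted IC50 is the exact inverse transform of predicted pIC50
  expect_equal(res$predicted_ic50_nM, 10^(9 - res$predicted_pic50))
  expect_true(all(res$best_anchor_id %in% small_set()$lig$table$id))
  expect_true(all(res$tanimoto_to_best_anchor >= 0 &
                    res$tanimoto_to_best_anchor <= 1))
  # deterministic re-run
  s <- small_set(); sf <- small_fusion(); cf <- candidate_fixture()
  res2 <- screen_library(sf$model, sc$rep_$models$extra_trees$fit,
                         sc$rep_$standardization, s$lig$table, cf$cand$table,
                         ligand_features = s$fe, candidate_features = cf$cfe)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("ranking is invariant to strictly increasing score transforms", {
  sc <- screen_fixture()
  scores <- sc$res$best_fusion_score
  expect_identical(order(-scores^3, sc$res$id), order(-scores, sc$res$id))
})

test_that("a candidate identical to a high-activity ligand outranks decoys", {
  s <- small_set(); sf <- small_fusion(); cf <- candidate_fixture()
  hi <- which(s$lab$klass == "high")
  rng <- ligscreen:::local_rng(17)
  picks <- rng(sample(hi, 20, replace = TRUE))
  wins <- 0L
  truth <- cf$cand$truth
  decoy_ids <- truth$id[!truth$is_analog]
  res <- screen_fixture()$res
  decoy_scores <- res$best_fusion_score[match(decoy_ids, res$id)]
  for (i in seq_len(20)) {
    # clone of a high-activity ligand scored against the anchors
    clone_feats <- list(fp = s$fe$fp[picks[i], , drop = FALSE],
                        desc = s$fe$desc[picks[i], , drop = FALSE],
                        selfies = s$fe$selfies[picks[i], , drop = FALSE])
    merged <- list(fp = rbind(clone_feats$fp, s$fe$fp),
                   desc = rbind(clone_feats$desc, s$fe$desc),
                   selfies = rbind(clone_feats$selfies, s$fe$selfies))
    sc_clone <- max(pair_score_many(sf$model, merged,
                                    rep(1L, length(hi)), 1L + hi))
    decoy <- decoy_scores[1 + (i %% length(decoy_scores))]
    if (sc_clone > decoy) wins <- wins + 1L
  }
  expect_gte(wins / 20, 0.9)
})

test_that("hit export writes stable, re-parsable tables and structures", {
  sc <- screen_fixture()
  d1 <- withr::local_tempdir()
  paths <- export_top_candidates(sc$res, 4L, dir = d1, prefix = "hits")
  tab <- utils::read.csv(paths$table)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$id, sc$res$id[1:4])
  # exported SMILES re-parse to the same canonical forms
  expect_equal(canonicalize_smiles(tab$smiles), sc$res$smiles[1:4])
  # SDF records carry the candidate ids as titles
  sdf_lines <- readLines(paths$sdf)
  expect_equal(sum(sdf_lines == "$$$$"), 4L)
  expect_true(all(sc$res$id[1:4] %in% sdf_lines))
  # byte-identical re-export
  d2 <- withr::local_tempdir()
  paths2 <- export_top_candidates(sc$res, 4L, dir = d2, prefix = "hits")
  expect_identical(readLines(paths$table), readLines(paths2$table))
  expect_identical(readLines(paths$sdf), readLines(paths2$sdf))
  expect_error(export_top_candidates(sc$res, 10000L), "exceeds")
})
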
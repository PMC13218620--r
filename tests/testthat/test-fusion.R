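test_that("pair dataset enumerates the documented positive/negative sets", {
  # 3 high + 2 low (+1 medium, excluded): C(3,2)=3 positives,
  # 2x3 cross + C(2,2)=7 negatives
  tab <- new_ligand_table(data.frame(
    id = letters[1:6], smiles = rep("CCO", 6),
    ic50_nM = 1, pic50 = c(8, 8.2, 9, 4, 4.5, 6), source = "x"))
  labels <- classify_activity(tab$pic50)
  pairs <- build_pair_dataset(tab, labels, max_pairs = 100L, balance = FALSE,
                              seed = 1)
  pos <- pairs[pairs$label == 1, ]; neg <- pairs[pairs$label == 0, ]
  expect_equal(nrow(pos), 3L)
  expect_equal(nrow(neg), 7L)
  hi <- which(labels$klass == "high"); lo <- which(labels$klass == "low")
  expect_true(all(pos$a_idx %in% hi & pos$b_idx %in% hi))
  expect_true(all(neg$a_idx %in% lo | neg$b_idx %in% lo))
  # medium molecules never appear
  expect_false(any(c(pairs$a_idx, pairs$b_idx) == 6L))
  # balance + determinism
  bal <- build_pair_dataset(tab, labels, max_pairs = 6L, balance = TRUE,
                            seed = 2)
  expect_equal(sum(bal$label == 1), sum(bal$label == 0))
  expect_identical(bal, build_pair_dataset(tab, labels, max_pairs = 6L,
                                           balance = TRUE, seed = 2))
  expect_error(build_pair_dataset(tab[1:3, ], classify_activity(tab$pic50[1:3]),
                                  seed = 1), "at least 2")
})

test_that("analytic gradients agree with numerical differentiation", {
  s <- small_set()
  cfg <- fusion_config(hidden_dim = 8L, n_heads = 2L, mlp_dims = c(8L, 4L),
                       dropout = 0, seed = 3L)
  model <- chemfusion_init(s$fe, cfg)
  model$scaling <- list(selfies = standardize_fit(s$fe$selfies),
                        desc = standardize_fit(s$fe$desc))
  X <- ligscreen:::fusion_scale_inputs(model, s$fe, c(1:4, 5:8))
  y <- c(1, 0, 1, 0)
  res <- ligscreen:::fusion_batch_grads(model, X, y)
  loss_at <- function(m) ligscreen:::fusion_batch_grads(m, X, y)$loss
  eps <- 1e-5
  for (nm in c("Ws", "Wf", "Wq", "Wk", "Wv", "Wo", "gamma_f", "beta_d",
               "Wm1", "Wm3", "bm2", "bs")) {
    par <- model$par[[nm]]
    idx <- if (is.matrix(par)) {
      rbind(c(1, 1), c(min(2, nrow(par)), min(2, ncol(par))))
    } else rbind(c(1, NA), c(min(2, length(par)), NA))
    for (k in seq_len(nrow(idx))) {
      m_hi <- model; m_lo <- model
      if (is.matrix(par)) {
        i <- idx[k, 1]; j <- idx[k, 2]
        m_hi$par[[nm]][i, j] <- par[i, j] + eps
        m_lo$par[[nm]][i, j] <- par[i, j] - eps
        g_analytic <- res$grads[[nm]][i, j]
      } else {
        i <- idx[k, 1]
        m_hi$par[[nm]][i] <- par[i] + eps
        m_lo$par[[nm]][i] <- par[i] - eps
        g_analytic <- res$grads[[nm]][i]
      }
      g_numeric <- (loss_at(m_hi) - loss_at(m_lo)) / (2 * eps)
      expect_equal(unname(g_analytic), g_numeric, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("pair scores are symmetric, bounded, and deterministic at inference", {
  sf <- small_fusion()
  s <- small_set()
  rng <- ligscreen:::local_rng(99)
  n <- nrow(s$lig$table)
  ab <- rng(cbind(sample.int(n, 1000, TRUE), sample.int(n, 1000, TRUE)))
  ok <- ab[, 1] != ab[, 2]
  ab <- ab[ok, ]
  s1 <- pair_score_many(sf$model, s$fe, ab[, 1], ab[, 2])
  s2 <- pair_score_many(sf$model, s$fe, ab[, 2], ab[, 1])
  expect_equal(s1, s2, tolerance = 1e-7)
  expect_true(all(s1 > 0 & s1 < 1))
  expect_identical(s1, pair_score_many(sf$model, s$fe, ab[, 1], ab[, 2]))
})

test_that("an untrained model with zeroed output layer scores 0.5", {
  s <- small_set()
  m <- chemfusion_init(s$fe, fusion_config(hidden_dim = 32L, seed = 1L))
  sc <- pair_score_many(m, s$fe, 1:5, 6:10)
  expect_equal(sc, rep(0.5, 5), tolerance = 1e-12)
})

test_that("molecule embeddings have length 3*hidden_dim and forcing uniform
           attention reproduces the mean of the value tokens", {
  s <- small_set()
  m <- chemfusion_init(s$fe, fusion_config(hidden_dim = 32L, n_heads = 4L,
                                           seed = 2L))
  e1 <- embed_molecule(m, features = s$fe, idx = 1L)
  expect_length(e1, 3L * 32L)
  expect_identical(e1, embed_molecule(m, features = s$fe, idx = 1L))

  m$force_uniform_attention <- TRUE
  X <- ligscreen:::fusion_scale_inputs(m, s$fe, 1:6)
  fw <- ligscreen:::fusion_forward_mols(m, X, training = FALSE, keep = TRUE)
  # with uniform weights the per-head context is the mean of the two
  # projected value tokens
  expect_equal(fw$ctx, (fw$Vf + fw$Vd) / 2, tolerance = 1e-12)
  expect_true(all(fw$af == 0.5))
})

test_that("training minimizes MSE, holds out validation pairs, and is
           deterministic under a fixed seed", {
  sf <- small_fusion()
  hist <- sf$model$history
  expect_lt(hist$train_loss[nrow(hist)], hist$train_loss[1])
  # validation pairs are disjoint from gradient pairs
  expect_length(intersect(sf$model$val_pairs, sf$model$train_pairs), 0L)
  expect_setequal(c(sf$model$val_pairs, sf$model$train_pairs),
                  seq_len(nrow(sf$pairs)))
  # full determinism: retrain with the same seed
  s <- small_set()
  cfg <- fusion_config(hidden_dim = 32L, mlp_dims = c(32L, 8L),
                       max_epochs = 6L, batch_size = 32L, seed = 7L)
  m1 <- train_fusion(chemfusion_init(s$fe, cfg), s$fe, sf$pairs)
  m2 <- train_fusion(chemfusion_init(s$fe, cfg), s$fe, sf$pairs)
  expect_equal(min(m1$history$val_loss), min(m2$history$val_loss),
               tolerance = 1e-6)
})

test_that("trained self-similarity exceeds random-decoy similarity", {
  sf <- small_fusion()
  s <- small_set()
  hi <- which(s$lab$klass == "high")
  lo <- which(s$lab$klass == "low")
  rng <- ligscreen:::local_rng(5)
  probes <- rng(list(a = sample(hi, 50, TRUE), d = sample(lo, 50, TRUE)))
  self_sc <- pair_score_many(sf$model, s$fe, probes$a, probes$a)
  decoy_sc <- pair_score_many(sf$model, s$fe, probes$a, probes$d)
  expect_gte(mean(self_sc > decoy_sc), 0.9)
})

test_that("Tanimoto matches brute-force set arithmetic", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  # bits {1,2,3} vs {2,3,4} -> 2 shared / 4 total
  a <- c(1, 1, 1, 0); b <- c(0, 1, 1, 1)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(numeric(8), numeric(8)), 1)   # both-empty convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
  # 50 random fingerprints: matrix vs element-wise brute force
  rng <- ligscreen:::local_rng(21)
  M <- rng(matrix(rbinom(50 * 64, 1, 0.3), 50, 64))
  Tm <- tanimoto_matrix(M)
  for (i in seq_len(10)) {
    for (j in seq_len(50)) {
      inter <- sum(M[i, ] & M[j, ]); un <- sum(M[i, ] | M[j, ])
      expect_identical(Tm[i, j], if (un == 0) 1 else inter / un)
    }
  }
})

test_that("similarity comparison merges per-pair records with a Pearson
           correlation matching the direct formula", {
  sf <- small_fusion()
  s <- small_set()
  sub <- sf$pairs[1:60, ]
  cmp <- compare_similarity_metrics(sf$model, s$fe, sub,
                                    ids = s$lig$table$id)
  expect_equal(nrow(cmp$table), 60L)
  expect_true(all(cmp$table$fusion_score > 0 & cmp$table$fusion_score < 1))
  expect_true(all(cmp$table$tanimoto >= 0 & cmp$table$tanimoto <= 1))
  x <- cmp$table$fusion_score; y <- cmp$table$tanimoto
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cmp$correlation, r_brute, tolerance = 1e-12)
  expect_equal(cmp$n, 60L)
})

test_that("enrichment at k behaves at the identities and under a
           permutation null", {
  is_high <- c(rep(TRUE, 20), rep(FALSE, 80))
  # all top-k high
  scores <- c(rep(1, 20), rep(0, 80))
  e <- enrichment_at_k(scores, is_high, 10)
  expect_equal(e$fraction, 1)
  expect_equal(e$fold, 1 / 0.2)
  # k = n reduces to the base rate
  en <- enrichment_at_k(scores, is_high, 100)
  expect_equal(en$fraction, en$base_rate)
  expect_equal(en$fold, 1)
  # permutation null: random scores give fold ~ 1
  rng <- ligscreen:::local_rng(31)
  folds <- rng(vapply(1:100, function(i) {
    enrichment_at_k(stats::runif(100), is_high, 10)$fold
  }, numeric(1)))
  se <- stats::sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 1), 4 * se + 1e-9)
  # degenerate base rate flagged
  e0 <- enrichment_at_k(scores, rep(FALSE, 100), 10)
  expect_false(e0$fold_defined)
  expect_error(enrichment_at_k(scores, is_high, 0), "k must")
})
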
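test_that("k-means selection reports monotone SSE and best-of-inits", {
  rng <- ligscreen:::local_rng(13)
  X <- rng(matrix(rbinom(40 * 32, 1, 0.3), 40, 32))
  y <- rng(rnorm(40, 6, 1))
  cr <- kmeans_select(X, y, k_range = 2:6, n_init = 10, seed = 2)
  expect_s3_class(cr, "cluster_report")
  expect_true(all(diff(cr$sse_curve) <= 1e-8))
  expect_true(all(cr$silhouette_curve >= -1 & cr$silhouette_curve <= 1))
  expect_true(cr$chosen_k %in% 2:6)
  # the standardized activity column used for clustering
  expect_equal(mean(cr$pic50_z), 0, tolerance = 1e-8)
  expect_equal(sd(cr$pic50_z), 1, tolerance = 1e-8)
  # best-of-n_init: more restarts never worsen the SSE
  cr1 <- kmeans_select(X, y, k_range = 2:6, n_init = 1, seed = 2)
  expect_true(all(cr$sse_curve <= cr1$sse_curve + 1e-8))
  expect_error(kmeans_select(X[1:3, ], y[1:3], k_range = 2:6), "clusters")
})

test_that("three well-separated blobs select k = 3 with high silhouette", {
  rng <- ligscreen:::local_rng(4)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- rng(do.call(rbind, lapply(1:3, function(i) {
    cbind(rnorm(20, centers[i, 1], 0.1), rnorm(20, centers[i, 2], 0.1))
  })))
  cr <- kmeans_select(X, rep(0, 60), k_range = 2:6, n_init = 10, seed = 1)
  expect_equal(cr$chosen_k, 3)
  expect_gt(cr$silhouette_curve[["3"]], 0.9)
})

test_that("k equal to the number of distinct points drives SSE to zero", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(9, 1), c(3, 7))
  cr <- kmeans_select(X, rep(0, 6), k_range = c(5, 6), n_init = 20, seed = 1)
  expect_equal(unname(cr$sse_curve[["6"]]), 0, tolerance = 1e-12)
})

test_that("k-means with k=2 attains the exhaustive-partition optimum", {
  rng <- ligscreen:::local_rng(8)
  X <- rng(matrix(rnorm(8 * 2), 8, 2))
  # brute force: all 2^7 bipartitions
  best_sse <- Inf
  for (mask in 1:(2^7)) {
    g <- c(1L, as.integer(intToBits(mask))[1:7] + 1L)
    if (length(unique(g)) < 2) next
    sse <- sum(vapply(split(seq_len(8), g), function(ix) {
      ctr <- colMeans(X[ix, , drop = FALSE])
      sum(sweep(X[ix, , drop = FALSE], 2, ctr)^2)
    }, numeric(1)))
    best_sse <- min(best_sse, sse)
  }
  cr <- kmeans_select(X, rep(0, 8), k_range = c(2, 3), n_init = 50, seed = 3)
  expect_equal(unname(cr$sse_curve[["2"]]), best_sse, tolerance = 1e-8)
})

test_that("silhouette matches the direct formula on a 6-point toy", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 10), c(10, 11), c(11, 10))
  assign_ <- c(1, 1, 1, 2, 2, 2)
  D <- as.matrix(dist(cbind(X, 0)))
  sil_direct <- vapply(1:6, function(i) {
    own <- setdiff(which(assign_ == assign_[i]), i)
    a <- mean(D[i, own])
    b <- mean(D[i, assign_ != assign_[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  sil_pkg <- cluster::silhouette(assign_, dist(cbind(X, 0)))[, "sil_width"]
  expect_equal(as.numeric(sil_pkg), sil_direct, tolerance = 1e-10)
})

test_that("PCA projection recovers rank-1 structure and matches an eigen
           oracle", {
  t_ <- seq(-2, 2, length.out = 30)
  X <- cbind(t_, 2 * t_, -t_) + 1e-6 * matrix(rnorm(90), 30, 3)
  p <- pca_project(X)
  expect_gt(p$explained[1], 0.999)
  expect_true(all(diff(p$explained) <= 1e-12))
  # invariance (up to sign) to mean shift
  p2 <- pca_project(sweep(X, 2, c(100, -50, 3), "+"))
  expect_equal(abs(p$coords), abs(p2$coords), tolerance = 1e-6)
  # eigen-decomposition oracle on a 5x4 matrix
  rng <- ligscreen:::local_rng(6)
  M <- rng(matrix(rnorm(20), 5, 4))
  pm <- pca_project(M)
  C <- stats::cov(scale(M, center = TRUE, scale = FALSE))
  ev <- eigen(C, symmetric = TRUE)
  coords_oracle <- scale(M, center = TRUE, scale = FALSE) %*% ev$vectors[, 1:2]
  expect_equal(abs(pm$coords), abs(coords_oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate zero-variance input flagged
  expect_true(pca_project(matrix(3, 5, 2))$degenerate)
})

test_that("bit frequencies match hand counts and the law of total
           expectation", {
  fp <- rbind(c(1, 0, 1), c(1, 0, 0), c(1, 1, 1),
              c(0, 0, 1), c(0, 0, 1), c(1, 0, 1))
  assign_ <- c(1, 1, 1, 2, 2, 2)
  bf <- bit_frequency_profile(assign_, fp)
  expect_equal(unname(bf["1", ]), c(1, 1 / 3, 2 / 3))
  expect_equal(unname(bf["2", ]), c(1 / 3, 0, 1))
  expect_true(all(bf >= 0 & bf <= 1))
  sizes <- as.numeric(table(assign_))
  overall <- colMeans(fp)
  expect_equal(unname(colSums(bf * sizes) / sum(sizes)), overall)
  # identical molecules give 0/1 frequencies only
  bfi <- bit_frequency_profile(rep(1, 3), fp[c(1, 1, 1), ])
  expect_true(all(bfi %in% c(0, 1)))
})

test_that("SAR correlations equal the direct Pearson formula and flag
           degenerate inputs", {
  desc <- cbind(MolLogP = c(1, 2, 3, 4, 5), MolWt = c(100, 150, 120, 180, 90),
                NumRotatableBonds = c(1, 2, 3, 1, 2), TPSA = c(30, 40, 35, 50, 20),
                NumHAcceptors = c(1, 2, 3, 4, 5), NumHDonors = rep(2, 5))
  pic50 <- 2 * desc[, "NumHAcceptors"] + 1
  sar <- sar_correlations(desc, pic50)
  expect_equal(sar$r[sar$descriptor == "NumHAcceptors"], 1)
  expect_equal(sar$flag[sar$descriptor == "NumHDonors"], "zero_variance")
  # 5-point oracle for an arbitrary descriptor
  x <- desc[, "MolWt"]
  r_direct <- sum((x - mean(x)) * (pic50 - mean(pic50))) /
    sqrt(sum((x - mean(x))^2) * sum((pic50 - mean(pic50))^2))
  expect_equal(sar$r[sar$descriptor == "MolWt"], r_direct, tolerance = 1e-12)
  # small clusters flagged, not dropped
  sar2 <- sar_correlations(desc[1:2, , drop = FALSE], pic50[1:2])
  expect_true(all(sar2$flag == "small_sample"))
  expect_true(all(is.na(sar2$r)))
})

test_that("MCS recovers the shared ring of phenol and aniline and the
           identity for duplicates", {
  m <- mcs_for_cluster(c("c1ccccc1O", "c1ccccc1N"))
  expect_equal(m$n_atoms, 6L)   # the aromatic carbon ring
  expect_equal(m$n_bonds, 6L)
  expect_false(m$timed_out)
  # pattern matches both members
  expect_true(ligscreen:::pattern_matches(m$pattern, mol_graph("c1ccccc1O")))
  expect_true(ligscreen:::pattern_matches(m$pattern, mol_graph("c1ccccc1N")))

  m2 <- mcs_for_cluster(c("CCO", "CCO"))
  expect_equal(m2$n_atoms, 3L)  # the whole molecule
  expect_equal(m2$smarts, "[#6]-[#6]-[#8]")

  # timeout reported distinctly from an empty pattern
  m3 <- mcs_for_cluster(c(GLUTATHIONE, METHOTREXATE), timeout = 0)
  expect_true(m3$timed_out)
  m4 <- mcs_for_cluster(c("CCCC", "O=S=O"))
  expect_true(m4$empty || m4$n_atoms <= 1L)
  expect_error(mcs_for_cluster("CCO"), "at least 2")
})

test_that("the planted high-activity cluster's MCS carries the hydroxyl", {
  s <- small_set()
  cr <- kmeans_select(s$fe$fp, s$lig$table$pic50, k_range = 2:8,
                      n_init = 10, seed = 1)
  means <- tapply(s$lig$table$pic50, cr$assignments, mean)
  hi_cluster <- as.integer(names(which.max(means)))
  ix <- which(cr$assignments == hi_cluster & s$lab$klass == "high")
  expect_gte(length(ix), 3L)
  m <- mcs_for_cluster(s$lig$table$smiles[ix], min_fraction = 0.9,
                       max_members = 12L)
  expect_false(m$empty)
  expect_true(mcs_contains_hydroxyl(m))
  # the pattern matches the members it claims to match
  checked <- 0L
  for (smi in s$lig$table$smiles[ix][1:min(5, length(ix))] ) {
    g <- mol_graph(smi)
    if (ligscreen:::pattern_matches(m$pattern, g)) checked <- checked + 1L
  }
  expect_gte(checked, 4L)
})
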
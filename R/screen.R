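# Candidate-library screening: diversity reduction of the raw library,
# similarity scoring of each candidate against the ligand anchors with the
# fusion model, activity prediction with the trained regressor, Lipinski
# annotation, hit thresholding and ranked export.

#' Diversity-reduce a candidate library
#'
#' Embeds candidate fingerprints into two dimensions by classical
#' multidimensional scaling (principal coordinates) of Tanimoto/Jaccard
#' distances, overlays a square grid whose resolution is tuned so that the
#' number of occupied cells approximates `target_count`, and keeps the
#' candidate nearest each occupied cell's centroid. Structurally redundant
#' compounds collapse into shared cells and are dropped.
#'
#' @param candidates A `ligand_table`.
#' @param target_count Desired number of kept candidates.
#' @param features Optional precomputed [featurize_table()] result.
#' @param fp_dim,radius Fingerprint parameters when `features` is NULL.
#' @param seed Seed recorded in the metadata (the embedding itself is
#'   deterministic).
#' @return List of class `diversity_selection`: `kept_ids`, `kept_idx`,
#'   `embedding` (n x 2), `method` metadata.
#' @export
diversity_reduce <- function(candidates, target_count, features = NULL,
                             fp_dim = 1024L, radius = 2L, seed = 1L) {
  n <- nrow(candidates)
  if (target_count < 1L || target_count > n) {
    stop("target_count must be in 1..n")
  }
  if (is.null(features)) {
    features <- featurize_table(candidates, fp_dim = fp_dim, radius = radius)
  }
  sim <- tanimoto_matrix(features$fp)
  d <- stats::as.dist(1 - sim)
  emb <- suppressWarnings(stats::cmdscale(d, k = min(2L, n - 1L)))
  if (!is.matrix(emb)) emb <- matrix(emb, nrow = n)
  while (ncol(emb) < 2L) emb <- cbind(emb, 0)
  emb <- emb[, 1:2, drop = FALSE]
  # axes that only carry numerical noise are flattened to zero
  spans <- apply(emb, 2, function(v) diff(range(v)))
  emb[, spans < 1e-6 * max(spans, 1e-12)] <- 0
  # fix reflection so the embedding is reproducible across platforms
  for (j in 1:2) {
    i0 <- which.max(abs(emb[, j]))
    if (emb[i0, j] < 0) emb[, j] <- -emb[, j]
  }

  occupied_cells <- function(res) {
    rng_x <- range(emb[, 1]); rng_y <- range(emb[, 2])
    w_x <- max(rng_x[2] - rng_x[1], 1e-9) / res
    w_y <- max(rng_y[2] - rng_y[1], 1e-9) / res
    cx <- pmin(floor((emb[, 1] - rng_x[1]) / w_x), res - 1)
    cy <- pmin(floor((emb[, 2] - rng_y[1]) / w_y), res - 1)
    cell <- cx * res + cy
    list(cell = cell, n = length(unique(cell)),
         wx = w_x, wy = w_y, x0 = rng_x[1], y0 = rng_y[1], res = res)
  }
  # binary search on grid resolution for ~target_count occupied cells
  lo <- 1L; hi <- max(2L, ceiling(2 * sqrt(n)) * 4L)
  best <- occupied_cells(hi)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    oc <- occupied_cells(mid)
    # prefer the count closest to the target; on ties keep the richer grid
    if (abs(oc$n - target_count) < abs(best$n - target_count) ||
        (abs(oc$n - target_count) == abs(best$n - target_count) &&
           oc$n > best$n)) {
      best <- oc
    }
    if (oc$n < target_count) lo <- mid + 1L else hi <- mid
  }
  oc <- best
  keep <- vapply(unique(oc$cell), function(cl) {
    members <- which(oc$cell == cl)
    if (length(members) == 1L) return(members)
    cx <- oc$x0 + (floor((cl %/% oc$res)) + 0.5) * oc$wx
    cy <- oc$y0 + ((cl %% oc$res) + 0.5) * oc$wy
    d2 <- (emb[members, 1] - cx)^2 + (emb[members, 2] - cy)^2
    members[which.min(d2)]
  }, integer(1))
  keep <- sort(keep)
  structure(list(
    kept_ids = candidates$id[keep], kept_idx = keep, embedding = emb,
    method = list(name = "pcoa_grid", metric = "jaccard",
                  grid_resolution = oc$res, target_count = target_count,
                  seed = seed)
  ), class = "diversity_selection")
}

#' Screen a candidate library against the ligand set
#'
#' Scores every candidate against every ligand anchor (or a configured
#' anchor subset) with the fusion model; records the best anchor, the
#' Tanimoto similarity to it, the regressor-predicted pIC50 (and the
#' implied IC50 in nM), Lipinski violations and the hit flag
#' (`best_fusion_score > hit_threshold`). Results are ranked by best
#' fusion score, ties broken by candidate id.
#'
#' @param model Trained `chemfusion`.
#' @param regressor A fitted `ligscreen_fit` predicting pIC50 from the
#'   concatenated (standardized) feature matrix.
#' @param regressor_standardization The [standardize_fit()] statistics the
#'   regressor was trained with.
#' @param ligands Ligand `ligand_table` (anchors).
#' @param candidates Candidate `ligand_table`.
#' @param ligand_features,candidate_features Optional precomputed feature
#'   containers (vocabulary must match the model).
#' @param hit_threshold Similarity threshold for the hit flag (default 0.8).
#' @param anchor_idx Optional anchor subsample (indices into `ligands`).
#' @return data.frame of class `screen_result`, one row per candidate.
#' @export
screen_library <- function(model, regressor, regressor_standardization,
                           ligands, candidates,
                           ligand_features = NULL, candidate_features = NULL,
                           hit_threshold = 0.8, anchor_idx = NULL) {
  if (is.null(ligand_features)) {
    ligand_features <- featurize_table(ligands, fp_dim = model$meta$fp_dim,
                                       radius = model$meta$radius,
                                       vocab = model$vocab)
  }
  if (is.null(candidate_features)) {
    candidate_features <- featurize_table(candidates,
                                          fp_dim = model$meta$fp_dim,
                                          radius = model$meta$radius,
                                          vocab = model$vocab)
  }
  if (ncol(candidate_features$fp) != model$meta$fp_dim ||
      !identical(candidate_features$vocab, model$vocab)) {
    stop("featurization metadata mismatch between model and candidates")
  }
  if (is.null(anchor_idx)) anchor_idx <- seq_len(nrow(ligands))
  n_c <- nrow(candidates); n_a <- length(anchor_idx)

  merged <- list(
    fp = rbind(candidate_features$fp, ligand_features$fp[anchor_idx, , drop = FALSE]),
    desc = rbind(candidate_features$desc, ligand_features$desc[anchor_idx, , drop = FALSE]),
    selfies = rbind(candidate_features$selfies,
                    ligand_features$selfies[anchor_idx, , drop = FALSE])
  )
  scores <- matrix(0, n_c, n_a)
  for (a in seq_len(n_a)) {
    scores[, a] <- pair_score_many(model, merged, seq_len(n_c),
                                   rep(n_c + a, n_c))
  }
  best_a <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(n_c), best_a)]
  tani <- vapply(seq_len(n_c), function(i) {
    tanimoto(candidate_features$fp[i, ],
             ligand_features$fp[anchor_idx[best_a[i]], ])
  }, numeric(1))

  Xc <- cbind(candidate_features$fp, candidate_features$desc)
  colnames(Xc) <- c(paste0("fp_", seq_len(ncol(candidate_features$fp))),
                    DESCRIPTOR_NAMES)
  Xc_std <- standardize_apply(Xc, regressor_standardization)
  pred_pic50 <- predict(regressor, Xc_std)
  lip <- lipinski(candidate_features$desc)

  out <- data.frame(
    id = candidates$id, smiles = candidates$smiles,
    best_fusion_score = best_score,
    best_anchor_id = ligands$id[anchor_idx[best_a]],
    tanimoto_to_best_anchor = tani,
    predicted_pic50 = pred_pic50,
    predicted_ic50_nM = 10^(9 - pred_pic50),
    lipinski_violations = lip$violations,
    hit = best_score > hit_threshold,
    stringsAsFactors = FALSE
  )
  ord <- order(-out$best_fusion_score, out$id)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "anchor_policy") <- list(
    n_anchors = n_a,
    subsampled = n_a < nrow(ligands),
    hit_threshold = hit_threshold
  )
  class(out) <- c("screen_result", "data.frame")
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x), " candidates, ", sum(x$hit),
      " hits (threshold ",
      attr(x, "anchor_policy")$hit_threshold, ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)[, c("id", "best_fusion_score",
                                                    "predicted_pic50", "hit")], 8))
  invisible(x)
}

#' Export top-ranked candidates for downstream docking
#'
#' Writes the first `n` rows of a ranked screen result as a delimited hit
#' table plus an SDF structure file (one record per hit, title = id).
#' Output is byte-stable across re-exports and never mutates the input.
#'
#' @param results A `screen_result`.
#' @param n Number of top candidates to export.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the paths written (`table`, `sdf`).
#' @export
export_top_candidates <- function(results, n, dir = ".", prefix = "top_hits") {
  if (n > nrow(results)) stop("n exceeds the number of screened candidates")
  top <- as.data.frame(results)[seq_len(n), ]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab_path <- file.path(dir, paste0(prefix, ".csv"))
  num <- vapply(top, is.numeric, logical(1))
  top[num] <- lapply(top[num], function(v) formatC(v, digits = 17, format = "g"))
  utils::write.table(top, tab_path, sep = ",", row.names = FALSE, quote = FALSE)

  sdf_path <- file.path(dir, paste0(prefix, ".sdf"))
  blocks <- vapply(seq_len(n), function(i) {
    blk <- ob_convert1(top$smiles[i], "SDF")
    if (is.na(blk)) stop("structure export failed for ", top$id[i])
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    lines[1] <- top$id[i]
    lines[2] <- "  ligscreen"        # drop the timestamped program line
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), sdf_path)
  invisible(list(table = tab_path, sdf = sdf_path))
}
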
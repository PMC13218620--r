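# Multi-representation similarity model. Three modality encoders (SELFIES
# token counts, Morgan fingerprint bits, physicochemical descriptors) map
# into a shared hidden space; a multi-head attention block uses the SELFIES
# embedding as the query over the fingerprint and descriptor embeddings as
# a two-token key/value sequence; the attended output is concatenated with
# the fingerprint and descriptor embeddings into the molecule embedding.
# Pairs are scored with shared (siamese) encoders through the symmetric
# combination [|e_a - e_b|, e_a * e_b] and a sigmoid MLP head, trained with
# MSE against {0,1} interaction-potential labels.
#
# The network is implemented directly on base-R matrices with analytic
# backpropagation (gradient-checked in the test suite), Adam updates, a
# reduce-on-plateau learning-rate schedule and early stopping.

#' Fusion model configuration
#'
#' @param hidden_dim Shared hidden width (divisible by `n_heads`).
#' @param n_heads Attention heads.
#' @param dropout Dropout probability in the encoders and fusion head.
#' @param mlp_dims Hidden widths of the fusion MLP.
#' @param lr Adam learning rate.
#' @param max_epochs Training epoch cap.
#' @param batch_size Pairs per minibatch.
#' @param patience Plateau patience: epochs without validation improvement
#'   before the learning rate is halved.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param val_fraction Fraction of pairs held out for validation.
#' @param seed Seed for initialization, batching and dropout.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(hidden_dim = 128L, n_heads = 4L, dropout = 0.2,
                          mlp_dims = c(128L, 32L), lr = 1e-3,
                          max_epochs = 50L, batch_size = 64L,
                          patience = 5L, early_stop_patience = 10L,
                          val_fraction = 0.15, seed = 1L) {
  if (hidden_dim %% n_heads != 0L) {
    stop("hidden_dim must be divisible by n_heads")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_heads = as.integer(n_heads), dropout = dropout,
                 mlp_dims = as.integer(mlp_dims), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "fusion_config")
}

init_mat <- function(nr, nc, scale) {
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

#' Initialize an untrained fusion model
#'
#' @param features A [featurize_table()] result (defines the input
#'   dimensions and the SELFIES vocabulary).
#' @param config A [fusion_config()].
#' @return An object of class `chemfusion` (untrained).
#' @export
chemfusion_init <- function(features, config = fusion_config()) {
  S <- ncol(features$selfies); Fd <- ncol(features$fp); D <- ncol(features$desc)
  h <- config$hidden_dim
  old <- local_rng(config$seed)
  par <- old({
    p <- list(
      Ws = init_mat(S, h, sqrt(2 / S)), bs = numeric(h),
      Wf = init_mat(Fd, h, sqrt(2 / Fd)), bf = numeric(h),
      Wd = init_mat(D, h, sqrt(2 / D)), bd = numeric(h),
      gamma_f = rep(1, h), beta_f = numeric(h),
      gamma_d = rep(1, h), beta_d = numeric(h),
      Wq = init_mat(h, h, sqrt(1 / h)), bq = numeric(h),
      Wk = init_mat(h, h, sqrt(1 / h)), bk = numeric(h),
      Wv = init_mat(h, h, sqrt(1 / h)), bv = numeric(h),
      Wo = init_mat(h, h, sqrt(1 / h)), bo = numeric(h)
    )
    dims <- c(6L * h, config$mlp_dims, 1L)
    n_layers <- length(dims) - 1L
    for (l in seq_len(n_layers)) {
      # zero-initialized output layer: an untrained model scores 0.5
      scale <- if (l == n_layers) 0 else sqrt(2 / dims[l])
      p[[paste0("Wm", l)]] <- init_mat(dims[l], dims[l + 1L], scale)
      p[[paste0("bm", l)]] <- numeric(dims[l + 1L])
    }
    p
  })
  structure(list(
    par = par, config = config,
    running = list(mean_f = numeric(h), var_f = rep(1, h),
                   mean_d = numeric(h), var_d = rep(1, h)),
    scaling = NULL,           # per-modality standardization, set at training
    vocab = features$vocab, meta = features$meta,
    n_mlp = length(config$mlp_dims) + 1L,
    trained = FALSE, history = NULL,
    force_uniform_attention = FALSE
  ), class = "chemfusion")
}

#' @export
print.chemfusion <- function(x, ...) {
  cfg <- x$config
  cat("<chemfusion> hidden_dim=", cfg$hidden_dim, " heads=", cfg$n_heads,
      " mlp=[", paste(cfg$mlp_dims, collapse = ","), "] ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  if (!is.null(x$history)) {
    best <- min(x$history$val_loss)
    cat("  epochs:", nrow(x$history), " best val MSE:",
        signif(best, 4), "\n")
  }
  invisible(x)
}

# scale inputs with training-set statistics (fingerprints stay 0/1)
fusion_scale_inputs <- function(model, feats, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(feats$fp))
  sc <- model$scaling
  Xs <- feats$selfies[idx, , drop = FALSE]
  Xd <- feats$desc[idx, , drop = FALSE]
  if (!is.null(sc)) {
    Xs <- standardize_apply(Xs, sc$selfies)
    Xd <- standardize_apply(Xd, sc$desc)
  }
  list(s = Xs, f = feats$fp[idx, , drop = FALSE], d = Xd)
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))
BN_EPS <- 1e-5

# Forward pass for a batch of molecules. training=TRUE uses batch
# statistics (and dropout); eval uses running statistics, no dropout.
# Returns the embedding and, when keep=TRUE, every intermediate needed by
# the backward pass.
fusion_forward_mols <- function(model, X, training = FALSE, keep = FALSE) {
  par <- model$par; cfg <- model$config
  h <- cfg$hidden_dim; nh <- cfg$n_heads; dh <- h %/% nh
  B <- nrow(X$s)

  Es <- X$s %*% par$Ws + rep(par$bs, each = B)

  enc_block <- function(Xin, W, b, gamma, beta, rmean, rvar) {
    A <- Xin %*% W + rep(b, each = B)
    R <- relu(A)
    if (training && cfg$dropout > 0) {
      mask <- matrix(stats::runif(length(R)) >= cfg$dropout, B, h) /
        (1 - cfg$dropout)
      Dp <- R * mask
    } else {
      mask <- NULL; Dp <- R
    }
    if (training) {
      mu <- colMeans(Dp)
      va <- colMeans(Dp^2) - mu^2
      va[va < 0] <- 0
    } else {
      mu <- rmean; va <- rvar
    }
    xhat <- sweep(sweep(Dp, 2, mu, "-"), 2, sqrt(va + BN_EPS), "/")
    E <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    list(A = A, R = R, mask = mask, Dp = Dp, mu = mu, va = va,
         xhat = xhat, E = E)
  }

  f <- enc_block(X$f, par$Wf, par$bf, par$gamma_f, par$beta_f,
                 model$running$mean_f, model$running$var_f)
  d <- enc_block(X$d, par$Wd, par$bd, par$gamma_d, par$beta_d,
                 model$running$mean_d, model$running$var_d)
  Ef <- f$E; Ed <- d$E

  Q <- Es %*% par$Wq + rep(par$bq, each = B)
  Kf <- Ef %*% par$Wk + rep(par$bk, each = B)
  Kd <- Ed %*% par$Wk + rep(par$bk, each = B)
  Vf <- Ef %*% par$Wv + rep(par$bv, each = B)
  Vd <- Ed %*% par$Wv + rep(par$bv, each = B)

  ctx <- matrix(0, B, h)
  af <- matrix(0, B, nh); ad <- matrix(0, B, nh)
  for (j in seq_len(nh)) {
    cols <- ((j - 1L) * dh + 1L):(j * dh)
    if (isTRUE(model$force_uniform_attention)) {
      afj <- rep(0.5, B)
    } else {
      sf <- rowSums(Q[, cols, drop = FALSE] * Kf[, cols, drop = FALSE]) / sqrt(dh)
      sd_ <- rowSums(Q[, cols, drop = FALSE] * Kd[, cols, drop = FALSE]) / sqrt(dh)
      m <- pmax(sf, sd_)
      ef <- exp(sf - m); ed <- exp(sd_ - m)
      afj <- ef / (ef + ed)
    }
    af[, j] <- afj; ad[, j] <- 1 - afj
    ctx[, cols] <- afj * Vf[, cols, drop = FALSE] +
      (1 - afj) * Vd[, cols, drop = FALSE]
  }
  O <- ctx %*% par$Wo + rep(par$bo, each = B)
  embed <- cbind(O, Ef, Ed)

  out <- list(embed = embed)
  if (keep) {
    out <- c(out, list(X = X, Es = Es, f = f, d = d, Ef = Ef, Ed = Ed,
                       Q = Q, Kf = Kf, Kd = Kd, Vf = Vf, Vd = Vd,
                       af = af, ad = ad, ctx = ctx))
  }
  out
}

# Fusion head on a batch of embedding pairs.
fusion_head_forward <- function(model, Ea, Eb, training = FALSE, keep = FALSE) {
  par <- model$par; cfg <- model$config
  n <- nrow(Ea)
  z <- cbind(abs(Ea - Eb), Ea * Eb)
  acts <- list(z)
  masks <- list()
  H <- z
  for (l in seq_len(model$n_mlp)) {
    W <- par[[paste0("Wm", l)]]; b <- par[[paste0("bm", l)]]
    A <- H %*% W + rep(b, each = n)
    if (l < model$n_mlp) {
      H <- relu(A)
      if (training && cfg$dropout > 0 && l == 1L) {
        mask <- matrix(stats::runif(length(H)) >= cfg$dropout, n, ncol(H)) /
          (1 - cfg$dropout)
        H <- H * mask
        masks[[l]] <- mask
      }
    } else {
      H <- A
    }
    acts[[l + 1L]] <- H
  }
  p <- sigmoid(as.numeric(H))
  out <- list(score = p)
  if (keep) out <- c(out, list(z = z, acts = acts, masks = masks))
  out
}

# Full forward + analytic gradients for one minibatch of pairs.
# Molecule rows: 1..n are the `a` members, n+1..2n the `b` members.
fusion_batch_grads <- function(model, X, y) {
  par <- model$par; cfg <- model$config
  h <- cfg$hidden_dim; nh <- cfg$n_heads; dh <- h %/% nh
  n <- length(y); B <- 2L * n

  fw <- fusion_forward_mols(model, X, training = TRUE, keep = TRUE)
  Ea <- fw$embed[seq_len(n), , drop = FALSE]
  Eb <- fw$embed[n + seq_len(n), , drop = FALSE]
  hd <- fusion_head_forward(model, Ea, Eb, training = TRUE, keep = TRUE)
  p <- hd$score
  loss <- mean((p - y)^2)

  g <- lapply(par, function(x) array(0, dim = if (is.matrix(x)) dim(x) else length(x)))
  for (nm in names(par)) if (!is.matrix(par[[nm]])) g[[nm]] <- numeric(length(par[[nm]]))

  # head backward
  dA <- matrix(2 * (p - y) * p * (1 - p) / n, ncol = 1)
  for (l in rev(seq_len(model$n_mlp))) {
    W <- par[[paste0("Wm", l)]]
    Hin <- hd$acts[[l]]
    g[[paste0("Wm", l)]] <- t(Hin) %*% dA
    g[[paste0("bm", l)]] <- colSums(dA)
    dH <- dA %*% t(W)
    if (l > 1L) {
      if (length(hd$masks) >= l - 1L && !is.null(hd$masks[[l - 1L]])) {
        dH <- dH * hd$masks[[l - 1L]]
      }
      dA <- dH * (hd$acts[[l]] > 0)       # relu mask of layer l-1 output
    } else {
      dz <- dH
    }
  }
  # careful: relu mask must come from the *pre-dropout* positive part; the
  # stored activation is positive exactly where the pre-activation was, so
  # the mask above is correct for dropout-less layers; for the dropout
  # layer the mask zeroes the same entries.

  dAbs <- dz[, seq_len(3 * h), drop = FALSE]
  dProd <- dz[, 3 * h + seq_len(3 * h), drop = FALSE]
  sgn <- sign(Ea - Eb)
  dEa <- dAbs * sgn + dProd * Eb
  dEb <- -dAbs * sgn + dProd * Ea
  dE <- rbind(dEa, dEb)                    # B x 3h

  dO <- dE[, seq_len(h), drop = FALSE]
  dEf <- dE[, h + seq_len(h), drop = FALSE]
  dEd <- dE[, 2 * h + seq_len(h), drop = FALSE]

  g$Wo <- t(fw$ctx) %*% dO
  g$bo <- colSums(dO)
  dctx <- dO %*% t(par$Wo)

  dQ <- matrix(0, B, h); dKf <- matrix(0, B, h); dKd <- matrix(0, B, h)
  dVf <- matrix(0, B, h); dVd <- matrix(0, B, h)
  for (j in seq_len(nh)) {
    cols <- ((j - 1L) * dh + 1L):(j * dh)
    dc <- dctx[, cols, drop = FALSE]
    afj <- fw$af[, j]; adj <- fw$ad[, j]
    dVf[, cols] <- afj * dc
    dVd[, cols] <- adj * dc
    if (!isTRUE(model$force_uniform_attention)) {
      daf <- rowSums(dc * fw$Vf[, cols, drop = FALSE])
      dad <- rowSums(dc * fw$Vd[, cols, drop = FALSE])
      dot <- daf * afj + dad * adj
      dsf <- afj * (daf - dot)
      dsd <- adj * (dad - dot)
      dQ[, cols] <- (dsf * fw$Kf[, cols, drop = FALSE] +
                       dsd * fw$Kd[, cols, drop = FALSE]) / sqrt(dh)
      dKf[, cols] <- dsf * fw$Q[, cols, drop = FALSE] / sqrt(dh)
      dKd[, cols] <- dsd * fw$Q[, cols, drop = FALSE] / sqrt(dh)
    }
  }

  g$Wq <- t(fw$Es) %*% dQ; g$bq <- colSums(dQ)
  g$Wk <- t(fw$Ef) %*% dKf + t(fw$Ed) %*% dKd
  g$bk <- colSums(dKf) + colSums(dKd)
  g$Wv <- t(fw$Ef) %*% dVf + t(fw$Ed) %*% dVd
  g$bv <- colSums(dVf) + colSums(dVd)

  dEs <- dQ %*% t(par$Wq)
  dEf_tot <- dEf + dKf %*% t(par$Wk) + dVf %*% t(par$Wv)
  dEd_tot <- dEd + dKd %*% t(par$Wk) + dVd %*% t(par$Wv)

  g$Ws <- t(X$s) %*% dEs; g$bs <- colSums(dEs)

  bn_back <- function(enc, dE_mod, gamma) {
    xhat <- enc$xhat
    dgamma <- colSums(dE_mod * xhat)
    dbeta <- colSums(dE_mod)
    dxhat <- sweep(dE_mod, 2, gamma, "*")
    istd <- 1 / sqrt(enc$va + BN_EPS)
    Bn <- nrow(xhat)
    # dDp = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
    dDp <- sweep(dxhat - matrix(rep(colMeans(dxhat), each = Bn), Bn) -
                   xhat * matrix(rep(colMeans(dxhat * xhat), each = Bn), Bn),
                 2, istd, "*")
    list(dgamma = dgamma, dbeta = dbeta, dDp = dDp)
  }

  bf_ <- bn_back(fw$f, dEf_tot, par$gamma_f)
  bd_ <- bn_back(fw$d, dEd_tot, par$gamma_d)
  g$gamma_f <- bf_$dgamma; g$beta_f <- bf_$dbeta
  g$gamma_d <- bd_$dgamma; g$beta_d <- bd_$dbeta

  dRf <- if (is.null(fw$f$mask)) bf_$dDp else bf_$dDp * fw$f$mask
  dRd <- if (is.null(fw$d$mask)) bd_$dDp else bd_$dDp * fw$d$mask
  dAf <- dRf * (fw$f$A > 0)
  dAd <- dRd * (fw$d$A > 0)
  g$Wf <- t(X$f) %*% dAf; g$bf <- colSums(dAf)
  g$Wd <- t(X$d) %*% dAd; g$bd <- colSums(dAd)

  list(loss = loss, grads = g, score = p,
       batch_stats = list(mu_f = fw$f$mu, va_f = fw$f$va,
                          mu_d = fw$d$mu, va_d = fw$d$va))
}

#' Build a labeled pair dataset from activity classes
#'
#' Positive pairs (label 1) are sampled from high-activity x high-activity
#' combinations; negative pairs (label 0) from pairs containing at least
#' one low-activity member. Medium-activity molecules are excluded
#' entirely. With `balance = TRUE` the classes are subsampled to equal
#' size, capped at `max_pairs` total.
#'
#' @param table A `ligand_table` (row order defines indices).
#' @param labels Result of [classify_activity()] aligned with `table`.
#' @param max_pairs Cap on total pairs (default 2000).
#' @param balance Force equal class sizes (default TRUE).
#' @param seed Sampling seed.
#' @return data.frame with columns `a_idx`, `b_idx`, `label`.
#' @export
build_pair_dataset <- function(table, labels, max_pairs = 2000L,
                               balance = TRUE, seed = 1L) {
  stopifnot(nrow(table) == nrow(labels))
  hi <- which(labels$klass == "high")
  lo <- which(labels$klass == "low")
  if (length(hi) < 2L || length(lo) < 2L) {
    stop("need at least 2 high-activity and 2 low-activity molecules")
  }
  pos <- t(utils::combn(hi, 2L))
  neg_ll <- t(utils::combn(lo, 2L))
  neg_lh <- as.matrix(expand.grid(a = lo, b = hi, KEEP.OUT.ATTRS = FALSE))
  neg <- rbind(neg_ll, neg_lh)
  rng <- local_rng(seed)
  rng({
    n_pos_cap <- if (balance) min(nrow(pos), nrow(neg), max_pairs %/% 2L) else
      min(nrow(pos), max_pairs %/% 2L)
    n_neg_cap <- if (balance) n_pos_cap else
      min(nrow(neg), max_pairs - n_pos_cap)
    pos <- pos[sample.int(nrow(pos), n_pos_cap), , drop = FALSE]
    neg <- neg[sample.int(nrow(neg), n_neg_cap), , drop = FALSE]
  })
  out <- data.frame(
    a_idx = c(pos[, 1], neg[, 1]),
    b_idx = c(pos[, 2], neg[, 2]),
    label = c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  )
  out[out$a_idx == out$b_idx, ] <- NA
  out <- out[stats::complete.cases(out), ]
  rownames(out) <- NULL
  out
}

#' Train the fusion similarity model
#'
#' Minimizes the mean squared error between pair scores and {0,1} labels
#' with Adam; the learning rate is halved when the validation loss
#' plateaus (`patience` epochs), training stops after
#' `early_stop_patience` epochs without improvement, and the
#' best-validation weights are restored. Per-modality standardization
#' statistics are fitted on the training molecules and stored with the
#' model.
#'
#' @param model A `chemfusion` from [chemfusion_init()].
#' @param features The [featurize_table()] result the pairs index into.
#' @param pairs data.frame from [build_pair_dataset()].
#' @param quiet Suppress progress output.
#' @return The trained `chemfusion`, with `history` (per-epoch train and
#'   validation loss and learning rate).
#' @export
train_fusion <- function(model, features, pairs, quiet = TRUE) {
  cfg <- model$config
  if (!nrow(pairs)) stop("empty pair dataset")
  mol_idx <- sort(unique(c(pairs$a_idx, pairs$b_idx)))
  model$scaling <- list(
    selfies = standardize_fit(features$selfies[mol_idx, , drop = FALSE]),
    desc = standardize_fit(features$desc[mol_idx, , drop = FALSE])
  )

  rng <- local_rng(cfg$seed + 7L)
  n <- nrow(pairs)
  n_val <- max(1L, round(cfg$val_fraction * n))
  val_ix <- rng(sort(sample.int(n, n_val)))
  tr_ix <- setdiff(seq_len(n), val_ix)
  if (!length(tr_ix)) stop("no training pairs left after validation split")

  adam <- list(m = lapply(model$par, function(x) x * 0),
               v = lapply(model$par, function(x) x * 0), t = 0L)
  lr <- cfg$lr
  best_val <- Inf; best_par <- model$par; best_running <- model$running
  bad_epochs <- 0L; plateau <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  mom <- 0.1

  val_loss_fn <- function(m) {
    sc <- pair_score_many(m, features, pairs$a_idx[val_ix], pairs$b_idx[val_ix])
    mean((sc - pairs$label[val_ix])^2)
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    # one private RNG scope per epoch covers the shuffle and every
    # dropout draw, making training bit-reproducible under the seed
    erng <- local_rng(cfg$seed + 100L + epoch)
    erng({
    ord <- sample(tr_ix)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; ep_n <- 0L
    for (b in batches) {
      ab <- c(pairs$a_idx[b], pairs$b_idx[b])
      X <- fusion_scale_inputs(model, features, ab)
      res <- fusion_batch_grads(model, X, pairs$label[b])
      if (!is.finite(res$loss)) {
        stop("fusion training diverged (non-finite loss) at epoch ", epoch)
      }
      ep_loss <- ep_loss + res$loss * length(b); ep_n <- ep_n + length(b)
      # Adam update
      adam$t <- adam$t + 1L
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (nm in names(model$par)) {
        gr <- res$grads[[nm]]
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * gr
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * gr^2
        mhat <- adam$m[[nm]] / (1 - b1^adam$t)
        vhat <- adam$v[[nm]] / (1 - b2^adam$t)
        model$par[[nm]] <- model$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      bs <- res$batch_stats
      model$running$mean_f <- (1 - mom) * model$running$mean_f + mom * bs$mu_f
      model$running$var_f <- (1 - mom) * model$running$var_f + mom * bs$va_f
      model$running$mean_d <- (1 - mom) * model$running$mean_d + mom * bs$mu_d
      model$running$var_d <- (1 - mom) * model$running$var_d + mom * bs$va_d
    }
    })
    vl <- val_loss_fn(model)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                   val_loss = vl, lr = lr))
    if (!quiet) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2g",
                      epoch, ep_loss / ep_n, vl, lr))
    }
    if (vl < best_val - 1e-6) {
      best_val <- vl; best_par <- model$par; best_running <- model$running
      bad_epochs <- 0L; plateau <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      plateau <- plateau + 1L
      if (plateau >= cfg$patience) {
        lr <- lr / 2
        plateau <- 0L
      }
      if (bad_epochs >= cfg$early_stop_patience) break
    }
  }
  model$par <- best_par
  model$running <- best_running
  model$trained <- TRUE
  model$history <- hist
  model$val_pairs <- val_ix
  model$train_pairs <- tr_ix
  model
}

#' Embed one molecule
#'
#' Runs the per-molecule pathway (three encoders, attention with the
#' SELFIES embedding as query over the fingerprint/descriptor embeddings,
#' concatenation) in evaluation mode.
#'
#' @param model A `chemfusion`.
#' @param bundle A feature bundle: list with `fp`, `desc`, `selfies_vec`
#'   vectors, or a [featurize_table()] result plus `idx`.
#' @param features,idx Alternative interface: features container and row
#'   index.
#' @return Numeric embedding of length `3 * hidden_dim`.
#' @export
embed_molecule <- function(model, bundle = NULL, features = NULL, idx = NULL) {
  if (is.null(features)) {
    features <- list(fp = matrix(bundle$fp, 1), desc = matrix(bundle$desc, 1),
                     selfies = matrix(bundle$selfies_vec, 1))
    idx <- 1L
  }
  if (ncol(features$fp) != model$meta$fp_dim) {
    stop("fingerprint dimension does not match the model's configuration")
  }
  X <- fusion_scale_inputs(model, features, idx)
  as.numeric(fusion_forward_mols(model, X, training = FALSE)$embed)
}

#' Vectorized pair scores
#'
#' Scores many molecule pairs at once; `a_idx`/`b_idx` index rows of the
#' feature container.
#'
#' @param model A `chemfusion`.
#' @param features A [featurize_table()] result.
#' @param a_idx,b_idx Equal-length integer vectors.
#' @return Numeric vector of similarity scores in (0, 1).
#' @export
pair_score_many <- function(model, features, a_idx, b_idx) {
  stopifnot(length(a_idx) == length(b_idx))
  n <- length(a_idx)
  X <- fusion_scale_inputs(model, features, c(a_idx, b_idx))
  emb <- fusion_forward_mols(model, X, training = FALSE)$embed
  Ea <- emb[seq_len(n), , drop = FALSE]
  Eb <- emb[n + seq_len(n), , drop = FALSE]
  fusion_head_forward(model, Ea, Eb, training = FALSE)$score
}

#' Similarity score for a molecule pair
#'
#' Symmetric by construction (the head consumes `[|e_a - e_b|, e_a * e_b]`)
#' and strictly inside (0, 1) via the final sigmoid.
#'
#' @param model A `chemfusion`.
#' @param bundle_a,bundle_b Feature bundles (see [embed_molecule()]).
#' @return Similarity score in (0, 1).
#' @export
pair_score <- function(model, bundle_a, bundle_b) {
  feats <- list(
    fp = rbind(bundle_a$fp, bundle_b$fp),
    desc = rbind(bundle_a$desc, bundle_b$desc),
    selfies = rbind(bundle_a$selfies_vec, bundle_b$selfies_vec)
  )
  pair_score_many(model, feats, 1L, 2L)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|A intersect B| / |A union B|` over set bits; defined as 1 when both
#' vectors are all-zero.
#'
#' @param fp_a,fp_b Equal-length binary vectors.
#' @return Similarity in [0, 1].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprint length mismatch")
  a <- fp_a != 0; b <- fp_b != 0
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' Tanimoto similarity matrix
#'
#' @param A n x bits binary matrix.
#' @param B m x bits binary matrix (default `A`).
#' @return n x m matrix of Tanimoto similarities.
#' @export
tanimoto_matrix <- function(A, B = A) {
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch")
  A <- (A != 0) * 1; B <- (B != 0) * 1
  inter <- A %*% t(B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  out <- ifelse(un == 0, 1, inter / pmax(un, 1))
  out
}

#' Merge fusion and Tanimoto similarity per pair
#'
#' One record per pair with both similarity scores and the pair label,
#' plus the Pearson correlation between the two metrics.
#'
#' @param model Trained `chemfusion`.
#' @param features Feature container the pairs index into.
#' @param pairs Pair data.frame (`a_idx`, `b_idx`, optional `label`).
#' @param ids Optional molecule identifiers for the output table.
#' @return List with `table` (pair_id, id_a, id_b, fusion_score, tanimoto,
#'   label), `correlation`, `n`.
#' @export
compare_similarity_metrics <- function(model, features, pairs, ids = NULL) {
  fs <- pair_score_many(model, features, pairs$a_idx, pairs$b_idx)
  tn <- vapply(seq_len(nrow(pairs)), function(i) {
    tanimoto(features$fp[pairs$a_idx[i], ], features$fp[pairs$b_idx[i], ])
  }, numeric(1))
  lab <- if ("label" %in% names(pairs)) pairs$label else NA_integer_
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features$fp)))
  tab <- data.frame(pair_id = seq_len(nrow(pairs)),
                    id_a = ids[pairs$a_idx], id_b = ids[pairs$b_idx],
                    fusion_score = fs, tanimoto = tn, label = lab)
  r <- if (stats::sd(fs) == 0 || stats::sd(tn) == 0) NA_real_ else
    stats::cor(fs, tn)
  list(table = tab, correlation = r, n = nrow(tab))
}

#' Enrichment of actives among the top-ranked candidates
#'
#' Fraction of high-activity entries among the k top-scored candidates and
#' the fold enrichment over the base rate. Ties are broken by the stable
#' candidate order.
#'
#' @param scores Per-candidate scores (higher = better).
#' @param is_high Logical vector of the same length.
#' @param k Number of top candidates.
#' @return List with `fraction`, `fold`, `base_rate`, `k`,
#'   `fold_defined`.
#' @export
enrichment_at_k <- function(scores, is_high, k) {
  stopifnot(length(scores) == length(is_high))
  if (k <= 0 || k > length(scores)) stop("k must be in 1..n")
  ord <- order(-scores, seq_along(scores))
  top <- ord[seq_len(k)]
  frac <- mean(is_high[top])
  base <- mean(is_high)
  if (base == 0) {
    list(fraction = frac, fold = NA_real_, base_rate = 0, k = k,
         fold_defined = FALSE)
  } else {
    list(fraction = frac, fold = frac / base, base_rate = base, k = k,
         fold_defined = TRUE)
  }
}
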
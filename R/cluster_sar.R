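# Post-screening analytics: K-means over fingerprints + standardized
# pIC50 with elbow/silhouette cluster-count selection, PCA projection,
# fingerprint-bit frequency profiles, per-cluster descriptor/activity
# correlations, and per-cluster maximum common substructure.

#' K-means with cluster-count selection
#'
#' Clusters the combined matrix of fingerprint bits and the z-scored pIC50
#' column. For each k in `k_range` the best of `n_init` seeded
#' k-means++ style restarts (lowest within-cluster SSE) is kept, the SSE
#' (elbow) and mean silhouette curves are recorded, and the chosen k is
#' the silhouette argmax (the elbow curve is reported for inspection).
#'
#' @param fp n x bits fingerprint matrix.
#' @param pic50 Numeric vector of activities (standardized internally).
#' @param k_range Candidate cluster counts (default 2:6).
#' @param n_init Restarts per k (default 20).
#' @param seed Seed for the restarts.
#' @return List of class `cluster_report`: `chosen_k`, `assignments`,
#'   `sse_curve`, `silhouette_curve`, `selection`, `features`.
#' @export
kmeans_select <- function(fp, pic50, k_range = 2:6, n_init = 20L, seed = 1L) {
  stopifnot(nrow(fp) == length(pic50))
  if (length(k_range) < 2L) stop("k_range must contain at least 2 values")
  n <- nrow(fp)
  if (n < max(k_range)) stop("more clusters requested than data points")
  z <- if (stats::sd(pic50) == 0) rep(0, n) else
    (pic50 - mean(pic50)) / stats::sd(pic50)
  X <- cbind(fp, pic50_z = z)
  D <- stats::dist(X)

  sse <- sil <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    best <- NULL
    for (init in seq_len(n_init)) {
      rng <- local_rng(seed + 1000L * k + init)
      # Hartigan-Wong can fail with empty clusters when k approaches n;
      # fall back to Lloyd in that case
      fit <- rng(tryCatch(
        stats::kmeans(X, centers = k, iter.max = 50L, nstart = 1L),
        error = function(e) tryCatch(
          suppressWarnings(stats::kmeans(X, centers = k, iter.max = 50L,
                                         nstart = 1L, algorithm = "Lloyd")),
          error = function(e2) NULL)))
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed for k = ", k)
    fits[[as.character(k)]] <- best
    sse[i] <- best$tot.withinss
    sil[i] <- if (length(unique(best$cluster)) < 2L) NA_real_ else {
      sw <- cluster::silhouette(best$cluster, D)
      # all-singleton clusterings have no defined silhouette
      if (!is.matrix(sw)) NA_real_ else mean(sw[, "sil_width"])
    }
  }
  chosen <- k_range[which.max(sil)]
  structure(list(
    chosen_k = chosen,
    assignments = fits[[as.character(chosen)]]$cluster,
    sse_curve = sse, silhouette_curve = sil,
    selection = "silhouette argmax (elbow curve reported alongside)",
    centers = fits[[as.character(chosen)]]$centers,
    features = X, pic50_z = z, seed = seed
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> chosen k =", x$chosen_k, "(", x$selection, ")\n")
  cat("  SSE:", paste(sprintf("k%s=%.1f", names(x$sse_curve), x$sse_curve),
                      collapse = "  "), "\n")
  cat("  silhouette:", paste(sprintf("k%s=%.3f", names(x$silhouette_curve),
                                     x$silhouette_curve), collapse = "  "),
      "\n")
  invisible(x)
}

#' PCA projection with explained variance
#'
#' @param X Numeric matrix.
#' @param dims Output dimensions (default 2).
#' @return List with `coords` (n x dims), `explained` (variance
#'   fractions, non-increasing), `degenerate` flag for zero-variance
#'   input.
#' @export
pca_project <- function(X, dims = 2L) {
  if (nrow(X) < dims) stop("need at least `dims` rows")
  v <- apply(X, 2, stats::var)
  if (all(!is.finite(v) | v == 0)) {
    return(list(coords = matrix(0, nrow(X), dims), explained = rep(0, dims),
                degenerate = TRUE))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(dims, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < dims) coords <- cbind(coords, matrix(0, nrow(X), dims - k))
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i0 <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords, explained = expl[seq_len(min(dims, length(expl)))],
       degenerate = FALSE)
}

#' Per-cluster fingerprint-bit frequencies
#'
#' Frequency = fraction of cluster members with the bit set.
#'
#' @param assignments Cluster id per molecule.
#' @param fingerprints n x bits binary matrix.
#' @return clusters x bits matrix of frequencies in [0, 1].
#' @export
bit_frequency_profile <- function(assignments, fingerprints) {
  stopifnot(length(assignments) == nrow(fingerprints))
  sizes <- table(assignments)
  if (any(sizes == 0)) stop("empty cluster in assignments")
  agg <- rowsum(fingerprints, assignments)
  out <- sweep(agg, 1, as.numeric(sizes[rownames(agg)]), "/")
  out
}

#' Descriptor / activity correlations within a cluster
#'
#' Pearson correlation of each of the six descriptors with pIC50.
#' Clusters smaller than 3 and zero-variance descriptors are flagged
#' rather than producing NaN.
#'
#' @param desc Members' descriptor matrix (columns as
#'   [compute_descriptors()]).
#' @param pic50 Members' activities.
#' @return data.frame with `descriptor`, `r`, `n`, `flag`.
#' @export
sar_correlations <- function(desc, pic50) {
  stopifnot(nrow(desc) == length(pic50))
  n <- length(pic50)
  rows <- lapply(colnames(desc), function(d) {
    x <- desc[, d]
    if (n < 3L) {
      return(data.frame(descriptor = d, r = NA_real_, n = n,
                        flag = "small_sample"))
    }
    if (stats::sd(x) == 0 || stats::sd(pic50) == 0) {
      return(data.frame(descriptor = d, r = NA_real_, n = n,
                        flag = "zero_variance"))
    }
    data.frame(descriptor = d, r = stats::cor(x, pic50), n = n, flag = "ok")
  })
  do.call(rbind, rows)
}

# --- maximum common substructure ------------------------------------------

# Light graph for MCS: symbol vector + bond table with a matching class.
# Ring bonds of order 1/2 share one class (kekulized double-bond positions
# inside a ring are an artifact of canonicalization, and rings must match
# rings); acyclic bonds and triple bonds match by exact order.
as_mcs_graph <- function(g) {
  bonds <- g$bonds[, c("a", "b", "order")]
  ring <- if ("ring" %in% names(g$bonds)) g$bonds$ring else
    rep(FALSE, nrow(bonds))
  bonds$cls <- ifelse(ring & bonds$order <= 2L, 0L, bonds$order)
  list(symbol = g$symbol, bonds = bonds, n = g$n_atoms)
}

mcs_adj <- function(g) {
  n_at <- if (!is.null(g$n)) g$n else g$n_atoms
  adj <- replicate(n_at, integer(0), simplify = FALSE)
  ord <- replicate(n_at, integer(0), simplify = FALSE)
  cls <- replicate(n_at, integer(0), simplify = FALSE)
  if (nrow(g$bonds)) {
    bc <- if ("cls" %in% names(g$bonds)) g$bonds$cls else g$bonds$order
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]; o <- g$bonds$order[k]
      adj[[a]] <- c(adj[[a]], b); ord[[a]] <- c(ord[[a]], o)
      adj[[b]] <- c(adj[[b]], a); ord[[b]] <- c(ord[[b]], o)
      cls[[a]] <- c(cls[[a]], bc[k]); cls[[b]] <- c(cls[[b]], bc[k])
    }
  }
  list(adj = adj, ord = ord, cls = cls)
}

bond_cls_between <- function(ad, u, w) {
  hit <- which(ad$adj[[u]] == w)
  if (!length(hit)) NA_integer_ else ad$cls[[u]][hit[1]]
}

bond_order_between <- function(ad, u, w) {
  hit <- which(ad$adj[[u]] == w)
  if (!length(hit)) NA_integer_ else ad$ord[[u]][hit[1]]
}

# Maximum common connected (induced-from-g1) subgraph via backtracking
# with a wall-clock deadline. Returns atom subset of g1 + mapping, or
# timed_out flag.
mces_pair <- function(g1, g2, deadline) {
  ad1 <- mcs_adj(g1); ad2 <- mcs_adj(g2)
  best <- list(atoms = integer(0), score = -1, het = -1L)
  timed_out <- FALSE

  extend <- function(map1, map2, excluded) {
    if (timed_out) return(invisible(NULL))
    if (Sys.time() > deadline) { timed_out <<- TRUE; return(invisible(NULL)) }
    size <- length(map1)
    het <- sum(g1$symbol[map1] != "C")
    # primary objective: atoms; tie-break: heteroatom count (the more
    # chemically informative of two equally large common substructures)
    if (size > best$score || (size == best$score && het > best$het)) {
      best <<- list(atoms = map1, map = map2, score = size, het = het)
    }
    nb1 <- unique(unlist(ad1$adj[map1]))
    cand_u <- setdiff(nb1, c(map1, excluded))
    if (!length(cand_u)) return(invisible(NULL))
    # bound: prune only branches that cannot even tie the best
    room <- min(g1$n - size - length(excluded), g2$n - size)
    if (size + room < best$score) return(invisible(NULL))
    if (size + room == best$score) {
      het_room <- sum(g1$symbol[setdiff(seq_len(g1$n), c(map1, excluded))] != "C")
      if (het + het_room <= best$het) return(invisible(NULL))
    }
    u <- cand_u[1]
    # candidates w in g2: element match, unmapped, bond-consistent with
    # every mapped neighbor of u
    for (w in seq_len(g2$n)) {
      if (g2$symbol[w] != g1$symbol[u]) next
      if (w %in% map2) next
      okw <- TRUE
      connected <- FALSE
      for (pi in seq_along(map1)) {
        c1 <- bond_cls_between(ad1, u, map1[pi])
        if (!is.na(c1)) {
          c2 <- bond_cls_between(ad2, w, map2[pi])
          if (is.na(c2) || c2 != c1) { okw <- FALSE; break }
          connected <- TRUE
        }
      }
      if (okw && connected) extend(c(map1, u), c(map2, w), excluded)
      if (timed_out) return(invisible(NULL))
    }
    # or leave u outside the common subgraph
    extend(map1, map2, c(excluded, u))
    invisible(NULL)
  }

  # every common subgraph containing g1 atom u was already explored when u
  # was the seed, so later seeds permanently exclude earlier seed atoms
  for (u in seq_len(g1$n)) {
    if (Sys.time() > deadline) { timed_out <- TRUE; break }
    ws <- which(g2$symbol == g1$symbol[u])
    for (w in ws) {
      extend(u, w, seq_len(u - 1L))
      if (timed_out) break
    }
    if (timed_out) break
  }
  atoms <- best$atoms
  if (!length(atoms)) {
    return(list(graph = NULL, timed_out = timed_out))
  }
  keep <- g1$bonds$a %in% atoms & g1$bonds$b %in% atoms
  remap <- match(seq_len(g1$n), atoms)
  bonds <- g1$bonds[keep, , drop = FALSE]
  bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
  list(graph = list(symbol = g1$symbol[atoms], bonds = bonds,
                    n = length(atoms)),
       timed_out = timed_out)
}

# does `pattern` occur as a (non-induced) subgraph of `g`, matching
# elements and bond orders?
pattern_matches <- function(pattern, g) {
  if (inherits(g, "molgraph")) g <- as_mcs_graph(g)
  if (is.null(pattern) || pattern$n == 0L) return(FALSE)
  if (pattern$n > g$n) return(FALSE)
  if (pattern$n == 1L) return(pattern$symbol[1] %in% g$symbol)
  gp <- igraph::graph_from_edgelist(as.matrix(pattern$bonds[, c("a", "b")]),
                                    directed = FALSE)
  if (igraph::vcount(gp) < pattern$n) {
    gp <- igraph::add_vertices(gp, pattern$n - igraph::vcount(gp))
  }
  gt <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a", "b")]),
                                    directed = FALSE)
  if (igraph::vcount(gt) < g$n) {
    gt <- igraph::add_vertices(gt, g$n - igraph::vcount(gt))
  }
  domains <- lapply(seq_len(pattern$n), function(i) {
    which(g$symbol == pattern$symbol[i])
  })
  if (any(!vapply(domains, length, integer(1)))) return(FALSE)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(gp, gt, method = "lad", domains = domains,
                                  induced = FALSE),
    error = function(e) list())
  adt <- mcs_adj(g)
  pcls <- if ("cls" %in% names(pattern$bonds)) pattern$bonds$cls else
    pattern$bonds$order
  for (m in maps) {
    mv <- as.integer(m)
    ok <- TRUE
    for (k in seq_len(nrow(pattern$bonds))) {
      cl <- bond_cls_between(adt, mv[pattern$bonds$a[k]],
                             mv[pattern$bonds$b[k]])
      if (is.na(cl) || cl != pcls[k]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# SMARTS string for a pattern graph (elements + explicit bond orders)
pattern_to_smarts <- function(p) {
  if (is.null(p) || p$n == 0L) return("")
  ad <- mcs_adj(p)
  visited <- logical(p$n)
  ring_id <- 0L
  ring_open <- list()
  bond_sym <- function(o, cl = o) {
    if (cl == 0L) "@" else c("-", "=", "#")[min(o, 3L)]
  }
  atom_sym <- function(i) paste0("[#", atomic_number(p$symbol[i]), "]")
  emitted_bonds <- new.env(parent = emptyenv())
  bkey <- function(a, b) paste(sort(c(a, b)), collapse = "-")

  walk <- function(i, via_order, via_cls) {
    visited[i] <<- TRUE
    s <- if (is.na(via_order)) atom_sym(i) else
      paste0(bond_sym(via_order, via_cls), atom_sym(i))
    # ring closures
    for (k in seq_along(ad$adj[[i]])) {
      j <- ad$adj[[i]][k]
      if (visited[j] && !exists(bkey(i, j), envir = emitted_bonds)) {
        assign(bkey(i, j), TRUE, envir = emitted_bonds)
        ring_id <<- ring_id + 1L
        lbl <- ring_id %% 10L
        s <- paste0(s, bond_sym(ad$ord[[i]][k], ad$cls[[i]][k]), lbl)
        ring_open[[bkey(i, j)]] <<- lbl
      }
    }
    kids <- which(!visited[ad$adj[[i]]])
    for (idx in seq_along(kids)) {
      k <- kids[idx]
      j <- ad$adj[[i]][k]
      if (visited[j]) next
      assign(bkey(i, j), TRUE, envir = emitted_bonds)
      sub <- walk(j, ad$ord[[i]][k], ad$cls[[i]][k])
      s <- if (idx < length(kids)) paste0(s, "(", sub, ")") else paste0(s, sub)
    }
    s
  }
  parts <- character(0)
  for (i in seq_len(p$n)) {
    if (!visited[i]) parts <- c(parts, walk(i, NA, NA))
  }
  paste(parts, collapse = ".")
}

#' Maximum common substructure of a cluster
#'
#' Folds a pairwise maximum common connected substructure (matching
#' elements and kekulized bond orders) across the cluster members,
#' smallest molecules first. With `min_fraction < 1`, members whose
#' inclusion would collapse the pattern may be skipped as long as at
#' least `min_fraction` of the members remain matched, mirroring the
#' threshold parameter of standard MCS implementations. A wall-clock
#' `timeout` applies to the whole search; timeouts are reported
#' distinctly from an empty common substructure.
#'
#' @param smiles Character vector of member SMILES (>= 2), or a list of
#'   `molgraph`s.
#' @param min_fraction Minimum fraction of members the pattern must match
#'   (default 1.0).
#' @param timeout Seconds of search budget (default 10).
#' @param max_members Cap on members folded (largest clusters are
#'   subsampled deterministically by taking the smallest molecules).
#' @return List of class `mcs_result`: `smarts`, `n_atoms`, `n_bonds`,
#'   `matched_members`, `skipped_members`, `timed_out`, `empty`.
#' @export
mcs_for_cluster <- function(smiles, min_fraction = 1.0, timeout = 10,
                            max_members = 20L) {
  graphs <- lapply(smiles, function(s) {
    if (inherits(s, "molgraph")) s else mol_graph(s)
  })
  if (any(vapply(graphs, is.null, logical(1)))) {
    stop("invalid structure among cluster members")
  }
  if (length(graphs) < 2L) stop("need at least 2 members")
  graphs <- graphs[order(vapply(graphs, function(g) g$n_atoms, numeric(1)))]
  if (length(graphs) > max_members) graphs <- graphs[seq_len(max_members)]
  mg <- lapply(graphs, as_mcs_graph)
  n_members <- length(mg)
  max_skip <- floor((1 - min_fraction) * n_members)

  deadline <- Sys.time() + timeout
  pattern <- mg[[1]]
  matched <- 1L; skipped <- 0L; timed_out <- FALSE
  for (i in 2:n_members) {
    res <- mces_pair(pattern, mg[[i]], deadline)
    if (res$timed_out) { timed_out <- TRUE }
    cand <- res$graph
    collapse <- is.null(cand) || cand$n < max(3L, ceiling(0.5 * pattern$n))
    if (collapse && skipped < max_skip) {
      skipped <- skipped + 1L
      next
    }
    if (is.null(cand)) {
      pattern <- NULL
      break
    }
    pattern <- cand
    matched <- matched + 1L
    if (timed_out) break
  }
  empty <- is.null(pattern) || pattern$n == 0L
  structure(list(
    smarts = if (empty) "" else pattern_to_smarts(pattern),
    pattern = pattern,
    n_atoms = if (empty) 0L else pattern$n,
    n_bonds = if (empty) 0L else nrow(pattern$bonds),
    matched_members = matched, skipped_members = skipped,
    timed_out = timed_out, empty = empty
  ), class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  if (x$timed_out) cat("<mcs_result> TIMED OUT (partial result)\n")
  cat("<mcs_result> ", x$n_atoms, " atoms / ", x$n_bonds, " bonds: ",
      x$smarts, "\n", sep = "")
  invisible(x)
}

#' Does an MCS pattern contain a hydroxyl group?
#'
#' A hydroxyl in a kekulized heavy-atom pattern is a terminal oxygen
#' attached by a single bond (its hydrogen being implicit).
#'
#' @param mcs An `mcs_result`.
#' @return Logical.
#' @export
mcs_contains_hydroxyl <- function(mcs) {
  p <- mcs$pattern
  if (is.null(p) || p$n == 0L) return(FALSE)
  deg <- integer(p$n)
  if (nrow(p$bonds)) {
    for (k in seq_len(nrow(p$bonds))) {
      deg[p$bonds$a[k]] <- deg[p$bonds$a[k]] + 1L
      deg[p$bonds$b[k]] <- deg[p$bonds$b[k]] + 1L
    }
  }
  for (i in which(p$symbol == "O")) {
    if (deg[i] == 1L) {
      k <- which(p$bonds$a == i | p$bonds$b == i)
      if (length(k) && p$bonds$order[k[1]] == 1L) return(TRUE)
    }
    if (deg[i] == 0L) return(TRUE)
  }
  FALSE
}
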
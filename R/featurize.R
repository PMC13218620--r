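# Molecular featurization: circular (Morgan/ECFP-style) fingerprints,
# the six-descriptor physicochemical vector, and the concatenated,
# optionally standardized feature matrix.

DESCRIPTOR_NAMES <- c("MolLogP", "MolWt", "NumRotatableBonds", "TPSA",
                      "NumHAcceptors", "NumHDonors")

# SMARTS definitions behind the counted descriptors. HBD counts N/O/S atoms
# bearing at least one hydrogen; HBA counts oxygens plus hydrogen-free
# nitrogens (reproducing the conventional donor/acceptor counts for
# reference drugs such as glutathione 6/6 and estrone 1/2). Rotatable bonds
# use the classic Daylight non-ring single-bond definition.
SMARTS_HBD <- "[#7,#8,#16;!H0]"
SMARTS_HBA_O <- "[#8]"
SMARTS_HBA_N <- "[#7;H0]"
SMARTS_ROTATABLE <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

# --- deterministic integer hashing (31-bit FNV-style) ---------------------
HASH_MOD <- 2147483647

hash_mulmod <- function(a, b) {
  hi <- b %/% 65536
  lo <- b %% 65536
  (((a * hi) %% HASH_MOD) * 65536 + a * lo) %% HASH_MOD
}

hash_ints <- function(v) {
  h <- 216613626
  for (x in v) {
    h <- hash_mulmod((h + x + 1) %% HASH_MOD, 16777619)
  }
  h
}

#' Morgan (circular) fingerprint
#'
#' Computes an ECFP-style binary fingerprint by iterative hashing of
#' atom-centered neighborhoods up to `radius` bonds, folded to `nbits`
#' bits. Atom seed invariants are (element, heavy degree, hydrogen count,
#' formal charge, ring membership); environments whose bond set duplicates
#' an already-emitted environment are removed, as in ECFP generation.
#' Identical molecules give identical fingerprints regardless of the SMILES
#' spelling, because the graph is built from the canonical atom order.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood radius in bonds (default 2, i.e. ECFP4-like).
#' @param nbits Fingerprint length (default 1024).
#' @return Integer vector of 0/1 of length `nbits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, nbits = 1024L) {
  g <- if (inherits(smiles, "molgraph")) smiles else mol_graph(smiles)
  if (is.null(g)) stop("invalid SMILES: ", smiles)
  nb <- mol_neighbors(g)
  n <- g$n_atoms

  inv <- vapply(seq_len(n), function(i) {
    hash_ints(c(atomic_number(g$symbol[i]), length(nb[[i]]$nbr), g$nH[i],
                g$charge[i] + 8L, as.integer(g$ring_atom[i])))
  }, numeric(1))

  # per-atom environment bond sets, grown one shell per iteration
  env_bonds <- replicate(n, integer(0), simplify = FALSE)
  env_atoms <- as.list(seq_len(n))
  bond_key <- function(bs) paste(sort(bs), collapse = ",")

  ids <- numeric(0)
  seen_envs <- character(0)
  emit <- function(id, bs) {
    key <- bond_key(bs)
    if (!(key %in% seen_envs)) {
      seen_envs <<- c(seen_envs, key)
      ids <<- c(ids, id)
    }
  }
  for (i in seq_len(n)) emit(inv[i], env_bonds[[i]])

  if (radius > 0L && nrow(g$bonds) > 0L) {
    bond_index <- function(a, b) {
      which((g$bonds$a == a & g$bonds$b == b) | (g$bonds$a == b & g$bonds$b == a))[1]
    }
    for (r in seq_len(radius)) {
      new_inv <- inv
      new_env_bonds <- env_bonds
      new_env_atoms <- env_atoms
      for (i in seq_len(n)) {
        nbr <- nb[[i]]$nbr
        if (length(nbr) == 0L) next
        ord <- order(nb[[i]]$order, inv[nbr])
        parts <- as.vector(rbind(nb[[i]]$order[ord], inv[nbr[ord]]))
        new_inv[i] <- hash_ints(c(inv[i], parts))
        # grow environment: all bonds incident to current env atoms
        cur_atoms <- env_atoms[[i]]
        add_bonds <- which(g$bonds$a %in% cur_atoms | g$bonds$b %in% cur_atoms)
        new_env_bonds[[i]] <- sort(unique(c(env_bonds[[i]], add_bonds)))
        new_env_atoms[[i]] <- sort(unique(c(cur_atoms,
                                            g$bonds$a[add_bonds],
                                            g$bonds$b[add_bonds])))
      }
      for (i in seq_len(n)) {
        if (length(nb[[i]]$nbr) == 0L) next        # environment cannot grow
        if (identical(new_env_bonds[[i]], env_bonds[[i]]) && r > 1L) next
        emit(new_inv[i], new_env_bonds[[i]])
      }
      inv <- new_inv
      env_bonds <- new_env_bonds
      env_atoms <- new_env_atoms
    }
  }

  fp <- integer(nbits)
  fp[(ids %% nbits) + 1L] <- 1L
  fp
}

#' Physicochemical descriptor vector
#'
#' Computes the six descriptors used throughout the package, in fixed
#' order: MolLogP (computed octanol/water partition estimate), MolWt
#' (average molecular weight, Da), NumRotatableBonds, TPSA (topological
#' polar surface area, A^2), NumHAcceptors, NumHDonors.
#'
#' @param smiles A single SMILES string.
#' @return Named numeric vector of length 6.
#' @examples
#' compute_descriptors("CC")  # ethane: zero donors/acceptors/rotors/TPSA
#' @export
compute_descriptors <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  if (is.na(can)) stop("invalid SMILES: ", smiles)
  pr <- ob_props1(can)
  if (is.null(pr)) stop("property computation failed for: ", smiles)
  out <- c(
    MolLogP = as.numeric(pr$logP),
    MolWt = as.numeric(pr$MW),
    NumRotatableBonds = as.numeric(smarts_count1(can, SMARTS_ROTATABLE)),
    TPSA = as.numeric(pr$TPSA),
    NumHAcceptors = as.numeric(smarts_count1(can, SMARTS_HBA_O) +
                                 smarts_count1(can, SMARTS_HBA_N)),
    NumHDonors = as.numeric(smarts_count1(can, SMARTS_HBD))
  )
  out
}

#' Monoisotopic (exact) mass
#'
#' Sum of most-abundant-isotope masses over all atoms including implicit
#' hydrogens, in Da.
#'
#' @param smiles A single SMILES string.
#' @return Monoisotopic mass in Da.
#' @examples
#' exact_mass("C")  # methane, 16.0313
#' @export
exact_mass <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  if (is.na(can)) stop("invalid SMILES: ", smiles)
  m <- ob_exact_mass1(can)
  if (is.na(m)) stop("exact mass computation failed for: ", smiles)
  m
}

#' Featurize every molecule of a ligand table
#'
#' Builds the per-molecule feature blocks used by the models: the
#' fingerprint matrix, the descriptor matrix and the SELFIES token-count
#' matrix (when a vocabulary is supplied or built).
#'
#' @param table A `ligand_table`.
#' @param fp_dim Fingerprint length.
#' @param radius Fingerprint radius.
#' @param vocab SELFIES vocabulary (ordered token list); `NULL` builds one
#'   from the table.
#' @return A list with `fp` (n x fp_dim), `desc` (n x 6), `selfies`
#'   (n x (|vocab|+1)), `vocab`, and `meta` (fp_dim, radius, vocab hash).
#' @export
featurize_table <- function(table, fp_dim = 1024L, radius = 2L, vocab = NULL) {
  n <- nrow(table)
  if (n == 0L) stop("empty ligand table")
  graphs <- lapply(table$smiles, mol_graph)
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad)) stop("unparsable SMILES in table at rows: ",
                     paste(which(bad), collapse = ", "))
  fp <- t(vapply(graphs, morgan_fingerprint, integer(fp_dim),
                 radius = radius, nbits = fp_dim))
  desc <- t(vapply(table$smiles, compute_descriptors, numeric(6)))
  rownames(desc) <- NULL
  tokens <- lapply(graphs, selfies_tokens)
  if (is.null(vocab)) vocab <- sort(unique(unlist(tokens)))
  selfies <- t(vapply(tokens, selfies_count_vector, numeric(length(vocab) + 1L),
                      vocab = vocab))
  list(fp = fp, desc = desc, selfies = selfies, vocab = vocab,
       meta = list(fp_dim = as.integer(fp_dim), radius = as.integer(radius),
                   vocab_hash = hash_ints(utf8ToInt(paste(vocab, collapse = "|")))))
}

#' Build the concatenated feature matrix
#'
#' Concatenates the fingerprint block and the descriptor block in table
#' order, optionally z-score standardizing each column with recorded means
#' and standard deviations. Constant columns are set to 0 and flagged
#' rather than producing NaN.
#'
#' @param table A `ligand_table`.
#' @param fp_dim,radius Fingerprint parameters.
#' @param standardize Standardize columns (z-score)?
#' @param features Optional precomputed result of [featurize_table()].
#' @return A numeric matrix with attributes `column_means`, `column_stds`,
#'   `constant_cols`, `standardized`.
#' @export
build_feature_matrix <- function(table, fp_dim = 1024L, radius = 2L,
                                 standardize = FALSE, features = NULL) {
  if (is.null(features)) {
    features <- featurize_table(table, fp_dim = fp_dim, radius = radius)
  }
  mat <- cbind(features$fp, features$desc)
  colnames(mat) <- c(paste0("fp_", seq_len(ncol(features$fp))), DESCRIPTOR_NAMES)
  if (standardize) {
    st <- standardize_fit(mat)
    mat <- standardize_apply(mat, st)
  } else {
    attr(mat, "standardized") <- FALSE
  }
  mat
}

#' Fit standardization parameters (training-set statistics)
#'
#' @param mat Numeric matrix.
#' @return List with `mean`, `sd`, `constant` per column.
#' @export
standardize_fit <- function(mat) {
  mu <- colMeans(mat)
  sd <- apply(mat, 2, stats::sd)
  constant <- !is.finite(sd) | sd == 0
  list(mean = mu, sd = sd, constant = constant)
}

#' Apply previously fitted standardization
#'
#' Columns flagged constant at fit time are set to 0.
#'
#' @param mat Numeric matrix with the same columns as at fit time.
#' @param st Result of [standardize_fit()].
#' @return Standardized matrix with bookkeeping attributes.
#' @export
standardize_apply <- function(mat, st) {
  out <- sweep(mat, 2, st$mean, "-")
  sdz <- ifelse(st$constant, 1, st$sd)
  out <- sweep(out, 2, sdz, "/")
  out[, st$constant] <- 0
  attr(out, "column_means") <- st$mean
  attr(out, "column_stds") <- st$sd
  attr(out, "constant_cols") <- which(st$constant)
  attr(out, "standardized") <- TRUE
  out
}
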
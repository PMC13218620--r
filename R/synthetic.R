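# Synthetic structure-activity test bed. Molecules are assembled from
# small aromatic/aliphatic scaffolds with two substitution points and a
# fragment alphabet containing one designated activity-boosting
# hydroxymethyl fragment. Activities follow a known linear model in the
# boost indicator, TPSA and rotatable-bond count, so every downstream
# stage (regression, pair learning, screening enrichment, cluster MCS)
# can be checked against planted truth.

SYN_SCAFFOLDS <- c(
  benzene = "c1cc({A})cc({B})c1",
  indole = "c1ccc2c(c1)c({A})c({B})[nH]2",
  piperidine = "C1CC({A})CCN1{B}",
  pyrimidine = "c1nc({A})cc({B})n1"
)

SYN_DECOY_SCAFFOLDS <- c(
  naphthalene = "c1ccc2cc({A})c({B})cc2c1",
  thiophene = "c1sc({A})c({B})c1",
  furan = "c1oc({A})c({B})c1",
  cyclohexane = "C1CC({A})CC({B})C1"
)

# Activity-boosting fragments: hydroxyl-bearing substituents whose oxygen
# always sits two bonds from the scaffold attachment point, so every
# boosted molecule shares the attachment-C-OH motif that the MCS stage is
# meant to recover.
SYN_BOOST_FRAGMENTS <- c("CO", "C(C)O", "C(CC)O", "C(C)(C)O", "C(CCC)O",
                         "C(C)(CC)O")

SYN_ALPHABET <- c("C", "CC", "CCC", "C(C)C", SYN_BOOST_FRAGMENTS[1], "OC",
                  "OCC", "N", "N(C)C", "F", "Cl", "Br", "C(=O)C",
                  "C(=O)OC", "C(F)(F)F", "C#N")

SYN_LINKERS <- c("", "C", "CC", "CCC")

#' Specification of a synthetic ligand set
#'
#' The activity model is
#' `pIC50 = beta0 + beta1 * boost + beta2 * (TPSA/100) + beta3 * nrot
#'  (+ beta_int * boost * TPSA/100 in nonlinear mode) + Normal(0, sigma)`,
#' where `boost` indicates the presence of the hydroxymethyl
#' activity-boosting fragment. Default coefficients are chosen so that at
#' `sigma = 0.4` roughly 40% of molecules are high-activity, 35% medium
#' and 25% low.
#'
#' @param n_ligands Number of unique molecules.
#' @param beta Coefficients `c(beta0, beta1, beta2, beta3)`.
#' @param sigma Gaussian noise standard deviation (pIC50 units).
#' @param p_boost Probability a molecule carries the boost fragment.
#' @param nonlinear Add the boost x TPSA interaction term.
#' @param beta_interaction Interaction coefficient (nonlinear mode).
#' @param scaffolds,alphabet,linkers Structure-generation building blocks.
#' @param seed Seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_ligands = 2000L,
                           beta = c(4.8, 2.6, 0.6, 0.05),
                           sigma = 0.4, p_boost = 0.4,
                           nonlinear = FALSE, beta_interaction = 1.0,
                           scaffolds = SYN_SCAFFOLDS,
                           alphabet = SYN_ALPHABET,
                           linkers = SYN_LINKERS,
                           seed = 1L) {
  if (!length(alphabet)) stop("empty substituent alphabet")
  structure(list(n_ligands = as.integer(n_ligands), beta = beta,
                 sigma = sigma, p_boost = p_boost, nonlinear = nonlinear,
                 beta_interaction = beta_interaction, scaffolds = scaffolds,
                 alphabet = alphabet, linkers = linkers,
                 boost_fragments = SYN_BOOST_FRAGMENTS,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

syn_substituent <- function(fragment, linker) paste0(linker, fragment)

syn_assemble <- function(template, sub_a, sub_b) {
  s <- sub("{A}", sub_a, template, fixed = TRUE)
  sub("{B}", sub_b, s, fixed = TRUE)
}

# sample one molecule recipe; the boost fragment is placed at site A when
# drawn, the remaining site uses non-boost fragments
syn_sample_recipe <- function(spec, scaffolds) {
  sc <- sample(names(scaffolds), 1L)
  boost <- stats::runif(1) < spec$p_boost
  plain <- setdiff(spec$alphabet, spec$boost_fragments)
  frag_a <- if (boost) sample(spec$boost_fragments, 1L) else sample(plain, 1L)
  frag_b <- sample(plain, 1L)
  # boost fragments always attach directly to the scaffold so the planted
  # hydroxyl motif is a fixed substructure recoverable by MCS
  lnk_a <- if (boost) "" else sample(spec$linkers, 1L)
  lnk_b <- sample(spec$linkers, 1L)
  smiles <- syn_assemble(scaffolds[[sc]],
                         syn_substituent(frag_a, lnk_a),
                         syn_substituent(frag_b, lnk_b))
  list(scaffold = sc, frag_a = frag_a, frag_b = frag_b, boost = boost,
       smiles = smiles)
}

#' Generate a synthetic ligand set with planted activities
#'
#' Draws `n_ligands` unique, chemically valid molecules and assigns pIC50
#' by the activity model carried in `spec`. The returned ground truth has the
#' design matrix actually used (boost flag, TPSA/100, rotatable bonds)
#' and the true coefficients, which downstream tests use as the recovery
#' oracle.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a `ligand_table`) and `truth` (list with
#'   `design`, `beta`, `sigma`, `seed`).
#' @export
generate_ligand_set <- function(spec = synthetic_spec()) {
  rng <- local_rng(spec$seed)
  rng({
    seen <- character(0)
    rows <- list()
    attempts <- 0L
    max_attempts <- 80L * spec$n_ligands
    while (length(rows) < spec$n_ligands && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- syn_sample_recipe(spec, spec$scaffolds)
      can <- canonicalize_smiles(r$smiles)
      if (is.na(can) || can %in% seen) next
      seen <- c(seen, can)
      r$smiles <- can
      rows[[length(rows) + 1L]] <- r
    }
    if (length(rows) < spec$n_ligands) {
      stop("could not generate ", spec$n_ligands, " unique molecules (got ",
           length(rows), "); enlarge the alphabet or lower n_ligands")
    }
    boost <- vapply(rows, `[[`, logical(1), "boost")
    smiles <- vapply(rows, `[[`, character(1), "smiles")
    desc <- t(vapply(smiles, compute_descriptors, numeric(6)))
    tpsa100 <- desc[, "TPSA"] / 100
    nrot <- desc[, "NumRotatableBonds"]
    mu <- spec$beta[1] + spec$beta[2] * boost + spec$beta[3] * tpsa100 +
      spec$beta[4] * nrot
    if (spec$nonlinear) mu <- mu + spec$beta_interaction * boost * tpsa100
    pic50 <- mu + stats::rnorm(length(mu), 0, spec$sigma)
    df <- data.frame(
      id = sprintf("syn_%05d", seq_along(smiles)),
      smiles = smiles,
      ic50_nM = 10^(9 - pic50),
      pic50 = pic50,
      source = "synthetic",
      stringsAsFactors = FALSE
    )
    truth <- list(
      design = data.frame(id = df$id, boost = boost, tpsa100 = tpsa100,
                          nrot = nrot,
                          scaffold = vapply(rows, `[[`, character(1), "scaffold"),
                          frag_a = vapply(rows, `[[`, character(1), "frag_a"),
                          frag_b = vapply(rows, `[[`, character(1), "frag_b")),
      beta = spec$beta, sigma = spec$sigma, nonlinear = spec$nonlinear,
      beta_interaction = spec$beta_interaction, seed = spec$seed
    )
    list(table = new_ligand_table(df), truth = truth)
  })
}

#' Generate a synthetic candidate library
#'
#' A fraction `analog_fraction` of candidates are single-substituent
#' edits of ligand-set molecules (same scaffold, one site re-drawn);
#' the remainder come from decoy scaffolds structurally disjoint from the
#' ligand scaffolds. No activities are assigned.
#'
#' @param spec The [synthetic_spec()] used for the ligand set.
#' @param ligand_set Result of [generate_ligand_set()] for that spec.
#' @param n_candidates Number of candidates.
#' @param analog_fraction Fraction of analog candidates in [0, 1].
#' @param seed Seed (defaults to `spec$seed + 1`).
#' @return List with `table` (a `ligand_table`, no activities) and
#'   `truth` (data.frame `id`, `is_analog`, `parent_id`, `scaffold`,
#'   `boost`).
#' @export
generate_candidate_library <- function(spec, ligand_set, n_candidates = 200L,
                                       analog_fraction = 0.3,
                                       seed = spec$seed + 1L) {
  if (analog_fraction < 0 || analog_fraction > 1) {
    stop("analog_fraction must be in [0, 1]")
  }
  n_analog <- round(n_candidates * analog_fraction)
  lig_truth <- ligand_set$truth$design
  rng <- local_rng(seed)
  rng({
    seen <- ligand_set$table$smiles
    rows <- list()
    attempts <- 0L
    max_attempts <- 200L * n_candidates
    plain <- setdiff(spec$alphabet, spec$boost_fragments)
    while (length(rows) < n_candidates && attempts < max_attempts) {
      attempts <- attempts + 1L
      make_analog <- length(rows) < n_analog
      if (make_analog) {
        # analog-series semantics: keep the parent's site-A substituent
        # (the pharmacophore position) and re-draw the peripheral site
        parent <- lig_truth[sample.int(nrow(lig_truth), 1L), ]
        frag_a <- parent$frag_a
        frag_b <- sample(setdiff(plain, parent$frag_b), 1L)
        lnk_a <- if (frag_a %in% spec$boost_fragments) "" else
          sample(spec$linkers, 1L)
        smiles <- syn_assemble(spec$scaffolds[[parent$scaffold]],
                               syn_substituent(frag_a, lnk_a),
                               syn_substituent(frag_b, sample(spec$linkers, 1L)))
        rec <- list(is_analog = TRUE, parent_id = parent$id,
                    scaffold = parent$scaffold,
                    boost = frag_a %in% spec$boost_fragments,
                    smiles = smiles)
      } else {
        # decoys: structurally disjoint scaffolds and no activity motif --
        # an inactive background library, as decoys are conventionally
        # defined in virtual-screening benchmarks
        sc <- sample(names(SYN_DECOY_SCAFFOLDS), 1L)
        frag_a <- sample(plain, 1L); frag_b <- sample(plain, 1L)
        smiles <- syn_assemble(SYN_DECOY_SCAFFOLDS[[sc]],
                               syn_substituent(frag_a, sample(spec$linkers, 1L)),
                               syn_substituent(frag_b, sample(spec$linkers, 1L)))
        rec <- list(is_analog = FALSE, parent_id = NA_character_,
                    scaffold = sc, boost = FALSE, smiles = smiles)
      }
      can <- canonicalize_smiles(rec$smiles)
      if (is.na(can) || can %in% seen) next
      seen <- c(seen, can)
      rec$smiles <- can
      rows[[length(rows) + 1L]] <- rec
    }
    if (length(rows) < n_candidates) {
      stop("could not generate ", n_candidates, " unique candidates")
    }
    df <- data.frame(
      id = sprintf("cand_%05d", seq_along(rows)),
      smiles = vapply(rows, `[[`, character(1), "smiles"),
      ic50_nM = NA_real_, pic50 = NA_real_, source = "synthetic_library",
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      id = df$id,
      is_analog = vapply(rows, `[[`, logical(1), "is_analog"),
      parent_id = vapply(rows, `[[`, character(1), "parent_id"),
      scaffold = vapply(rows, `[[`, character(1), "scaffold"),
      boost = vapply(rows, `[[`, logical(1), "boost"),
      stringsAsFactors = FALSE
    )
    list(table = new_ligand_table(df), truth = truth)
  })
}

#' Write the ground-truth sidecar of a synthetic set
#'
#' @param x Result of [generate_ligand_set()] or
#'   [generate_candidate_library()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(x, path) {
  jsonlite::write_json(x$truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
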
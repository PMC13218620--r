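# Molecular graph construction. A "molgraph" is the package's internal
# chemistry workhorse: heavy atoms with element / charge / hydrogen counts /
# ring flags, plus a kekulized bond list. Built from OpenBabel's explicit-H
# MDL block parsed by ChemmineR, so the atom order is the canonical order.

MOL_CHARGE_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

#' Build a molecular graph from a SMILES string
#'
#' Parses a molecule into a heavy-atom graph: element symbols, formal
#' charges, attached-hydrogen counts, ring membership flags (atoms and
#' bonds), and a bond table with kekulized bond orders. The atom order is
#' OpenBabel's canonical order, so two SMILES spellings of one molecule give
#' identical graphs.
#'
#' @param smiles A single SMILES string.
#' @return A list of class `molgraph` with elements `symbol`, `charge`,
#'   `nH`, `ring_atom`, `bonds` (data.frame `a`, `b`, `order`, `ring`),
#'   `n_atoms`, and `smiles` (canonical); or `NULL` if the SMILES is invalid.
#' @export
mol_graph <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  if (is.na(can)) return(NULL)
  blk <- ob_molblock(can)
  if (is.na(blk)) return(NULL)
  lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
  sdf <- tryCatch(
    methods::as(ChemmineR::read.SDFstr(lines), "SDFset"),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) < 1L) return(NULL)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  syms <- sub("_.*$", "", rownames(ab))
  n_all <- length(syms)

  # formal charges: old-style atom-block code, overridden by M CHG lines
  charge_all <- rep(0L, n_all)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    hit <- code %in% names(MOL_CHARGE_CODE)
    charge_all[hit] <- MOL_CHARGE_CODE[code[hit]]
  }
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
    npair <- flds[1]
    for (k in seq_len(npair)) {
      charge_all[flds[2 * k]] <- flds[2 * k + 1]
    }
  }

  heavy <- which(syms != "H")
  idx_map <- integer(n_all)
  idx_map[heavy] <- seq_along(heavy)

  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  a_all <- as.integer(bb[, "C1"]); b_all <- as.integer(bb[, "C2"])
  o_all <- as.integer(bb[, "C3"])

  nH <- integer(length(heavy))
  keep <- syms[a_all] != "H" & syms[b_all] != "H"
  toH <- xor(syms[a_all] == "H", syms[b_all] == "H")
  for (i in which(toH)) {
    hv <- if (syms[a_all[i]] == "H") b_all[i] else a_all[i]
    if (syms[hv] != "H") nH[idx_map[hv]] <- nH[idx_map[hv]] + 1L
  }
  bonds <- data.frame(
    a = idx_map[a_all[keep]], b = idx_map[b_all[keep]],
    order = o_all[keep]
  )

  # ring perception: a bond is in a ring iff it is not a bridge
  ring_bond <- logical(nrow(bonds))
  if (nrow(bonds) > 0L) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a", "b")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < length(heavy)) {
      g <- igraph::add_vertices(g, length(heavy) - igraph::vcount(g))
    }
    br <- igraph::bridges(g)
    ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  bonds$ring <- ring_bond
  ring_atom <- logical(length(heavy))
  if (any(ring_bond)) {
    ring_atom[unique(c(bonds$a[ring_bond], bonds$b[ring_bond]))] <- TRUE
  }

  structure(
    list(
      symbol = syms[heavy],
      charge = charge_all[heavy],
      nH = nH,
      ring_atom = ring_atom,
      bonds = bonds,
      n_atoms = length(heavy),
      smiles = can
    ),
    class = "molgraph"
  )
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, "\n  ", x$n_atoms, " heavy atoms, ",
      nrow(x$bonds), " bonds, ", sum(x$ring_atom), " ring atoms\n", sep = "")
  invisible(x)
}

# adjacency list: for atom i, data.frame(nbr, order)
mol_neighbors <- function(g) {
  nb <- vector("list", g$n_atoms)
  for (i in seq_len(g$n_atoms)) nb[[i]] <- list(nbr = integer(0), order = integer(0))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]; o <- g$bonds$order[k]
      nb[[a]]$nbr <- c(nb[[a]]$nbr, b); nb[[a]]$order <- c(nb[[a]]$order, o)
      nb[[b]]$nbr <- c(nb[[b]]$nbr, a); nb[[b]]$order <- c(nb[[b]]$order, o)
    }
  }
  nb
}

ATOMIC_NUMBERS <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Se = 34L, Br = 35L, I = 53L
)

atomic_number <- function(symbol) {
  z <- ATOMIC_NUMBERS[symbol]
  z[is.na(z)] <- 0L
  unname(z)
}
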
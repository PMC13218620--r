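# SELFIES-style molecular string tokens. The encoder walks the kekulized
# molecular graph depth-first and emits SELFIES v2-convention tokens
# ([C], [=O], [Branch1] + index symbols, [Ring1] + index symbols). Only
# token counts feed the downstream model (bag-of-tokens vectorization), so
# the stream's job is to be a faithful, deterministic structural
# tokenization with the standard token vocabulary.

SELFIES_INDEX_ALPHABET <- c(
  "[C]", "[Ring1]", "[Ring2]", "[Branch1]", "[=Branch1]", "[#Branch1]",
  "[Branch2]", "[=Branch2]", "[#Branch2]", "[O]", "[N]", "[=N]", "[=C]",
  "[#C]", "[S]", "[P]"
)

selfies_index_symbols <- function(value) {
  stopifnot(value >= 0)
  if (value == 0) return(SELFIES_INDEX_ALPHABET[1])
  digits <- integer(0)
  v <- value
  while (v > 0) {
    digits <- c(v %% 16, digits)
    v <- v %/% 16
  }
  SELFIES_INDEX_ALPHABET[digits + 1L]
}

selfies_bond_prefix <- function(order) {
  switch(as.character(order), `1` = "", `2` = "=", `3` = "#", "")
}

selfies_atom_token <- function(g, i, order = 1L) {
  sym <- g$symbol[i]
  chg <- g$charge[i]
  chg_s <- if (chg > 0) paste0("+", chg) else if (chg < 0) as.character(chg) else ""
  paste0("[", selfies_bond_prefix(order), sym, chg_s, "]")
}

# Branch or Ring token sized to the number of index symbols that follow.
selfies_overload_token <- function(base, n_index, order = 1L) {
  paste0("[", selfies_bond_prefix(order), base, n_index, "]")
}

#' Tokenize a molecule as a SELFIES-style string
#'
#' Produces the deterministic SELFIES token stream for a molecule: a
#' depth-first traversal of the canonical-order molecular graph emitting
#' atom tokens with bond-order prefixes, `[BranchN]` tokens with length
#' index symbols, and `[RingN]` closure tokens with distance index symbols.
#'
#' @param x A SMILES string or a `molgraph`.
#' @return Character vector of tokens (e.g. `c("[C]", "[C]", "[O]")` for
#'   ethanol).
#' @export
selfies_tokens <- function(x) {
  g <- if (inherits(x, "molgraph")) x else mol_graph(x)
  if (is.null(g)) stop("invalid SMILES for SELFIES encoding")
  n <- g$n_atoms
  if (n == 0L) return(character(0))
  nb <- mol_neighbors(g)

  visited <- logical(n)
  atom_pos <- integer(n)        # emission index of each atom
  n_emitted <- 0L
  ring_done <- new.env(parent = emptyenv())

  encode_atom <- function(i, order, parent = 0L) {
    visited[i] <<- TRUE
    n_emitted <<- n_emitted + 1L
    atom_pos[i] <<- n_emitted
    toks <- selfies_atom_token(g, i, order)
    if (parent > 0L) {
      assign(paste(sort(c(i, parent)), collapse = "-"), TRUE,
             envir = ring_done)
    }

    # ring closures back to already-visited atoms (excluding the tree edge)
    nbrs <- nb[[i]]$nbr
    ords <- nb[[i]]$order
    back <- which(visited[nbrs] & nbrs != i)
    for (k in back[order(nbrs[back])]) {
      j <- nbrs[k]
      key <- paste(sort(c(i, j)), collapse = "-")
      if (exists(key, envir = ring_done)) next
      assign(key, TRUE, envir = ring_done)
      q <- atom_pos[i] - atom_pos[j] - 1L
      idx <- selfies_index_symbols(q)
      toks <- c(toks,
                selfies_overload_token("Ring", length(idx), ords[k]), idx)
    }

    # spanning-tree children, ascending atom index; all but the last child
    # are wrapped as branches
    kids <- which(!visited[nbrs])
    kids <- kids[order(nbrs[kids])]
    if (length(kids)) {
      for (pos in seq_along(kids)) {
        k <- kids[pos]
        j <- nbrs[k]
        if (visited[j]) next                    # visited through a sibling
        sub <- encode_atom(j, ords[k], parent = i)
        # wrap as a branch only if the main chain continues afterwards
        later <- if (pos < length(kids)) kids[(pos + 1L):length(kids)] else integer(0)
        if (any(!visited[nbrs[later]])) {
          idx <- selfies_index_symbols(length(sub) - 1L)
          toks <- c(toks,
                    selfies_overload_token("Branch", length(idx), ords[k]),
                    idx, sub)
        } else {
          toks <- c(toks, sub)
        }
      }
    }
    toks
  }

  out <- character(0)
  for (start in seq_len(n)) {
    if (!visited[start]) out <- c(out, encode_atom(start, 1L))
  }
  out
}

#' Build a SELFIES token vocabulary from a ligand table
#'
#' Collects the sorted unique token set over all molecules of the training
#' table. The vocabulary is stored with trained models so that screening
#' uses the identical token dimension; unseen tokens at predict time land
#' in the unknown bin.
#'
#' @param table A `ligand_table`.
#' @return Ordered character vector of tokens.
#' @export
build_selfies_vocab <- function(table) {
  if (!nrow(table)) stop("empty ligand table")
  toks <- unlist(lapply(table$smiles, selfies_tokens))
  sort(unique(toks))
}

selfies_count_vector <- function(tokens, vocab) {
  v <- numeric(length(vocab) + 1L)
  idx <- match(tokens, vocab)
  known <- !is.na(idx)
  if (any(known)) {
    tab <- table(idx[known])
    v[as.integer(names(tab))] <- as.numeric(tab)
  }
  v[length(vocab) + 1L] <- sum(!known)
  names(v) <- c(vocab, "<unk>")
  v
}

#' Encode a molecule as a token-count vector
#'
#' Tokenizes the molecule and counts token occurrences over `vocab`, with a
#' final unknown-token bin for tokens outside the vocabulary. The vector
#' sums to the molecule's token count.
#'
#' @param smiles A SMILES string (or `molgraph`).
#' @param vocab Ordered token list from [build_selfies_vocab()].
#' @return Non-negative numeric vector of length `length(vocab) + 1`.
#' @examples
#' encode_selfies("CCO", vocab = c("[C]"))  # c(2, 1): oxygen is unknown
#' @export
encode_selfies <- function(smiles, vocab) {
  selfies_count_vector(selfies_tokens(smiles), vocab)
}
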
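# Low-level OpenBabel bridge (via ChemmineOB). Everything chemistry-aware in
# the package funnels through these wrappers so that parsing quirks are
# handled in exactly one place.

# OpenBabel accepts some malformed SMILES (e.g. "C(" parses as methane).
# Reject obviously broken strings before they reach the parser: unbalanced
# parentheses/brackets, unmatched ring-bond digits, illegal characters.
smiles_syntax_ok <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(FALSE)
  }
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\.%*]", smiles)) return(FALSE)
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L
  brk <- 0L
  ring <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
    if (ch == "[") {
      if (brk > 0L) return(FALSE)
      brk <- 1L
    }
    if (ch == "]") {
      if (brk == 0L) return(FALSE)
      brk <- 0L
    }
    if (brk == 0L && grepl("[0-9]", ch)) {
      ring <- c(ring, as.integer(ch))
    }
    if (brk == 0L && ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        return(FALSE)
      }
      ring <- c(ring, as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (depth != 0L || brk != 0L) return(FALSE)
  # every ring-closure label must occur an even number of times
  if (length(ring) && any(table(ring) %% 2L != 0L)) return(FALSE)
  TRUE
}

# Convert a single SMILES with OpenBabel, returning NA_character_ on failure
# instead of raising. OB emits diagnostics on stderr; they are harmless.
ob_convert1 <- function(smiles, to = "CAN", options = NULL) {
  src <- paste0(smiles, "\tm\n")
  out <- tryCatch(
    if (is.null(options)) ChemmineOB::convertFormat("SMI", to, src)
    else ChemmineOB::convertFormat("SMI", to, src, options = options),
    error = function(e) ""
  )
  if (!is.character(out) || length(out) != 1L || !nzchar(out)) {
    return(NA_character_)
  }
  out
}

#' Canonicalize a SMILES string
#'
#' Returns the OpenBabel canonical SMILES for a molecule, or `NA_character_`
#' when the input does not parse. Canonicalization is idempotent and maps all
#' spellings of a molecule to one string, which is what deduplication and
#' fingerprint reproducibility rely on.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` for rejected inputs.
#' @examples
#' canonicalize_smiles(c("CCO", "OCC", "C("))
#' @export
canonicalize_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (!smiles_syntax_ok(s)) return(NA_character_)
    out <- ob_convert1(s, "CAN")
    if (is.na(out)) return(NA_character_)
    can <- sub("\t.*$", "", sub("\n$", "", out))
    if (!nzchar(can)) NA_character_ else can
  }, character(1), USE.NAMES = FALSE)
}

# Run f(obmol) for one SMILES; returns f's value or NULL on parse failure.
with_obmol <- function(smiles, f) {
  res <- NULL
  tryCatch(
    ChemmineOB::forEachMol("SMILES", paste0(smiles, " m"), function(m) {
      res <<- f(m)
    }),
    error = function(e) NULL
  )
  res
}

# Count unique SMARTS matches in one molecule.
smarts_count1 <- function(smiles, pattern) {
  n <- with_obmol(smiles, function(m) {
    ChemmineOB::smartsSearch_OB(list(m), pattern, uniqueMatches = TRUE)
  })
  if (is.null(n)) NA_integer_ else as.integer(n)
}

# OpenBabel-computed bulk properties for one molecule (logP, MW, TPSA, ...).
ob_props1 <- function(smiles) {
  with_obmol(smiles, function(m) ChemmineOB::prop_OB(m))
}

ob_exact_mass1 <- function(smiles) {
  v <- with_obmol(smiles, function(m) ChemmineOB::exactMass_OB(list(m)))
  if (is.null(v)) NA_real_ else as.numeric(v)
}

# SMILES -> MDL mol block with explicit hydrogens (kekulized bond orders).
ob_molblock <- function(smiles) {
  ob_convert1(smiles, "SDF", options = data.frame(names = "h", args = ""))
}
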
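# Compound table I/O and activity-unit conventions. Every unit decision in
# the package (IC50 unit handling, the pIC50 convention) lives here.

IC50_UNIT_FACTOR_NM <- c(nM = 1, uM = 1e3, M = 1e9)

#' Convert IC50 to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the IC50 expressed in molar,
#' so 100 nM corresponds to pIC50 = 7. The function is monotone decreasing
#' in IC50.
#'
#' @param ic50 Positive numeric vector of IC50 values.
#' @param unit Unit of `ic50`: one of `"nM"`, `"uM"`, `"M"`.
#' @return Numeric vector of pIC50 values.
#' @examples
#' ic50_to_pic50(100, "nM")   # 7
#' ic50_to_pic50(1, "M")      # 0
#' @export
ic50_to_pic50 <- function(ic50, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  ic50 <- as.numeric(ic50)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 must be finite and strictly positive")
  }
  # computed via the nM scale so round decades (100 nM -> 7) are exact
  9 - log10(ic50 * IC50_UNIT_FACTOR_NM[[unit]])
}

#' Convert pIC50 back to IC50
#'
#' Inverse of [ic50_to_pic50()]: returns `10^(9 - pic50)` for nM.
#'
#' @param pic50 Numeric vector of pIC50 values.
#' @param unit Output unit.
#' @return IC50 in the requested unit.
#' @export
pic50_to_ic50 <- function(pic50, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  if (any(!is.finite(pic50))) stop("pic50 must be finite")
  10^(9 - pic50) / IC50_UNIT_FACTOR_NM[[unit]]
}

# Multi-fragment (salt) SMILES: keep the largest organic fragment, measured
# in heavy atoms with carbon-containing fragments preferred.
largest_organic_fragment <- function(smiles) {
  if (!grepl(".", smiles, fixed = TRUE)) return(smiles)
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) <= 1L) return(smiles)
  n_heavy <- vapply(frags, function(f) {
    sum(gregexpr("Cl|Br|Si|Se|[BCNOPSFI]|\\[[A-Za-z]", f)[[1]] > 0)
  }, numeric(1))
  has_c <- grepl("C|c", frags)
  score <- n_heavy + 1000 * has_c
  frags[[which.max(score)]]
}

#' Construct a ligand table from a data.frame
#'
#' Low-level constructor used by the loaders and the synthetic generator;
#' expects at least `id` and `smiles` columns.
#'
#' @param df A data.frame.
#' @param rejected,dedup,n_raw Row-accounting attributes.
#' @return A `ligand_table`.
#' @export
new_ligand_table <- function(df, rejected = 0L, dedup = 0L, n_raw = nrow(df)) {
  stopifnot(all(c("id", "smiles") %in% names(df)))
  rownames(df) <- NULL
  structure(df,
            class = c("ligand_table", "data.frame"),
            rejected_count = as.integer(rejected),
            dedup_count = as.integer(dedup),
            n_raw = as.integer(n_raw))
}

#' @export
print.ligand_table <- function(x, ...) {
  cat("<ligand_table> ", nrow(x), " compounds",
      " (rejected ", attr(x, "rejected_count"),
      ", deduplicated ", attr(x, "dedup_count"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n")
  invisible(x)
}

#' Load and normalize a ligand activity table
#'
#' Reads a delimited compound table, validates and canonicalizes every
#' SMILES, converts IC50 values to nanomolar and computes pIC50. Rows with
#' unparsable SMILES or missing / non-positive / out-of-range IC50 are
#' removed and counted in `rejected_count`; exact duplicates (identical
#' canonical SMILES) are collapsed to one record with the median IC50 and
#' counted in `dedup_count`. The accounting identity
#' `rejected + dedup + kept == raw rows` always holds.
#'
#' A `pic50` column may be supplied instead of IC50, in which case IC50 is
#' derived from it.
#'
#' @param path Path to a delimited text file with a header row.
#' @param ic50_unit Unit of the IC50 column: `"nM"` (default), `"uM"`, `"M"`.
#' @param smiles_column,ic50_column,id_column Column names in the file.
#'   `ic50_column = NULL` looks for a `pic50` column; if neither exists the
#'   table is loaded without activities (candidate-library mode).
#' @param sep Field separator (default comma).
#' @param ic50_bounds Plausibility bounds in nM; values outside are treated
#'   as anomalous and rejected.
#' @return A `ligand_table`: data.frame with columns `id`, `smiles`,
#'   `ic50_nM`, `pic50`, `source` and attributes `rejected_count`,
#'   `dedup_count`, `n_raw`.
#' @export
load_ligand_table <- function(path, ic50_unit = c("nM", "uM", "M"),
                              smiles_column = "smiles",
                              ic50_column = "ic50",
                              id_column = "id",
                              sep = ",",
                              ic50_bounds = c(1e-3, 1e12)) {
  ic50_unit <- match.arg(ic50_unit)
  if (!file.exists(path)) stop("ligand table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", check.names = FALSE)
  if (nrow(raw) == 0L) stop_data("ligand table is empty: ", path)
  if (!smiles_column %in% names(raw)) {
    stop("missing SMILES column '", smiles_column, "' in ", path)
  }
  has_ic50 <- !is.null(ic50_column) && ic50_column %in% names(raw)
  has_pic50 <- "pic50" %in% names(raw)
  if (!is.null(ic50_column) && !has_ic50 && !has_pic50) {
    stop("missing IC50 column '", ic50_column, "' (and no 'pic50') in ", path)
  }
  ids <- if (id_column %in% names(raw)) as.character(raw[[id_column]]) else
    sprintf("mol_%04d", seq_len(nrow(raw)))
  smi_in <- as.character(raw[[smiles_column]])

  n_raw <- nrow(raw)
  stripped <- vapply(smi_in, largest_organic_fragment, character(1),
                     USE.NAMES = FALSE)
  can <- canonicalize_smiles(stripped)

  if (has_ic50) {
    ic50 <- suppressWarnings(as.numeric(raw[[ic50_column]])) *
      IC50_UNIT_FACTOR_NM[[ic50_unit]]
  } else if (has_pic50) {
    p <- suppressWarnings(as.numeric(raw[["pic50"]]))
    ic50 <- ifelse(is.finite(p), 10^(9 - p), NA_real_)
  } else {
    ic50 <- rep(NA_real_, n_raw)
  }
  activities <- has_ic50 || has_pic50
  # an activity column that is entirely missing (e.g. a candidate library
  # serialized with NA activities) means "no activities", not "reject all"
  if (activities && all(is.na(ic50))) {
    activities <- FALSE
    ic50 <- rep(NA_real_, n_raw)
  }

  ok_smiles <- !is.na(can)
  ok_act <- if (activities) {
    is.finite(ic50) & ic50 > 0 & ic50 >= ic50_bounds[1] & ic50 <= ic50_bounds[2]
  } else rep(TRUE, n_raw)
  keep <- ok_smiles & ok_act
  rejected <- sum(!keep)

  df <- data.frame(id = ids[keep], smiles = can[keep],
                   ic50_nM = ic50[keep], stringsAsFactors = FALSE)
  # collapse exact duplicates (canonical SMILES) to the median IC50
  dedup <- 0L
  if (nrow(df) > 0L && anyDuplicated(df$smiles)) {
    grp <- split(seq_len(nrow(df)), df$smiles)
    first <- vapply(grp, `[`, integer(1), 1L)
    med <- vapply(grp, function(ix) stats::median(df$ic50_nM[ix]), numeric(1))
    ord <- order(first)
    dedup <- nrow(df) - length(grp)
    df <- data.frame(id = df$id[first[ord]], smiles = names(grp)[ord],
                     ic50_nM = med[ord], stringsAsFactors = FALSE)
  }
  if (activities && nrow(df) == 0L) {
    stop_data("no valid compound rows left after filtering: ", path)
  }
  df$pic50 <- if (activities) 9 - log10(df$ic50_nM) else NA_real_
  if (!activities) df$ic50_nM <- NA_real_
  df$source <- basename(path)
  if (anyDuplicated(df$id)) {
    df$id <- make.unique(df$id, sep = "_dup")
  }
  new_ligand_table(df, rejected = rejected, dedup = dedup, n_raw = n_raw)
}

#' Write a normalized ligand table
#'
#' Serializes a `ligand_table` as delimited text with columns `id`,
#' `smiles`, `ic50_nM`, `pic50`. Writing then reloading reproduces the
#' records exactly (pIC50 to full double precision via 17 significant
#' digits).
#'
#' @param table A `ligand_table`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_ligand_table <- function(table, path, sep = ",") {
  df <- as.data.frame(table)[, c("id", "smiles", "ic50_nM", "pic50")]
  df$ic50_nM <- formatC(df$ic50_nM, digits = 17, format = "g")
  df$pic50 <- formatC(df$pic50, digits = 17, format = "g")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a candidate library from delimited text or SDF
#'
#' Candidate libraries carry structures and identifiers but no activities.
#' SDF input uses the molecule title as the identifier.
#'
#' @param path Path to a `.sdf` file or a delimited text file.
#' @param ... Passed on to [load_ligand_table()] for delimited input.
#' @return A `ligand_table` with `NA` activities.
#' @export
load_candidate_library <- function(path, ...) {
  if (!file.exists(path)) stop("candidate library not found: ", path)
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    smi <- vapply(seq_along(sdf), function(i) {
      blk <- paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n")
      out <- tryCatch(
        ChemmineOB::convertFormat("SDF", "CAN", paste0(blk, "\n")),
        error = function(e) ""
      )
      if (!nzchar(out)) NA_character_ else sub("\t.*$", "", sub("\n$", "", out))
    }, character(1))
    keep <- !is.na(smi)
    df <- data.frame(id = as.character(ids[keep]), smiles = smi[keep],
                     ic50_nM = NA_real_, pic50 = NA_real_,
                     source = basename(path), stringsAsFactors = FALSE)
    if (anyDuplicated(df$id)) df$id <- make.unique(df$id, sep = "_dup")
    new_ligand_table(df, rejected = sum(!keep), dedup = 0L, n_raw = length(smi))
  } else {
    load_ligand_table(path, ic50_column = NULL, ...)
  }
}

# Data-content errors get their own condition class so callers can tell
# "bad data" apart from plain I/O failures.
stop_data <- function(...) {
  stop(structure(class = c("ligscreen_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
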
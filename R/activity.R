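# Activity discretization and drug-likeness rules. Thresholds default to
# the conventional medicinal-chemistry values (class boundaries at pIC50 5
# and 7, Lipinski's Rule of Five) and are exposed as arguments.

#' Classify compound activity from pIC50
#'
#' Three-level scheme with inclusive medium boundaries: low (pIC50 < 5),
#' medium (5 <= pIC50 <= 7), high (pIC50 > 7); plus the binary
#' discretization high = pIC50 > `high_threshold` used by the
#' classification metrics. The partition is exhaustive and mutually
#' exclusive, and monotone in pIC50.
#'
#' @param pic50 Finite numeric vector.
#' @param low_threshold,high_threshold Class boundaries (defaults 5 and 7).
#' @return A data.frame with columns `klass` (factor low/medium/high) and
#'   `binary_high` (logical).
#' @examples
#' classify_activity(c(4.9, 5, 7, 7.01))
#' @export
classify_activity <- function(pic50, low_threshold = 5, high_threshold = 7) {
  if (any(!is.finite(pic50))) stop("pic50 must be finite")
  klass <- ifelse(pic50 < low_threshold, "low",
                  ifelse(pic50 > high_threshold, "high", "medium"))
  data.frame(
    klass = factor(klass, levels = c("low", "medium", "high")),
    binary_high = pic50 > high_threshold
  )
}

#' Lipinski Rule-of-Five evaluation
#'
#' Applies the four strict inequalities: LogP < 5, molecular weight
#' < 500 Da (average molecular weight, the conventional basis of the
#' rule), hydrogen bond donors < 5, hydrogen bond acceptors < 10.
#'
#' @param desc A 6-descriptor vector from [compute_descriptors()], or a
#'   matrix with one row per molecule.
#' @param logp_max,mw_max,hbd_max,hba_max Rule bounds.
#' @return A data.frame with logical columns `logp_ok`, `mw_ok`, `hbd_ok`,
#'   `hba_ok` and integer `violations` (0-4).
#' @export
lipinski <- function(desc, logp_max = 5, mw_max = 500, hbd_max = 5,
                     hba_max = 10) {
  if (is.null(dim(desc))) desc <- matrix(desc, nrow = 1,
                                         dimnames = list(NULL, names(desc)))
  need <- c("MolLogP", "MolWt", "NumHDonors", "NumHAcceptors")
  if (!all(need %in% colnames(desc))) {
    stop("descriptor input must carry columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    logp_ok = desc[, "MolLogP"] < logp_max,
    mw_ok = desc[, "MolWt"] < mw_max,
    hbd_ok = desc[, "NumHDonors"] < hbd_max,
    hba_ok = desc[, "NumHAcceptors"] < hba_max
  )
  out$violations <- as.integer(rowSums(!out))
  rownames(out) <- NULL
  out
}
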
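#' Similarity-adjusted property prediction
#'
#' Blends a model prediction with the experimental value of the most similar
#' training-set analogue. With similarity `s` below the threshold (default
#' 0.9) the model value is returned unchanged; at or above the threshold the
#' prediction is `s * p_exp + (1 - s) * p_qp`, so at `s = 1` the prediction
#' equals the measured experimental property exactly.
#'
#' @param s Similarity in `[0, 1]` (e.g. Tanimoto, see [tanimoto()]).
#' @param p_exp Experimental value of the most similar training compound.
#' @param p_qp Model-predicted value for the query compound.
#' @param threshold Similarity below which the model value is used (0.9).
#' @return Adjusted prediction (vectorised).
#' @examples
#' similarity_adjusted_prediction(0.95, p_exp = 2, p_qp = 4)  # 2.1
#' similarity_adjusted_prediction(0.8, p_exp = 2, p_qp = 4)   # 4
#' @export
similarity_adjusted_prediction <- function(s, p_exp, p_qp, threshold = 0.9) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    abort("similarity s must lie in [0, 1]")
  }
  ifelse(s < threshold, p_qp, s * p_exp + (1 - s) * p_qp)
}

#' Maximum transdermal transport rate (Jm)
#'
#' `Jm = Kp * MW * S_wat` with `Kp = 10^logK_p` (cm/h) and
#' `S_wat = 10^logS_wat` (mol/L). With MW in g/mol the product is on the
#' microgram cm^-2 h^-1 scale used for reporting; `scale` exposes the unit
#' constant (identity by default) should a different convention be needed.
#'
#' @param log_kp Log skin-permeability coefficient.
#' @param mw Molecular weight (g/mol).
#' @param log_s_wat Log aqueous solubility (mol/L); `-Inf` is allowed and
#'   yields 0.
#' @param scale Multiplicative unit constant (default 1).
#' @return Non-negative transport rate (vectorised).
#' @examples
#' transdermal_rate(-2.5, 300, -3)  # 300 * 10^-5.5
#' @export
transdermal_rate <- function(log_kp, mw, log_s_wat, scale = 1) {
  if (any(is.na(log_kp)) || any(is.na(mw)) || any(is.na(log_s_wat)) ||
      any(!is.finite(mw)) || any(log_kp == Inf) || any(log_s_wat == Inf)) {
    abort("transdermal_rate requires finite inputs (-Inf logs allowed)")
  }
  10^log_kp * mw * 10^log_s_wat * scale
}

#' Transdermal-rate flag
#'
#' Flags compounds whose predicted maximum transdermal transport rate
#' strictly exceeds the threshold (default 100, the reporting cut used for
#' library summaries).
#'
#' @param jm Transport rate from [transdermal_rate()].
#' @param threshold Strict threshold (default 100).
#' @return Logical (vectorised); `jm` exactly at the threshold is `FALSE`.
#' @export
jm_exceeds <- function(jm, threshold = 100) {
  jm > threshold
}

#' CNS-activity flag
#'
#' Predicted CNS activity is scored on an integer scale from -2 (inactive) to
#' +2 (active); a compound is called CNS-active when the score is strictly
#' greater than 1, i.e. only at +2.
#'
#' @param cns_score Integer score(s) in -2..+2.
#' @return Logical (vectorised).
#' @export
cns_active <- function(cns_score) {
  if (any(is.na(cns_score)) || any(cns_score < -2) || any(cns_score > 2) ||
      any(cns_score != round(cns_score))) {
    abort("cns_score must be integers in -2..+2")
  }
  cns_score > 1
}

#' Qualitative oral-absorption class from percent absorption
#'
#' Bins percent human oral absorption into the qualitative 1 = low,
#' 2 = medium, 3 = high scale. The bin edges are not published upstream; the
#' defaults (< 25 low, 25-80 medium, > 80 high) are a documented assumption
#' and configurable.
#'
#' @param percent_hoa Percent human oral absorption, 0-100.
#' @param low_below Values strictly below this are class 1 (default 25).
#' @param high_above Values strictly above this are class 3 (default 80).
#' @return Integer class (vectorised).
#' @export
oral_absorption_class <- function(percent_hoa, low_below = 25,
                                  high_above = 80) {
  if (any(is.na(percent_hoa)) || any(percent_hoa < 0) ||
      any(percent_hoa > 100)) {
    abort("percent_hoa must lie in [0, 100]")
  }
  ifelse(percent_hoa < low_below, 1L,
         ifelse(percent_hoa > high_above, 3L, 2L))
}

# --- fingerprints & training sets -------------------------------------------

#' Hashed substructure fingerprint of a molecule
#'
#' A deterministic bit fingerprint over simple structural features (element
#' counts, bonded element pairs with bond order, and two-bond element paths),
#' hashed into `n_bits` positions. Intended for Tanimoto similarity in
#' similarity-adjusted prediction; the upstream similarity property space is
#' undisclosed, so the metric is pluggable.
#'
#' @param mol A [molecule_record()].
#' @param n_bits Fingerprint length (default 256).
#' @return Logical vector of length `n_bits`.
#' @export
fingerprint_molecule <- function(mol, n_bits = 256) {
  stopifnot(inherits(mol, "molecule_record"))
  el <- mol$atoms$element
  feats <- paste0("E:", el)
  if (nrow(mol$bonds) > 0) {
    b <- mol$bonds
    pair <- vapply(seq_len(nrow(b)), function(k) {
      e <- sort(c(el[b$from[k]], el[b$to[k]]))
      paste0("B:", e[1], b$order[k], e[2])
    }, character(1))
    feats <- c(feats, pair)
    nb <- heavy_neighbours(mol)
    for (j in seq_along(nb)) {
      ix <- nb[[j]]
      if (length(ix) >= 2) {
        cmb <- utils::combn(ix, 2)
        feats <- c(feats, apply(cmb, 2, function(p) {
          e <- sort(el[p])
          paste0("P:", e[1], el[j], e[2])
        }))
      }
    }
  }
  bits <- rep(FALSE, n_bits)
  for (f in unique(feats)) {
    h <- sum(utf8ToInt(f) * seq_along(utf8ToInt(f)) * 131) %% n_bits
    bits[h + 1] <- TRUE
  }
  bits
}

#' Tanimoto similarity between two bit fingerprints
#' @param a,b Logical vectors of equal length.
#' @return Similarity in `[0, 1]` (0 when both fingerprints are empty).
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Read an experimental training set
#'
#' CSV with columns `id,smiles,experimental_value`; fingerprints are computed
#' from the SMILES at read time. No training set ships with the package (the
#' upstream set is proprietary) — supply your own.
#'
#' @param path CSV path.
#' @param n_bits Fingerprint length.
#' @return Tibble `id`, `experimental_value`, `fingerprint` (list column).
#' @export
read_training_set <- function(path, n_bits = 256) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    id = "c", smiles = "c", experimental_value = "d"), progress = FALSE)
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi))
  writeLines(paste(tab$smiles, tab$id), smi)
  mols <- read_structures(smi, "smiles")
  tab$fingerprint <- map(mols, fingerprint_molecule, n_bits = n_bits)
  tab[, c("id", "experimental_value", "fingerprint")]
}

#' Similarity-adjusted prediction against a training set
#'
#' Finds the training compound most similar to the query (Tanimoto on hashed
#' fingerprints by default) and applies [similarity_adjusted_prediction()].
#'
#' @param mol Query [molecule_record()].
#' @param training Training tibble from [read_training_set()].
#' @param p_qp Model-predicted value for the query.
#' @param threshold Similarity threshold (default 0.9).
#' @param metric Similarity function `(a, b) -> [0, 1]`.
#' @return Tibble with `nearest_id`, `similarity`, `prediction`.
#' @export
predict_with_training_set <- function(mol, training, p_qp, threshold = 0.9,
                                      metric = tanimoto) {
  if (nrow(training) == 0) abort("training set is empty")
  fp <- fingerprint_molecule(mol, n_bits = length(training$fingerprint[[1]]))
  sims <- map_dbl(training$fingerprint, metric, b = fp)
  k <- which.max(sims)
  tibble(nearest_id = training$id[k], similarity = sims[k],
         prediction = similarity_adjusted_prediction(
           sims[k], training$experimental_value[k], p_qp, threshold))
}
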
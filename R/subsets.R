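#' Drug-like, lead-like and fragment-like subset definitions
#'
#' Inequality sets for the three standard library subsets, with the exact
#' printed strictness:
#' * drug-like: MW < 500, logP < 5, HBD <= 5, HBA <= 10
#' * lead-like: 150 <= MW <= 350, logP <= 4, HBD <= 3, HBA <= 6
#' * fragment-like: MW <= 250, -2 <= logP <= 3, HBD < 3, HBA < 6, NRB < 3
#'
#' Definitions ship as an editable CSV in the same dialect as the range
#' panels.
#'
#' @param path Optional CSV (`subset,descriptor,comparator,value,value2`) with
#'   comparators `lt`, `le`, `gt`, `ge`, `between` (both bounds inclusive).
#' @return Tibble of clauses.
#' @export
subset_definitions <- function(path = NULL) {
  path <- path %||% extdata("subset_rules.csv")
  defs <- readr::read_csv(path, col_types = readr::cols(
    subset = "c", descriptor = "c", comparator = "c",
    value = "d", value2 = "d"), progress = FALSE)
  bad <- setdiff(defs$comparator, c("lt", "le", "gt", "ge", "between"))
  if (length(bad) > 0) abort(paste0("unknown comparator(s): ",
                                    paste(bad, collapse = ", ")))
  btw <- defs$comparator == "between"
  if (any(btw & (is.na(defs$value2) | defs$value > defs$value2))) {
    abort("between clauses need ordered value <= value2")
  }
  defs
}

#' @keywords internal
eval_clause <- function(v, comparator, value, value2) {
  switch(comparator,
         lt = v < value, le = v <= value,
         gt = v > value, ge = v >= value,
         between = v >= value & v <= value2)
}

#' Does each compound satisfy a subset definition?
#'
#' The conjunction of the subset's clauses, evaluated with the printed
#' strictness (so a compound with MW exactly 500 is not drug-like).
#'
#' @param profiles Profiles tibble.
#' @param definition Clause tibble for one subset (rows of
#'   [subset_definitions()]).
#' @return Logical vector, one element per compound.
#' @export
subset_matches <- function(profiles, definition) {
  need <- unique(definition$descriptor)
  absent <- setdiff(need, names(profiles))
  if (length(absent) > 0) {
    abort(paste0("profiles lack descriptor(s): ",
                 paste(absent, collapse = ", ")))
  }
  na_rows <- profiles$id[!complete.cases(profiles[need])]
  if (length(na_rows) > 0) {
    abort(paste0("missing values for subset descriptors in compound(s): ",
                 paste(head(na_rows, 5), collapse = ", "),
                 if (length(na_rows) > 5) ", ..."))
  }
  ok <- rep(TRUE, nrow(profiles))
  for (k in seq_len(nrow(definition))) {
    ok <- ok & eval_clause(profiles[[definition$descriptor[k]]],
                           definition$comparator[k],
                           definition$value[k], definition$value2[k])
  }
  ok
}

#' Classify a library into the standard subsets
#'
#' Subsets are not exclusive: a compound is a member of every subset whose
#' clauses it satisfies (the printed bounds make every lead-like and every
#' fragment-like compound also drug-like).
#'
#' @param profiles Profiles tibble.
#' @param definitions Clause tibble, see [subset_definitions()].
#' @return Tibble with `id` and one logical column per subset. An empty
#'   library returns an empty tibble.
#' @export
classify_library <- function(profiles, definitions = subset_definitions()) {
  out <- tibble(id = if (nrow(profiles)) profiles$id else character(0))
  for (s in unique(definitions$subset)) {
    def <- definitions[definitions$subset == s, ]
    out[[s]] <- if (nrow(profiles)) subset_matches(profiles, def) else logical(0)
  }
  out
}

#' Rule-of-Three oral-bioavailability compliance
#'
#' Jorgensen's Rule of Three: a compound is more likely to be orally
#' available when `logS_wat > -5.7`, `Caco2 > 22` nm/s and fewer than seven
#' primary metabolic reactions (`n_metab < 7`). All three comparisons are
#' strict. `compliant` requires the full conjunction; `criteria_met` counts
#' the satisfied clauses (0-3) for "all or some" style reporting.
#'
#' @param profiles Profiles tibble carrying `logS_wat`, `Caco2`, `n_metab`.
#' @param logS_min,caco2_min,metab_max The three thresholds (defaults -5.7,
#'   22 nm/s, 7).
#' @return Tibble with `id`, `criteria_met`, `compliant`.
#' @examples
#' ro3_evaluate(tibble::tibble(id = "a", logS_wat = -3.13,
#'                             Caco2 = 1207.91, n_metab = 3))
#' @export
ro3_evaluate <- function(profiles, logS_min = -5.7, caco2_min = 22,
                         metab_max = 7) {
  need <- c("logS_wat", "Caco2", "n_metab")
  absent <- setdiff(need, names(profiles))
  if (length(absent) > 0) {
    abort(paste0("profiles lack descriptor(s): ",
                 paste(absent, collapse = ", ")))
  }
  na_rows <- profiles$id[!complete.cases(profiles[need])]
  if (length(na_rows) > 0) {
    abort(paste0("missing Rule-of-Three descriptor value(s) for compound(s): ",
                 paste(head(na_rows, 5), collapse = ", "),
                 if (length(na_rows) > 5) ", ..."))
  }
  met <- (profiles$logS_wat > logS_min) +
    (profiles$Caco2 > caco2_min) +
    (profiles$n_metab < metab_max)
  tibble(id = profiles$id, criteria_met = as.integer(met),
         compliant = met == 3L)
}
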
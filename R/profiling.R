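#' Per-descriptor library means
#'
#' Arithmetic means over present values; missing values are excluded from
#' numerator and denominator alike.
#'
#' @param profiles Profiles tibble (non-empty).
#' @param descriptors Descriptors to summarise; defaults to every numeric
#'   descriptor column.
#' @return Tibble `descriptor`, `mean`, `n_present`.
#' @export
summarize_means <- function(profiles, descriptors = NULL) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort("profiles must be a non-empty data frame")
  }
  descriptors <- descriptors %||%
    names(profiles)[vapply(profiles, is.numeric, logical(1))]
  descriptors <- setdiff(descriptors, "id")
  rows <- map(descriptors, function(d) {
    v <- profiles[[d]]
    v <- v[!is.na(v)]
    tibble(descriptor = d,
           mean = if (length(v)) mean(v) else NA_real_,
           n_present = length(v))
  })
  bind_rows(rows)
}

#' Subset-by-descriptor percent-compliance table
#'
#' The library-level compliance report: one row per panel descriptor plus
#' summary rows for Rule-of-Three compliance (`ro3`), full panel compliance
#' (`stars0`) and at-most-two-violations (`stars_le2`); one column per
#' library subset (always including `total`). Cells for empty subsets are
#' `NA` (undefined), never 0.
#'
#' @param profiles Profiles tibble.
#' @param panel Range panel.
#' @param subsets Membership tibble from [classify_library()], or `NULL` to
#'   classify on the fly (requires the subset descriptors); `FALSE` for a
#'   total-only table.
#' @param descriptors Panel descriptors to report; defaults to those present.
#' @return Tibble with `descriptor` and one percentage column per subset.
#' @export
summarize_compliance <- function(profiles, panel = drugs95_panel(),
                                 subsets = NULL, descriptors = NULL) {
  panel <- validate_panel(panel)
  if (isFALSE(subsets)) {
    membership <- tibble(id = profiles$id)
  } else {
    subsets <- subsets %||% classify_library(profiles)
    membership <- subsets
  }
  subset_names <- c("total", setdiff(names(membership), "id"))
  descriptors <- descriptors %||%
    intersect(panel$descriptor, names(profiles))
  can_ro3 <- all(c("logS_wat", "Caco2", "n_metab") %in% names(profiles))
  row_names <- c(descriptors, if (can_ro3) "ro3", "stars0", "stars_le2")
  out <- tibble(descriptor = row_names)
  for (s in subset_names) {
    keep <- if (s == "total") rep(TRUE, nrow(profiles)) else
      profiles$id %in% membership$id[membership[[s]]]
    sub <- profiles[keep, , drop = FALSE]
    col <- rep(NA_real_, length(row_names))
    if (nrow(sub) > 0) {
      pc <- tryCatch(
        percent_compliance(sub, descriptors, panel),
        error = function(e) NULL)
      if (!is.null(pc)) {
        col[match(pc$descriptor, row_names)] <- pc$percent
      }
      if (can_ro3) {
        col[row_names == "ro3"] <-
          round(100 * mean(ro3_evaluate(sub)$compliant), 2)
      }
      st <- evaluate_compliance(sub, panel)$stars$stars
      col[row_names == "stars0"] <- round(100 * mean(st == 0), 2)
      col[row_names == "stars_le2"] <- round(100 * mean(st <= 2), 2)
    }
    out[[s]] <- col
  }
  out
}

#' Left-closed histogram with lower-edge labels
#'
#' Bins values as `floor((v - origin) / width)`; each bin is closed on its
#' lower edge and open on the upper, and is labelled by its lower edge (a
#' label of 0 with width 1 covers values in [0, 1)). Counts conserve the
#' number of input values.
#'
#' @param values Numeric vector (finite).
#' @param width Bin width (> 0).
#' @param origin Origin of the binning grid.
#' @return Tibble `lower_edge`, `count`, ordered by edge; empty bins between
#'   occupied ones are included with count 0.
#' @examples
#' histogram_counts(c(0, 0, 1, 2), width = 1)
#' @export
histogram_counts <- function(values, width = 1, origin = 0) {
  if (length(values) == 0) abort("values must be non-empty")
  if (width <= 0) abort("width must be > 0")
  bad <- which(!is.finite(values))
  if (length(bad) > 0) {
    abort(paste0("non-finite values at position(s): ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) ", ..."))
  }
  k <- floor((values - origin) / width)
  rng <- seq(min(k), max(k))
  cnt <- tabulate(k - min(k) + 1L, nbins = length(rng))
  tibble(lower_edge = origin + rng * width, count = as.integer(cnt))
}

#' Render a library report
#'
#' Writes the summary tables and histograms as CSV, JSON or Markdown files in
#' `dir`. Output is deterministic: identical inputs give byte-identical
#' files.
#'
#' @param means Means tibble from [summarize_means()] (or `NULL`).
#' @param compliance Compliance table from [summarize_compliance()] (or
#'   `NULL`).
#' @param histograms Named list of histogram tibbles from
#'   [histogram_counts()] (possibly empty; the report then has no figures
#'   section).
#' @param dir Output directory (created if needed).
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(means = NULL, compliance = NULL,
                          histograms = list(), dir,
                          format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(tab, stem) {
    f <- file.path(dir, paste0(stem, switch(format, csv = ".csv",
                                            json = ".json", markdown = ".md")))
    switch(format,
      csv = readr::write_csv(tab, f, na = "", progress = FALSE),
      json = jsonlite::write_json(tab, f, dataframe = "rows", digits = NA,
                                  na = "null"),
      markdown = writeLines(markdown_table(tab), f))
    f
  }
  if (!is.null(means)) files <- c(files, emit(means, "means"))
  if (!is.null(compliance)) files <- c(files, emit(compliance, "compliance"))
  for (nm in names(histograms)) {
    files <- c(files, emit(histograms[[nm]], paste0("hist_", nm)))
  }
  invisible(files)
}

#' @keywords internal
markdown_table <- function(tab) {
  fmt <- function(x) {
    ifelse(is.na(x), "",
           ifelse(vapply(x, is.numeric, logical(1)) | is.numeric(x),
                  vapply(x, function(v) {
                    if (is.numeric(v)) sprintf("%.6g", v) else as.character(v)
                  }, character(1)),
                  as.character(x)))
  }
  cells <- vapply(tab, fmt, character(nrow(tab)))
  if (nrow(tab) == 1) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(tab), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
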
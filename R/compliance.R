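#' The "95% of known drugs" property-range panel
#'
#' Loads one of the shipped range panels. `"methods"` carries the ranges as
#' printed alongside the descriptor definitions (logK_HSA upper 1.2, logBB
#' upper 1.0, 0-15 metabolic reactions); `"results"` carries the variant
#' bounds quoted in the results discussion (1.5, 1.2 and 1-8 respectively).
#' Both variants ship because the source itself prints both; neither is
#' privileged. Bounds are closed: a value equal to a printed endpoint is in
#' range. Panels are data, not code — edit the CSV or supply your own via
#' [read_panel()].
#'
#' @param variant `"methods"` (default) or `"results"`.
#' @return A range-panel tibble with columns `descriptor`, `lower`, `upper`,
#'   `star` (does the descriptor count toward the stars total?), `note`.
#' @examples
#' drugs95_panel()
#' @export
drugs95_panel <- function(variant = c("methods", "results")) {
  variant <- match.arg(variant)
  file <- if (variant == "methods") "drugs95.csv" else "drugs95_results.csv"
  read_panel(extdata("panels", file))
}

#' Read a range panel from CSV
#'
#' @param path CSV with columns `descriptor,lower,upper,star[,note]`; use
#'   `-Inf`/`Inf` for one-sided guidance (e.g. the HERG concern threshold is
#'   encoded as `[-5, Inf)`).
#' @return A range-panel tibble.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, col_types = readr::cols(
    descriptor = "c", lower = "d", upper = "d", star = "l",
    .default = "c"), progress = FALSE, na = c("", "NA"))
  validate_panel(panel)
}

#' @keywords internal
validate_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  need <- c("descriptor", "lower", "upper")
  if (!all(need %in% names(panel))) {
    abort("panel needs columns descriptor, lower, upper")
  }
  if (is.null(panel$star)) panel$star <- TRUE
  if (is.null(panel$note)) panel$note <- NA_character_
  panel$lower[is.na(panel$lower)] <- -Inf
  panel$upper[is.na(panel$upper)] <- Inf
  if (anyDuplicated(panel$descriptor)) {
    abort("panel has duplicate descriptors")
  }
  if (any(panel$lower > panel$upper)) {
    abort("panel has lower > upper")
  }
  unreg <- panel$descriptor[!is_registered(panel$descriptor)]
  if (length(unreg) > 0) {
    warn(paste0("panel descriptor(s) not in registry: ",
                paste(unreg, collapse = ", ")))
  }
  panel
}

#' Score profiles against a range panel (the stars count)
#'
#' For each compound and each panel descriptor, the value is classified
#' `in_range` (within the closed interval), `out_of_range` (strictly below the
#' lower or strictly above the upper bound) or `missing`. The compound's
#' `stars` is the number of star-member descriptors out of range — 0 means the
#' compound sits inside the property space of 95% of known drugs on every
#' evaluated descriptor.
#'
#' @param profiles Profiles tibble (`id` + descriptor columns).
#' @param panel Range panel, see [drugs95_panel()].
#' @param missing `"skip"` (default): missing descriptors are recorded but not
#'   counted; `"fail"`: any missing star descriptor raises an error listing
#'   the descriptors concerned.
#' @return An object of class `admet_compliance`: list with `status` (long
#'   tibble id/descriptor/value/status), `stars` (tibble id/stars/evaluated)
#'   and the panel. Use [tidy()][generics::tidy] and
#'   [glance()][generics::glance] to extract tidy summaries.
#' @examples
#' prof <- tibble::tibble(id = "a", S_mol = 1200, logS_wat = -3)
#' res <- evaluate_compliance(prof)
#' res$stars
#' @export
evaluate_compliance <- function(profiles, panel = drugs95_panel(),
                                missing = c("skip", "fail")) {
  missing <- match.arg(missing)
  panel <- validate_panel(panel)
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort("profiles must be a non-empty data frame")
  }
  if (!"id" %in% names(profiles)) abort("profiles must have an 'id' column")
  long <- purrr::pmap(panel, function(descriptor, lower, upper, star, ...) {
    v <- if (descriptor %in% names(profiles)) profiles[[descriptor]] else
      rep(NA_real_, nrow(profiles))
    tibble(id = profiles$id, descriptor = descriptor, value = as.numeric(v),
           star = star,
           status = dplyr::case_when(
             is.na(v) ~ "missing",
             v < lower | v > upper ~ "out_of_range",
             TRUE ~ "in_range"))
  }) %>% bind_rows()
  if (missing == "fail") {
    miss <- long %>% filter(.data$star, .data$status == "missing") %>%
      pull(.data$descriptor) %>% unique()
    if (length(miss) > 0) {
      abort(paste0("missing star descriptor(s): ", paste(miss, collapse = ", ")))
    }
  }
  stars <- long %>%
    filter(.data$star) %>%
    group_by(.data$id) %>%
    summarise(stars = sum(.data$status == "out_of_range"),
              evaluated = sum(.data$status != "missing"),
              .groups = "drop")
  stars <- stars[match(profiles$id, stars$id), ]
  structure(list(status = long %>% select(-"star"), stars = stars,
                 panel = panel, n = nrow(profiles)),
            class = "admet_compliance")
}

#' @export
print.admet_compliance <- function(x, ...) {
  g <- glance(x)
  cat("<admet_compliance> ", x$n, " compounds, ",
      nrow(x$panel), " panel descriptors (",
      sum(x$panel$star), " star members)\n", sep = "")
  cat(sprintf("  stars = 0: %.2f%%   stars <= 2: %.2f%%\n",
              g$pct_stars0, g$pct_stars_le2))
  invisible(x)
}

#' @rdname evaluate_compliance
#' @param x An `admet_compliance` object.
#' @param ... Unused.
#' @export
tidy.admet_compliance <- function(x, ...) x$status

#' @rdname evaluate_compliance
#' @export
glance.admet_compliance <- function(x, ...) {
  s <- x$stars$stars
  tibble(n = x$n,
         n_stars0 = sum(s == 0),
         pct_stars0 = round(100 * mean(s == 0), 2),
         pct_stars_le2 = round(100 * mean(s <= 2), 2),
         mean_stars = mean(s))
}

#' Percent compliance of descriptors across a library
#'
#' For each requested descriptor, the percentage of compounds whose value lies
#' in the panel range, among compounds that carry the descriptor at all
#' (missing values never enter the denominator). Percentages are reported to
#' two decimals; the raw fraction is retained alongside.
#'
#' @param profiles Profiles tibble.
#' @param descriptors Descriptors to evaluate; defaults to every panel
#'   descriptor present in `profiles`.
#' @param panel Range panel.
#' @return Tibble with columns `descriptor`, `n_present`, `n_in_range`,
#'   `fraction`, `percent`.
#' @export
percent_compliance <- function(profiles, descriptors = NULL,
                               panel = drugs95_panel()) {
  panel <- validate_panel(panel)
  descriptors <- descriptors %||%
    intersect(panel$descriptor, names(profiles))
  missing_range <- setdiff(descriptors, panel$descriptor)
  if (length(missing_range) > 0) {
    abort(paste0("no range in panel for: ",
                 paste(missing_range, collapse = ", ")))
  }
  rows <- map(descriptors, function(d) {
    v <- if (d %in% names(profiles)) profiles[[d]] else numeric(0)
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      abort(paste0("descriptor '", d, "' absent from every compound; ",
                   "percent compliance undefined"))
    }
    lo <- panel$lower[panel$descriptor == d]
    hi <- panel$upper[panel$descriptor == d]
    frac <- mean(v >= lo & v <= hi)
    tibble(descriptor = d, n_present = length(v),
           n_in_range = sum(v >= lo & v <= hi),
           fraction = frac, percent = round(100 * frac, 2))
  })
  bind_rows(rows)
}

#' Distribution of the stars count across a library
#'
#' @inheritParams percent_compliance
#' @return Tibble `stars`, `count`, ordered by stars; counts sum to the
#'   library size.
#' @export
stars_distribution <- function(profiles, panel = drugs95_panel()) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort("profiles must be a non-empty data frame")
  }
  res <- evaluate_compliance(profiles, panel)
  res$stars %>%
    count(.data$stars, name = "count") %>%
    arrange(.data$stars)
}
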
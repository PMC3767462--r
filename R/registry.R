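#' Canonical descriptor registry
#'
#' Every descriptor handled by the package has one canonical name (used as the
#' column name in profile tables), a unit, a one-line description and a set of
#' known external aliases. External tables are mapped onto canonical names
#' through this registry, so that e.g. a column headed `QPlogS` or `logS`
#' lands in the canonical `logS_wat` column.
#'
#' @param path Optional path to a registry CSV with columns
#'   `canonical,units,description,aliases` (aliases `|`-separated). Defaults to
#'   the registry shipped with the package.
#' @return A tibble with columns `canonical`, `units`, `description`,
#'   `aliases` (list column of character vectors).
#' @examples
#' descriptor_registry()
#' @export
descriptor_registry <- function(path = NULL) {
  path <- path %||% extdata("descriptor_registry.csv")
  reg <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  reg$aliases <- lapply(reg$aliases, function(a) {
    if (is.na(a) || !nzchar(a)) character(0) else strsplit(a, "|", fixed = TRUE)[[1]]
  })
  dup <- unlist(reg$aliases)[unlist(reg$aliases) %in% reg$canonical]
  if (length(dup) > 0) {
    abort(paste0("registry invalid: canonical name(s) listed as alias: ",
                 paste(unique(dup), collapse = ", ")))
  }
  tibble::as_tibble(reg)
}

#' QikProp export header aliases
#'
#' The column headers written by the QikProp descriptor program (e.g.
#' `QPlogPo/w`, `#stars`, `QPPCaco`). Ships as an editable CSV
#' (`alias,canonical`); pass your own file to track a different export dialect.
#'
#' @param path Optional path to an alias CSV.
#' @return Named character vector mapping alias -> canonical name.
#' @export
qikprop_aliases <- function(path = NULL) {
  path <- path %||% extdata("qikprop_aliases.csv")
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  setNames(tab$canonical, tab$alias)
}

#' Resolve descriptor names to canonical form
#'
#' Resolution is idempotent: an already-canonical name is returned unchanged.
#' Unknown names resolve to `NA`.
#'
#' @param x Character vector of column headers / descriptor names.
#' @param registry Registry tibble from [descriptor_registry()].
#' @param extra_aliases Optional named character vector (alias -> canonical)
#'   consulted in addition to the registry, e.g. [qikprop_aliases()].
#' @return Character vector of canonical names, `NA` where unresolved.
#' @examples
#' resolve_descriptor_names(c("mol.MW", "QPlogPo/w", "MW", "mystery"))
#' @export
resolve_descriptor_names <- function(x, registry = descriptor_registry(),
                                     extra_aliases = qikprop_aliases()) {
  alias_map <- c(
    setNames(rep(registry$canonical, lengths(registry$aliases)),
             unlist(registry$aliases)),
    extra_aliases
  )
  out <- ifelse(x %in% registry$canonical, x,
                unname(alias_map[x]))
  as.character(out)
}

#' @keywords internal
is_registered <- function(x, registry = descriptor_registry()) {
  x %in% registry$canonical
}

`%||%` <- function(a, b) if (is.null(a)) b else a
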
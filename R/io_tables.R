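#' Read a per-compound descriptor table
#'
#' Ingests descriptor tables into the package's wide profile format: a tibble
#' with an `id` column and one numeric column per canonical descriptor.
#' Column headers are resolved through the descriptor registry (and, for the
#' `qikprop_export` dialect, the editable QikProp alias table); columns that
#' do not resolve are retained under their raw names with a warning. Missing
#' cells stay `NA` — they are never imputed, so the compliance engine can
#' distinguish "out of range" from "unknown".
#'
#' @param path Path to the table.
#' @param dialect `"generic_csv"` (comma-separated, `.` decimal, first column
#'   is the compound id), `"qikprop_export"` (same layout, QikProp headers) or
#'   `"sdf_tags"` (values carried as SDF property tags).
#' @param registry Descriptor registry, see [descriptor_registry()].
#' @param aliases Extra alias map for `qikprop_export`; defaults to
#'   [qikprop_aliases()].
#' @return A profiles tibble. Descriptor provenance (`"imported"`) is recorded
#'   in the `provenance` attribute, see [provenance()].
#' @export
read_descriptor_table <- function(path,
                                  dialect = c("generic_csv", "qikprop_export",
                                              "sdf_tags"),
                                  registry = descriptor_registry(),
                                  aliases = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "sdf_tags") {
    return(profiles_from_sdf_tags(path, registry))
  }
  aliases <- aliases %||%
    if (dialect == "qikprop_export") qikprop_aliases() else
      setNames(character(0), character(0))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 1) abort(paste0("no columns in ", path))
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate compound id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  headers <- names(raw)[-1]
  canon <- resolve_descriptor_names(headers, registry, aliases)
  unresolved <- headers[is.na(canon)]
  if (length(unresolved) > 0) {
    warn(paste0("unresolved column(s) kept under raw names: ",
                paste(unresolved, collapse = ", ")))
  }
  out_names <- ifelse(is.na(canon), headers, canon)
  cols <- list(id = ids)
  for (k in seq_along(headers)) {
    x <- raw[[k + 1]]
    registered <- !is.na(canon[k])
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(trimws(x)) & is.na(num))
    if (length(bad) > 0) {
      if (registered) {
        abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                      x[bad[1]], headers[k], bad[1]))
      }
      cols[[out_names[k]]] <- x  # unregistered free-text column
    } else {
      num[!is.na(x) & !nzchar(trimws(x))] <- NA_real_
      cols[[out_names[k]]] <- num
    }
  }
  prof <- tibble::as_tibble(cols)
  set_provenance(prof, setNames(rep("imported", length(out_names)), out_names))
}

#' @keywords internal
profiles_from_sdf_tags <- function(path, registry) {
  mols <- read_structures(path, "sdf")
  if (length(mols) == 0) abort(paste0("no molecules in ", path))
  ids <- map_chr(mols, "id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate compound id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  rows <- map(mols, function(m) {
    tags <- m$properties
    if (length(tags) == 0) return(tibble(id = m$id))
    canon <- resolve_descriptor_names(names(tags), registry)
    nm <- ifelse(is.na(canon), names(tags), canon)
    vals <- suppressWarnings(as.numeric(unlist(tags)))
    bad <- is.na(vals) & nzchar(trimws(unlist(tags)))
    keep <- !is.na(vals)
    tibble::as_tibble(c(list(id = m$id),
                        setNames(as.list(vals[keep]), nm[keep])))
  })
  prof <- bind_rows(rows)
  desc <- setdiff(names(prof), "id")
  unresolved <- desc[!is_registered(desc, registry)]
  if (length(unresolved) > 0) {
    warn(paste0("unresolved tag(s) kept under raw names: ",
                paste(unresolved, collapse = ", ")))
  }
  set_provenance(prof, setNames(rep("imported", length(desc)), desc))
}

#' Write compound profiles
#'
#' Writes a profiles tibble to CSV, JSON, or an SDF whose property tags carry
#' the descriptor values (a minimal one-atom molblock is emitted per record,
#' since profile tables carry no geometry). Values survive a write/read
#' round-trip to better than six significant digits.
#'
#' @param profiles Profiles tibble (must be non-empty; `id` column required).
#' @param path Output path.
#' @param format `"csv"`, `"sdf_tags"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("csv", "sdf_tags", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort("profiles must be a non-empty data frame")
  }
  if (!"id" %in% names(profiles)) abort("profiles must have an 'id' column")
  desc <- setdiff(names(profiles), "id")
  unregistered <- desc[!is_registered(desc)]
  if (length(unregistered) > 0) {
    warn(paste0("unregistered descriptor(s) written under raw names: ",
                paste(unregistered, collapse = ", ")))
  }
  ok <- tryCatch({
    switch(format,
      csv = readr::write_csv(profiles, path, na = "", progress = FALSE),
      json = jsonlite::write_json(profiles, path, dataframe = "rows",
                                  digits = NA, na = "null"),
      sdf_tags = write_profiles_sdf(profiles, path))
    TRUE
  }, error = function(e) {
    abort(paste0("cannot write ", path, ": ", conditionMessage(e)))
  })
  invisible(path)
}

#' @keywords internal
write_profiles_sdf <- function(profiles, path) {
  desc <- setdiff(names(profiles), "id")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(profiles))) {
    writeLines(c(
      profiles$id[i], "  admetscreen profile record", "",
      "  2  1  0  0  0  0  0  0  0  0999 V2000",
      "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "  1  2  1  0  0  0  0",
      "M  END"), con)
    for (d in desc) {
      v <- profiles[[d]][i]
      if (is.na(v)) next
      writeLines(c(paste0("> <", d, ">"),
                   if (is.numeric(v)) sprintf("%.10g", v) else as.character(v),
                   ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Descriptor provenance of a profiles table
#'
#' Each descriptor column is tagged `"computed"` (produced by this package
#' from structures) or `"imported"` (read from an external table).
#'
#' @param profiles Profiles tibble.
#' @return Named character vector, one entry per descriptor column.
#' @export
provenance <- function(profiles) {
  attr(profiles, "provenance") %||%
    setNames(character(0), character(0))
}

#' @keywords internal
set_provenance <- function(profiles, prov) {
  old <- attr(profiles, "provenance")
  attr(profiles, "provenance") <- c(old[setdiff(names(old), names(prov))], prov)
  profiles
}
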
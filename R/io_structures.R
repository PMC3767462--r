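#' Read molecular structures from SDF or SMILES files
#'
#' SDF (MDL V2000) files are parsed with ChemmineR; per-record property tags
#' are preserved in the `properties` field. SMILES files (one molecule per
#' line, optional whitespace-separated name) are converted through Open Babel,
#' which assigns 2D layout coordinates; such records carry connectivity and
#' implicit-hydrogen information but are not suitable for 3D surface
#' descriptors.
#'
#' @param path Path to the structure file.
#' @param format `"sdf"` or `"smiles"`.
#' @return A list of [molecule_record()] objects, one per molecule. An empty
#'   file yields an empty list with a warning.
#' @examples
#' sdf <- system.file("extdata", "example.sdf", package = "admetscreen")
#' mols <- read_structures(sdf, "sdf")
#' length(mols)
#' @export
read_structures <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    warn(paste0("empty structure file: ", path))
    return(list())
  }
  if (format == "smiles") {
    n_expected <- sum(nzchar(trimws(lines)))
    sdf_path <- tempfile(fileext = ".sdf")
    on.exit(unlink(sdf_path), add = TRUE)
    ChemmineOB::convertFormatFile("SMI", "SDF", path, sdf_path)
    mols <- read_sdf_records(sdf_path)
    if (length(mols) != n_expected) {
      abort(sprintf(
        "parsed %d of %d SMILES lines from %s; check the unparsed entries",
        length(mols), n_expected, path))
    }
    return(mols)
  }
  read_sdf_records(path)
}

#' @keywords internal
read_sdf_records <- function(path) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) abort(paste0("failed to parse SDF ", path, ": ",
                                     conditionMessage(e)))
  )
  ids <- ChemmineR::sdfid(sdfset)
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    rec <- tryCatch(sdf_to_record(sdfset[[i]], ids[i], i),
                    error = function(e) {
                      abort(sprintf("unparseable SDF record %d (%s): %s",
                                    i, path, conditionMessage(e)))
                    })
    out[[i]] <- rec
  }
  out
}

#' @keywords internal
sdf_to_record <- function(sdf, id, i) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  # V2000 charge codes: 1..7 -> +3,+2,+1,radical,-1,-2,-3
  code <- if ("C5" %in% colnames(ab)) ab[, "C5"] else rep(0, nrow(ab))
  charge_map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- charge_map[as.character(code)]
  charge[is.na(charge)] <- 0L
  atoms <- tibble(element = elements,
                  x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]),
                  charge = charge)
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    NULL
  } else {
    tibble(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }
  props <- as.list(ChemmineR::datablock(sdf))
  if (is.null(id) || is.na(id) || !nzchar(id)) id <- paste0("mol_", i)
  molecule_record(id = id, atoms = atoms, bonds = bonds, name = id,
                  properties = props)
}
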
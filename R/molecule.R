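#' Construct a molecule record
#'
#' A light container for one small molecule: element symbols, 3D coordinates
#' (in Angstrom), formal charges, a bond list and free-form property tags.
#' Coordinates may be wholly absent (all `NA`) for connectivity-only records
#' (e.g. parsed from SMILES); geometry descriptors then refuse to run.
#'
#' @param id Compound identifier.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`, `charge`.
#' @param bonds Data frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (1, 2, 3; 4 denotes an aromatic bond).
#' @param name Human-readable name (defaults to `id`).
#' @param properties Named list of property tags (kept as text).
#' @return An object of class `molecule_record`.
#' @examples
#' m <- molecule_record("c1", atoms = data.frame(
#'   element = "C", x = 0, y = 0, z = 0, charge = 0L))
#' n_atoms(m)
#' @export
molecule_record <- function(id, atoms, bonds = NULL, name = id,
                            properties = list()) {
  atoms <- tibble::as_tibble(atoms)
  if (!all(c("element", "x", "y", "z") %in% names(atoms))) {
    abort("atoms must have columns element, x, y, z")
  }
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  has_na <- anyNA(coords)
  if (has_na && !all(is.na(coords))) {
    abort(paste0("molecule '", id, "': coordinates must be all present or all absent"))
  }
  if (!has_na && any(!is.finite(coords))) {
    abort(paste0("molecule '", id, "': non-finite coordinates"))
  }
  if (is.null(bonds)) {
    bonds <- tibble(from = integer(0), to = integer(0), order = integer(0))
  }
  bonds <- tibble::as_tibble(bonds)
  if (nrow(bonds) > 0) {
    idx <- c(bonds$from, bonds$to)
    if (any(idx < 1 | idx > nrow(atoms))) {
      abort(paste0("molecule '", id, "': bond refers to atom index outside 1..",
                   nrow(atoms)))
    }
  }
  known <- atoms$element %in% bondi_radii()$element
  structure(
    list(id = as.character(id), name = as.character(name),
         atoms = atoms, bonds = bonds,
         properties = properties,
         unknown_elements = unique(atoms$element[!known])),
    class = "molecule_record"
  )
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record> ", x$id,
      " (", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

#' Number of atoms / heavy atoms in a molecule record
#' @param mol A `molecule_record`.
#' @param heavy Count only non-hydrogen atoms?
#' @return Integer count.
#' @export
n_atoms <- function(mol, heavy = FALSE) {
  stopifnot(inherits(mol, "molecule_record"))
  if (heavy) sum(mol$atoms$element != "H") else nrow(mol$atoms)
}

#' @keywords internal
has_coords <- function(mol) {
  nrow(mol$atoms) > 0 && !anyNA(mol$atoms$x)
}

#' @keywords internal
coord_matrix <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

# Sum of explicit bond orders at each atom; aromatic (order 4) counts 1.5.
#' @keywords internal
bond_order_sums <- function(mol) {
  ord <- ifelse(mol$bonds$order == 4, 1.5, as.numeric(mol$bonds$order))
  v <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      v[mol$bonds$from[k]] <- v[mol$bonds$from[k]] + ord[k]
      v[mol$bonds$to[k]] <- v[mol$bonds$to[k]] + ord[k]
    }
  }
  v
}

# Implicit hydrogen count per atom from standard organic valences, adjusted by
# formal charge (protonated N gains a slot, deprotonated O loses one).
#' @keywords internal
implicit_h_counts <- function(mol) {
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
               F = 1, Cl = 1, Br = 1, I = 1, B = 3)
  v <- valence[mol$atoms$element]
  v <- ifelse(is.na(v), 0, v + mol$atoms$charge)
  pmax(0L, as.integer(floor(v - bond_order_sums(mol))))
}

# Indices of heavy-atom neighbours of each atom (list).
#' @keywords internal
heavy_neighbours <- function(mol) {
  nb <- vector("list", nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(ix) ix[mol$atoms$element[ix] != "H"])
}
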
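#' Standard atomic mass table
#' @param path Optional path to a CSV (`element,mass`) overriding the shipped
#'   IUPAC 2021 values.
#' @return Tibble with columns `element`, `mass`.
#' @export
atomic_masses <- function(path = NULL) {
  path <- path %||% extdata("atomic_masses.csv")
  readr::read_csv(path, col_types = readr::cols(element = "c", mass = "d"),
                  progress = FALSE)
}

#' Molecular weight (MW)
#'
#' Sum of standard atomic masses over explicit atoms plus implicit hydrogens
#' (inferred from standard valences where hydrogens are not explicit).
#'
#' @param mol A [molecule_record()].
#' @param masses Mass table, see [atomic_masses()].
#' @return Molecular weight in Dalton.
#' @examples
#' molecular_weight(generate_fixture_molecules()$benzene)  # 78.11
#' @export
molecular_weight <- function(mol, masses = atomic_masses()) {
  stopifnot(inherits(mol, "molecule_record"))
  m <- setNames(masses$mass, masses$element)[mol$atoms$element]
  if (anyNA(m)) {
    abort(paste0("unknown element(s): ",
                 paste(unique(mol$atoms$element[is.na(m)]), collapse = ", ")))
  }
  h_mass <- masses$mass[masses$element == "H"]
  sum(m) + sum(implicit_h_counts(mol)) * h_mass
}

#' Hydrogen-bond pattern set
#'
#' The structural rules used by [count_hba()] and [count_hbd()]. They are
#' deliberately simple, explicit and editable: acceptors are nitrogen and
#' oxygen atoms; donors are nitrogen/oxygen atoms bearing at least one
#' (explicit or implicit) hydrogen, counted per heavy atom (so water
#' contributes one donor, not two).
#'
#' @param acceptor_elements Elements counted as acceptors.
#' @param donor_elements Elements whose H-bearing atoms count as donors.
#' @return A list with the two element sets.
#' @export
hbond_patterns <- function(acceptor_elements = c("N", "O"),
                           donor_elements = c("N", "O")) {
  list(acceptor_elements = acceptor_elements,
       donor_elements = donor_elements)
}

#' Count hydrogen-bond acceptors (HBA)
#' @param mol A [molecule_record()].
#' @param patterns Pattern set from [hbond_patterns()].
#' @return Non-negative integer.
#' @export
count_hba <- function(mol, patterns = hbond_patterns()) {
  stopifnot(inherits(mol, "molecule_record"))
  sum(mol$atoms$element %in% patterns$acceptor_elements)
}

#' Count hydrogen-bond donors (HBD)
#'
#' Heavy-atom donor convention: each N/O atom with at least one attached
#' hydrogen counts once, however many hydrogens it bears.
#' @inheritParams count_hba
#' @return Non-negative integer.
#' @export
count_hbd <- function(mol, patterns = hbond_patterns()) {
  stopifnot(inherits(mol, "molecule_record"))
  el <- mol$atoms$element
  cand <- which(el %in% patterns$donor_elements)
  if (length(cand) == 0) return(0L)
  expl_h <- integer(nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    if (el[i] == "H") expl_h[j] <- expl_h[j] + 1L
    if (el[j] == "H") expl_h[i] <- expl_h[i] + 1L
  }
  h <- expl_h + implicit_h_counts(mol)
  sum(h[cand] > 0)
}

#' Count rotatable bonds (NRB)
#'
#' A bond is rotatable when it is a single bond between two heavy atoms, not
#' in a ring, both ends carry at least one further heavy-atom neighbour (i.e.
#' the bond is non-terminal), and it is not an amide C-N bond (the default,
#' configurable exclusion).
#'
#' @param mol A [molecule_record()].
#' @param exclude_amide Exclude amide C-N bonds?
#' @return Non-negative integer.
#' @export
count_rotatable_bonds <- function(mol, exclude_amide = TRUE) {
  stopifnot(inherits(mol, "molecule_record"))
  if (nrow(mol$bonds) == 0) return(0L)
  el <- mol$atoms$element
  g <- igraph::graph_from_data_frame(
    mol$bonds[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
  br <- igraph::bridges(g)
  bridge_idx <- as.integer(br)  # edge indices, in bond-list order
  in_ring <- !(seq_len(nrow(mol$bonds)) %in% bridge_idx)
  hn <- heavy_neighbours(mol)
  n_rot <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    if (mol$bonds$order[k] != 1) next
    if (in_ring[k]) next
    if (el[i] == "H" || el[j] == "H") next
    if (length(setdiff(hn[[i]], j)) == 0 || length(setdiff(hn[[j]], i)) == 0) next
    if (exclude_amide && is_amide_cn(mol, i, j)) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

# amide C-N: one end is N, the other a C with a double bond to O
#' @keywords internal
is_amide_cn <- function(mol, i, j) {
  el <- mol$atoms$element
  pair <- c(i, j)
  c_at <- pair[el[pair] == "C"]; n_at <- pair[el[pair] == "N"]
  if (length(c_at) != 1 || length(n_at) != 1) return(FALSE)
  b <- mol$bonds
  any((b$from == c_at | b$to == c_at) & b$order == 2 &
        el[ifelse(b$from == c_at, b$to, b$from)] == "O")
}

#' Globularity (Glob)
#'
#' `Glob = 4 * pi * r^2 / S_mol`, where `r` is the radius of the sphere whose
#' volume equals the molecular volume. Equals 1 for a perfect sphere and
#' decreases for elongated shapes; for 95% of known drugs it lies in
#' 0.75-0.95.
#'
#' @param v_mol Molecular volume (cubic Angstrom).
#' @param s_mol Surface area (square Angstrom).
#' @return Dimensionless globularity.
#' @examples
#' globularity(4 / 3 * pi * 2^3, 4 * pi * 2^2)  # 1
#' @export
globularity <- function(v_mol, s_mol) {
  if (any(!is.finite(v_mol)) || any(!is.finite(s_mol)) ||
      any(v_mol <= 0) || any(s_mol <= 0)) {
    abort("globularity requires positive finite v_mol and s_mol")
  }
  r <- (3 * v_mol / (4 * pi))^(1 / 3)
  4 * pi * r^2 / s_mol
}

#' Cohesion interaction index (Ind_coh)
#'
#' `Ind_coh = HBA * HBD / S_mol`, an index of hydrogen-bond-driven cohesion in
#' solids; 0.0-0.05 for 95% of known drugs.
#'
#' @param hba,hbd Hydrogen-bond acceptor/donor counts.
#' @param s_mol Solvent-accessible surface area (square Angstrom).
#' @return Dimensionless index.
#' @export
cohesion_index <- function(hba, hbd, s_mol) {
  if (any(!is.finite(s_mol)) || any(s_mol <= 0)) {
    abort("cohesion_index requires positive finite s_mol")
  }
  hba * hbd / s_mol
}

# --- pluggable logP backends -------------------------------------------------

.logp_backends <- new.env(parent = emptyenv())

#' Register a logP estimation backend
#'
#' The octanol/water partition model used upstream is proprietary, so logP is
#' a pluggable interface. Two backends ship: `"zero"` (testing stub, always
#' 0) and `"atomic"`, a transparent per-element contribution sum whose
#' parameter table is an editable CSV (see [logp_atom_contributions()]).
#'
#' @param name Backend identifier.
#' @param fun Function `(mol) -> numeric(1)`.
#' @return `name`, invisibly.
#' @export
register_logp_backend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .logp_backends)
  invisible(name)
}

#' Per-element logP contribution table
#' @param path Optional CSV (`element,contribution`) overriding the shipped
#'   table.
#' @return Tibble with columns `element`, `contribution`.
#' @export
logp_atom_contributions <- function(path = NULL) {
  path <- path %||% extdata("logp_atom_contributions.csv")
  readr::read_csv(path, col_types = readr::cols(element = "c",
                                                contribution = "d"),
                  progress = FALSE)
}

#' Estimate logP through a registered backend
#' @param mol A [molecule_record()].
#' @param backend Backend identifier (default `"atomic"`).
#' @return Estimated logP (deterministic for fixed backend and input).
#' @export
estimate_logp <- function(mol, backend = "atomic") {
  if (!exists(backend, envir = .logp_backends, inherits = FALSE)) {
    abort(paste0("unregistered logP backend: ", backend,
                 " (registered: ",
                 paste(ls(.logp_backends), collapse = ", "), ")"))
  }
  get(backend, envir = .logp_backends)(mol)
}

#' @keywords internal
logp_atomic_backend <- function(mol) {
  tab <- logp_atom_contributions()
  contrib <- setNames(tab$contribution, tab$element)
  cc <- contrib[mol$atoms$element]
  if (anyNA(cc)) {
    abort(paste0("no logP contribution for element(s): ",
                 paste(unique(mol$atoms$element[is.na(cc)]), collapse = ", ")))
  }
  sum(cc) + sum(implicit_h_counts(mol)) * contrib[["H"]]
}

# registered at load time
.onLoad <- function(libname, pkgname) {
  register_logp_backend("zero", function(mol) 0)
  register_logp_backend("atomic", logp_atomic_backend)
}

#' Compute the formula-defined descriptor block for a set of molecules
#'
#' Runs the full computed-descriptor pipeline (MW, HBA, HBD, NRB, S_mol,
#' S_mol_hfob, V_mol, Glob, Ind_coh, logP) over a list of molecule records and
#' returns a profiles tibble with provenance `"computed"`. Molecules without
#' 3D coordinates get `NA` for the geometry descriptors with a warning.
#'
#' @param mols List of [molecule_record()] objects.
#' @param params [surface_params()].
#' @param radii [bondi_radii()] table.
#' @param logp_backend Backend name for [estimate_logp()].
#' @return Profiles tibble (one row per molecule).
#' @export
compute_descriptors <- function(mols, params = surface_params(),
                                radii = bondi_radii(),
                                logp_backend = "atomic") {
  if (inherits(mols, "molecule_record")) mols <- list(mols)
  rows <- map(mols, function(m) {
    geo <- if (has_coords(m)) {
      s <- sasa_total(m, params, radii)
      v <- molecular_volume(m, params, radii)
      list(S_mol = s,
           S_mol_hfob = sasa_hydrophobic(m, params, radii),
           V_mol = v,
           Glob = globularity(v, s))
    } else {
      warn(paste0("molecule '", m$id, "' has no 3D coordinates; ",
                  "geometry descriptors set to NA"))
      list(S_mol = NA_real_, S_mol_hfob = NA_real_, V_mol = NA_real_,
           Glob = NA_real_)
    }
    hba <- count_hba(m); hbd <- count_hbd(m)
    tibble(id = m$id, MW = molecular_weight(m),
           logP = estimate_logp(m, logp_backend),
           HBA = hba, HBD = hbd,
           NRB = count_rotatable_bonds(m),
           S_mol = geo$S_mol, S_mol_hfob = geo$S_mol_hfob,
           V_mol = geo$V_mol, Glob = geo$Glob,
           Ind_coh = if (is.na(geo$S_mol)) NA_real_ else
             cohesion_index(hba, hbd, geo$S_mol))
  })
  prof <- bind_rows(rows)
  desc <- setdiff(names(prof), "id")
  set_provenance(prof, setNames(rep("computed", length(desc)), desc))
}
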
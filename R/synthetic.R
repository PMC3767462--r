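#' Default marginal distributions for synthetic libraries
#'
#' One marginal per descriptor, centred on the mean values reported for a
#' large natural-product screening library (n = 1,859 compounds from
#' medicinal plants): MW 426.70 Da, logP 4.18, HBA 5.85, HBD 2.39, NRB 5.31,
#' and so on. Spreads are not reported at the library level and are set once
#' to field-plausible values (see the methods vignette). Count-type
#' descriptors are discretised truncated normals.
#'
#' @return Named list of marginal specifications; each is a list with
#'   `dist` (`"normal"` or `"lognormal"`), `mean`, `sd` (log-scale for
#'   lognormal), optional truncation `lower`/`upper`, and `integer`.
#' @export
default_marginals <- function() {
  m <- function(mean, sd, lower = -Inf, upper = Inf, integer = FALSE,
                dist = "normal") {
    list(dist = dist, mean = mean, sd = sd, lower = lower, upper = upper,
         integer = integer)
  }
  list(
    MW = m(426.70, 150, lower = 50),
    logP = m(4.18, 2.0),
    HBA = m(5.85, 2.5, lower = 0, integer = TRUE),
    HBD = m(2.39, 1.5, lower = 0, integer = TRUE),
    NRB = m(5.31, 3.0, lower = 0, integer = TRUE),
    logBB = m(-1.30, 1.0),
    Caco2 = m(1199.37, 900, lower = 0),
    S_mol = m(696.28, 180, lower = 1),
    S_mol_hfob = m(409.24, 160, lower = 0),
    V_mol = m(1304.41, 350, lower = 1),
    logS_wat = m(-5.11, 2.0),
    logK_HSA = m(0.46, 0.7),
    MDCK = m(661.25, 500, lower = 0),
    Ind_coh = m(0.013, 0.010, lower = 0),
    Glob = m(0.84, 0.06, lower = 0.3, upper = 1),
    QP_polrz = m(42.47, 12, lower = 1),
    logHERG = m(-4.64, 1.2),
    logK_p = m(-2.96, 1.5),
    n_metab = m(5.56, 2.5, lower = 0, integer = TRUE),
    pct_HOA = m(74, 25, lower = 0, upper = 100),
    CNS = m(-1, 1, lower = -2, upper = 2, integer = TRUE)
  )
}

#' Configuration for the synthetic library generator
#'
#' @param n Library size (> 0).
#' @param seed Integer seed; the generator is fully reproducible under a
#'   fixed seed (Mersenne-Twister stream).
#' @param marginals Named list of marginal specs, see [default_marginals()].
#' @param correlations Optional correlation matrix (symmetric positive
#'   semi-definite, dimnames a subset of the marginal names); imposed through
#'   a Gaussian copula. Planted quotas override sampled values and so
#'   attenuate the realised correlation for planted descriptors.
#' @param planted_compliance Optional named vector of target in-range
#'   fractions, e.g. `c(logS_wat = 0.7)`: exactly `round(0.7 * n)` compounds
#'   get an in-range value, by deterministic quota assignment followed by
#'   within-region sampling.
#' @param planted_stars0_fraction Optional target fraction of compounds with
#'   zero panel violations; the remaining compounds are guaranteed at least
#'   one violation.
#' @param panel Range panel defining "in range" for planting.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 1834, seed = 1L,
                             marginals = default_marginals(),
                             correlations = NULL,
                             planted_compliance = NULL,
                             planted_stars0_fraction = NULL,
                             panel = drugs95_panel()) {
  if (length(n) != 1 || is.na(n) || n < 1) abort("n must be a positive count")
  if (!is.list(marginals) || is.null(names(marginals))) {
    abort("marginals must be a named list")
  }
  if (!is.null(planted_compliance)) {
    if (is.null(names(planted_compliance)) ||
        any(planted_compliance < 0 | planted_compliance > 1)) {
      abort("planted_compliance must be a named vector of fractions in [0, 1]")
    }
    unknown <- setdiff(names(planted_compliance), names(marginals))
    if (length(unknown) > 0) {
      abort(paste0("planted_compliance for descriptors without marginals: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(planted_stars0_fraction) &&
      (planted_stars0_fraction < 0 || planted_stars0_fraction > 1)) {
    abort("planted_stars0_fraction must lie in [0, 1]")
  }
  if (!is.null(correlations)) {
    if (!isSymmetric(unname(correlations))) {
      abort("correlations must be symmetric")
    }
    if (min(eigen(correlations, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8) {
      abort("correlations must be positive semi-definite")
    }
    if (is.null(dimnames(correlations)) ||
        !all(rownames(correlations) %in% names(marginals))) {
      abort("correlations dimnames must name a subset of the marginals")
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 marginals = marginals, correlations = correlations,
                 planted_compliance = planted_compliance,
                 planted_stars0_fraction = planted_stars0_fraction,
                 panel = validate_panel(panel)),
            class = "synthetic_config")
}

# quantile of a truncated marginal at uniform u; bounds [lo, hi] are
# intersected with the marginal's own support
#' @keywords internal
q_marginal <- function(u, spec, lo = -Inf, hi = Inf) {
  L <- max(spec$lower %||% -Inf, lo)
  U <- min(spec$upper %||% Inf, hi)
  if (spec$dist == "lognormal") {
    pa <- if (L <= 0) 0 else pnorm(log(L), spec$mean, spec$sd)
    pb <- if (U <= 0) 0 else pnorm(log(U), spec$mean, spec$sd)
    if (pb - pa < 1e-12) return(rep(NA_real_, length(u)))
    exp(qnorm(pa + u * (pb - pa), spec$mean, spec$sd))
  } else {
    pa <- pnorm(L, spec$mean, spec$sd)
    pb <- pnorm(U, spec$mean, spec$sd)
    if (pb - pa < 1e-12) return(rep(NA_real_, length(u)))
    qnorm(pa + u * (pb - pa), spec$mean, spec$sd)
  }
}

# probability mass of the marginal inside [lo, hi] (within its support)
#' @keywords internal
p_marginal_mass <- function(spec, lo, hi) {
  L <- max(spec$lower %||% -Inf, lo)
  U <- min(spec$upper %||% Inf, hi)
  if (L >= U) return(0)
  if (spec$dist == "lognormal") {
    pa <- if (L <= 0) 0 else pnorm(log(L), spec$mean, spec$sd)
    pb <- if (U <= 0) 0 else pnorm(log(U), spec$mean, spec$sd)
    pb - pa
  } else {
    pnorm(U, spec$mean, spec$sd) - pnorm(L, spec$mean, spec$sd)
  }
}

#' Generate a synthetic compound library
#'
#' Draws per-compound descriptor vectors from the configured marginals
#' (optionally correlated through a Gaussian copula). Planted compliance
#' fractions are achieved exactly by construction: quota labels are assigned
#' first, then each value is sampled from its marginal conditioned on the
#' assigned region, so the compliance module recovers the configured
#' fractions without sampling error. When a target stars-zero fraction is
#' planted, every star descriptor with a marginal is constrained: quota
#' compounds are sampled in range throughout, the rest receive at least one
#' out-of-range value (on a descriptor without its own planted fraction).
#'
#' @param config A [synthetic_config()].
#' @return Profiles tibble with ids `syn_000001`, ...; reproducible for a
#'   fixed seed.
#' @examples
#' cfg <- synthetic_config(n = 50, seed = 42,
#'                         planted_compliance = c(logS_wat = 0.7))
#' prof <- generate_profiles(cfg)
#' percent_compliance(prof, "logS_wat")$percent  # exactly 70
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  D <- names(config$marginals)
  set.seed(config$seed, kind = "Mersenne-Twister")

  # base uniforms (copula for the correlated block)
  U <- matrix(runif(n * length(D)), nrow = n, dimnames = list(NULL, D))
  if (!is.null(config$correlations)) {
    cd <- rownames(config$correlations)
    Z <- matrix(rnorm(n * length(cd)), nrow = n) %*%
      chol(config$correlations + diag(1e-10, length(cd)))
    U[, cd] <- pnorm(Z)
  }
  side_u <- matrix(runif(n * length(D)), nrow = n, dimnames = list(NULL, D))

  panel <- config$panel
  range_of <- function(d) {
    k <- match(d, panel$descriptor)
    if (is.na(k)) NULL else c(panel$lower[k], panel$upper[k])
  }
  star_desc <- intersect(D, panel$descriptor[panel$star])
  planted <- config$planted_compliance %||% setNames(numeric(0), character(0))
  for (d in names(planted)) {
    if (is.null(range_of(d))) {
      abort(paste0("cannot plant compliance for '", d,
                   "': no range in panel"))
    }
  }

  # region labels: NA = unconstrained, TRUE = in range, FALSE = out of range
  region <- matrix(NA, nrow = n, ncol = length(D), dimnames = list(NULL, D))
  f0 <- config$planted_stars0_fraction
  if (!is.null(f0)) {
    n0 <- round(f0 * n)
    stars0_idx <- sample.int(n, n0)
    others <- setdiff(seq_len(n), stars0_idx)
    region[, star_desc] <- TRUE
    out_idx <- list()
    for (d in intersect(names(planted), star_desc)) {
      q <- round((1 - planted[[d]]) * n)
      if (q > length(others)) {
        abort(sprintf(
          "infeasible planting: %d out-of-range '%s' needed but only %d compounds may violate",
          q, d, length(others)))
      }
      out_idx[[d]] <- if (q > 0) sample(others, q) else integer(0)
    }
    uncovered <- setdiff(others, unlist(out_idx))
    if (length(uncovered) > 0) {
      filler <- setdiff(star_desc, names(planted))[1]
      if (is.na(filler)) {
        abort("infeasible planting: no unplanted star descriptor left to absorb required violations")
      }
      out_idx[[filler]] <- c(out_idx[[filler]], uncovered)
    }
    for (d in names(out_idx)) region[out_idx[[d]], d] <- FALSE
    # planted fractions on non-star descriptors handled below
    planted_rest <- planted[setdiff(names(planted), star_desc)]
  } else {
    planted_rest <- planted
  }
  for (d in names(planted_rest)) {
    q <- round((1 - planted_rest[[d]]) * n)
    region[, d] <- TRUE
    if (q > 0) region[sample.int(n, q), d] <- FALSE
  }

  vals <- matrix(NA_real_, nrow = n, ncol = length(D),
                 dimnames = list(NULL, D))
  for (d in D) {
    spec <- config$marginals[[d]]
    rg <- range_of(d)
    lab <- region[, d]
    free <- is.na(lab)
    if (any(free)) vals[free, d] <- q_marginal(U[free, d], spec)
    if (any(!free)) {
      lo <- rg[1]; hi <- rg[2]
      pad <- if (isTRUE(spec$integer)) 0.5 else 1e-9 * max(1, abs(lo), abs(hi))
      inn <- which(lab %in% TRUE)
      if (length(inn) > 0) {
        v <- q_marginal(U[inn, d], spec, lo, hi)
        if (anyNA(v)) {
          abort(paste0("infeasible planting: marginal of '", d,
                       "' has no mass inside its range"))
        }
        vals[inn, d] <- v
      }
      out <- which(lab %in% FALSE)
      if (length(out) > 0) {
        m_left <- p_marginal_mass(spec, -Inf, lo - pad)
        m_right <- p_marginal_mass(spec, hi + pad, Inf)
        if (m_left + m_right < 1e-12) {
          abort(paste0("infeasible planting: marginal of '", d,
                       "' has no mass outside its range"))
        }
        left <- side_u[out, d] < m_left / (m_left + m_right)
        if (any(left)) {
          vals[out[left], d] <- q_marginal(U[out[left], d], spec, -Inf, lo - pad)
        }
        if (any(!left)) {
          vals[out[!left], d] <- q_marginal(U[out[!left], d], spec, hi + pad, Inf)
        }
      }
    }
    if (isTRUE(spec$integer)) vals[, d] <- round(vals[, d])
  }

  prof <- bind_cols(tibble(id = sprintf("syn_%06d", seq_len(n))),
                    tibble::as_tibble(vals))
  set_provenance(prof, setNames(rep("simulated", length(D)), D))
}

#' Hand-coded fixture molecules with exact geometry
#'
#' Small structures used throughout the test suite: single atoms (H, C, O), a
#' far-separated carbon pair (additivity checks), an overlapping carbon dimer
#' at exactly 1.5 Angstrom (closed-form union oracles), methane, water,
#' ethanol and benzene.
#'
#' @return Named list of [molecule_record()] objects.
#' @examples
#' names(generate_fixture_molecules())
#' @export
generate_fixture_molecules <- function() {
  at <- function(element, x, y, z, charge = 0L) {
    tibble(element = element, x = x, y = y, z = z, charge = charge)
  }
  bd <- function(from, to, order = 1L) tibble(from = from, to = to, order = order)
  a <- 1.09 / sqrt(3)
  methane <- molecule_record("methane",
    atoms = at(c("C", "H", "H", "H", "H"),
               c(0, a, a, -a, -a), c(0, a, -a, a, -a), c(0, a, -a, -a, a)),
    bonds = bd(rep(1L, 4), 2:5))
  water <- molecule_record("water",
    atoms = at(c("O", "H", "H"),
               c(0, 0.9572, -0.2400), c(0, 0, 0.9266), c(0, 0, 0)),
    bonds = bd(c(1L, 1L), c(2L, 3L)))
  ethanol <- molecule_record("ethanol",
    atoms = at(c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
               x = c(0, 1.54, 2.02, -0.51, -0.51, -0.51, 1.95, 1.95, 2.98),
               y = c(0, 0, 1.35, 0.89, -0.80, -0.09, -0.52, -0.52, 1.35),
               z = c(0, 0, 0, 0.36, 0.53, -0.94, 0.82, -0.82, 0)),
    bonds = bd(c(1L, 2L, 1L, 1L, 1L, 2L, 2L, 3L),
               c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L)))
  ang <- (0:5) * pi / 3
  benzene <- molecule_record("benzene",
    atoms = at(c(rep("C", 6), rep("H", 6)),
               x = c(1.397 * cos(ang), 2.481 * cos(ang)),
               y = c(1.397 * sin(ang), 2.481 * sin(ang)),
               z = rep(0, 12)),
    bonds = bd(c(1:6, 1:6),
               c(2:6, 1L, 7:12),
               order = c(rep(c(1L, 2L), 3), rep(1L, 6))))
  list(
    atom_H = molecule_record("atom_H", at("H", 0, 0, 0)),
    atom_C = molecule_record("atom_C", at("C", 0, 0, 0)),
    atom_O = molecule_record("atom_O", at("O", 0, 0, 0)),
    cc_far = molecule_record("cc_far", at(c("C", "C"), c(0, 100), c(0, 0), c(0, 0))),
    cc_dimer = molecule_record("cc_dimer",
                               at(c("C", "C"), c(0, 1.5), c(0, 0), c(0, 0)),
                               bonds = bd(1L, 2L)),
    methane = methane, water = water, ethanol = ethanol, benzene = benzene
  )
}
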
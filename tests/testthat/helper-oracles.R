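# Independent oracles and random-case generators shared across tests.

# Closed-form surface area of a union of two spheres with radii r1, r2 at
# centre distance d (overlapping, neither engulfed): each sphere loses one
# spherical cap.
two_sphere_union_area <- function(r1, r2, d) {
  stopifnot(d < r1 + r2, d > abs(r1 - r2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)  # distance centre1 -> plane of circle
  h1 <- r1 - x1
  h2 <- r2 - (d - x1)
  (4 * pi * r1^2 - 2 * pi * r1 * h1) + (4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# Closed-form volume of the union of two spheres (inclusion-exclusion with
# the lens volume from the two spherical caps).
two_sphere_union_volume <- function(r1, r2, d) {
  stopifnot(d < r1 + r2, d > abs(r1 - r2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  h2 <- r2 - (d - x1)
  cap <- function(r, h) pi * h^2 * (3 * r - h) / 3
  4 / 3 * pi * (r1^3 + r2^3) - (cap(r1, h1) + cap(r2, h2))
}

# Naive per-descriptor stars count, independent of evaluate_compliance()'s
# vectorised path: plain loops and if/else.
oracle_stars <- function(profiles, panel) {
  out <- integer(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    s <- 0L
    for (k in seq_len(nrow(panel))) {
      if (!isTRUE(panel$star[k])) next
      d <- panel$descriptor[k]
      if (!d %in% names(profiles)) next
      v <- profiles[[d]][i]
      if (is.na(v)) next
      if (v < panel$lower[k]) s <- s + 1L
      else if (v > panel$upper[k]) s <- s + 1L
    }
    out[i] <- s
  }
  out
}

# Random profiles over the default panel descriptors, spread wide enough to
# fall on both sides of every range.
random_profiles <- function(n, seed, descriptors = NULL) {
  panel <- drugs95_panel()
  descriptors <- descriptors %||% panel$descriptor
  set.seed(seed)
  cols <- lapply(descriptors, function(d) {
    k <- match(d, panel$descriptor)
    lo <- panel$lower[k]; hi <- panel$upper[k]
    if (!is.finite(lo)) lo <- hi - 10
    if (!is.finite(hi)) hi <- lo + 10
    w <- hi - lo
    runif(n, lo - w, hi + w)
  })
  names(cols) <- descriptors
  dplyr::bind_cols(tibble::tibble(id = sprintf("r%04d", seq_len(n))),
                   tibble::as_tibble(cols))
}

# Random panel over registered descriptors with random closed bounds and a
# random star subset.
random_panel <- function(seed, n_desc = 8) {
  base <- drugs95_panel()
  set.seed(seed)
  pick <- sample(base$descriptor, n_desc)
  lo <- runif(n_desc, -5, 5)
  tibble::tibble(descriptor = pick, lower = lo,
                 upper = lo + runif(n_desc, 0.5, 10),
                 star = sample(c(TRUE, FALSE), n_desc, replace = TRUE,
                               prob = c(0.8, 0.2)),
                 note = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A mid-range profile: every panel descriptor at the midpoint of its range
# (finite midpoint required; one-sided ranges use a point just inside).
midrange_profile <- function(panel = drugs95_panel(), id = "mid") {
  v <- mapply(function(lo, hi) {
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else if (is.finite(lo)) lo + 1 else hi - 1
  }, panel$lower, panel$upper)
  out <- tibble::as_tibble(as.list(stats::setNames(v, panel$descriptor)))
  dplyr::bind_cols(tibble::tibble(id = id), out)
}
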
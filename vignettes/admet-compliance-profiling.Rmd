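---
title: "DMPK compliance profiling: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DMPK compliance profiling: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`admetscreen` profiles compound libraries against the property space of
known drugs. This vignette is the package's account of the science: what is
modelled, which knobs matter, what the synthetic generator does and does not
emulate, and where genuinely open design choices were decided.

## The compliance model

Every compound is reduced to a vector of canonical descriptors (the
registry in `descriptor_registry()` fixes names and units). Descriptors
come from two sources with recorded provenance:

* **computed** — formula-defined quantities the package derives from 3D
  structures: MW, HBA, HBD, NRB, S~mol~, S~mol,hfob~, V~mol~, Glob,
  Ind~coh~, and a pluggable logP;
* **imported** — QSPR-model predictions (aqueous solubility, blood/brain
  partitioning, Caco-2 and MDCK permeabilities, HSA binding, HERG IC~50~,
  skin permeability, metabolic-reaction count, oral absorption) whose
  upstream models are proprietary. They enter through descriptor tables and
  are treated as data, never recomputed.

Compliance is evaluated against a panel of closed intervals — the ranges
that cover 95 % of known drugs. A value strictly below the lower or above
the upper bound is a violation; the per-compound violation count is the
`stars` statistic, and `stars = 0` marks a fully compliant compound.
Missing values are a distinct third state: under the default `skip` policy
they are excluded from both the numerator and denominator of any rate, so
"unknown" is never conflated with "out of range". This is why the importer
refuses to impute and the profile tables keep `NA`.

### Panel choices

Two details of the shipped `drugs95` panel are deliberate decisions rather
than transcription:

1. **Panel membership.** The full upstream compliance score draws on 24
   descriptors, but only 14 ranges are printed alongside the descriptor
   definitions, and the descriptor tables add MW, logP, HBA, HBD and NRB.
   The shipped panel therefore carries those 19, using the standard
   95 %-of-drugs ranges for the latter five (MW 130–725, logP −2–6.5,
   HBA 2–20, HBD 0–6, NRB 0–15). Membership is data (`star` column), so a
   different approximation is one CSV edit away.
2. **Band encodings.** One-sided guidance is encoded as half-open
   intervals: HERG concern below −5 becomes [−5, ∞). The printed
   permeability guidance is qualitative ("<25 poor, >500 great" for MDCK);
   both MDCK and Caco-2 default to the recommended [25, 500] nm/s band,
   configurable per panel file.

Where the source material prints two variants of the same range
(logK~HSA~ upper 1.2 vs 1.5; logBB upper 1.0 vs 1.2; metabolic reactions
0–15 vs 1–8), both ship (`drugs95_panel("methods")` and
`drugs95_panel("results")`) and neither is privileged: guessing intent
would silently change compliance rates.

Bounds are **closed** — a value exactly at a printed endpoint is
compliant. Printed ranges like "300 to 1,000" read as inclusive; the
boundary tests pin this behaviour.

## Geometry descriptors

S~mol~ is computed by Shrake–Rupley sampling: each atom's Bondi radius is
inflated by the probe radius (default 1.4 Å, a water molecule), the
inflated sphere is covered by a deterministic Fibonacci point lattice
(default 960 points), and a point contributes area iff it lies outside
every other inflated sphere. No randomness is involved by default; a seeded
random rotation (`jitter`) exists for sensitivity checks only.
S~mol,hfob~ sums the per-atom areas over a configurable hydrophobic set —
carbon, Cl/Br/I, and hydrogens bonded to carbon — because the upstream
definition of the "hydrophobic portion" is unpublished; an explicit,
editable set is the only auditable substitute.

V~mol~ integrates the union of inflated spheres on a uniform grid (cell
centres, default spacing 0.1 Å). The choice of a grid over analytic
inclusion–exclusion keeps arbitrary overlaps trivial to handle and the
error easy to state: against closed-form sphere and two-sphere-union
oracles the defaults land well inside 1 % (the acceptance script prints the
achieved errors, about 0.3–0.4 % for volumes and ≤ 0.1 % for areas).
Doubling `sphere_points` moves fixture SASA by < 0.5 %, the convergence
criterion used in the tests.

Glob and Ind~coh~ are exact arithmetic on those quantities, and both
reject non-positive inputs rather than return nonsense. Hydrogens are
explicit members of the surface and volume (and are generated implicitly
from standard valences when a structure omits them); whether the upstream
implementation includes them is unknown, so the choice is documented here
and fixed.

HBA/HBD use a deliberately simple, shipped pattern set: acceptors are N
and O atoms; donors are N/O atoms bearing ≥ 1 hydrogen, counted per heavy
atom (water: one donor). The upstream counting rules are undisclosed;
transparency beats mimicry, and the sets are configuration. NRB counts
single, acyclic (non-bridge, via graph bridge detection), non-terminal
heavy-atom bonds, excluding amide C–N by default. logP is a pluggable
backend (`register_logp_backend()`); the shipped `atomic` backend is a
per-element contribution sum with an editable parameter table — crude, but
deterministic and fully auditable, which is what the test oracles need.

## Filters and pharmacokinetic rules

The subset definitions and the Rule of Three are transcribed with their
exact strictness (MW = 500 fails drug-like; logS~wat~ = −5.7 fails its ro3
clause). The printed bounds make lead-like and fragment-like proper subsets
of drug-like; the test suite checks the implication on random profiles
rather than assuming it. "Number of primary metabolites" is mapped to the
`n_metab` descriptor — the only metabolism count in the data model — and
ro3 "compliance" is the full conjunction, with `criteria_met` (0–3)
reported for all-or-some analyses.

Similarity-adjusted prediction returns the model value below similarity
0.9 and the blend `S·P_exp + (1−S)·P_QP` above it: constant below the
threshold, linear to the experimental value at S = 1. The similarity space
is pluggable (default: Tanimoto over a hashed substructure fingerprint)
because the upstream property space is undisclosed, and no training set
ships. The transdermal rate `Jm = 10^logKp × MW × 10^logSwat` is reported
on the µg cm⁻² h⁻¹ scale under the natural unit reading (K~p~ in cm/h,
S~wat~ in mol/L, MW in g/mol) with an identity scale constant exposed in
case a different unit convention is needed; the Jm > 100 flag and the
CNS > 1 flag are strict comparisons. Oral-absorption binning has no
published edges; the defaults (< 25 low, 25–80 medium, > 80 high) are an
explicit assumption.

## The synthetic generator

`generate_profiles()` emulates a descriptor table, not chemistry: each
descriptor is drawn from a configurable marginal (normal or lognormal,
optionally truncated; counts discretised), optionally correlated through a
Gaussian copula. Default marginal means are the published averages of a
1,859-compound medicinal-plant library (MW 426.70 Da, logP 4.18, HBA 5.85,
HBD 2.39, NRB 5.31, …); spreads are not published at the library level and
were chosen once as field-plausible values (e.g. MW sd 150 Da, logP sd 2
— typical natural-product breadth) and not revisited.

Planted fractions are achieved **by construction**: in/out labels are
assigned as exact quotas first, then each value is sampled from its
marginal truncated to the assigned region (integer descriptors use a ±0.5
guard so rounding cannot cross a range edge). When a stars-zero fraction is
planted, every star descriptor is constrained — quota compounds in range
throughout, each remaining compound given at least one violation on a
descriptor without its own planted target — so the compliance module
recovers the configured fractions with zero sampling error. Infeasible
requests (a marginal with no mass outside its range, more violators than
non-quota compounds) fail loudly instead of drifting.

What passing tests therefore show is that the *analysis machinery* is
exact: scoring, counting, classification and reporting reproduce known
ground truth. What they do not show is anything about real chemistry: the
generator's independent marginals carry none of the strong correlations of
real libraries (size, surface and volume co-vary; solubility anti-varies
with lipophilicity). One visible consequence: with ~19 independent
descriptors the probability of zero violations is a product of per-range
probabilities, so an unplanted default library shows a stars = 0 fraction
below 1 %, whereas real libraries sit near 50 % — reproducing such rates
requires either planting or a realistic correlation structure supplied by
the user.

## Numerical and interface choices

* Profile tables are plain tibbles (wide, `id` + canonical columns);
  everything composes with dplyr, and results ship `tidy()`/`glance()`
  methods and ggplot builders.
* Percentages are reported at two decimals (matching the conventional
  presentation of compliance tables); raw fractions are retained.
* Histograms are left-closed with lower-edge labels: a value exactly on an
  edge opens its bin.
* Reports are byte-deterministic for fixed input, per format.
* The RNG is R's Mersenne-Twister, seeded explicitly everywhere; the CLI
  seeds every stage from its flags/config and identical configuration gives
  byte-identical outputs.
* Problem sizes used by the test suite and acceptance script — 200
  profiles for the scoring oracle, 10,000 for filter logic, 1,000 for the
  planted pipeline run, 10,000 for mean-recovery — were chosen as the
  smallest sizes at which the checks are sharp (exact quotas need no
  asymptotics; the mean-recovery check uses a 3-standard-error band).

## Known limitations

* Imported QSPR descriptors are taken at face value; the package provides
  no in-house solubility/permeability/toxicity models, only the pluggable
  hooks.
* The HBA/HBD/NRB/logP rules are intentionally minimal; they will not match
  any particular commercial implementation compound-for-compound.
* SDF input is trusted as-is: no protonation, salt stripping, conformer
  search or minimisation (upstream structure preparation is out of scope).
* Molecules parsed from SMILES carry 2D layout coordinates; the geometry
  descriptors refuse them only when coordinates are wholly absent, so
  surface areas computed from 2D layouts are meaningful only as smoke
  tests.
* 25 of the 1,859 compounds in the motivating library had no computable
  descriptors upstream for unstated reasons; the importer tolerates
  descriptor-free records (all-`NA` rows under the skip policy) but cannot
  reproduce the cause.
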
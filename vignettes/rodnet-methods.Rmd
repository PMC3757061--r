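---
title: "Methods: cascade modelling and structure-network analytics in rodnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade modelling and structure-network analytics in rodnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodnet)
```

# Scope

`rodnet` couples two levels of description of G-protein signalling in
rod photoreceptors: a mass-action reaction-network model of the
phototransduction cascade, and structure-ensemble analytics that
quantify intramolecular communication in the proteins of that
cascade. This vignette records the modelling conventions and
numerical choices; the README shows worked examples.

# Reaction-network layer

## Representation and integration

A `reaction_network` holds species with initial amounts, irreversible
mass-action reactions (reversible inputs are split on load), a
parameter map, and optionally a symbolic photocurrent output and a
declaration of how many Gα subunits each species carries. Rates are
`k * prod(concentrations^stoichiometry)`; a reaction may instead
carry an arbitrary `rate_expr` evaluated in the species/parameter
environment (used for cGMP turnover). Integration uses
`deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-12`. Before a flash,
the network is relaxed to its dark steady state (default 2000 s,
convergence when the max absolute derivative falls below tolerance),
so the reported response is `dJ = J - J_dark` with
`J = J_dark * (cG / cG_dark)^3`.

SBML import/export covers mass-action kinetic laws; the writer adds a
small custom annotation carrying the output expression and the
Gα-unit declaration so that write/read round-trips are lossless. The
curated rod model (BioModels BIOMD0000000326) is an optional external
input; the built-in `gen_toy_cascade()` provides a 14-reaction
cascade whose constants are package choices tuned only for
plausible rod-like behaviour (dim-flash peak below 1 pA, recovery on
the 10 s scale, I₀ near 90 photons/µm²), plus a linear two-step
variant with a closed-form double-exponential solution used as an
integration oracle.

## Dark precoupling

`add_precoupling()` appends reversible R–Gt complex formation. Given
a target dark precoupled fraction *f* (default 0.20) and an
association constant `kon`, the dissociation constant is
reconstructed in a depletion-aware way,
`koff = kon * (R0 - f * Gt0) * (1 - f) / f`, so that the dark steady
state of the *closed* system precouples the requested fraction of
the transducin pool exactly, not just in the excess-R limit.

## Mutant grafting

`build_mutant()` introduces an explicit mutant Gα species. For every
species carrying `u` Gα units it creates the mixed-composition
variants with `0..u` mutant units (labelled `X_m`, or `X_m1`/`X_m2`
for two-unit complexes), duplicates each Gα-consuming reaction over
all reactant compositions, and scales the designated rate constants
(defaults: activation rates kP1, kP2 cut 35 000-fold, GAP-binding
kRGS1 halved) for mutant-containing channels. Zygosity sets the
initial composition: heterozygous = 25 % mutant at native total
expression; homozygous = 100 % mutant at 35 % expression. Crucially,
`rate_expr` reactions and the output expression are rewritten by
symbol substitution `X -> (X + X_m [+ X_m2])` so that pooled
concentrations (e.g. total activated effector in the cGMP turnover)
include mutant-containing complexes.

## Photoresponse features

`time_to_peak` and `peak_amplitude` are read from `|dJ|`;
`recovery_time` is the first time after the peak from which `|dJ|`
*stays* within 1 % of the peak to the end of the window (returns `NA`
with attributes if the window is too short). `normalize_family` peaks
over a flash family; `half_max_intensity` interpolates the normalized
sensitivity curve at 0.5 on a log-intensity grid, or fits a
hyperbolic saturation function when `method = "fit"`.

# Structure-ensemble layer

## Synthetic ensembles with planted truth

`gen_ensemble(ensemble_spec(...))` builds frames of labelled atoms:
Cα plus a configurable number of side-chain pseudo-atoms per residue,
optionally ligand nodes (GTP/Mg/water analogues). The reference Cα
trace is a coarse helix (never collinear, so superposition is
well-posed). On top of rigid-body noise per frame it plants

* isotropic Gaussian displacements of sd σ per coordinate
  (expected RMSF = σ√3),
* pairwise correlations via shared latent factors (exact target LMI),
* low-rank collective modes with known 3n-direction,
* side-chain contacts persistent in a chosen fraction of frames.

Contact plans may chain (their graph must be a union of simple
paths); contacting side chains are placed by a breadth-first oriented
construction so that in "on" frames every planned atom pair is within
the 4.5 Å cutoff and in "off" frames none is. Generator defaults are
the study conditions and are fixed; they were not adjusted to test
outcomes.

## Protein structure network

The interaction strength between residues *i*, *j* in one frame is
`I_ij = 100 * n_ij / sqrt(N_i * N_j)` with `n_ij` the number of
side-chain atom pairs within 4.5 Å and normalization factors
N: 100 for the synthetic residue type, 361.3 for GTP, 23.8 for Mg²⁺,
27.0 for water. Same-chain amino-acid pairs within ±3 sequence
positions are excluded. An edge enters the graph when present in at
least 30 % of frames (inclusive) with mean strength above the cutoff
I_min. `optimal_imin()` scans a 0.01 grid and returns the lowest cut
that halves the size of the *global* largest cluster relative to
I_min = 0 (warning and 0 if the graph is already edgeless). Hubs are
nodes with ≥ 4 links.

## Communication paths

Shortest paths are computed deterministically: breadth-first layers
give minimal hop count, dynamic programming maximizes the summed
interaction strength along minimal paths, lexicographic order breaks
remaining ties. Extremity pairs exclude same-chain sequence distance
≤ 5. A path is retained if some *internal* node has linear mutual
information ≥ 0.3 with either extremity; direct links are kept with
correlation score 1. Path frequency is the fraction of frames whose
recomputed path has the identical node sequence (≥ 30 %). The
meta-path keeps links appearing in ≥ 30 % of the maximal recurrence
`r(l) = 100 * paths-containing-l / total`; length-3 fragments are
counted direction-agnostically.

## Essential dynamics, FMA, SASA

Frames are superposed with `bio3d::fit.xyz` (fit to frame 1, refined
against the mean). PCA diagonalizes the 3n covariance; the essential
subspace truncates at 90 % cumulative variance; subspace similarity
is RMSIP over `D = min(n_modes)` modes. FMA regresses a scalar
observable on the first *n* PC projections with 5-fold
cross-validation and returns the maximally correlated mode as a unit
3n vector in PC span. SASA uses Shrake–Rupley quadrature (960
golden-spiral points, Bondi radii, probe 1.4 Å); the two-sphere
analytic cap and the isolated sphere serve as oracles.

# Known limitations

* Only mass-action (plus the explicit `rate_expr` escape hatch) rate
  laws are supported in SBML import.
* Chained synthetic contacts place side chains deterministically
  along one axis; they are geometric gadgets for testing the contact
  pipeline, not physical side-chain rotamers.
* The full-model analyses need the optional BioModels file described
  in the README; without it the package operates on the toy cascade.
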
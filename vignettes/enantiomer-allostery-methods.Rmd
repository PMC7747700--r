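---
title: "Methods: ensemble persistence, dynamical-network allostery, and assay models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble persistence, dynamical-network allostery, and assay models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the
methodology was genuinely open, and what validation on synthetic data does
and does not establish about real structural and assay data.

## The scientific setting

Two enantiomers of the same nuclear-receptor agonist can bind a ligand
binding domain (LBD) with similar affinity yet activate the receptor very
differently. Resolving why requires three kinds of evidence to be analysed
consistently: (i) crystallographic ensemble-refinement models, in which a
ligand-receptor interaction either holds or fails in each of a few dozen
coordinate models; (ii) molecular-dynamics trajectories, in which the same
interactions persist for some fraction of frames and in which correlated
residue motion carries allosteric signals from the ligand pocket to the
coactivator-binding activation function surface; and (iii) solution
assays: competition fluorescence-polarization (FP) binding and
differential scanning fluorimetry (DSF) thermal stability. `allonet`
implements the full analysis layer for all three tracks.

## Interaction criteria and persistence

A criterion is evaluated independently in every model of an `ensemble`
(crystallographic models and trajectory frames share the same container).
Persistence is the fraction of models in which it holds; reported percents
use half-up rounding (5/35 → 14%) with full precision retained internally.

* **Hydrogen bond** — heavy-atom donor–acceptor distance < 3.5 Å, strict
  inequality, no angular term. The distance-only rule matches how
  per-model hydroxyl contacts are typically read off ensemble models,
  where hydrogens are not modelled; the cutoff is an argument.
* **Edge-to-face π–π stacking** — the angle between ring planes must lie
  in [60°, 120°] and ring centroids within 5.5 Å. Planes are least-squares
  fits (SVD of the centred ring coordinates), which generalises cleanly to
  five-membered imidazole rings; the plane angle is reported raw in
  [0°, 180°). The sign of a fitted normal is arbitrary, so an angle θ and
  180° − θ are the same physical configuration; the symmetric window makes
  the acceptance decision independent of that ambiguity.
* **Water network** — the network size is the number of water oxygens in
  the connected component (links < 3.5 Å) reachable from polar anchor
  atoms, and the network is intact when it reaches the expected count
  (default four waters). "Intact" has no standard definition; the
  component rule was chosen because it captures water-mediated bridging
  (a displaced middle water disconnects everything beyond it), and a
  simpler count-within-radius rule is available via `rule = "radius"`.

## Synthetic ensembles: planted, not sampled

`make_interaction_ensemble()` places geometry so that a chosen number of
models satisfy each criterion *exactly*: criterion-defining atoms are
positioned after positional jitter is applied, at distances/angles drawn
from bands with safe margins on the correct side of each cutoff
(hydrogen-bond true models at 2.6-3.3 Å, false at ≥ 4.5 Å; stacking true
at 70-110° and ≤ 5.2 Å, false at ≤ 30° and 7 Å). Planted counts are
therefore constructions, not random outcomes, and the test suite verifies
them with an independently written geometry checker. The synthetic
receptor is deliberately minimal — a Cα helix with a thioether acceptor, a
hydroxyl anchor, one aromatic ring, a ligand with hydroxyl and ring, four
waters — because the interaction mathematics needs geometry, not
chemistry.

## Trajectories with a planted communication corridor

`make_correlated_trajectory()` draws frames as a deterministic mean
structure plus multivariate-normal displacements. The three coordinate
axes are sampled independently with the same residue-residue correlation
matrix, which makes the displacement-vector correlation
`C_ij = <Δr_i·Δr_j>/sqrt(<|Δr_i|²><|Δr_j|²>)` equal to the target matrix
in population.

Two structural choices deserve comment:

* **Corridor correlations are AR(1).** A flat correlation ρ_c on every
  consecutive pair of a chain is not a valid correlation structure (the
  matrix loses positive definiteness as the chain grows), so corridor
  members at separation s correlate as ρ_c^s. The target matrix is
  eigendecomposed and rejected before sampling if not positive definite.
* **The mean structure makes the corridor a contact path.** Residues sit
  on a tight helix (3.8 Å bond length); when a corridor with non-adjacent
  hops is requested, a deterministic stress minimisation moves
  corridor-consecutive pairs to ~4.0 Å (inside the 4.5 Å contact cutoff)
  while pushing all unrelated pairs beyond it. Recovery of the planted
  corridor by the network stage is therefore a geometric consequence of
  the construction, not a tuned coincidence.

Desk-scale defaults stand in for microsecond trajectories: 2000 frames
(5000 in convergence checks), 20-50 residues, 0.3 Å per-axis displacement.
These sizes keep the full validation suite and the acceptance script in
the minutes range on one CPU while leaving sampling error well inside the
tolerances being tested.

## Superposition, RMSF and the correlation estimator

Superposition is the Kabsch SVD solution with reflections excluded. RMSF
uses the conventional iterated-mean reference: fit all frames to the first
frame, form the mean, refit to the mean once, and measure fluctuations
about the refitted mean.

One estimator subtlety: superposing frames onto the mean removes six rigid
degrees of freedom. For real trajectories that is exactly what is wanted
(global tumbling is not internal motion). For synthetic frames that are
generated in a common lab frame with no global motion, the removed degrees
of freedom are partly *correlated internal signal* — with a strongly
correlated 6-residue corridor in a 20-residue chain, superposition biases
the corridor correlation from 0.90 to about 0.81. `correlation_matrix()`
therefore takes `superpose` (default `TRUE` for real data); recovery
validations use `superpose = FALSE` because the generator's frames share
the lab frame by construction. The network stage is insensitive to the
distinction here (the corridor remains the shortest route either way).

## The dynamical network

Nodes are Cα atoms, one per residue. An edge joins residues i, j when
their contact fraction — frames with closest heavy-atom distance < 4.5 Å —
is at least 0.75, and the edge length is `w_ij = −log|C_ij|`, the standard
length in dynamical-network analysis (perfect correlation → zero length;
uncorrelated contacts → effectively unreachable). Contacts with exactly
zero correlation are dropped with a warning rather than given infinite
weight silently.

Choices within this stage:

* **Contact rule.** The closest-heavy-atom rule is the convention of the
  established network tools; a literal Cα-Cα 4.5 Å rule would leave a real
  protein chain nearly edgeless (consecutive Cα sit at 3.8 Å but almost
  nothing else does). A `mode = "calpha"` flag provides the literal rule.
* **Sequence neighbours.** Edges between residues i and i±1 are excluded
  from path search by default: covalently bonded neighbours are always in
  contact and would provide trivial backbone shortcuts. A flag restores
  them; the trajectory analysis driver uses it deliberately, because in
  the synthetic chain the backbone carries near-zero correlation and
  provides the population of long alternative routes that fills out the
  suboptimal-path histogram.
* **Path enumeration.** All-pairs optimal lengths come from a vectorised
  Floyd–Warshall with successor reconstruction. The top-k suboptimal
  paths come from bounded depth-first search: starting at the optimal
  length, the cap is raised in 25% increments until k simple paths fit
  under it, with exact shortest-distance-to-sink pruning — the
  length-offset strategy of the classical `subopt` tools. Equal-length
  paths are ordered lexicographically by node sequence, making output
  deterministic. The enumeration is validated against exhaustive
  simple-path enumeration on hundreds of random ≤ 8-node graphs, and
  Floyd–Warshall against per-source Dijkstra.

## Assay models

**Competition FP.** The displacement curve is fit as written, with unit
Hill slope (a variable-slope variant sits behind a flag but is not the
default, matching the fixed-slope model the curve equation states). All
replicate wells are fit jointly; per-experiment log Ki values for paired
tests come from fitting each experiment separately. The probe correction
`logKi = logEC50 − log10(1 + [Probe]/Kd)` is exact algebra; the probe Kd
is always an input, never re-fit, because it is measured in separate
saturation experiments. Synthetic defaults mirror the study conditions:
10 nM probe with a 10 nM Kd (LRH-1-like) or 30 nM probe with a 50 nM Kd
(SF-1-like), doses 2×10⁻¹¹-2×10⁻⁴ M in tenfold steps, four replicates,
homoscedastic Gaussian noise at 2% of the dynamic range (no noise model is
standard for plate FP; homoscedastic mP-scale noise is the simplest
defensible choice).

**DSF.** Melts are fit with the Boltzmann sigmoid; because dye-based
melts decay after the unfolding transition (dye release), the fit window
is truncated at the fluorescence maximum by default, and a no-protein
blank column is subtracted pointwise when present. Tm is the inflection;
ligand effects are reported as ΔTm against a named reference. Fitting uses
Levenberg–Marquardt (minpack.lm) with midpoint-crossing initialisation and
multiple slope starts; convergence is reported honestly and degenerate
inputs (flat or monotone-decreasing curves) are errors, not silent
extrapolations.

## Degenerate inputs and tie-breaking

* Selections that should name one atom error when they resolve to any
  other count; empty selections are errors only where an answer would be
  meaningless (B-factor means), not for queries (atom selection).
* Collinear "ring" atoms have no plane and error.
* Zero-variance residues get zero off-diagonal correlation with a warning
  and a unit diagonal.
* Zero within-pair variance makes the paired t-test degenerate; it is
  flagged rather than reported as an arbitrarily extreme p-value.
* Equal-length paths and equal-occupancy altloc ties break
  deterministically (lexicographic node order; first altloc on ties).

## What passing tests do and do not show

The generators emulate the *statistical skeleton* of the real inputs:
exact interaction occupancies, a prescribed correlation structure with a
contact backbone, assay curves from the fitted models plus Gaussian noise.
They do not emulate force-field physics, solvent, anisotropic B-factors,
crystallographic restraints, or heteroscedastic plate effects. Passing
recovery tests therefore establishes that the estimators and the network
machinery are correct and unbiased under their stated assumptions — not
that those assumptions hold for any particular experimental system. The
one check that requires real data (superposing the two deposited crystal
structures, expected near 0.1 Å Cα RMSD) is included in the test suite but
can only run when those coordinate files are fetched locally.
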
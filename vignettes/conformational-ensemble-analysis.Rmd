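---
title: "Conformational ensemble analysis with confens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensemble analysis with confens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confens)
```

## Scope and model

`confens` analyses ensembles of conformations of a protein fragment: the
chains of a crystal asymmetric unit, the models of a multi-model PDB, or
the frames of a simulation trajectory. The motivating system is the
glucocorticoid receptor DNA-binding domain, whose lever-arm loop
(residues 450--456) samples fewer distinct conformations as the domain
binds DNA and dimerizes -- conformational selection driven by binding.
The package provides the four analyses that question requires:
superposition/RMSD, fluctuation (RMSF), backbone-dihedral statistics, and
fixed-radius RMSD clustering, plus a ground-truth synthetic generator.

All analyses operate on a named atom selection, a `fragment_spec`: a
residue range in author numbering plus atom-name filter (default
C-alpha). Presets ship for the lever arm (450--456), the core domain
(421--491, and the simulation truncation 421--490 -- both forms appear in
the literature, so both are provided), the D-loop (457--465), and the
second-zinc-finger helix (469--473).

## Superposition and RMSD

`kabsch_fit()` computes the closed-form SVD solution for the proper
rotation minimizing RMSD between paired coordinate sets. Two numerical
choices matter:

* **Reflections are forbidden.** When the unconstrained orthogonal
  optimum is improper, the sign of the smallest singular vector is
  flipped. Molecular chirality must be preserved, so an improper "fit"
  would silently compare a molecule to its mirror image.
* **Degenerate geometry errors.** Fewer than 3 atoms, or a centered
  configuration of rank < 2 (collinear points), leaves the rotation
  undetermined; the fit refuses rather than returning an arbitrary
  rotation.

No per-atom weighting is applied anywhere: the analyses this package
reproduces are uniform-weight C-alpha fits. The sign convention for
torsions is IUPAC (cis = 0, trans = 180, range (-180, 180]); note that
a torsion is *invariant* under reversing the four points' order and
anti-symmetric under reflection -- the property tests assert exactly
this.

`average_structure()` iterates fit-to-mean / re-mean from the first frame
until the mean moves less than `tol` (default 1e-6 Angstrom, maximum 50
iterations). Initialization at frame 1 is fixed so results are exactly
reproducible; non-convergence flags the result rather than erroring,
since a near-converged mean is still a usable RMSF reference.

## RMSF

`rmsf()` fits every frame, on a chosen fit selection, to the average
structure of that selection, then measures fluctuations on a (possibly
different) measure selection. The default convention -- fit on a rigid
core, measure everywhere -- prevents flexible-region motion from being
absorbed into the superposition, which would deflate exactly the signal
of interest. The reference is the mean structure, not frame 1: RMSF about
the mean is the standard definition and is what the closed form
E(RMSF) = sigma * sqrt(3) for isotropic per-coordinate noise applies to.
A small deflation (about sqrt(1 - 6/(3N))) arises because the fit removes
six rigid degrees of freedom; at the 70-atom scale used in the tests this
is ~1.4% and sits well inside the 5% test band.

## Dihedral statistics and state assignment

Backbone phi(i) requires C(i-1), N(i), CA(i), C(i); psi(i) requires N(i),
CA(i), C(i), N(i+1). Angles whose supporting atoms are absent (chain
termini, broken chains) are reported as missing, never fabricated.

Circular summaries use directional statistics: mean = atan2 of the mean
resultant, SD = sqrt(-2 log R) in degrees. A resultant length below 1e-12
(uniform angles) raises an undefined-mean error instead of returning
noise.

Per-residue variability (the box-plot view of an ensemble's dihedrals)
uses a **circular IQR**: values are unwrapped about their circular median
-- each observation shifted by a multiple of 360 into (median - 180,
median + 180] -- and the ordinary IQR is taken. The unwrap makes the
statistic well defined for angle clusters straddling +/-180. Quantile
type 2 is used so that for two conformations the IQR equals their
difference, the natural two-model reading of a box plot.

State classification (`assign_states()`) uses windowed nearest-mean
labels: a value is assigned to the closest state mean (circular distance)
among the states whose window mean +/- 2 SD contains it, else
"unassigned". The window prevents forced labels far from every state
(e.g. at 90 degrees between the His453 "in" and "out" basins), at the
cost that ~4.6% of in-basin mass falls outside its own 2-SD window --
which is why classifier accuracy on the two-state preset settles just
above 95%. Transition counting skips unassigned gaps (a -> unassigned ->
b counts one a -> b transition), making counts insensitive to brief
window exits during a crossing. The published third state (intermediate,
119 +/- 13) ships as a preset but is off by default: its window lies
inside the "out" window, and with nearest-mean tie-breaking it would
absorb part of the out basin -- whether it was treated as a classified
state or a descriptive observation in the source analysis is unclear, so
the two-state classifier is the default.

## Fixed-radius RMSD clustering

`kclust()` re-specifies the MMTSB "kclust" behaviour as a fully pinned,
deterministic algorithm, since the original tool documents its radius but
not its exact iteration:

1. *Seeding*: scan frames in order; a frame joins the nearest existing
   centroid if its Kabsch-fitted RMSD is within the radius, else it seeds
   a new cluster.
2. *Refinement*: recompute each centroid as the coordinate-wise mean of
   its members after fitting each member to the current centroid; then
   reassign every frame to its nearest centroid with **no radius test**;
   drop emptied clusters; repeat until assignments are stable or
   `max_iter` (default 100).

Ties in nearest-centroid distance go to the earlier-seeded cluster;
reported clusters are ordered by decreasing size with the same
tie-break. The algorithm is deterministic given frame order -- there is
no internal randomness to seed. The default radius is 2.3 Angstrom on
lever-arm C-alpha coordinates, the published cutoff; no automatic radius
selection is implemented because the selection procedure behind that
value is not documented -- radius is an explicit parameter.

Default frame budgets mirror the published protocol (50,000 evenly spaced
snapshots for single-trajectory runs, 5,000 per source for combined
runs); even subsampling uses indices floor(j * L / n), so the first frame
is always included. Combined clustering pools the subsamples with
provenance labels and runs a single clustering; occupancy is the fraction
of a source's frames per cluster, and a cluster is *shared* by two
sources iff both occupancies are >= the 10% floor (strict >=, so
(0.12, 0.09) is not shared).

## The synthetic generator: what it emulates, and what it does not

`generate_ensemble()` emulates the statistical skeleton of a trajectory:
k reference conformations, a Markov chain over them, isotropic Gaussian
coordinate noise, and an arbitrary proper rigid motion per frame (so
nothing may rely on a pre-aligned trajectory). `make_reference_states()`
builds state 1 as a deterministic pseudo-random coil with exact 3.8
Angstrom consecutive C-alpha spacing; states 2..k displace a contiguous
block along mutually equidistant directions -- a regular simplex embedded
in the block's coordinate space, kept orthogonal to the block's
rigid-body subspace so the Kabsch fit cannot absorb the displacement --
and the simplex edge lengths are iteratively corrected (classical MDS
re-embedding per round) until **every** pairwise fitted RMSD is within 5%
of the declared target. If a direction draw cannot close the band, new
directions are drawn from deterministically derived sub-seeds before the
request is declared infeasible.

Two candid limitations follow from that design. First, displaced states
are abstract conformers: their pairwise RMSD geometry is exact, but bond
lengths inside and at the edges of the displaced block are not
maintained -- a displacement large enough to give a 6--8 Angstrom fitted
RMSD cannot preserve 3.8 Angstrom spacing. Only the base coil is
physically proportioned. Second, the noise model (i.i.d. isotropic
Gaussian, memoryless state switching) lacks the correlated, anharmonic
fluctuations of real dynamics. Passing tests therefore demonstrate that
the *analysis machinery* is correct (superposition optimal, counts and
occupancies right, classifiers calibrated), not that any conclusion about
real trajectories would be recovered at these noise levels.

The bundled `fig_standin_specs()` presets encode the qualitative
hierarchy under study -- 12 accessible states for the free domain, 6 for
the inverted-repeat-bound form, 2 for the dimer-bound form -- with an 8
Angstrom inter-state RMSD (comfortably beyond twice the 2.3 Angstrom
radius plus four within-state spreads, the separation at which count
recovery is guaranteed), per-coordinate noise of 0.3 Angstrom, stay
probability 0.9, and 200 frames per accessible state. The stay
probability and per-state frame budget are chosen so every accessible
state is visited many times over a chain short enough for test-suite run
times; the methods are insensitive to these choices once all states are
visited.

Dihedral series use wrapped-Gaussian emission rather than von Mises: the
states being emulated are described as mean +/- SD, which the wrapped
Gaussian matches directly, and the two distributions are
indistinguishable at SD <= 20 degrees.

Problem sizes used by the test suite and the acceptance script -- e.g.
5,000 frames for the RMSF closed form, 100--200 frames per state for
cluster recovery, 10,000 frames for the classifier -- are the package's
chosen demonstration scales: large enough that every statistical
tolerance is met with margin, small enough to keep the whole suite in the
low minutes.

## Degenerate inputs and tie-breaks, collected

* Superposition: < 3 atoms or rank-< 2 centered configurations error;
  identical inputs short-circuit to RMSD exactly 0 (the singular-value
  identity otherwise carries ~1e-7 cancellation noise).
* Selection: alternate locations resolve to highest occupancy, then
  alphabetically first label; heteroatoms (including the structural
  Zn2+) are parsed but never enter fitting selections; a residue missing
  a requested atom errors unless `allow_missing` drops it everywhere;
  insertion codes are unsupported and error loudly.
* Classification: exact distance ties take the first state listed;
  values in no window are "unassigned", never force-labeled.
* Clustering: `max_iter` exhaustion returns the model flagged
  `converged = FALSE` rather than discarding work.
* Average structure: non-convergence at `max_iter` flags, does not
  throw.

## Interfaces

The analysis surface is functional: `read_pdb()` / `write_pdb()`,
`select_atoms()`, `kabsch_fit()` / `pairwise_rmsd_matrix()` /
`average_structure()`, `rmsd_timeseries()` / `rmsf()`,
`backbone_dihedrals()` / `variability_profile()` / `assign_states()`,
`kclust()` / `combined_cluster()` / `overlap_report()`, and the
orchestrators `compare_structures()`, `analyze_trajectory()`,
`combine_trajectories()` with `write_outputs()` (TSV/JSON, each stamped
with a config hash so outputs from different configurations never mix
silently). R functions, not a shell binary, are the intended interface:
the package is a library its users script against, and the orchestrators
are those scripts' entry points.
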
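---
title: "Methods: quantifying GPCR activation from trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying GPCR activation from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrtraj)
```

`gpcrtraj` turns a membrane-protein trajectory into the observables by which
class-A GPCR activation is usually judged: rotamer switch events around the
conserved core, hydration of conserved polar residues, the TM7 kink, backbone
RMSD, and conformational-state assignments from intracellular helix-end
distances. This vignette is the package's methods account: the models and
conventions, the parameters that matter, the numerical choices, what the
synthetic generator does and does not emulate, and known limitations.

## Inputs and conventions

Trajectories are multi-model PDB files: a topology (atom/residue table, with
waters identified by residue name — `HOH`, `WAT`, `TIP3`, `SOL`, `SPC` by
default, overridable) plus `F × A × 3` coordinates in Å and frame times in
ns. PDB files carry no time stamps, so times are `dt_ns × (model − 1)` with
`dt_ns` from the config (the synthetic fixtures use 1 frame = 1 ns).
Residue numbers are the author numbering taken verbatim from the file; no
renumbering is performed. Alternate locations other than blank/`A` are
dropped on reading; hydrogens are kept when present (needed for hydrogen-bond
angles) but all distance-based analyses use heavy atoms only. Coordinates
are assumed whole (no periodic wrapping): the water-counting convention
therefore matches simulations post-processed with molecules made whole,
which is the normal situation for published hydration counts.

Ballesteros–Weinstein generic numbers are assigned per helix from an anchor
residue: position(r) = anchor_position + (r − anchor_seq). Anchors need not
sit at position 50 — TM6 of S1P₁ is conveniently anchored directly at its
6.48 tryptophan (W269), since that is the residue the literature actually
prints. Indices are stored as integer (helix, position) pairs and rendered
`H.PP` only at I/O, avoiding 2.5-vs-2.50 floating-point ambiguity. The
shipped `s1p1_helices()` table uses reconstructed helix boundaries: they are
consistent with every published residue/superscript pair for this receptor,
but are not structure-derived annotations and should be replaced when exact
boundaries matter.

## Dihedrals and rotamer switches

χ angles use IUPAC atom names (χ₁ = N–CA–CB–G, χ₂ = CA–CB–G–D, with G/D
resolved per residue type; χ₂ of Phe/Tyr/Trp uses CD1) and the signed
convention on (−180°, 180°]; residues lacking the requested angle are
rejected rather than silently skipped. The torsion is computed by the
projection formulation and cross-checked in the tests against an
independently coded plane-normal oracle and against `bio3d::torsion.xyz`.

Rotamer classification is circular binning. The default three-state set is
gauche− (−120°, 0°], gauche+ (0°, 120°], trans (120°, −120°] wrapping; for
toggle-switch analyses of the 6.48 tryptophan, whose χ₂ alternates between
roughly 0° and 90°, `rotamer_bins_from_centers(c(down = 0, up = 90))`
splits the circle at the midpoints between centers. Before binning, the
series is unwrapped (cumulative wrapped differences) and median-filtered —
window 21 frames by default — so the ±180° seam never fragments the trans
state and single-frame noise cannot masquerade as a transition. A switch
event is reported at the first frame of each maximal run of a new state
lasting at least `min_dwell` frames (default 50); shorter excursions are
ignored. Both windows are configurable: published time series are typically
read by eye off smoothed plots, so the defaults encode an explicit,
reproducible version of that smoothing. Detected event times can therefore
lag or lead the underlying transition by up to the filter half-window
(10 frames at the default).

Hydrogen bonds use the common geometric criterion: donor–acceptor heavy-atom
distance ≤ 3.5 Å and, when the donor carries hydrogens (inferred from a
D–H distance ≤ 1.2 Å in the first frame), a D–H···A angle ≥ 150°. Without
hydrogens the angle term is dropped and the result is flagged
(`attr(x, "mode") == "heavy"`). Ligand–receptor contacts count a residue as
contacting when any heavy-atom pair is within 4 Å, the same length scale as
the hydration shell.

## Hydration

A water is in the shell of a selection when its *oxygen* lies within the
cutoff (default 4 Å) of any heavy atom of the selection; each water counts
once per frame. Measuring from the oxygen rather than from hydrogens or the
whole molecule makes counts independent of whether the water model carries
explicit hydrogens. The NPxxY-motif selection is all heavy atoms of the
five motif residues (7.49–7.53). Water bridges are distance-only: a water
bridges two disjoint selections when its oxygen is within the cutoff of
both in the same frame. No angular term is applied because bridge reports
of this kind are geometric observations about water position, not bond
assignments.

## Helix axes and the kink angle

The kink is κ = 180° − arccos(u·v), with u and v the N→C axes of the arms
flanking the pivot residue (pivot excluded, 7 residues per arm by default —
about two helical turns, the most that fits the short intracellular segment
of TM7). A straight helix reads ≈180° and κ decreases as the helix bends,
matching the convention in which TM7 drifts from ~155° to ~130° during
activation.

The axis estimator needs care at this arm length. The naive choice — the
principal component of the raw Cα positions — is biased by the helical
spiral itself: over a 7-residue window (1.94 turns) the fitted axis tilts
~18° from the true axis, and a perfectly straight helix would read a "kink"
of ~157°. `fit_helix_axis()` therefore first smooths the Cα run with a
4-tap kernel whose weights (0.742, 1, 1, 0.742, normalised) are chosen so
that the 100°-per-residue helical phase cancels exactly
(Σ wⱼ·exp(i·100°·j) = 0); the smoothed points lie on the axis for ideal
geometry and their principal component is the axis. For the minimum window
of 4 residues the estimator falls back to the cross product of successive
Cα bisectors, which is also exact on an ideal helix. Both are equivariant
under rigid motion.

With 0.2 Å coordinate noise, a single-frame kink estimate from 7-residue
arms has an irreducible spread of ~2.4° — the information limit of 14 noisy
Cα positions. `kink_series()` therefore applies a running median over
frames (window 21, partial windows at the series edges) so that endpoint
readouts are stable at the ~0.5° level; raw per-frame values are available
with `smooth_frames = 0`.

## RMSD and end distances

`rmsd_series()` superposes each frame independently onto the reference
frame (frame 1 by default — the equilibrated starting structure) over the
selection, then reports √(Σd²/n). Superposition is the optimal
least-squares (Kabsch) fit via SVD with the usual reflection guard;
collinear or sub-3-point selections are rejected. The default selection is
all backbone atoms; restricting to TM residues is a one-line selection
string. Whether to superpose on a crystal structure instead of the first
frame is a user choice via `reference_frame`.

The intracellular end of a helix is the centroid of the Cα of its
`end_length` (default 4, one turn) most intracellular residues; which end
is intracellular is declared per helix. `end_distance_series()` reports the
three pairwise distances in the order TM7–TM3, TM3–TM6, TM6–TM7.

## State clustering

Frames are partitioned by k-means (k = 3, 50 restarts under a fixed seed,
`iter.max` 200) on the raw distances in Å — the three axes share units, so
no standardisation is applied. Cluster labels follow the centroid
coordinate sum, ascending: activation opens the intracellular face, so the
smallest-sum cluster is `inactive` and the largest `active`. Separation is
quantified by the mean silhouette coefficient, and each state's "central
structure" is its medoid frame (minimum summed distance to cluster
members). k-means with a deliberately chosen k is the simplest method
consistent with three visually separated clusters; density-based or
hierarchical alternatives and automatic k selection are out of scope.

## The synthetic generator

`build_bundle()` realises a `synthetic_spec()`: seven ideal α-helices
(Cα rise 1.5 Å, 100°/residue twist, Cα radius 2.3 Å; N, C, O, CB placed by
ideal internal geometry) stood vertically on a 12 Å circle, with helix *h*
numbered h·100+1 … h·100+n and anchored at index 13 (= position 50,
intracellular end at the N-terminus). On this scaffold it plants, exactly
and before noise:

* **χ schedules** — side-chain pseudo-atoms (G, and D when χ₂ is scheduled)
  placed by internal-coordinate (NeRF) construction so the scheduled
  dihedral is realised to machine precision;
* **kink schedules** — rigid rotation of the intracellular arm about an
  in-membrane axis through the pivot Cα by 180° − κ(t), κ(t)
  piecewise-linear;
* **end-distance schedules** — per-phase target triples (with Gaussian
  jitter) realised by whole-helix translations of TM6 and TM7 solved from
  the target triangle; translations preserve planted kinks, so the two
  schedules compose rather than conflict. Targets violating the triangle
  inequality are a spec error;
* **water schedules** — single-oxygen `HOH` residues placed 2.5–3.2 Å from
  a random heavy atom of the target residue (deliberately inside the 4 Å
  cutoff so that coordinate noise cannot eject them), surplus shell waters
  parked far outside every shell, plus background waters 55–75 Å out as
  negative controls;

and finally adds i.i.d. Gaussian noise (σ = 0.2 Å in the standard
fixtures) to every coordinate. Everything is deterministic given the seed;
identical specs produce byte-identical PDB output.

`condition_spec()` packages three study conditions with schedule timings as
fractions of the run: an apo-like trajectory (early 2.57 χ₁ flip at 1/7 of
the run, stable 6.48/6.44, 3–4 shell waters), an antagonist-like one (late
2.57 flip at 11/14, a 6.48 χ₂ toggling 0°↔90° over the first ~70%, 5–7
waters) and an agonist-like one (stable 2.57, planted 6.48/6.44 flips at
150/700, 400/700 and 300/700 of the run, 8–10 waters, a TM7 kink drifting
155°→130°, and a three-phase inactive/intermediate/active end-distance
schedule with ~2–3 Å between phase centroids and 0.25 Å jitter, i.e.
well-separated at the ≥5σ level). The occupancy ranges and the kink
endpoints are the values reported for the corresponding ligand states of
S1P₁; phase centroids are set near the natural geometry of the synthetic
bundle so the planted translations stay small.

What the generator does *not* emulate: physical dynamics (no correlated
motions, no dwell-time kinetics beyond the schedules), membrane and ligand
atoms, realistic side-chain packing (pseudo-atoms only), rotamer libraries,
and periodic boundaries. Passing the recovery suites therefore demonstrates
that the *analysis operators* are correct and robust at realistic noise
amplitudes — not that they would segment, e.g., a poorly converged real
trajectory sensibly. On real data the median-filter and dwell parameters
are the knobs that absorb autocorrelated noise, and they should be reported
alongside results.

Recovery tolerances used by the test suite: planted kink endpoints within
±2° (after the temporal median), flip frames within ±11 frames (the filter
half-window), shell-occupancy means within two standard errors, clustering
ARI ≥ 0.95 on the planted labels, and χ *segment means* within ±3°. The
segment-mean form is deliberate: at σ = 0.2 Å the per-frame torsion noise
through ~1.5 Å pseudo-bonds is 20–30° sd, so a per-frame ±3° guarantee is
not attainable by any estimator; the mean over a schedule segment is the
quantity that carries the planted signal.

## Pipeline, sizes and determinism

`run_analysis()` executes I/O → BW map → χ/rotamer/switch → H-bonds →
hydration → contacts → kink → RMSD → end distances → clustering from one
YAML config; any stage key may be omitted. Config validation reports every
problem at once. Outputs are TSVs plus a JSON summary whose provenance
block records the package version, a config hash, the seeds, and the
defaults in force (4 Å shells and contacts, 3.5 Å/150° H-bonds, dwell 50,
filter 21, k = 3, arm window 7, end length 4). With fixed seeds the whole
simulate-and-analyze path is byte-deterministic, which the tests verify
with repeated runs.

The shipped test suite exercises full-scale recovery on one 700-frame
agonist-like trajectory (~1000 atoms) and uses 40–300-frame versions of the
same conditions elsewhere; these sizes keep the complete suite around a
minute on a single core while leaving every property identical in shape to
the full-length fixtures, whose timings are simple fractions of the run.

## Known limitations

* The kink-angle convention (arm axes, 7-residue windows, temporal median)
  is one of several in circulation; absolute κ values are comparable only
  under the same convention, although trends and endpoint drifts are
  robust to it.
* Selections resolve by residue number and name only; insertion codes and
  duplicate author numbering across chains require the `chain` argument.
* The PDB reader trusts the fixed-column format; mmCIF and binary
  trajectory formats (DCD/XTC) are not supported — convert to multi-model
  PDB first.
* Water counting assumes whole molecules; wrapped periodic images would
  undercount shells near the box boundary.
* k-means assumes roughly isotropic, comparable-volume clusters; strongly
  elongated conformational basins would need a different geometry.
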
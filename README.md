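# gpcrtraj

Trajectory analysis of G protein–coupled receptor (GPCR) activation in R.

Molecular-dynamics studies of class-A GPCRs such as the sphingosine
1-phosphate receptor S1P₁ characterise activation through a recurring set of
observables: side-chain rotamer "toggle switch" transitions around the
conserved 6.48 tryptophan and its neighbours, water influx into the shell of
the conserved 2.50 aspartate and the NPxxY motif, the kink of TM7 about its
7.50 proline pivot, backbone RMSD of the transmembrane bundle, and the
distances between the intracellular ends of TM3/TM6/TM7, which separate
frames into inactive, intermediate and active conformational states.
`gpcrtraj` implements this analysis pipeline as composable, pipe-friendly
functions over multi-model PDB trajectories, for structural biologists and
simulation practitioners who want the standard GPCR activation readouts
without a bespoke script stack.

## What it computes

* **Ballesteros–Weinstein numbering** — generic indices H.PP from per-helix
  anchor residues: position(r) = anchor_position + (r − anchor_seq), with the
  conserved residue of helix H at H.50.
* **χ dihedral series and switch events** — IUPAC-signed torsions
  (χ₁ = N–CA–CB–G, χ₂ = CA–CB–G–D), circular rotamer binning after a running
  median filter, and switch events at the first frame of each new state that
  dwells at least `min_dwell` frames.
* **Hydration shells and water bridges** — per-frame counts of water oxygens
  within a cutoff (default 4 Å) of a target's heavy atoms, and waters
  simultaneously within the cutoff of two selections.
* **Helix kink** — κ = 180° − arccos(u·v), where u, v are the axes of the
  arms flanking the pivot; a straight helix reads ≈180° and κ falls as the
  helix bends (e.g. a TM7 drift from ~155° to ~130° on activation).
* **Superposition RMSD** — per-frame least-squares (Kabsch) fit onto a
  reference frame.
* **State clustering** — k-means (k = 3, 50 seeded restarts) in the
  (TM7–TM3, TM3–TM6, TM6–TM7) intracellular end-distance space, labels
  ordered so larger distances (a more open intracellular face) mean more
  active; silhouette and medoid ("central structure") frames reported.
* **Synthetic trajectories with planted truth** — an ideal 7-helix bundle
  generator with scheduled rotamer flips, kink drifts, shell occupancies and
  state sequences, so every stage is testable without external data.

## Worked example

```r
library(gpcrtraj)

# a 700-frame synthetic agonist-like trajectory with planted ground truth
spec <- condition_spec("agonist", n_frames = 700, seed = 11)
b    <- build_bundle(spec)
hel  <- synthetic_helix_defs(spec)

# TM7 kink about the 7.50 pivot (residue 713 in the synthetic numbering)
kk <- kink_series(b$trajectory, hel[[7]], pivot_seq = 713, window = 7)
round(c(first = kk$kink[1], last = kk$kink[700]), 1)
#>  first   last
#>  154.9  130.0

# rotamer toggle of the 6.48 tryptophan analogue (chi2, 0 vs 90 degrees)
st <- chi_series(b$trajectory, 611, "chi2") |>
  classify_rotamers(rotamer_bins_from_centers(c(down = 0, up = 90)))
detect_switches(st, min_dwell = 50)[, c("frame", "from_state", "to_state")]
#> # A tibble: 2 × 3
#>   frame from_state to_state
#>   <int> <chr>      <chr>
#> 1   150 down       up
#> 2   399 up         down

# hydration of the 2.50 shell, then activation-state clustering
mean(water_count_series(b$trajectory, "resid 213 and heavy")$count)
#> [1] 9.011429

fit <- end_distance_series(b$trajectory, hel[c(3, 6, 7)]) |>
  cluster_states(k = 3, seed = 1)
glance(fit)
#> # A tibble: 1 × 5
#>       k n_frames silhouette tot_withinss  seed
#>   <dbl>    <int>      <dbl>        <dbl> <dbl>
#> 1     3      700      0.751         166.     1
```

The kink endpoints track the planted 155°→130° schedule, the two detected
switch frames sit within a few frames of the planted flips at 150 and 400,
the mean shell count matches the planted 8–10 occupancy, and the three
clusters recover the planted state sequence (silhouette ≈ 0.75: well
separated). `autoplot(fit)` draws the pairwise end-distance panels;
`tidy(fit)`/`augment(fit)` give the centroid and per-frame tables.

Real trajectories enter through `read_structure()` + `read_trajectory()`
(multi-model PDB), and a single YAML config can drive the whole pipeline via
`run_analysis()`; see the vignette and
`inst/extdata/example_config.yaml`. A thin CLI wrapper lives at
`inst/scripts/gpcrtraj` (`simulate`, `analyze`, `compare`).

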
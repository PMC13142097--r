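---
title: "Profiling conformational diversity across crystal ensembles, trajectories and NOE data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling conformational diversity across crystal ensembles, trajectories and NOE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflex)
```

## The problem and the model

Multidomain scaffold proteins often pack several copies of a construct into
one crystal's asymmetric unit, and several crystal forms of the same
construct may be available. Each copy is an independent snapshot of the
molecule under slightly different lattice restraints. `conflex` treats these
copies as a conformational ensemble: if a region adopts visibly different
conformations across snapshots — and keeps doing so after the systematic
chain-to-chain (packing) differences are accounted for — that diversity is
evidence of intrinsic flexibility rather than noise. The motivating system
is a tandem PDZ pair (PDZ1, residues 114–193; PDZ2, residues 197–273, author
numbering), where the question is whether the loops around one domain's
ligand-binding cleft are genuinely plastic.

The analysis chain is:

1. extract each domain copy (chain × residue range) as a Cα trace with
   B-factors, recording unmodelled residues as gaps;
2. restrict all copies to the residues resolved in *every* copy (matching is
   by author residue number only; no sequence alignment);
3. superpose every unordered pair by least squares (Kabsch) and record the
   RMSD and the per-residue deviations;
4. cluster the pairwise RMSD matrix, and average the per-residue deviations
   over pairs to localize the diversity;
5. corroborate with cross-structure B-factor tracks, replicate-averaged
   trajectory RMSF, and heteronuclear NOE ratios.

Each modality has a calling rule that converts a per-residue track into
flexible regions: maximal contiguous runs strictly beyond a threshold, at
least `min_length` residues long, with gaps in residue numbering breaking
runs. Single-residue spikes are thereby excluded from region calls (they are
still visible in the profile itself).

## Superposition and its numerical policy

`kabsch_superpose()` solves the orthogonal Procrustes problem by SVD of the
3×3 cross-covariance matrix of the centered coordinates. The reflection case
is corrected by flipping the sign of the smallest singular direction, so the
returned rotation always has determinant +1 (enforced to 1e-10) even for
synthetically mirrored inputs. The fit may be restricted to a subset of
sites (`fit_selection`), but deviations and the RMSD are always reported
over *all* sites after applying the fitted transform — this is what lets a
rigid-core fit expose the displacement of a single loop residue in the
per-residue profile. Degenerate fits (fewer than 3 sites, or a collinear
selection, detected as a relative second singular value below 1e-8) are
refused rather than silently regularized. Pair RMSD is symmetric to 1e-8 Å;
the tolerance constants are fixed package-wide.

The residue correspondence is deliberately naive (author numbers within one
chain). Flexible or partial-order alignment is out of scope; if two crystal
forms number residues differently, the caller must renumber first.

## Ensemble diversity

`pairwise_rmsd_matrix()` computes all n(n−1)/2 pairs on the common residues.
Clustering is standard agglomerative linkage on that precomputed matrix;
average linkage (UPGMA) is the default because it is monotone and matches
the "mean of cross-pairs" aggregation used for inter-cluster distances.
No linkage was prescribed by the underlying protocol, so the choice is
configurable (`single`, `complete`). Members are sorted lexicographically by
label before merging so equal-height ties resolve deterministically and the
merge history is permutation-stable up to relabeling. Heatmap ordering
follows the dendrogram leaf order.

For the per-residue profile, the fit protocol behind published per-residue
averages is typically unstated. The default here is a global superposition
on all common residues per pair; a core-restricted `fit_selection` is
available when a rigid reference frame is preferred. Likewise the averaged
pair set is configurable (`members =`) because one may want all pairs, or
only within-group pairs (e.g. only chain-B copies) when groups differ
systematically.

## Thresholds and their defaults

| Track | Default threshold | Direction | Unit |
|---|---|---|---|
| average pairwise RMSD | 1.0 | strictly above | Å |
| trajectory RMSF | 0.12 | strictly above | Å |
| B-factor | grand mean of the mean track | strictly above | Å² |
| heteronuclear NOE ratio | 0.75 | strictly **below** | unitless |

All comparisons are strict inequalities: a residue sitting exactly at the
threshold is never flagged. `min_length` defaults to 2 residues everywhere.
The 0.12 Å RMSF default is unusually small for loop fluctuations (0.12 *nm*
would be a more common magnitude in trajectory post-processing, which often
emits nanometres); the package keeps the printed Å value as the default,
makes the threshold configurable, and provides `nm_to_angstrom()` so unit
provenance is explicit at input time.

## B-factor aggregation

Members are ranked by their mean Cα B over common residues; the argmax and
argmin members' full tracks are reported alongside the per-residue mean over
all members. Ranking by the mean (rather than, say, the maximum) is robust
to track length and to single spiky atoms. Raw B values are used by default
because that is how such profiles are usually drawn; an optional per-member
z-score normalization (`normalize = TRUE`) removes crystal-to-crystal
offsets in overall B and is documented as a deviation from the default path.
Only the Cα B-factor represents a residue, matching the Cα-based analyses
elsewhere in the package.

## Trajectory RMSF

`select_frames()` implements the analysis-window protocol: keep frames in
`[t_min, t_max]` (defaults 40 000–200 000 ps, i.e. the final 160 ns of a
200 ns run), then subsample on a stride grid (default 100 ps) by
nearest-frame matching — trajectories already on the stride grid pass
through unchanged. `rmsf()` superposes all frames onto an iteratively
refined mean structure (reference = running mean, convergence when the mean
moves < 1e-6 Å, at most 10 iterations) rather than onto frame 1, which
removes the arbitrary dependence on the first snapshot. Replicate profiles
are aggregated residue-wise as mean and *population* SD (five replicates is
the expected design; SD is 0 for a single replicate).

For iid per-coordinate Gaussian fluctuations of width σ the analytic
expectation is RMSF = σ√3, which the generator-based tests recover within
sampling error at 1600 frames.

## Heteronuclear NOE ratios

`noe_ratio()` computes `I_sat / I_unsat` per assigned residue. Unassigned or
overlapped residues are absent rows, never zeros; rows with `I_unsat == 0`
cannot form a ratio and are excluded with a warning and an `excluded`
record. Ratios are scale-invariant in the intensities, and no uncertainty
propagation is attempted (plain ratios are reported). The low-ratio call
uses the same region machinery with the direction inverted.

## Interdomain contacts

A residue pair is in contact when any heavy-atom pair across the two domains
is within 4.5 Å; a polar (hydrogen-bond proxy) flag requires an N/O–N/O pair
within 3.5 Å. The proxy is donor/acceptor-agnostic and angle-free because
typical crystal models carry no hydrogens; both cutoffs are parameters, and
`contact_fraction_sweep()` reports how a region's contact-participation
fraction moves with the heavy-atom cutoff, since participation percentages
are sensitive to the (unstandardized) contact definition. Waters are
excluded; water-mediated networks, interface energetics and buried surface
area are out of scope.

## The synthetic generator: what it emulates, and what it does not

`make_crystal_set()` emulates the study design the crystal analysis expects:
10 structures × 2 chains, each chain carrying a PDZ1-like (114–193) and a
PDZ2-like (197–273) domain built on per-domain scaffolds shared by all
copies. Flexibility is injected as iid per-coordinate Gaussian displacements
— σ = 1.5 Å inside the designated loops (defaults 119–125 and 181–184 on
chain B), σ = 0.05 Å elsewhere — plus a per-structure, per-chain rigid-body
jitter (rotation ≤ 5°, translation ≤ 2 Å) that superposition must undo.
Chain asymmetry is modelled as a chain-A σ-reduction (chain A simply never
receives the loop σ), emulating the restraining effect of tighter packing
contacts without building explicit lattice neighbours. B-factors are written
from the generating σ via the isotropic relation B = 8π²σ² (78.96 Å² at
σ = 1 Å), NOE ratios as `clip(0.85 − 0.2·σ + ε, 0, 1)` with ε ~ N(0, 0.02),
and trajectories as scaffold + iid noise with optional restrained regions
(σ divided by 3) standing in for tandem-interface damping. The scaffold
itself is an idealized helical curve (consecutive Cα distances 3.8 ± 0.1 Å)
with a seeded orientation.

Everything derives from one integer seed through per-artifact sub-seed
streams, so datasets are byte-identical under a fixed seed and adding one
artifact never shifts another. A ground-truth record (flexible spans, σ
values) is emitted beside every dataset so tests recover parameters against
the record, not the generator's internals.

Deliberate simplifications, and hence the limits of what passing tests show
about real data: displacements are iid about a shared mean — there are no
correlated loop modes, no anharmonic double-well conformers, no lattice
contacts, no sequence, no side chains, and no refinement-model error in the
B-factors. Parameter recovery on this generator demonstrates that the
statistics detect localized variance of the injected magnitude against the
stated background; it does not demonstrate robustness to correlated motion
or to crystallographic model bias. Conclusions about any real system should
rest on running the same pipeline on deposited structures.

## Problem sizes and determinism in the test suite

The test suite builds everything at run time: ensembles of 10–20 members of
80 residues, trajectories of 120–1600 frames, and 20–100 regenerated
datasets for the rate-style checks (loop-region recovery across 100 seeds;
chain-asymmetry and restraint-ordering checks across 20 seeds each). These
sizes keep the full suite under a minute while leaving the statistical
margins wide — e.g. the loop-recovery check passes at the ≥ 95 % level with
boundary tolerance ± 1 residue. All stochastic tests fix their seeds; the
brute-force superposition oracle used in the tests is a vectorized
Euler-angle grid search refined to 1° (and further for the 10⁻³ Å
equivalence check), kept wholly independent of the SVD code path it
validates.

## Known limitations

- Residue correspondence is by author numbering only; renumbered or
  insertion-code-heavy constructs need preprocessing (insertion codes are
  carried but ordered only within a number).
- Altloc handling keeps a single conformer (highest occupancy, ties by
  altloc id); ensembles of altloc conformers are not expanded.
- Anisotropic B-factors, TLS groups and resolution normalization across
  crystals are not handled.
- Binary MD formats are not read natively; trajectories enter as
  multi-model PDB or TSV frame tables (an explicit nm→Å converter is
  provided).
- The hydrogen-bond proxy is distance-only; no angular criterion.
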
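# conflex

Conformational-diversity profiling of protein structure ensembles, built for
the kind of question posed by tandem PDZ scaffolds such as syntenin-1: when
ten crystals of the same PDZ1–PDZ2 construct are solved, is the variation
seen in one domain's binding-cleft loops an intrinsic property of the protein
or an artifact of crystal packing? `conflex` answers this by treating the
crystallographic copies as a statistical ensemble and cross-checking the
result against molecular-dynamics fluctuations and NMR relaxation data.

The package is aimed at structural biologists and modellers who have:

- several crystal structures (PDB/mmCIF) of the same construct, often with
  two or more copies per asymmetric unit;
- optionally, per-replicate MD trajectory frames; and
- optionally, steady-state heteronuclear NOE peak intensities.

## What it computes

For an ensemble of domain copies restricted to their shared residues
(author numbering), after optimal rigid superposition (Kabsch, SVD-based,
reflection-corrected so det(R) = +1):

- **Pairwise Cα RMSD matrix** over all n(n−1)/2 unordered pairs, with
  agglomerative clustering (UPGMA by default), flat cuts and inter-cluster
  distances, and Newick/TSV export;
- **Per-residue average pairwise RMSD**: for each pair, the per-site
  deviation after global (or core-restricted) superposition, averaged over
  pairs; contiguous runs strictly above a threshold (default 1.0 Å, minimum
  length 2) are called as flexible regions;
- **B-factor profiles**: the member with the highest overall Cα B, the
  per-residue mean over all members, the lowest member, and regions above
  the grand mean;
- **Trajectory RMSF** per Cα after iterative superposition onto the mean
  structure, `RMSF_i = sqrt(mean_t |x_i(t) − ⟨x_i⟩|²)`, with window/stride
  frame selection, replicate mean ± SD, and flagging above 0.12 Å;
- **Heteronuclear NOE ratios** `I_sat / I_unsat` with flagging of runs
  strictly below 0.75;
- **Interdomain contacts**: residue pairs with any heavy-atom distance
  ≤ 4.5 Å, a distance-only N/O–N/O hydrogen-bond proxy at ≤ 3.5 Å, and
  region contact-participation fractions with cutoff-sensitivity sweeps.

A fully seeded synthetic-data generator (`make_crystal_set()`,
`make_trajectory()`, `make_noe_table()`, `make_contact_structure()`)
produces every input with known ground truth, so each stage is verifiable
without downloading deposited structures.

## Worked example

Generate the default synthetic study — 10 crystal-like structures, two
chains each, a PDZ1-like domain (residues 114–193) whose chain-B copies
carry two flexible loops (119–125 and 181–184, per-coordinate σ = 1.5 Å) —
and run the diversity analysis:

```r
library(conflex)

spec <- synthetic_ensemble_spec(seed = 1)
cs   <- make_crystal_set(spec)
res  <- run_diversity(cs$structures, domain = "PDZ1", quiet = TRUE)

res$ensemble
#> <aligned_ensemble> 20 members, 80 common residues (114-193)
res$matrix
#> <rmsd_matrix> 20 members, 190 pairs; RMSD 0.11-1.83 A (mean 0.841)
res$regions
#> # A tibble: 2 × 5
#>   first  last n_res  peak mean_value
#>   <int> <int> <int> <dbl>      <dbl>
#> 1   119   125     7  2.44       1.97
#> 2   181   184     4  2.27       2.09
```

The 20 members are the two chains of the 10 structures; the two called
regions recover the loops the generator made flexible, and their peak
average pairwise RMSD (≈ 2.3–2.4 Å) stands far above the ~0.2 Å scaffold
baseline. The NOE module agrees from the solution side — ratios generated
anticorrelated with the same flexibility dip below the 0.75 flag exactly in
those loops:

```r
sm  <- data.frame(resno = 114:193,
                  sigma = ifelse(114:193 %in% c(119:125, 181:184), 1.5, 0.05))
flag_low_noe(noe_ratio(make_noe_table(sm, seed = 1)))
#> # A tibble: 2 × 5
#>   first  last n_res  peak mean_value
#>   <int> <int> <int> <dbl>      <dbl>
#> 1   119   125     7 0.501      0.550
#> 2   181   184     4 0.556      0.568
```

and a 1600-frame trajectory with per-coordinate σ = 0.4 Å recovers the
analytic fluctuation law:

```r
tr   <- make_trajectory(1600, data.frame(resno = 1:60,
                                         sigma = c(rep(0, 30), rep(0.4, 30))),
                        seed = 1)
prof <- rmsf(tr, fit_selection = 1:30)
mean(prof$value[31:60])
#> [1] 0.691   # sigma * sqrt(3) = 0.693 A
```

Every result type has `tidy()`, `glance()` and `autoplot()` methods, and a
command-line wrapper (`inst/cli/conflex.R`) exposes the stages as
`simulate`, `diversity`, `bfactor`, `rmsf`, `noe` and `contacts`
subcommands.

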
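# trajdiverge

Per-residue divergence analysis for molecular dynamics trajectories.

Long equilibrium simulations of the same protein under two conditions —
for instance a coarse-grained cryptochrome with its flavin cofactor in
different redox states — raise the question of *where* the protein's
conformational behaviour differs. Mobility measures cannot answer it: a
loop can fluctuate strongly in both runs while sampling the same
region, and a quiet residue can sit in two different places.
`trajdiverge` answers it with the symmetrized Kullback–Leibler
divergence between the discretized positional distributions of each
residue's backbone bead:

    KLD(P_i, Q_i) = Σ_k  q_k ln(q_k / p_k)
    KLD_sym(i)    = ½ [ KLD(P_i, Q_i) + KLD(Q_i, P_i) ]

where `P_i`, `Q_i` are 3-D histograms of residue *i*'s position over the
two superposed trajectories, on a shared per-residue bounding box with a
pseudocount so values stay finite. A moving window (at most 50
snapshots, growing at the start and shrinking at the end of the
trajectory) gives the time-resolved variant; windowed maps from a whole
comparison set are normalized by one global constant so that 1.0 marks
the largest difference observed anywhere in the set.

The package is aimed at structural-bioinformatics users comparing
(coarse-grained) MD runs. It provides:

- `readStructure` / `readTrajectory` — GRO, PDB, multi-model PDB,
  binary DCD, and a plain-text TSV fixture format (nm internally;
  Å-based formats converted at the boundary);
- `resolveSelection` — a small selection language
  (`"backbone and resid 440-460"`, `"name FLA1 FLA2 FLA3 FLA4 FLA5"`);
- `kabschSuperpose`, `alignToReference`, `iterativeAlign` — weighted
  rigid-body superposition and the iterative variance-reweighted
  alignment used before divergence calculations;
- `divergenceProfile`, `windowedDivergence`, `normalizeMaps`,
  `detectChangePoint` — the divergence machinery;
- `rmsdSeries`, `distanceSeries`, `sasa` — RMSD in Å, center-of-mass
  distance distributions (e.g. flavin to tryptophan-tetrad residues),
  and Shrake–Rupley SASA with a 0.26 nm coarse-grained probe;
- `generatePair`, `generateGateSystem` — a synthetic trajectory
  generator with planted conformational changes (mean shifts, two-state
  switches, group flips, rigid-body drift) so the entire pipeline is
  testable with known ground truth;
- `comparisonPlan` / `runComparison` — the end-to-end workflow with
  TSV outputs, plus a thin CLI at `inst/scripts/trajdiverge.R`
  (`simulate`, `align`, `compare`, `window`, `rmsd`, `sasa`, `dist`,
  `report`).

## Worked example

Two synthetic 100-residue, 2000-frame trajectories share baseline
thermal noise (σ = 0.1 nm) and independent rigid-body drift; residues
40–60 in the second trajectory are shifted by 0.5 nm:

```r
library(trajdiverge)

cfg <- syntheticConfig(nResidues = 100, nFrames = 2000, seed = 42,
                       events = list(event("mean_shift", 40:60, 0.5)))
p    <- generatePair(cfg)
al   <- iterativeAlign(p$A, p$B, p$A, "backbone")
prof <- divergenceProfile(al$A@trajectory, al$B@trajectory)
prof
#> DivergenceProfile [synthetic_A_seed42 vs synthetic_B_seed42], 100 residues, nats
#>   max 2.862 at residue 60

sort(divergenceValues(prof), decreasing = TRUE)[1:5]
#>    60    52    41    55    49
#> 2.862 2.805 2.790 2.771 2.764

rs <- regionSet(list(shifted = 40:60, flank = 20:39, CT = 80:100))
regionReport(list(pair = prof), regionset = rs)
#>   comparison  region meanDivergence maxDivergence meanRmsd rank degenerate
#> 1       pair shifted          2.700         2.862       NA    1      FALSE
#> 2       pair   flank          0.449         0.526       NA    2      FALSE
#> 3       pair      CT          0.434         0.523       NA    3      FALSE
```

The planted region dominates the profile (~2.7 nats against a ~0.45 nat
background from finite sampling), and the regional report ranks it
first. All 21 shifted residues are the top-21 profile values; the
background level falls as the number of frames grows. For a switch
planted mid-trajectory, `windowedDivergence` + `detectChangePoint`
localize the transition to within one window width.

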
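---
title: "Comparing MD trajectories with per-residue positional divergence"
author: "trajdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing MD trajectories with per-residue positional divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajdiverge)
```

## The question the package answers

Given two long equilibrium simulations of the same protein — say, a
coarse-grained cryptochrome simulated with its flavin cofactor in two
different redox states — *where* does the protein behave differently?
Classical per-residue fluctuation measures (RMSF) answer "where is each
simulation mobile", which is not the same question: a loop can be highly
mobile in both simulations yet explore exactly the same region of space,
and a quiet residue can sit in two different places in the two runs.

The statistic at the core of this package compares, residue by residue,
the *distributions of positions* that the two trajectories realize. For
residue $i$, let $P_i$ and $Q_i$ be the discretized distributions of its
backbone-bead position over the two (superposed) trajectories, with bin
probabilities $p_k$ and $q_k$. The directed Kullback–Leibler divergence

$$\mathrm{KLD}(P_i, Q_i) = \sum_k q_k \ln\frac{q_k}{p_k}$$

is made symmetric by averaging the two directions,

$$\mathrm{KLD}^{\mathrm{sym}}_i = \tfrac12\left[\mathrm{KLD}(P_i,Q_i)
  + \mathrm{KLD}(Q_i,P_i)\right],$$

yielding one nonnegative number per residue: zero when the two clouds
coincide, large when a residue occupies genuinely different regions in
the two runs. Because distributions — not frame-by-frame displacements —
are compared, shared thermal motion is suppressed: two equally mobile
but identically distributed residues score near zero
(`divergenceProfile` tests verify this directly). The time-resolved
variant evaluates the same statistic in a moving window so that one can
see *when* a difference develops.

## The processing chain and its assumptions

1. **Superposition.** Every frame of both trajectories is superposed on
   the first frame of a designated reference trajectory by weighted
   least-squares rigid-body fitting (Kabsch, with the SVD sign
   correction so reflections are never produced). Alignment is
   iterative: after a uniform-weight pass, the per-residue positional
   variance pooled over both aligned trajectories is computed and the
   weights are reset to $w_i = 1/(\sigma_i^2 + \varepsilon)$, scaled to
   a maximum of 1, before realigning. Mobile loops thus stop steering
   the fit, which would otherwise smear their apparent motion over the
   rigid core. Iteration stops when the mean per-frame rotation change
   drops below `tol` (default $10^{-3}$ rad) or after `maxIter`
   (default 10) passes; running out of iterations is reported in the
   result, not an error. The regularizer $\varepsilon = 10^{-4}$ nm²
   bounds the weight contrast where residues are nearly rigid.
   Residue correspondence across trajectories is by index — the package
   does no sequence alignment.
2. **Discretization.** For each residue, a joint axis-aligned bounding
   box is computed over *both* trajectories' positions of that residue,
   padded by one bin on every side, and subdivided into cubic bins of
   `binWidth` (default 0.1 nm, about half a coarse-grained bead
   diameter; residue-local boxes keep bin counts in the hundreds).
   Sharing the box guarantees both histograms live on identical
   geometry. A pseudocount (default 0.5 per bin) is added before
   normalization so that every $\ln(q_k/p_k)$ is finite; the divergence
   of two identical samples is exactly zero because equal counts,
   equal $n$ and equal pseudocount make $p_k = q_k$ bin by bin.
3. **Windows.** The moving window holds at most $W$ snapshots (default
   50): window $w$ covers snapshots $\max(1, w-W+1)$ to $\min(w, N)$,
   so the window grows from a single snapshot, slides at full width,
   and shrinks from the left after the trajectory end — the map has
   $N + W - 1$ rows. All windows of a residue reuse the joint box of
   the full trajectories, which makes a window spanning all snapshots
   *bit-identical* to the whole-trajectory profile (and the test suite
   asserts exactly that).
4. **Normalization.** Windowed maps from all comparisons of one study
   are divided by the single largest value across the whole set, so
   1.0 marks the largest difference observed anywhere and maps remain
   mutually comparable. Per-comparison normalization is available
   behind a flag.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `binWidth` | 0.1 | nm | histogram resolution; smaller resolves finer differences but raises small-sample noise |
| `pseudocount` | 0.5 | counts/bin | keeps divergences finite; sets the saturation level for disjoint clouds |
| `W` | 50 | snapshots | time resolution of the windowed map |
| `tol`, `maxIter` | 1e-3 rad, 10 | — | alignment convergence |
| `eps` | 1e-4 | nm² | variance-reweighting regularizer |
| `probe` | 0.26 | nm | SASA probe, one regular coarse-grained bead radius |
| `nPoints` | 960 | — | quadrature points per bead (deterministic spiral) |

The logarithm base is $e$ (nats) with a `bits` option; the base only
rescales values. The symmetrization convention (arithmetic mean of the
two directions) is recorded in every result object so downstream
comparisons are self-consistent.

## Small-sample behaviour of the windowed estimator

The plug-in KLD estimator on a $W$-snapshot window is biased upward for
*identical* distributions: with $W = 50$ points in a 3-D histogram whose
bin width matches the fluctuation scale, most occupied bins hold one or
two counts, and two independent samples of the same distribution rarely
occupy the same bins. Measured on the default synthetic conditions
($\sigma = 0.1$ nm, bin 0.1 nm, pseudocount 0.5), this noise floor sits
near 0.04 nats while the plateau of a fully developed 0.5 nm two-state
shift is near 0.08 nats — the baseline is a substantial fraction of the
plateau, which any change-point rule must respect. `detectChangePoint`
therefore thresholds at the midpoint between a baseline estimate (lower
quantile of the window signal) and a plateau estimate (upper quantile),
and requires the signal to stay above threshold for several consecutive
windows before declaring a transition. When the baseline is negligible
this reduces to "half the plateau"; at realistic window sizes it is the
rule that actually localizes a planted switch to within one window
width, which the acceptance suite verifies over 20 seeds. The
full-trajectory profile does not suffer from this floor in the same
way: its bias shrinks as $n$ grows, and the null-calibration test
(99th profile percentile falling with $n$) checks that consistency.

## What the synthetic generator does and does not emulate

`generatePair` produces two bead-per-residue trajectories sharing an
ideal-helix reference geometry (rise 0.15 nm, radius 0.23 nm,
100°/residue — chosen so residue ranges map to spatially coherent
segments) with: independent isotropic Gaussian fluctuation per residue
(default $\sigma = 0.1$ nm, a typical coarse-grained backbone RMSF);
independent rigid-body random walks per trajectory (rotation step 0.02
rad/frame, translation step 0.01 nm/frame — large enough that skipping
alignment ruins the analysis, small enough that consecutive frames
overlap, as in a real unwrapped trajectory); and planted events —
persistent mean shifts, two-state switches, and the exchange of two
residue groups' mean positions (a side-chain-flip analog, which needs an
explicit partner group). Defaults are 100 residues × 2000 frames. One
RNG stream is seeded once and consumed in fixed order, so adding an
event never perturbs other residues' draws and identical configurations
give bit-identical fixtures.

This model satisfies the divergence machinery's assumptions *exactly*
(per-residue positional distributions, stationary within a state),
which is the point: recovery failures indict the implementation, not
the model. It deliberately omits what real trajectories add: bonded
constraints, excluded volume, correlated collective motions,
non-Gaussian multi-well kinetics and periodic-boundary artifacts.
Passing the planted-recovery tests therefore demonstrates correctness
of the machinery, not statistical power on real proteins; on real data
correlated motion can spread divergence over neighbouring residues, and
alignment weights interact with genuinely mobile regions.

## Geometry analyses

RMSD series are computed against a reference frame with *no*
re-superposition, so a region's series on a globally aligned trajectory
reports how the region moves relative to the protein frame; values are
returned in Å (the plotting convention), coordinates are nm internally
throughout. Center-of-mass distances (e.g. flavin beads FLA1–FLA5 to a
tryptophan of the electron-transfer tetrad) are rigid-motion invariant,
so they need no alignment; the summary keeps min, max and mean, the
quantities distance-distribution plots are built from. SASA uses
Shrake–Rupley with a deterministic generalized-spiral point set (960
points/bead) and a 0.26 nm probe matching a regular coarse-grained
bead; context beads occlude without contributing area. Bead radii
default to 0.26 nm and can be overridden per bead. The quadrature is
deterministic by design so SASA results are exactly reproducible;
accuracy at 960 points is well under the 1–2% the validation demands.

## Numerical and design choices

- All user-facing indices (residues, frames, windows) are 1-based;
  ranges are inclusive. This matches how residue ranges like "440–460"
  are quoted in structural biology and avoids a mixed convention inside
  R.
- The windowed KLD inner loop is compiled (Rcpp): per window, counts
  are rebuilt from at most $W$ snapshots and the divergence is summed
  over occupied bins only — exact, because bins empty in both
  histograms contribute zero when $n$, bin count and pseudocount agree
  on both sides.
- Snapshot pairing across trajectories is positional after truncating
  both to the shorter length (with a warning); only the counts matter
  for equilibrium distributions, and truncation keeps window indices
  aligned between maps.
- Degenerate superpositions (fewer than 3 points, collinear sets) are
  errors; non-convergence of the iterative alignment is a flag plus
  warning, since the aligned coordinates are still usable.
- Window right edges label the map's time axis; trailing (shrinking)
  windows share the final snapshot as right edge and are reported with
  their explicit start/end ranges.
- The phosphate-binding-loop residue span is configuration-supplied
  with no default: loop boundaries are structure- and
  numbering-specific, and a wrong silent default would corrupt regional
  reports. The EEE (440–460), OPP (80–90) and C-terminal (480–end)
  regions default to their conventional spans.
- Validation problem sizes: recovery experiments run 20 seeds at the
  generator defaults (100 residues × 2000 frames); oracle equivalence
  uses 200 random histogram pairs; the Monte-Carlo SASA cross-check
  uses $10^5$ surface points. These sizes give the properties under
  test comfortable margins while keeping a full validation run in
  minutes on one core.

## Known limitations

Absolute divergence values depend on bin width and pseudocount, which
the original figure conventions leave free; profiles are therefore
comparable within a configuration, and the windowed maps are reported
normalized. The analysis assumes unwrapped trajectories (no
periodic-boundary handling) and index-based residue correspondence.
KLD peaks carry no significance calibration — the package flags *where*
distributions differ, not whether the difference exceeds sampling
noise, beyond what the null-calibration behaviour documents. SASA is
bead-level (no volumetric decomposition), and the CLI's binary
trajectory support covers the DCD class; XTC requires conversion
upstream.
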
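---
title: "Methods: receptor-vesicle geometry and calcium-driven secretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor-vesicle geometry and calcium-driven secretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Chromaffin cells of the adrenal medulla release catecholamines by regulated
exocytosis. The trigger is acetylcholine acting on α3β4 nicotinic receptors
(nAChRs): cation channels that depolarize the cell and, to a small degree
(~2.5% of their current), conduct Ca²⁺ themselves. If nAChR clusters sit
*next to* the secretory machinery (SNAP-25 clusters, recent-fusion sites
marked by surface DBH), even that small direct calcium flux can load the
fusion sensors of nearby docked vesicles and accelerate the onset of
release. `chromsec` provides the two computational halves of that argument:

1. **Image statistics** quantifying whether receptor patches really are
   closer to secretory sites than chance predicts (nearest-centroid
   distances against a randomized-mask null; Pearson and Manders
   colocalization coefficients).
2. **A particle-based stochastic simulator** of calcium entry through
   gating nAChRs, buffered diffusion and vesicle fusion in a conical
   sub-membrane domain, contrasting *random* and *colocalized*
   channel-vesicle geometries.

Because the underlying micrographs are not publicly deposited, the package
also ships a synthetic two-channel image generator with known ground truth,
so every statistic can be validated end to end.

## The gating model

The receptor is a seven-state continuous-time Markov chain:

```
C0 = C1 = C2 = O,   O = D = D2,   O = B
```

`C0`-`C2` are the unliganded, mono- and doubly-liganded closed states (the
binding chain carries the standard 2x statistical factors for two
equivalent agonist sites); `O` is the single conducting state; `D`/`D2`
a fast desensitization branch; `B` a slow agonist-driven inactivated state.
Default rate constants (100 µM ACh):

| parameter | value | units | role |
|---|---|---|---|
| k₊ | 227 | µM⁻¹s⁻¹ | ACh binding |
| k₋ | 38,541 | s⁻¹ | ACh unbinding |
| β / α | 50,600 / 2,024 | s⁻¹ | opening / closing |
| k₊g / k₋g | 49 / 512 | s⁻¹ | desensitization |
| k₊b / k₋b | 241.5 / 0.3 | M⁻¹s⁻¹ / s⁻¹ | slow inactivation |
| f_Ca | 0.025 | — | calcium fraction of the current |
| i_unit | 2 | pA | single-channel current (not a published value; configurable) |

**The one genuinely open design choice** is the agonist scaling of the `B`
step. Read with a per-micromolar convention, `k₊b·[ACh]` at 100 µM equals
24,150 s⁻¹ against a recovery of 0.3 s⁻¹: every channel would be trapped
within ~10 ms, the agonist-evoked current would collapse to a
sub-millisecond spike, and a 1-s pulse could not produce sustained
sub-membrane calcium or secretion — contradicting both the slow
(seconds-scale) inactivation of bovine chromaffin nAChR currents that this
constant was calibrated against and the simulated 1-s responses the model
is meant to reproduce. `chromsec` therefore applies the printed digits
with the *molar* convention used elsewhere in the same parameter set
(buffer binding is quoted in M⁻¹s⁻¹), giving an O→B rate of 0.024 s⁻¹ at
100 µM, a seconds-scale sag of the open probability (stationary open
occupancy ≈ 0.68), and physiologically sensible 1-s behavior. The choice
is one argument away (`build_rate_graph(b_step = "per_uM")` restores the
literal reading, `"const"` removes the agonist dependence), and the graph
itself is data (JSON-serializable states/edges), so an alternative
topology can be substituted without touching code. All tests are
topology-independent: the stochastic sampler is always checked against
the master-equation/null-space oracle of whatever graph is supplied.

Deterministic propagation uses the matrix exponential of the generator;
the stationary law comes from the SVD null space of the transposed
generator — an oracle independent of any time stepping. The stochastic
ensemble sampler advances aggregated per-state counts with sequential
binomial draws, sub-stepping so every per-substep exit probability stays
below 0.1.

## The secretion simulator

**Domain.** A cone of base radius 1 µm and height 5 µm — the sub-membrane
wedge of a spherical cell reaching its center — discretized on a regular
orthogonal grid with Δx = 70 nm (~15,300 voxels). Slice 0 (the base)
represents the plasma membrane and carries the channels and vesicles.
Boundaries reflect ("bounce back"): by symmetry the lateral flux out
equals the flux in, so no ions are exchanged across the walls.

**Particles.** The fundamental variables are integer molecule counts.
Free Ca²⁺ ions random-walk on the lattice (move probability `6·D·dt/dx²`,
D = 220 µm²s⁻¹; the master step `dt = dx²/(6D) ≈ 3.7 µs` saturates the
stability bound). One molecule per (70 nm)³ voxel ≈ 4.84 µM. An immobile
endogenous buffer (500 µM, k_on = 5·10⁸ M⁻¹s⁻¹, K_d = 10 µM) occupies
each voxel with a fixed integer total (103 sites/voxel); binding and
unbinding are sampled per event with probabilities `1 − exp(−k·dt_s)`,
sub-stepped so each probability stays ≤ 0.1. (The fused kernel compounds
the substep probabilities into one draw per molecule per master step —
`p = 1 − (1 − p_s)^n` for binding, with unbinding candidates given their
within-step rebind chance over a uniformly drawn remainder of substeps —
which reproduces the substep-resolved bind/unbind equilibrium at a fifth
of the cost; the R-level `reaction_step()` keeps the explicit substep
loop and serves as its reference.) Vesicles occupy one membrane
voxel each, sense only that voxel's free calcium, carry three
non-cooperative sites (k_on = 8·10⁶ M⁻¹s⁻¹, K_d = 13 µM) and fuse
irreversibly at 1000 s⁻¹ once all three are occupied; fusion is evaluated
on the state at step entry, so a fully bound cohort fuses at exactly the
nominal hazard over one step.

**Coupling.** Each master step: (i) channel gating (per-channel jump
sampling, sub-stepped); (ii) a Poisson number of ions injected at each
open channel's membrane voxel with mean `f_Ca · i_unit /(2e) · dt`
(≈ 1.56·10⁵ ions/s per open channel at the defaults); (iii) diffusion;
(iv) buffer and vesicle kinetics. Basal calcium (0.1 µM) is placed as
per-voxel Poisson counts and pre-equilibrated against the buffer for
10 ms before the pulse. An integer conservation ledger (injected + basal =
free + buffer-bound + vesicle-bound + consumed) must balance exactly at
every recorded step, and does.

**Geometries.** `random` scatters vesicles uniformly over free membrane
voxels; `colocalized` first places the channels, then fills the nearest
available distinct voxels (ties broken reproducibly). Channels and
vesicles never share a voxel — a vesicle and a channel cannot occupy the
same membrane patch. Paired configurations share the channel-placement
seed so geometry is the only difference.

**Choices the published description leaves open** (all config-exposed): the vesicle count
(default 10; outputs are percentages so the statistics do not depend on
it), the fate of vesicle-bound calcium after fusion (retired from the
ledger as "consumed" — fusion releases the granule contents, not sensor
calcium), the single-vesicle sensing volume (its own voxel), and i_unit
(2 pA, an order-of-magnitude single-channel amplitude).

**Numerics worth knowing.** The per-event probability cap (0.1) bounds the
operator-splitting bias of the bind/unbind equilibrium at ~4% on the
bound:free ratio at the master step; validation tests choose smaller
probabilities (≤ 0.005), where the bias is far below their 3-standard-
error resolution. Halving `dt` moves the replicate-averaged release by
less than three replicate standard errors (tested). The hot loops draw
from an inline xoshiro256++ generator seeded from R's RNG, so `set.seed`
still makes entire runs bit-reproducible; low-rate draws (gating,
injection, binomial counts) stay on R's own generator.

## Image statistics

- **Threshold**: a pixel survives at 50% of the channel's maximum
  intensity *within the cell mask*. The reference level is not defined in
  the original ImageJ-based workflow; 50%-of-max is the shipped default, and a
  background-subtracted variant (50% of the dynamic range) is available.
- **Patches**: 8-connected components of ≥ 4 pixels; area = pixel count ×
  pixel area; centroid = unweighted mean of pixel centers; equivalent
  diameter `2·sqrt(area/π)`.
- **Proximity**: per reference patch, the Euclidean XY distance to the
  nearest query centroid. Distances beyond the isolation cutoff — twice
  the mean secretory-patch equivalent diameter, 0.756 µm for the reported
  0.378 µm mean — are flagged "isolated" and excluded from the summary
  mean. The cutoff uses the mean of per-patch diameters, not the diameter
  of the mean area (which would give ≈ 0.391 µm from the same data); both
  conventions are exposed.
- **Null**: as many circular masks as real receptor patches (diameter
  0.397 µm), centers uniform over the cell mask (a uniformly chosen mask
  pixel plus a uniform within-pixel offset — exactly uniform over the
  region, with none of rejection sampling's termination worries), masks
  free to overlap.
- **Colocalization**: Pearson correlation over the ROI and Manders
  M1/M2 on the thresholded masks. Undefined cases (constant channel, zero
  denominator) are reported as `NA`, never silently zero.

## The synthetic-data generator

Green "secretory" disks (diameter 0.378 ± 0.020 µm) in a disk-shaped cell
(radius 6 µm, ~14 patches — the per-cell scale implied by ~345 patches
over 24 cells), each paired with a red "receptor" disk (0.397 ± 0.021 µm)
displaced by an isotropic 2D Gaussian of scale σ (displacement lengths are
then Rayleigh(σ), mean σ·√(π/2)); a configurable fraction of unpaired red
patches placed ≥ 0.756 µm from any green patch so that ground-truth
isolation matches the pipeline's definition; anti-aliased rendering, then
optional Gaussian PSF blur and Gaussian/Poisson noise. Same-channel
patches keep a minimum separation (1.2× the mean diameter) so labeling
recovers the true count — real micrographs do have merging patches, so a
green test here certifies the measurement chain, not segmentation of
overlapping structures. The default σ = 0.2 µm puts the mean pair distance
at ≈ 0.25 µm, between the reported stimulated (0.18-0.31 µm) means.

What the generator does *not* emulate: realistic optics (full PSF,
spectral bleed-through), 3D stacks, intensity heterogeneity within
patches, clustered (non-Poisson) backgrounds. Conclusions about those
belong to real data.

## What the acceptance checks establish

The experimental distance/coefficient tables derive from micrographs that
are not available, so acceptance is property-based: the gating sampler
against its master-equation oracle; lattice MSD against 6Dt; buffer
equilibrium against B/(B+K_d); the fusion hazard against its exponential
law; the randomized null against the 2D-Poisson nearest-neighbor closed
form 1/(2√λ); Rayleigh-σ recovery within 10%; the printed worked examples
(0.756 µm cutoff, toy coefficient vectors); and the headline qualitative
result — across ≥ 20 paired seeds, colocalized geometries release
earlier than random ones (one-sided paired Wilcoxon on the area under the
cumulative-release curve, α = 0.05). The secretion replica is scaled
(0.2-s pulse, one replicate per arm) to fit a single-CPU budget; the
effect it certifies is the early-phase geometry contrast, not the full
1-s release magnitude.

## Known limitations

- The exact seven-state gating topology is not published alongside its
  rate constants; the shipped chain is a standard reconstruction, and the
  data-driven graph makes substitution trivial.
- The single-channel current is not printed either; absolute current,
  calcium and release *magnitudes* therefore inherit i_unit's
  uncertainty. Geometry contrasts (random vs. colocalized) are internally
  controlled and robust to it.
- Operator splitting at the master step slightly biases the instantaneous
  bound:free calcium ratio (see above); all quantitative validation runs
  at small per-step probabilities.
- The proximity pipeline is 2D (XY in the imaging plane) by design.
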
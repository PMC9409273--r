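# chromsec

Stochastic modeling of calcium-driven secretion and receptor-vesicle
colocalization in chromaffin cells.

## The problem

Chromaffin cells secrete catecholamines when acetylcholine opens α3β4
nicotinic receptor channels (nAChRs). Besides depolarizing the cell,
these channels carry a small fractional calcium current (f_Ca ≈ 2.5%). If
receptor clusters sit next to the secretory machinery — SNAP-25 clusters
and recent-fusion sites marked by surface DBH — that local calcium can
pre-load the fusion sensors of docked vesicles and speed up the onset of
release. `chromsec` is for cell physiologists and modelers who want to
test both halves of that idea computationally:

- **Is the proximity real?** Patch statistics for two-channel cortical
  images: 50% thresholding, 8-connected patch extraction,
  nearest-centroid distances `d_i = min_j ‖c_i − q_j‖` with an isolation
  cutoff (2× the mean secretory-patch equivalent diameter,
  `d_eq = 2√(A/π)`), a randomized-mask null (uniform centers over the
  cell mask; mean nearest-neighbor distance `1/(2√λ)` for density λ),
  and Pearson / Manders coefficients
  `M1 = Σ R_i·1[G_i ∈ mask] / Σ R_i`.
- **Does proximity matter?** A particle-based Monte Carlo simulator: a
  7-state Markov nAChR gating model (binding chain C0⇌C1⇌C2, gate C2⇌O
  with β/α = 50,600/2,024 s⁻¹, desensitization O⇌D⇌D2, slow inactivation
  O⇌B), Poisson calcium injection `f_Ca·i_unit/(2e)` per open channel,
  lattice diffusion (D = 220 µm²/s, Δx = 70 nm) with an immobile 500 µM
  buffer (K_d = 10 µM) in a cone (base 1 µm = membrane, height 5 µm), and
  vesicles with three non-cooperative Ca²⁺ sites (K_d = 13 µM) fusing at
  1000 s⁻¹ — comparing **random** vs. **colocalized** channel-vesicle
  geometries.
- **Known ground truth.** A synthetic two-channel image generator
  (Gaussian-displaced patch pairs, Rayleigh(σ) displacement lengths) so
  the whole pipeline is testable without experimental data.

## Worked example 1: proximity vs. the randomized null

```r
library(chromsec)
cells <- lapply(1:10, function(i) image_scenario(sigma = 0.2, seed = 100 + i))
study <- run_proximity_study(cells, seed = 1)
study
#> <proximity_study> 10 cells; cutoff 0.752 um
#>   real mean distance: 0.239 um; null mean distance: 0.437 um
#>   one-sided paired Wilcoxon (real < null): p = 0.000977
```

Ten synthetic cells with receptor patches displaced σ = 0.2 µm from
secretory patches. The auto-cutoff (twice the measured mean green patch
diameter) lands at 0.752 µm, reproducing the 0.756 µm convention; the
measured mean retained distance (0.239 µm ≈ σ√(π/2)) sits far below the
matched random-mask null (0.437 µm), and the paired one-sided Wilcoxon
test over cells confirms the separation.

## Worked example 2: colocalized geometry releases earlier

```r
cfg <- sim_config(mode = "colocalized", pulse_s = 0.2, n_replicates = 2, seed = 1)
res <- run_pulse(cfg)
res
#> <sim_result> mode = colocalized, 7 channels, 10 vesicles, pulse 0.2 s, 2 replicate(s)
#>   final mean release: 35.0%; peak mean slice-0 [Ca]: 2.82 uM
as.data.frame(res)[c(50, 100, 150, 201), ]
#>  time_s mean_current_pA mean_ca_slice0_uM mean_release_pct
#>  0.0499           0.225              1.13                0
#>  0.0999           0.200              1.44                0
#>  0.1498           0.225              2.15               25
#>  0.2000           0.250              2.82               35
```

Seven channels at 100 µM ACh inject ~0.3 pA of calcium current; the mean
free [Ca²⁺] in the 0-70 nm membrane layer climbs into the low-micromolar
range (small next to voltage-gated calcium channel domains, but enough),
and vesicles begin to fuse within the first 0.2 s. The paired study
(`run_secretion_study(...)`) runs the same seeds in both geometries —
channel placements shared, vesicle placement the only difference — and
tests one-sidedly that colocalized releases earlier (by area under the
cumulative-release curve).

Every replicate carries an integer conservation ledger (injected + basal
= free + buffer-bound + vesicle-bound + consumed) that must balance
exactly; `conservation_ledger(res)` exposes it.

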
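# kneepca

Post-hoc correction of kinematic **cross-talk** in 3-D knee joint angles.

In marker-based gait analysis the knee is described by three Cardan angles
— flexion/extension (α), ab/adduction (β), axial rotation (γ). Because the
segment coordinate systems are built from palpated skin markers, small
placement errors reorient the frames, and the large flexion waveform leaks
into the two small channels: varus/valgus curves of 10° and more appear in
knees that can mechanically move a few degrees in the frontal plane. This
package removes that artifact for people doing clinical and research gait
analysis: movement scientists, physiotherapy researchers, and anyone whose
frontal-plane knee curves look suspiciously like scaled flexion.

## The method

For each subject and side, all gait cycles (time-normalized to 101 points)
are stacked into an (n·101)×3 matrix and one PCA is fitted:

- covariance **C** of the mean-centered angle columns; eigenvalues
  λ₁ ≥ λ₂ ≥ λ₃ with unit eigenvectors w_j and variance contributions
  δ_j = λ_j / Σλ;
- the eigenvectors are arranged into an orthonormal **transfer matrix P**:
  the column permutation maximizing Σ|P_ii| is selected by exhaustive
  enumeration, then column signs are flipped so every diagonal entry is
  ≥ 0;
- corrected angles are the principal components of the *uncentered*
  samples: **(ψ, ξ, ρ)ᵀ = Pᵀ (α, β, γ)ᵀ**;
- the same P corrects the static posture trial, so the corrected
  varus/valgus can be compared against a radiographic measurement.

Corrected components are exactly uncorrelated over the stacked samples
(cross-talk r² = 0 to machine precision), total centered variance is
conserved (P is orthonormal), and static deformities pass through the
rotation instead of being subtracted.

The package also ships the surrounding pipeline: rotation algebra with a
configurable Cardan sequence, raw-trial preprocessing (cubic-spline gap
filling, GCV smoothing splines, coordinate-based heel-strike/toe-off
detection, 101-point stride normalization), evaluation statistics
(cross-talk r², profile variance δ², posture-versus-radiograph errors,
group summaries), a seeded synthetic gait generator with known ground
truth, and plain CSV/JSON interchange.

## Worked example

```r
library(kneepca)

cfg <- gait_sim_config(deformity = 5, seed = 2)  # OA-like: +5 deg varus truth
sim <- simulate_subject(cfg)                     # 20 cycles + posture, 10 deg misalignment
fit <- crosstalk_pca(sim$observed)
summary(fit)
```

```
Cross-talk PCA correction: subject SYN01, right side, 20 cycle(s)
Transfer matrix P (observed angles -> principal axes):
              psi     xi     rho
flexion    0.9878 0.1430 -0.0612
abduction -0.1429 0.9897  0.0056
rotation   0.0614 0.0032  0.9981
Permutation: 1 3 2  signs: +-+
Variance contributions: 0.963241 0.032206 0.004553

Cross-talk r^2 (flexion vs abduction): 0.8074 -> 2.303e-30
Profile variance, flexion   (deg^2): 322.3 -> 330.3
Profile variance, abduction (deg^2): 7.425 -> 0.6891
Profile SD,       abduction (deg)  : 2.725 -> 0.8301
Posture abduction (deg): 3.541 -> 4.754
```

Reading this: the observed abduction channel was 81 % explained by flexion
(r² = 0.81); after correction the correlation is annihilated. The spurious
frontal variance (7.4 deg², SD 2.7°) collapses to a physiological 0.69 deg²
(SD 0.83°) and reappears in flexion (322 → 330 deg²) — the transform moves
variance, it does not delete it. The posture trial, measured at 3.54° under
the misaligned frames, is restored to 4.75°, close to the generator's true
5° deformity. `plot(fit)` draws the before/after mean profiles;
`predict(fit, newdata)` applies the fitted P to new cycles or a posture
triple.

A thin command-line front end over the same functions is provided in
`inst/scripts/kneepca-pipeline.R` (subcommands `simulate`, `correct`,
`evaluate`, `pipeline`).

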
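---
title: "Correcting knee joint angle cross-talk with per-subject PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting knee joint angle cross-talk with per-subject PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
```

```{r setup}
library(kneepca)
```

## The problem

Optical gait analysis reports knee motion as three Cardan angles: the
rotation between femur and tibia frames is decomposed into flexion/extension
(about the mediolateral axis), ab/adduction (anterior axis) and axial
rotation (longitudinal axis), in that sequence. The segment frames are
constructed from skin markers placed on palpated bony landmarks. A few
degrees of error in that construction reorients the frames, and because the
knee articulates overwhelmingly about one axis, the large flexion waveform
leaks into the two small channels. This *cross-talk* inflates varus/valgus
curves well beyond the few degrees a healthy knee can mechanically produce,
and it is the dominant artifact in frontal-plane knee kinematics.

## The correction

Let $x_t = (\alpha_t, \beta_t, \gamma_t)^\top$ be the observed angle triple
at sample $t$, with all gait cycles of one subject and side stacked into an
$(n \cdot 101) \times 3$ matrix. The correction fits one principal
component analysis per subject/side:

1. compute the covariance $C$ of the mean-centered columns;
2. take eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$ and unit
   eigenvectors $w_j$; the fractions $\delta_j = \lambda_j / \sum_k
   \lambda_k$ summarize how much variance each principal axis carries;
3. arrange the eigenvectors into an orthonormal *transfer matrix* $P$:
   among the six column permutations the one maximizing
   $\sum_i |P_{ii}|$ is chosen (each principal axis is matched to the
   anatomical angle it most resembles), then column signs are flipped so
   that every diagonal entry is nonnegative (corrected flexion increases
   with observed flexion);
4. corrected angles are the principal components of the *uncentered*
   observations, $(\psi_t, \xi_t, \rho_t)^\top = P^\top x_t$.

The corrected components are exactly uncorrelated over the stacked samples
-- cross-talk, measured as the squared correlation between the flexion and
ab/adduction channels, is annihilated to machine precision -- and because
$P$ is orthonormal, total centered variance is conserved: the correction
moves the leaked variance back into flexion/extension rather than deleting
it. Applying $P^\top$ to uncentered angles matters: static offsets, such as
a fixed varus deformity, must pass through the transform rather than being
subtracted, which is what makes the last step possible:

5. the same $P$ is applied to the mean angles of a static posture trial, so
   the corrected frontal-plane angle can be compared with a radiographic
   varus/valgus measurement taken in the same position.

The underlying hypothesis is anatomical: true knee motion has a dominant
flexion axis and essentially uncorrelated residual components, so the
principal axes of the observed cloud are the misaligned images of the
anatomical axes.

```{r}
cfg <- gait_sim_config(deformity = 5, seed = 2)
sim <- simulate_subject(cfg)
fit <- crosstalk_pca(sim$observed)
summary(fit)
```

```{r, fig.height = 3}
plot(fit)
```

## Assumptions, and when they fail

* **One dominant axis.** $\lambda_1$ must belong unambiguously to flexion.
  True for gait; not necessarily for joints or tasks without a dominant
  rotation.
* **Uncorrelated true components.** Any genuine correlation between true
  channels -- for instance flexion-coupled axial rotation (screw-home) --
  is indistinguishable from cross-talk and is partly removed. The
  generator's `coupling` parameter exists precisely to study this: with
  `coupling > 0` the corrected axial rotation is a rotated mixture, not the
  true one.
* **Identifiable small axes.** The frontal and axial principal axes are
  separated only as far as $\lambda_2 \neq \lambda_3$. Physiologically the
  axial range (~10-15 degrees) comfortably exceeds the frontal range
  (~3 degrees), which is what keeps the assignment stable under
  stride-to-stride noise. Near-degenerate spectra are flagged
  (`eigen_summary()$degenerate`), and a covariance of rank < 2 is refused.
* **Linearity.** The transform is linear while Cardan composition is not,
  so the correction is exact only to first order in the misalignment; see
  *Limitations*.

## The misalignment model in the generator

A coordinate-system error is a rigid rotation $D$ of the segment frames.
Three frame models are implemented in `apply_misalignment()`:
`"proximal"` ($D R$), `"distal"` ($R D$) and `"shared"`
($D R D^\top$). The generator defaults to `"shared"` about the
longitudinal axis: the Plug-in-Gait-style knee marker defines the flexion
axis of *both* the thigh and shank frames, so misplacing it reorients both
frames together, and a transverse-plane malrotation of the flexion axis is
the classic mechanism converting flexion into spurious varus/valgus
(observed ab/adduction error $\approx -\sin m \, \sin\alpha$, plus an
axial error $\approx -m(1 - \cos\alpha)$).

Two alternatives were considered and rejected as defaults, though both
remain available. A proximal-only error adds a constant to the axial
channel; an anterior-axis error adds a constant to the frontal channel. A
linear map without translation cannot restore constants that arise
nonlinearly, so such errors are provably beyond any transfer-matrix
correction -- worth simulating when studying failure modes, but not as the
canonical cross-talk mechanism.

## What the generator emulates

`gait_sim_config()` fixes the study conditions; defaults were chosen once,
on physiological grounds:

| parameter | default | rationale |
|---|---|---|
| flexion waveform | bumps of 12 and 57 degrees over a 3 degree baseline at 14 % and 72 % of the cycle | stance peak ~15 degrees, swing peak ~60 degrees, the canonical double-bump profile |
| `abd_amplitude` | 1.5 degrees | true frontal oscillation of ~3 degrees range; the asymptomatic envelope is ~7 degrees (`abd_bound`), enforced by rescaling |
| `rot_amplitude` | 6 degrees | axial range ~12 degrees, typical for gait; also what makes the frontal/axial axes identifiable |
| `coupling` | 0.15 | modest screw-home coupling from centered flexion into axial rotation |
| `noise_sd` | 1 degree | smooth stride-to-stride variability: Gaussian knots at 13 points splined over the cycle, not white noise, so smoothing is non-trivial |
| `mis_range` | 8-15 degrees | cohort misalignment magnitudes, drawn uniformly per subject |
| `posture_flexion` | 8 degrees | mild flexion contracture typical of the OA patients whose posture trials matter |
| `n_subjects`, `n_cycles` | 20, 20 | cohort and per-subject sizes used throughout the tests and the acceptance script |

The true frontal and axial oscillations are constructed orthogonal, over
the 101-point grid, to the flexion waveform and to each other
(`coupling` then re-introduces correlation deliberately). This is not a
convenience: zero true cross-axis correlation is the exact condition under
which the principal axes coincide with the anatomical axes, i.e. the
condition the method itself assumes. Same-frequency sinusoids with random
phases would be mutually correlated by $\cos\Delta\phi$ and would make
ground-truth recovery untestable for reasons unrelated to the method.

The generator does **not** emulate: soft-tissue artifact, marker-level 3-D
trajectories, asymmetric left/right mechanics, speed-dependent waveform
changes, or non-stationary (fatigue-like) drift. Passing tests therefore
demonstrate correctness of the estimator under its stated assumptions, not
robustness to everything real data can do.

## Numerical and design choices

* **Covariance divisor** is $1/(n-1)$ by default (`"ml"` gives $1/n$);
  eigenvectors and $\delta_j$ are unaffected by the choice.
* **Cross-talk $r^2$** is computed, by default, over the stacked samples --
  the observations the PCA decorrelates -- so the corrected value is zero
  to machine precision. `r2_mode = "profile"` instead correlates the two
  101-point mean profiles; with cycle noise the corrected profile value is
  near but not exactly zero (the fit is on stacked samples, not profiles).
  Profile variances are reported as variances (squared degrees), with SDs
  (degrees) alongside in summaries, since the latter is often the scale
  reported in gait tables.
* **Sorting ties** (score difference below 1e-12) are broken by the
  lexicographically smallest permutation and flagged; they do not occur on
  physiological data, where flexion variance dominates.
* **Gimbal lock** is declared within 1e-6 rad of a +/-90 degree middle
  angle -- far outside the knee's range; decomposition errors there are
  raised, not patched.
* **Gap filling** uses cubic interpolating splines with the "fmm" end
  condition (exact for cubic polynomials); gaps of at most 9 frames are
  filled and any stride still containing a gap of 10 or more frames is
  rejected, with the rejection logged so cycles in = cycles out + rejected.
* **Smoothing** uses a cubic smoothing spline with GCV-chosen roughness by
  default; an explicit roughness of 0 is the interpolating limit and
  returns the input unchanged.
* **Time normalization** resamples each heel-strike-to-heel-strike stride
  at 101 equally spaced points with the same spline family, and is
  idempotent on already-normalized cycles.
* **Left/right conventions**: `cardan_convention(signs = )` maps mirrored
  lab conventions so positive abduction means varus on both sides; sides
  are always fitted independently (a posture trial can only be corrected
  by a $P$ fitted on the same side's gait cycles).

## Limitations

* **Nonlinearity of Cardan composition.** The exact angle-space image of a
  rigid misalignment is nonlinear in flexion; a linear $P^\top$ removes
  its first-order part only. Residuals grow roughly quadratically with the
  misalignment magnitude. In the package's own zero-noise measurements
  (recomputed by `scripts/acceptance.R`), flexion and abduction recover
  well within 1 degree RMS up to 15 degrees of misalignment, while the
  axial channel -- whose cross-talk term $-m(1-\cos\alpha)$ is curved in
  flexion -- exceeds 1 degree RMS slightly beyond about 12 degrees of
  misalignment.
* **Static axial offsets are unidentifiable.** Frame errors that shift a
  channel by a constant cannot be undone by any linear, translation-free
  map; the corrected axial channel inherits whatever static offset the
  frame error created.
* **True coupling is removed.** Decorrelation cannot distinguish
  physiological coupling from artifact; corrected data are uncorrelated by
  construction, which is a modelling stance, not a discovery.
* **Downstream kinematics are out of scope.** The correction reorients the
  knee angles only; recomputing hip/ankle kinematics from re-derived
  segment frames is deliberately not attempted.
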
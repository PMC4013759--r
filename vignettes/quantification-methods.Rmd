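---
title: "Methods: multimodal MRI and histology quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal MRI and histology quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstemq)
```

# Scope

`brainstemq` implements the quantification stack used in multimodal MRI +
histology studies of brainstem motor-nucleus pathology in the SOD1-G93A
mouse model of ALS: parametric maps (ADC trace, MTR, gadolinium
enhancement), ROI-normalised contrast in the trigeminal (V), facial (VII)
and hypoglossal (XII) nuclei, detection of MPIO-induced T2* hypointensities,
DAB densitometry by colour deconvolution, H&E vacuolation scoring, and the
group-comparison statistics. Everything runs on synthetic phantoms with
exact ground truth, so each stage is verifiable without animal data.
Acquisition, registration, atlas localisation and wet-lab protocols are out
of scope; volumes entering the pipeline are assumed aligned, as in a
single-session acquisition under anaesthesia.

# Parametric maps

**ADC.** Diffusion-weighted signal is modelled as mono-exponential decay
per gradient direction, $S(b) = S_0 e^{-bD}$, sampled at $b \in \{125, 500,
1000\}$ s/mm$^2$ (no $b=0$ image is acquired). The fit is ordinary least
squares of $\ln S$ on $b$ *with intercept*; $D$ is minus the slope. For
three points on an exact exponential this is exact, and the intercept
absorbs $\ln S_0$. The trace map is the unweighted mean of the three
directional maps — no weighting is implied by a three-orthogonal-axes
acquisition. Numerical detail: the slope uses the centred formula
$\sum(y-\bar y)(b-\bar b)/\sum(b-\bar b)^2$, so a constant signal yields
exactly $D=0$ rather than floating-point dust, whose sign would otherwise
decide between "valid zero" and "invalid negative".

Voxels with non-positive or non-finite signal at any $b$ cannot be
log-fitted and are invalidated (`NA`, mask `FALSE`) and counted — never
silently dropped. Negative fitted $D$ (noise) is likewise invalidated by
default rather than clipped, preserving the noise diagnostic; pass
`clip_negative = TRUE` to clip at the directional level instead. The trace
is only valid where all three directions are.

**MTR and enhancement.** $\mathrm{MTR} = (S_{off}-S_{on})/S_{off}$ as a
fraction (percent only in human-readable output), and
$E = (\mathrm{post}-\mathrm{pre})/\mathrm{pre}$ for the gadolinium pair.
Both are exact pointwise formulas; voxels with a non-positive denominator
are invalidated and counted.

**Geometry.** `voxel_resolution()` is `fov / zerofill` — zero-filling
interpolates the reconstruction grid, so the 22.5 mm field of view over 256
zero-filled points gives the 88 µm nominal resolution. `scan_duration()` is
`TR × phase encodes × averages × repeats` for a conventional spin-echo
loop; it reproduces the protocol's printed 4 min 16 s (T1) and 12 min 48 s
(three-b diffusion series) figures. One printed MT duration (9 min 35 s)
differs by 1 s from `TR × 128`; no attempt is made to reproduce that
discrepancy.

# ROI-normalised contrast

The study's contrast measure is $(\text{ROI} - \text{control}) /
\text{control}$, with a circular ROI over each nucleus and a paired control
region within the brainstem but outside the nuclei, pooled across the
slices used. For ADC and MTR, where pathology *lowers* the value, `invert =
TRUE` negates the contrast so that disease effects carry a positive sign on
every modality. The measure is invariant to global intensity rescaling,
which the tests verify with random scale factors.

ROI sizes deserve a note: the source protocol prints "diameters" of
1.4/1.2/1.1 with mm$^2$ units, which is self-contradictory. The package
reads the numbers as diameters in mm by default (a circle of area 1.2
mm$^2$ would have diameter 1.24 mm, so the two readings differ by ~3–13%);
`size_unit = "area_mm2"` selects the other reading, so the ambiguity is an
explicit parameter rather than a silent assumption. Rasterisation is by
centre-of-voxel inclusion, which is deterministic and
resolution-independent. Indices (voxels, slices) are 1-based, the R
convention; world coordinates are mm from the volume origin.

The control-region mean is pooled across slices (the protocol does not say
per-slice or pooled); fold-change series default to age-matched wild-type
means as reference, with the earliest-age baseline selectable — the source
figures do not state their normalisation, so the choice is recorded in the
output's metadata.

# MPIO hypointensity detection

The detection rule is applied literally: threshold at `fraction` (default
0.65) of the mean signal of *all* voxels in the tissue mask (sub-threshold
voxels included in the mean; no iterative re-estimation), strict `<` so
ties at the threshold are not hypointense; group sub-threshold voxels into
connected components; exclude components larger than `size_cutoff` (default
20 voxels) to omit large hypointense structures such as sinuses. Excluded
voxels do not count toward `percent_hypointense` but stay in the
denominator. "Contiguous" is undefined in 3D in the source protocol;
connectivity is a parameter (6, 18 or 26, default 26) and is recorded in
the result, as is the `>` vs `≥` reading of the cutoff (`size_rule`,
default `>`, i.e. size-20 components are retained). Whether the original
rule ran on the acquired or zero-filled grid is unknown; the detector
operates on whatever grid it is given.

Labelling is implemented as connected components of the voxel adjacency
graph (via igraph); the test suite checks it against an independently
written flood-fill oracle on hundreds of random volumes at all three
connectivities, and against phantoms with injected clusters of known size
and depth.

# Histology quantification

**Optical density and unmixing.** Absorbance is $OD_c = -\log_{10}(I_c /
I0_c)$ per channel (the protocol's own wording of this definition is
garbled; the standard Beer–Lambert form is implemented). Intensities are
clipped to $[\varepsilon, I_0]$ with $\varepsilon = 10^{-6} I_0$ before the
log, capping OD at 6; the clip floor is recorded. Stain separation is
Ruifrok–Johnston deconvolution: stain absorption vectors form the rows of
$M$, each pixel satisfies $od = d\,M$, and $d = od\,M^{-1}$. Two-stain sets
are completed with the unit vector orthogonal to both rows; near-collinear
matrices are rejected by reciprocal condition number. Negative densities
are clipped to zero with counts reported. Default vectors are the published
hematoxylin/DAB pair, since the original analysis names only the software,
not the vectors.

**DAB densitometry.** Mean DAB density inside a fixed measurement circle,
averaged without weighting over the sections through the nucleus. The
original "circle with a diameter of 500 units" has unspecified units, so
the diameter in pixels is a required explicit argument here.

**Vacuolation.** Background subtraction (morphological opening with a disc,
radius configurable; 0 disables), binarisation to 1 inside vacuoles (Otsu
by default; fixed threshold for deterministic tests; a single-intensity
image under Otsu falls back to a fixed threshold with a warning), then
within the drawn ROI the score is area × mean binary value — numerically
computed as the positive-pixel count so the identity holds exactly. A
degenerate all-vacuole ROI scores fraction 1; an empty ROI is an error.

# Statistics

Group comparisons are a factorial ANOVA (group × age, both categorical,
with interaction — the source does not state the design matrix, and
treating age as categorical matches a five-time-point cross-sectional
design) followed by planned pairwise two-sample t-tests with Holm–Bonferroni
step-down adjustment ("Hulm–Bonferroni" in the source is read as Holm).
Welch tests are the default; the pooled-variance Student form is available
and is what the type-I-error simulations use, since the simulated cells are
homoscedastic by construction. Effect sizes are Cohen's d with pooled SD
(the source says only "the standard deviation"); Glass's Δ (control-group
SD) is selectable. Correlations are Pearson's r, and two correlations are
compared by Fisher's transformation, $z' = \operatorname{atanh} r$, with
$z = (z_1' - z_2')/\sqrt{1/(n_1-3) + 1/(n_2-3)}$ and a two-sided normal
p-value.

# What the phantom generator emulates — and what it does not

The MRI phantom is an ellipsoidal brainstem containing three spherical
nuclei on a configurable grid (default 48 × 48 × 24 voxels at 0.15 mm).
Every modality is synthesised from the ground-truth parameters by the same
formulas the analysers invert, so noise-free recovery is exact by
construction and any discrepancy is an implementation defect — that is the
point of the design. Defaults are chosen to emulate the study's end-stage
conditions:

* `t2_fold_change`: V = 10, VII = 15, XII = 8. The 15-fold facial-nucleus
  value matches the reported end-stage T2 signal increase, with the facial
  nucleus carrying the largest effect; the V and XII values are plausible
  smaller effects, not reported quantities.
* `adc_truth`: 0.7 × 10⁻³ mm²/s isotropic in brainstem (typical rodent
  brain), reduced to 0.55 × 10⁻³ in the nuclei (ADC falls at end stage;
  the magnitude is not printed in the source, so this is a realistic
  choice).
* `mtr_truth`: 0.35 brainstem, 0.30 nuclei (typical brain MTR, reduced by
  pathology).
* `enhancement_truth`: 0 everywhere — no blood–brain-barrier leakage was
  found in this model; set it non-zero to exercise the Gd path.
* `noise_model`: Rician by default (magnitude reconstruction physics;
  background magnitude mean $\sigma\sqrt{\pi/2}$ is verified by test),
  Gaussian available for linear-regime checks, `none` for exactness tests.
* MPIO clusters are specified by centre, voxel count and *depth* — their
  intensity as a fraction of the in-mask mean — so detector threshold
  behaviour is directly controllable. Cluster voxels are the `size`
  nearest grid voxels to the centre (ties broken by linear index),
  which yields compact 26-connected blobs.

The cohort generator draws independent normal per-animal measurements per
(group, age, region) cell; its default design has wild-type contrast
centred on zero and transgenic contrast rising earliest and furthest in the
facial nucleus to 14 (i.e. 15-fold) at 120 days, with SDs scaling with the
mean (floor 0.15) — per-animal variances are not published, so the SDs are
free parameters of the simulation, not reported values.

None of this emulates anatomy, partial-volume effects, coil
inhomogeneity, motion, registration error, k-space artefacts, or the
spatial texture of real staining. Passing tests therefore demonstrate that
the *computations* are correct and self-consistent, not that the pipeline
is robust to every property of real data.

The histology generator synthesises RGB fields through the same
Beer–Lambert model the deconvolution inverts, with elliptical vacuoles
rendered at the white level, so the unmixing round-trip and the vacuole
pixel count are exact oracles at zero noise.

# Problem sizes and reproducibility

Tests and the acceptance script run on deliberately small problems chosen
to exercise every code path while keeping the default suite fast: 32³
volumes for detector/oracle equivalence, 10³-voxel regions for noisy ADC
recovery, ~4 000–15 000-voxel phantoms for map recovery, 2 000–10 000
replicates for the type-I-error simulations. All randomness is seeded;
identical spec + seed reproduces volumes, images, cohorts and result files
bit for bit, and generators restore the caller's RNG state.

# Known limitations

* The ADC model is mono-exponential; no tensor or multi-compartment fits.
* No coregistration: misaligned inputs produce silently wrong maps.
* The rolling-ball background subtraction of the original ImageJ workflow
  is approximated by a morphological opening; for the synthetic images
  used in validation the two coincide (flat background), but on real
  slides they differ in detail.
* Under Rician noise the log-linear ADC fit is slightly biased (the
  magnitude floor raises low signals); at SNR 20 with the study's b-values
  the voxelwise trace error is of the order of a tenth of the true value,
  as the acceptance report quantifies.
* `anova_with_posthoc` is cross-sectional (each animal measured once);
  repeated-measures or mixed models are out of scope.
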
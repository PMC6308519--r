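---
title: "Limited-angle micro-CT reconstruction with sinogram completion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limited-angle micro-CT reconstruction with sinogram completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lair)
```

# The problem

A micro-CT scan acquires line integrals of the object's linear attenuation
coefficient $\mu(\mathbf{r})$ (units mm$^{-1}$) along X-ray paths, organised
as a *sinogram*: one row per view angle, one column per detector bin. A
*limited-angle* (LA) acquisition covers only 90° of the rotation instead of
the full 360°, cutting the radiation dose to roughly a quarter but leaving a
270°-wide band of the sinogram unmeasured. Filtered backprojection (FBP) of
such data produces severe streak and shading artifacts because the missing
band removes an entire wedge of the object's Fourier spectrum.

`lair` implements a two-step remedy studied for flat-panel micro-CT systems:

1. **Completion** — a context-encoder (CE) adversarial network inpaints the
   missing angular band of the sinogram, conditioned on the measured band;
2. **Reconstruction** — the completed sinogram is reconstructed either
   analytically (FBP, the central-slice specialisation of the Feldkamp
   cone-beam method) or with TV-constrained iterative algorithms (EM-TV,
   ASD-POCS) driven by an image-quality-based stopping rule.

Everything runs from synthetic phantoms, so the whole study is reproducible
from a single seed on one CPU.

# Scan geometry and protocols

The geometry model is a rotating source–flat-detector pair: source-to-rotation
centre distance (SOD), source-to-detector distance (SID), detector pitch and
bin count. The reference system uses SOD 299 mm, SID 325 mm and a 75 µm
flat panel, giving magnification SID/SOD = 1.087 and an isocentre sampling of
$75 \cdot 299/325 = 69.00$ µm; a high-resolution configuration with SOD 49 mm
and SID 211.1 mm gives 17.4088 µm. Three acquisition protocols are built in:

| protocol | step | coverage | views |
|---|---|---|---|
| LA | 1°/view | 90° | 90 |
| DSFC | 1°/view | 360° | 360 |
| LSFC | 5°/view | 360° | 72 |

DSFC (densely-sampled full coverage) is the reference scan; LSFC emulates
sparse sampling at a comparable dose to LA.

Angles are degrees, counter-clockwise, 0° along the +x axis of the image
grid; the source–detector pair rotates while the object is fixed. The fan
beam (flat equidistant detector) is the default; a parallel mode exists
because its Radon transform has closed-form test cases. The paper-scale cone
beam is treated slice-by-slice as fan beam (central-slice approximation);
full 3D cone weighting is out of scope.

# Forward model and projector

Projection is the linear system $\mathbf{p} = A\mathbf{f}$, where $a_{ij}$ is
the exact intersection length of ray $j$ with pixel $i$. The system matrix is
built by Siddon-style parametric ray traversal (in C++) and stored sparse;
backprojection uses the matched transpose, so the adjoint identity
$\langle A f, g\rangle = \langle f, A^\top g\rangle$ holds to machine
precision by construction and is tested as such. Matrices are cached
in-process per (geometry, grid, angle set) because their construction
dominates the cost of iterative studies.

The grid is sized to the demagnified detector pitch with a `fill` factor: the
reconstruction studies use fill 0.9 (grid corners slightly beyond the fan,
flagged by a truncation warning and irrelevant for centred phantoms), while
the training-data generator uses fill 0.7 so that the *entire* grid square —
corners included — stays inside the fan at every angle and no training
phantom is ever truncated.

# Filtered backprojection

FBP follows the standard flat-fan chain: cosine pre-weighting
$\mathrm{SOD}/\sqrt{\mathrm{SOD}^2+s^2}$ in the demagnified detector
coordinate $s$, convolution of each row with the band-limited discrete ramp
(zero-padded to twice the row length; kernel $h[0]=1/4h^2$,
$h[n\ \mathrm{odd}]=-1/(\pi n h)^2$, zero even lags, DC bin forced to zero),
then $1/U^2$-weighted backprojection with linear detector interpolation,
scaled by the angular step (halved beyond 180° of coverage, where every line
is measured twice). Shepp-Logan and Hann apodisation windows are available;
the default is the pure band-limited ramp at full cutoff.

One numerical subtlety is documented in `ramp_filter_rows()`: with
zero-padding (correct linear convolution) a constant row maps to an
edge-localised response even though the filter's DC gain is exactly zero; a
`circular` mode trades wrap-around for an exactly zero response to constant
rows. Reconstruction always uses the padded mode. The absolute scale is
validated against phantoms of known attenuation (a 0.03 mm$^{-1}$ disc
reconstructs to its nominal value within 2%), not against any external
reference.

# Iterative reconstruction

Both iterative algorithms minimise a data-fidelity term under a
total-variation constraint, with nonnegativity enforced at every iterate.
The isotropic discrete TV uses forward differences with a zero-gradient
boundary; its smoothed form $\sum\sqrt{|\nabla f|^2+\varepsilon^2}$
(default $\varepsilon = 10^{-6}$) supplies an analytic gradient that is
verified against numeric differentiation.

**EM-TV** alternates the multiplicative MLEM update
$f' = f \cdot A^\top(p/(Af)) / A^\top 1$ (with $0/0 := 0$; nonnegativity is
automatic and the Poisson log-likelihood is non-decreasing, which is tested)
with `tv_steps` unit-gradient descent steps on the smoothed TV whose total
length is $\lambda\, \cdot$ `tv_step_size` $\cdot\, \|\Delta_{EM}\|$ — tying
the regularisation travel to the fidelity travel keeps the balance
scale-free. Defaults: $\lambda = 0.2$, 10 TV steps of relative size 0.1.

**ASD-POCS** performs a view-sequential SART pass — for each view $v$ in
turn, $f \mathrel{+}= \beta\, A_v^\top((p_v - A_v f)/A_v 1)/A_v^\top 1$
followed by a nonnegativity projection — then an adaptive TV descent of
total length `alpha_frac` $\cdot\, \|\Delta_{POCS}\|$; `alpha_frac` shrinks
by `alpha_red` whenever TV travel exceeds `r_max` times the data travel, and
$\beta$ decays by `beta_red` each iteration
($\beta_0 = 1$, `beta_red` 0.995, `alpha_frac` 0.2, `alpha_red` 0.95,
`r_max` 0.95 — conventional values from the ASD-POCS literature family,
recorded in the configuration object so every run is reproducible). The
view-sequential ordering matters: a simultaneous (SIRT-like) update needs
several times more iterations for the same residual.

Neither optimiser's hyperparameters were published for the original system,
so all of them live in `ir_config()` and are echoed into every report.

## The image-quality stopping rule

Instead of a pixel-difference tolerance, iteration is scored against a
reference image $f$ — the ground-truth phantom in simulation, or the FBP
reconstruction of the completed sinogram when no ground truth exists — with
the per-iteration record of PSNR, UIQI, SSIM and rTV. The rule tracks
$s_t = \mathrm{UIQI}_t - \mathrm{rTV}_t$ **among iterations whose PSNR
exceeds the gate** $k$ (default 35 dB), stops once $s$ has not improved for
`patience` (default 3) eligible iterations, and returns the argmax-$s$
eligible iterate. If the gate is never met the run continues to its budget
and returns the last iterate with reason `"psnr-gate-unmet"`.

Two deliberate choices: (i) the score subtracts rTV *literally*, although
rTV's ideal value is 1, not 0 — this follows the stated criterion; a variant
$\mathrm{UIQI} - |\mathrm{rTV} - 1|$ is available via
`stopping_config(metric = "uiqi_minus_abs_rtv_dev")`. Because rTV grows
towards (and slightly past) 1 as edges sharpen, the literal score favours
earlier, smoother iterates; the gate is what keeps the returned iterate
sharp. (ii) The "best over the budget" benchmark used in tests is the best
score *among gate-eligible iterates*, because that is the constrained
optimum the rule is defined to find.

# Figures of merit

* `psnr()` — $10\log_{10}(\max^2/\mathrm{MSE})$ with the peak taken as the
  joint maximum pixel value of both images; identical images give the `Inf`
  sentinel.
* `uiqi()` — the universal image quality index
  $4\mu_1\mu_2\sigma_{12}/((\mu_1^2+\mu_2^2)(\sigma_1^2+\sigma_2^2))$ on
  global statistics, computed as the product of its correlation, luminance
  and contrast factors so degenerate factors drop out as 1 (a zero-mean sign
  flip scores exactly −1).
* `ssim()` — default mode uses the conventional 11×11 Gaussian window
  (σ = 1.5), mean-pooled over the valid region;
  `mode = "global"` evaluates the single-window formula on whole-image
  statistics. Regularisers $c_1 = (0.01L)^2$, $c_2 = (0.03L)^2$.
* `rtv()` — ratio of TV norms, 1.0 when the reconstruction's edge content
  matches the reference.
* `cnr()`, `snr()` — ROI-based contrast-to-noise
  $|\mu_s-\mu_b|/\sqrt{\sigma_s^2+\sigma_b^2}$ and signal-to-noise
  $\mu/\sigma$ (with `Inf` for a zero-variance ROI).
* `fwhm()` — least-squares Gaussian-plus-baseline fit of a wire profile;
  $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. A fit started exactly on a
  symmetric peak can hit a singular Jacobian, so a retry from a quarter-step
  offset is built in.
* `linearity()` — Pearson correlation of ROI means against nominal
  hydroxyapatite densities.

Global metrics are invariant to a joint permutation of both images' pixels;
windowed SSIM deliberately is not (documented and tested).

# Phantoms and the synthetic data generator

The Monte-Carlo cylinder phantom draws 1–4 filled discs with radii uniform
in 10–20 px and centres uniform under full containment; disc values are
uniform in 0.01–0.05 mm$^{-1}$, soft-tissue-like attenuation near 60 kVp
(the generation rules fix count, position, radius and pose, but not
intensities — the value range is this package's choice). Pose augmentation
adds a uniform rotation, an optional left–right reflection and a
"reversed rotation" flag that the dataset generator consumes by negating the
angular ordering of the sinogram rows. The classic 10-ellipse head phantom
is provided in 2D and 3D; the 2D version is rendered with 4× area-weighted
supersampling by default, since hard binary-membership
edges alias the projector and depress FBP fidelity relative to the
area-weighted rendering. Digit-like phantoms (random
thick strokes and ring blobs) stand in for handwritten-digit shapes so that
no external dataset is needed. Four QA layouts (wire, contrast, water,
hydroxyapatite) carry their ROI and profile-line annotations; ROI offsets
are configuration values chosen so the 3×3 mm² ROIs sit strictly inside
their inserts and strictly outside neighbouring ones.

`generate_dataset()` chains phantom → pose → 360° projection → 450°
extension → LA masking (→ optional resampling to the network dimensions)
and records one seed per slice, so any sample can be regenerated
bit-identically from `(config, master seed)`.

What the generator does *not* emulate: polychromatic spectra, scatter,
detector gain/dark-field structure, ring artifacts, or anatomical texture.
A Poisson transmission-noise switch exists but is off by default. Passing
tests on this data therefore demonstrates the algorithms' correctness and
their relative ordering under ideal physics, not clinical performance.

# The sinogram manipulation chain

A full-rotation sinogram repeats after 360°, so the first 90° of rows are
copied after the 360° mark to form a 450° reference (`extend_to_450()`);
the band [90°, 360°) is then zeroed and flagged missing (`apply_la_mask()`);
the known/missing mask is carried separately from the values, so a measured
zero is never confused with a missing sample. `resize_for_ce()` resamples
bilinearly to the network input size with metadata rescaled by the dimension
ratios (541 bins at 75 µm → 544 at 74.586 µm; 450 rows at 1° → 448 at
1.004°). After completion, `fold_back_360()` averages the duplicated
[0°, 90°) and [360°, 450°) bands — exact on consistent data, and it halves
completion noise in that band; a `keep-first` alternative is provided.

# The context encoder

The generator consumes the full masked sinogram (`bins × angles`, both
divisible by 16) as the context: four stride-2 3×3 convolution stages of
depths 2/4/8/16 (LeakyReLU 0.2, batch-norm momentum 0.8, dropout 0.5 on the
last stage), a channel-wise fully-connected bottleneck mapping each
channel's `bins/16 × angles/16` map to a `bins/16 × region/16` decoder seed,
four 2×-upsampling stages of depths 16/8/4/2 (ReLU, batch-norm), and a
single-channel tanh output covering only the missing-band region. The
discriminator applies 3×3 convolutions of depths 64/128/128 (first two
stride-2) and a fully-connected sigmoid unit. At the full-scale profile
(544×448) the bottleneck is 34×28 and the seed 34×17 → a 544×272 region; at
the desk profile (176×112) they are 11×7 and 11×4 → 176×64.

The missing band after resampling spans 60% of the rows (≈269 of 448); the
region is rounded to the nearest multiple of 16 (272, or 64 at the desk
profile) and centred on the band, overlapping 1–2 known rows at the
full-scale profile — compositing overwrites those rows from the measured
input, so known data always pass through bit-exactly. At the desk profile
the 64-row window leaves ~2 straddling rows at each band edge to the
resampling; they are small mixtures of measured data and zeros and are the
price of the 16-divisibility constraint.

Training minimises `0.999 · masked-region L2 + 0.001 · adversarial BCE`
with Adam; the discriminator sees real and generated regions and the
generator receives the adversarial gradient through it. Each epoch draws 32
training and 16 validation sinograms from the pool and performs one
generator update (so "epochs" count optimisation steps). The network and
its backpropagation are implemented natively on BLAS matrix kernels inside
the package; convolutions, batch-norm and activations run in C++, and a
finite-difference check of every layer's gradient is part of the test
suite.

## Desk-scale training choices

The desk profile departs from full-scale GAN conventions in three
documented ways, each driven by the 300-step optimisation budget:

* **Learning rate.** Adam at 2×10⁻⁴ (the usual choice for this GAN family
  over thousands of steps) moves the generator far too little in 300 steps;
  the desk default is 2×10⁻³ with first-moment decay 0.9 (the generator update is regression-dominated, so plain Adam momentum applies rather than the GAN convention of 0.5). The full-scale convention remains available
  through `ce_training_config(lr = 2e-4)`.
* **Adversarial cadence.** The discriminator is two orders of magnitude
  more expensive than the generator at these sizes while contributing 0.1%
  of the loss; the desk default runs the adversarial pathway every 10th
  epoch on a random half-batch (`adv_every = 10`, `disc_batch = 16`), with
  every-epoch coupling available.
* **Normalisation.** Sinogram values are mapped affinely onto the tanh
  range; the desk default centres the range symmetrically about zero so
  that the dominant background value sits in the responsive part of tanh
  rather than at its −1 saturation.

## What the desk-scale results can and cannot show

Cylinder sinograms at 176×112 are a *harder* completion task, sample for
sample, than full-scale anatomical data: every training slice is a novel
random configuration, whereas anatomical slice stacks are highly redundant.
The architecture routes all global information through the
coarse bottleneck (1/16 resolution), so fine structure in the missing band
must be hallucinated from a 704-dimensional seed; the achievable region
fidelity at this scale is therefore limited, and the desk study should be
read as a *directional* demonstration — completion lifts the missing band
far above the zero-filled baseline and the downstream reconstructions
consistently beat uncompleted limited-angle FBP — not as a reproduction of
full-scale fidelity numbers.

# The protocol study and the pipeline

`run_protocol_study()` evaluates every protocol × algorithm cell: simulate
the acquisition, complete it if it is LA and a model is supplied (resample →
inpaint → resample back → restore measured rows bit-exactly → fold to
360°), reconstruct, and score PSNR/UIQI/SSIM/rTV against the reference —
the DSFC FBP reconstruction by convention (so the DSFC/FBP cell scores rTV
exactly 1 against itself), or the ground-truth phantom.
`run_end_to_end_demo()` wires the whole chain — dataset, toy training,
completion, FBP and EM-TV, reports — into one seeded artifact folder, and
rerunning it with the same seed reproduces the report values.

Problem sizes throughout the package's tests and scripts: reconstruction
studies at 128², completion studies at 96² phantoms with 176×112 sinograms
and 224-slice datasets, statistical checks at 300–1000 draws. These sizes
were chosen so a full run of every check completes on a single CPU core in
well under an hour while leaving each claim's effect size clearly resolved.

# Known limitations

* Per-slice 2D treatment of a cone-beam system (central-slice
  approximation); no 3D cone weighting, no helical trajectories.
* No detector physics beyond an optional Poisson transmission switch; no
  ring-artifact or beam-hardening handling.
* The completion model is dimension-locked to its architecture
  (variable-angle recovery is out of scope by design).
* The printed flattened layer widths of the original architecture table
  cannot be reconciled with its convolution stack; layer widths here are
  derived from the shape algebra (input/16 bottleneck, region/16 seed),
  which reproduces the printed seed and region dimensions.
* At the desk profile, absolute completion fidelity is bottleneck-limited
  (see above); full-scale dimensions are available behind the default
  `ce_architecture()` profile for machines that can afford them.
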
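# lair — Limited-Angle Iterative Reconstruction for micro-CT

`lair` is an R toolkit for studying **limited-angle (LA) computed
tomography** on a desktop: what happens when a micro-CT scan covers only 90°
of the rotation instead of the full 360° (about a quarter of the radiation
dose), and how much of the lost image quality can be recovered by
**inpainting the missing band of the sinogram with a context-encoder
adversarial network** before reconstruction.

The package contains the full experimental chain, self-contained and seeded:

* **Geometry & protocols** — flat-panel fan-beam scan geometry (SOD/SID,
  detector pitch), magnification arithmetic, and the three study protocols:
  LA (1°/view, 90°), DSFC (1°/view, 360°, the dense reference) and LSFC
  (5°/view, 360°, sparse sampling).
* **Projector** — an exact sparse system matrix `A` (Siddon ray tracing in
  C++); forward projection is the linear model `p = A f`, backprojection the
  matched adjoint.
* **Phantoms & synthetic data** — Monte-Carlo cylinder phantoms, the classic
  head phantom (2D/3D), digit-like stroke phantoms, QA phantoms (wire,
  contrast, water, hydroxyapatite) with ROI/profile annotations, and a
  seeded dataset generator producing (complete, limited-angle, mask)
  sinogram triples.
* **Sinogram operations** — 360°→450° extension (a sinogram repeats after
  360°), LA masking of the [90°, 360°) band, bilinear resampling to the
  network dimensions (541×450 → 544×448 with 74.586 µm / 1.004° metadata),
  and fold-back to 360° after completion.
* **Context encoder** — the encoder/decoder GAN with a channel-wise
  fully-connected bottleneck (Table-level architecture: 3×3 convolutions,
  depths 2/4/8/16 → seed → 16/8/4/2, tanh output over the missing region;
  64/128/128 discriminator), implemented natively on BLAS matrix kernels
  with full backpropagation — no external deep-learning framework.
* **Reconstruction** — fan-beam FBP (ramp/Shepp-Logan/Hann filters) and two
  TV-constrained iterative algorithms: EM-TV (multiplicative MLEM + TV
  descent) and ASD-POCS (view-sequential SART + adaptive TV descent), both
  with nonnegativity at every iterate.
* **IQ-driven stopping** — per-iteration PSNR/UIQI/SSIM/rTV against a
  reference image; iteration stops when `UIQI − rTV` plateaus among
  iterates whose PSNR clears a 35 dB gate, returning the best-scoring
  iterate.
* **Figures of merit** — PSNR, UIQI, SSIM, rTV, CNR, SNR, Gaussian-fit FWHM
  and ROI linearity.

The model at the core, in standard notation: reconstruction solves

  f* = argmin_f ( U(f) + λ V(f) ),  subject to f ≥ 0,

with data fidelity `U` (Poisson likelihood for EM-TV; least squares for
ASD-POCS) and the isotropic total variation `V(f) = Σ √(Σ_d (∇_d f)²)`;
iteration is stopped by

  f** = argmax over iterates of ( UIQI(f*, f) − rTV(f*, f) ),
  subject to PSNR(f*, f) > k = 35 dB,

where `f` is the reference image (ground-truth phantom in simulation, the
FBP of the completed sinogram otherwise) and `rTV = ‖f*‖_TV / ‖f‖_TV`.

## A worked example

Ninety-degree limited-angle FBP versus the same data after sinogram
completion (the full desk-scale training run; ~4 minutes on one CPU core):

```r
library(lair)

arch  <- ce_architecture(176, 112)        # desk-scale network profile
ds    <- generate_dataset(224, "cylinders", arch = arch, seed = 101)
model <- train_ce(ds, arch,
                  ce_training_config(epochs = 300, seed = 1),
                  holdout = 201:224)

sg <- study_geometry(det_count = 176, grid_n = 96, fill = 0.7)
ph <- random_cylinder_phantom(96, voxel_mm = sg$voxel_mm, seed = 1001)

acq_la <- simulate_acquisition(ph, sg$geometry, protocol_la(),
                               voxel_mm = sg$voxel_mm)          # 90 views only
acq_ce <- simulate_acquisition(ph, sg$geometry, protocol_la(),
                               ce_model = model, voxel_mm = sg$voxel_mm)

rec_la <- fbp_reconstruct(acq_la$sinogram, sg$geometry, 96, voxel_mm = sg$voxel_mm)
rec_ce <- fbp_reconstruct(acq_ce$sinogram, sg$geometry, 96, voxel_mm = sg$voxel_mm)

cat(sprintf("LA-FBP      : PSNR %5.2f dB, UIQI %.3f\n", psnr(rec_la, ph), uiqi(rec_la, ph)))
cat(sprintf("LA+CE -> FBP: PSNR %5.2f dB, UIQI %.3f\n", psnr(rec_ce, ph), uiqi(rec_ce, ph)))
```

```
LA-FBP      : PSNR 12.06 dB, UIQI 0.492
LA+CE -> FBP: PSNR 19.93 dB, UIQI 0.781
```

The first line scores the raw 90° acquisition: the missing 270° band
produces heavy directional shading, so FBP agrees poorly with the phantom.
The second line reconstructs after the context encoder has filled the band:
almost 8 dB is recovered and the structural agreement (UIQI) rises from
0.49 to 0.78 — the directional ordering the package's acceptance checks
assert across the held-out slices. `run_end_to_end_demo()` packages this whole
chain (dataset → training → completion → FBP/EM-TV → JSON report) into one
seeded artifact folder, and `run_protocol_study()` produces the full
protocol × algorithm comparison table against the DSFC reference.

A thin command-line front end over the same functions ships in
`inst/cli/lair.R` (`project`, `fbp`, `recon`, `simulate`, `ce-train`,
`ce-inpaint`, `iq`, `demo`).

## Further reading

The methods vignette (`vignettes/limited-angle-reconstruction.Rmd`) documents
the models and their assumptions, every tunable parameter with units and
defaults, the synthetic-data generator's scope, numerical choices, and known
limitations.
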
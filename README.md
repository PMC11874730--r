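# spiralcine

Joint reconstruction and segmentation of undersampled spiral real-time
cardiac cine MRI, in R.

Clinical cardiac function assessment rests on ECG-gated, breath-hold,
segmented Cartesian cine MRI. That protocol fails exactly where it is
needed most: patients who cannot hold their breath or whose heartbeat is
irregular. An alternative is *real-time* imaging with highly
undersampled spiral readouts — a full frame every 48 ms, no gating, no
breath-hold — if the reconstruction can remove the aliasing that
undersampling causes and the left ventricle (LV) can be segmented
automatically in every frame.

`spiralcine` implements that processing chain end to end for
researchers working on non-Cartesian reconstruction and learned
postprocessing:

* **Trajectory design** — variable-density center-out spirals with 13
  interleaves per frame, azimuthal undersampling rising from ~5 at the
  k-space center to ~15 at the edge ($k_{max}$ normalized to 0.5);
  largest-gap rotation schedules across repeated patterns; gradient
  system transfer function (GSTF) application and gradient-to-k-space
  integration; analytic density compensation.
* **Encoding** — Kaiser–Bessel gridding NUFFT (exactly adjoint by
  construction, with an exact-DFT reference mode), simulated phased
  arrays, adaptive (Walsh-style) coil-map estimation, and a CG-SENSE
  interim reconstruction: 10 conjugate-gradient iterations on the
  normal equations $E^H E \rho = E^H y$.
* **Self-gating** — the k-space center sample acquired every TR is a
  cardiac navigator; band-pass filtering and peak detection yield
  triggers, arms are binned into cardiac phases, and one 13-arm pattern
  per heartbeat with distinct rotations assembles a segmented
  (8 x 13 = 104 arm) k-space from the same acquisition.
* **Model** — a disentangled multi-task network: a U-Net encodes 8
  binary anatomy factors (straight-through binarization); a shallow
  3-convolution segmentor reads LV / myocardium / RV masks off them; a
  variational encoder produces a length-8 modality (contrast) vector; a
  FiLM-conditioned decoder re-renders the image; and a refinement U-Net
  fuses the decoded image with the CG-SENSE interim estimate into the
  final reconstruction. Trained with Dice + cross-entropy, KL,
  modality-reconstruction and perceptual losses. The layer engine
  (conv/pool/BN/FiLM/dense with hand-derived backprop over BLAS
  kernels) lives in the package — no external deep-learning runtime.
* **Function analysis** — per-frame LV volumes, local extrema with
  median aggregation across the covered heartbeats, and
  $EF = 100\,(EDV - ESV)/EDV$; Dice, NRMSE, PSNR and SSIM metrics.
* **Phantom** — an analytic dynamic short-axis phantom (LV, thickening
  myocardium, RV crescent, chest wall) with exact masks, configurable
  heart rate, arrhythmia (lognormal RR), respiration and noise,
  standing in for in-vivo data so the whole chain runs at desk scale.

## Worked example

Train the joint model on simulated spiral pairs, then run the full
chain — session simulation, self-gating, per-frame CG-SENSE, model
reconstruction and segmentation — and read off the ejection fraction:

```r
library(spiralcine)

# train the joint model on simulated spiral pairs (about 12 min on 1 CPU)
train <- make_phantom_training_set(200, grid = 64, seed = 11)
val   <- make_phantom_training_set(12,  grid = 64, seed = 12,
                                   phases_per_subject = 4)
model <- xsdnet_train(train, val, xsdnet_config(grid = 64, seed = 1),
                      epochs = 30, batch_size = 8, lr = 1e-3, seed = 1)
print(model)
#> xSDNet model (trained): grid 64, 8 anatomy factors, z length 8
#>   U-Net depth 3, base width 8; 118,398 parameters
#>   trained 30 epochs; final val Dice(LV) 0.918, val NRMSE 0.0338

# end-to-end run on a noise-free 3-slice phantom
cfg <- run_config(seed = 31, grid = 64, mode = "breathhold",
                  duration_s = 5.7, n_slices = 3,
                  phantom_overrides = list(noise_level = 0))
run <- run_end_to_end(cfg, model = model)
print(run)
#> spiralcine run: 3 slice(s), mode breathhold, 5.7 s/slice
#>   EF 59.7%  (EDV 46.6 ml, ESV 18.8 ml)
```

The phantom's analytic ejection fraction is 60 %: with model
segmentations the pipeline recovers it to a fraction of a percentage
point here (with ground-truth masks, 59.4 %). `report_timing(run)`
breaks the wall time down by stage; `predict(model, interim)` gives
per-frame reconstructions, masks and latents; `plot(model)` shows the
training curves.

The numbers above are what the code printed for these exact calls
(seeds included); re-running them reproduces the output bit for bit.

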
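# perfmoco

Breathing-motion compensation for first-pass gadolinium-enhanced myocardial
perfusion MRI, with a section-wise time-intensity-curve validation framework
and a synthetic perfusion phantom, in R.

## The problem

A first-pass perfusion study images one short-axis slice per heart beat for
about a minute while a contrast bolus passes RV → LV → LV myocardium.
Perfusion is quantified from the mean intensity of myocardial regions over
time, so a region outlined on one frame must cover the same tissue in every
frame.  ECG triggering fixes the cardiac phase, but free breathing leaves
quasi-periodic respiratory motion (about one cycle per six frames at rest)
that must be removed by non-rigid registration — under intensity changes so
strong that plain intensity matching fails.

Two compensation pipelines are implemented on a shared cubic B-spline
free-form-deformation core (SSD and normalized-gradient-field similarity,
curvature regularization, analytic gradients, multi-resolution):

* **ICA-SP** — an independent component analysis of the series yields
  spatial feature images and per-frame mixing curves; a Daubechies-wavelet
  analysis of the mixing curves (with a mean-frequency fallback above
  14 breaths/min for stress studies) labels the motion component, which is
  left out when the components are recombined into motion-free synthetic
  reference frames; every frame is registered to its reference with SSD
  (knot spacing 16 at working scale 0.5, curvature weight 10), for up to 5
  passes.  When the RV/LV components are identified, their feature images
  are segmented and — unless the 30 mm centre-distance sanity check rejects
  the segmentation — processing is restricted to a region of interest.
* **QUASI-P** — exploits the quasi-periodicity of breathing: a global
  reference and the subset of frames in the same breathing phase are found
  with an NGF similarity measure; the subset is registered to the reference
  by NGF; synthetic references for all frames are interpolated linearly in
  time from the registered subset; the remaining frames are registered to
  their references with SSD (knot spacing 5, curvature weight 0.1, gradient
  descent with start step 0.01 and epsilon 0.01).

Validation follows the time-intensity-curve methodology: the myocardium is
divided into 12 sections by rotating the ray from the LV centre through the
RV insertion point clockwise in 30° increments; per section, curves from the
per-frame ground-truth masks (`K_gt`), the unaltered LV-peak key-frame masks
(`K_org`) and the transform-adjusted key-frame masks on the registered
series (`K_reg`) are compared by NMSE (lower is better) and Pearson
correlation (higher is better; an empty transformed section scores exactly
0).

The phantom module renders a moving ellipse scene (static chest, RV/LV
cavities, myocardial ring, a sub-diaphragmatic mass that moves with the
heart) with gamma-variate enhancement kinetics, quasi-periodic breathing
translation, proton-density lead-in frames and Gaussian noise — plus exact
per-frame segmentations, truth transforms and truth curves — so the entire
test bed runs without external data.  Series can be written and read as
DICOM or 8-bit PNG + JSON sidecar; segmentations as XML against a shipped
XSD.

## Worked example

```r
library(perfmoco)

# a free-breathing phantom at half resolution (same field of view and
# physical knot spacing as the published 256x192 @ 1.4 mm configuration)
ph <- generate_series(phantom_config(n_frames = 45, matrix = c(96, 128),
                                     spacing = c(2.8, 2.8), seed = 1))
res <- run_icasp(ph$series)          # strips the 2 PD frames itself
cat(res$log, sep = "\n")

series <- strip_proton_density(ph$series)
segs <- seg_strip_pd(ph$truth_segmentation, 2)
curves <- build_curves(series, res$registered_series, segs, res$transforms)
scores <- score_curves(curves, method = "ICA-SP")
summarize_scores(scores, split_study = FALSE)
```

Output from this exact script (seed 1):

```
pass 1: ICA mode deflation, labelling wavelet (motion IC 3)
pass 1: ROI rejected (RV/LV centre distance 13.2 mm below 30 mm); motion compensation on the full domain
pass 1: max displacement update 1.269 px
pass 2: ICA mode deflation, labelling wavelet (motion IC 5)
...
pass 5: max displacement update 1.192 px
  study measure        phase  mean variation median    min   max  n
1   all    NMSE unregistered 1.002    1.3867  0.527 0.0444 4.016 12
2   all    NMSE       ICA-SP 0.029    0.0193  0.022 0.0099 0.077 12
3   all      R2 unregistered 0.685    0.2904  0.750 0.1025 0.981 12
4   all      R2       ICA-SP 0.987    0.0093  0.991 0.9636 0.996 12
```

On this phantom the RV/LV IC segmentation fails its 30 mm sanity check, so
compensation runs on the full domain — the same fallback the rejection rule
exists for on real data.  The unregistered key-frame masks mis-sample the
moving myocardium (mean section NMSE 1.00, correlation 0.69); after ICA-SP
compensation the curves essentially match the ground truth (NMSE 0.03,
correlation 0.99).
`run_quasip(ph$series)` runs the second method; `run_experiment()` batches
phantoms, methods and seeds into the published table layout.

A command-line front end ships in `inst/cli/perfmoco`
(`simulate`, `icasp`, `quasip`, `validate`, `experiment`).

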
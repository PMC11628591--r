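---
title: "Methods: segmentation-based infarct-size quantification for TTC-stained heart slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-based infarct-size quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In preclinical cardioprotection research, infarct size (IS) is the primary
endpoint. After ischemia/reperfusion the heart is cut into transverse slices,
the area at risk (AAR) is delineated by blue-dye exclusion and viable tissue
is stained red with triphenyl tetrazolium chloride (TTC); infarcted tissue
remains white. IS is then quantified by planimetry of the cut surfaces,
traditionally by manual outlining — slow and subject to inter-observer
variability. `ttcseg` implements the automated alternative: a five-class
semantic segmentation network applied to digital photographs of the slice
faces, followed by mass-normalized planimetry, plus the full statistical
machinery needed to show that the automated and manual quantifications
agree.

The five classes are fixed package-wide: 0 remaining (background, lumina,
epicardial projection), 1 remote myocardium, 2 non-infarcted AAR, 3 infarct,
4 right ventricle.

## Synthetic phantom cohorts

No public cohort of annotated TTC photographs exists, so the package ships a
generator (`phantom_config()`, `generate_cohort()`) that serves both as
training input and as a test oracle. Each cut face is a perturbed annulus:
the left-ventricular wall lies between two Fourier-perturbed circles
(harmonics 2–4, amplitudes within a few percent of the radius), the AAR is
an angular sector of that annulus, the infarct a transmural sub-sector
growing from the endocardium, and the right ventricle a cosine-tapered
crescent appended opposite the AAR. Lumen and background are "remaining".
This matches the visual layout of real slice photographs without modelling
anatomy.

Two properties make the generator an oracle rather than just a texture
source:

* **Exact continuous fractions.** Sector half-spans are solved numerically
  on a 4096-point angular grid so that the continuous AAR/LV and
  infarct/AAR area fractions hit their targets exactly; the rasterizer then
  applies the same inequalities to pixel centres. Pixel counts therefore
  differ from the continuous truth only by rasterization error, which is
  why recovery of the true IS from ground-truth masks is required to within
  1% of AAR at 256 px and above.
* **A non-trivial mass model.** The slice mass is a tissue-density constant
  (1.05 mg/mm^3) times thickness times the mean physical LV+RV area of the
  slice's two faces, with a millimetre-per-pixel scale drawn per heart.
  Masses are therefore correlated with, but not proportional to, any single
  face's pixel areas, so the mass-normalization step of the quantification
  is exercised non-trivially.

Cohort structure follows the porcine study design the package emulates: 5–7
slices per heart at 10–20 mm thickness, AAR between 9 and 38% of the LV,
IS between 0 and 73% of the AAR, and a protected subgroup
(`protection_fraction`, default 0.42) whose IS target is drawn from a
low-IS Beta regime (Beta(1.2, 3.2) versus Beta(2.8, 1.8) scaled to the IS
range) — protection shifts the cohort IS mean downward without leaving the
configured bounds, because every per-slice fraction is clamped to them. The
two faces of a slice share their geometry up to small independent
perturbations, creating realistic within-slice disagreement; the outermost
apical and basal surfaces of each heart are not cut faces and are not
imaged, so a heart with *n* slices yields 2*n* − 2 images. The per-experiment
ground truth (`true_is()`) is computed from the continuous areas of the
imaged faces through the same averaging and mass-normalization formula as
the pixel path, so parameter-recovery tests isolate segmentation and
rasterization error.

The `rat` profile shrinks the ventricle (5.5–7.5 mm outer radius), thins the
slices (~2 mm) and uses 5–6 slices; `degrade_contrast` pulls the tissue
colours toward their common mean to emulate the weaker staining contrast of
isolated saline-perfused preparations.

What the phantoms deliberately do not emulate: specular highlights, wet
tissue texture, out-of-plane tilt, annotation error (masks are exact by
construction) and inter-observer variability. Passing tests on phantoms
therefore demonstrates the correctness of the pipeline's computations and
its end-to-end learnability, not clinical-grade performance on photographs.

## Preprocessing

`remove_background()` substitutes a deterministic procedure for neural
matting: the background colour is the median of the image border, pixels
within a chroma distance of 40 (of 255) are background, the largest
connected component is kept, closed with a disc of radius 3 and
hole-filled. `pad_to_square()` centres the content on a black square;
`resize_uniform()` interpolates images bilinearly and masks by
nearest-neighbour index mapping (no new labels can appear). The identical
geometric operations are applied to image and mask, preserving alignment.

Resize quality is audited with SSIM and PSNR (`quality_report()`): each
image is resized down to the model size and back up to native resolution
(bilinear both ways) and compared with the original. The down-then-up
protocol is a package decision — the comparison needs equal dimensions and
this direction measures exactly the information the model loses. SSIM uses
a 7-px uniform window with the standard stabilization constants
k1 = 0.01, k2 = 0.03 on a 255 dynamic range, averaged over windows and
channels; PSNR is 10·log10(255²/MSE) with an infinity sentinel for
identical images.

## The segmentation network

`build_unet()` constructs an encoder–decoder (U-Net) whose decoder widths
are derived from the actual encoder feature shapes at build time — the
"dynamic" sizing contract, so changing the encoder re-sizes the decoder
automatically. Each encoder level applies two 3×3 convolutions with ReLU
and halves resolution by 2×2 max-pooling; the bottleneck doubles the
deepest width and carries dropout; decoder levels upsample (nearest, ×2),
concatenate the matching encoder skip and convolve; a 1×1 convolution
yields the five class logits, and a per-pixel softmax the probability maps.
The forward pass, composite loss and full backpropagation are implemented
in compiled code (RcppArmadillo) with analytic gradients, verified against
finite differences in the test-suite. A pre-trained encoder is not used:
initialization is He-normal from the configured seed, which keeps every
training run self-contained and reproducible.

The composite loss is

$$L = w_{ce} \cdot \mathrm{wCE} + w_{mae} \cdot \mathrm{MAE} + w_{dice} \cdot (1 - \overline{\mathrm{DSC}}_{soft})$$

with weighted cross-entropy (class weights default to inverse pixel
frequency on the training split, mean-normalized), the mean absolute error
between probability maps and the one-hot target over all pixels and
classes, and soft Dice computed on probability mass per class, averaged
over the five classes. Component weights default to (1, 1, 1); all three
components vanish exactly at the one-hot-correct prediction. MAE operands
and the component weights are package decisions where the reference
training recipe leaves them open; both are configurable.

Optimization is Adam (β₁ = 0.9, β₂ = 0.999) with decoupled weight decay
0.005 ("0.5%" interpreted in optimizer units). Training runs a fixed number
of epochs with no early stopping, logs the composite loss and the
validation overall DSC each epoch, and returns the checkpoint of the
best-validation epoch. Augmentation applies rotation, zoom, shear warp and
flips identically to image and mask, photometric jitter and Gaussian blur
to the image only, and paired random erasing (erased image pixels are
zeroed and the corresponding mask region set to class 0).

Two execution profiles exist. The `paper` profile records the reference
conditions: 384-px inputs, learning rate 1e-4, ≥ 300 epochs, batch 26,
dropout 50%, depth 4, 16 base channels. The `tiny` profile is the
desk-scale setting every test uses: 96-px inputs, 20 epochs, batch 8,
depth 2, 6 base channels, learning rate 3e-3. The larger learning rate is
deliberate: the tiny schedule takes roughly two orders of magnitude fewer
optimizer steps than the reference schedule, and a small fully-trained
network on colour-separable phantoms neither needs nor tolerates the
reference rate. Parameter-recovery testing uses threefold (rather than
fivefold) cross-validation on its 24-heart cohort — with eight hearts per
validation fold the out-of-fold estimate is already stable, and the
training cost of the desk-scale suite stays proportionate; the pipeline
default for full-scale runs remains fivefold.

## Infarct-size quantification

For each slice, the per-class pixel areas of the available cut faces
(`areas_from_mask()`) are averaged — slices whose outermost face is not
imaged fall back to their single cut face — and normalized to the weighed
slice mass:

$$m_c = m_{slice} \cdot \bar A_c \,/\, (\bar A_{inf} + \bar A_{aarNI} + \bar A_{rem}),$$

so the LV area is defined as infarct + non-infarcted AAR + remote,
excluding RV and remaining; classes 0 and 4 receive no LV mass. Masses are
summed over slices and

$$\mathrm{IS} = 100 \cdot \frac{\sum_s m_{inf,s}}{\sum_s (m_{inf,s} + m_{aarNI,s})}, \qquad
\mathrm{AAR} = 100 \cdot \frac{\sum_s (m_{inf,s} + m_{aarNI,s})}{\sum_s m_{LV,s}}.$$

Mass weighting makes the estimate robust to varying slice thickness, scale
invariant in the pixel areas, and conservative: per-slice class masses sum
exactly to the slice mass. `quantify_from_masks()` runs the identical code
path for annotation masks and predicted masks, which is what makes the
annotation-versus-prediction agreement analysis meaningful. The formula is
isolated in `slice_class_masses()` so it can be revised independently if a
different normalization is ever preferred.

## Evaluation

Per class: Dice coefficient 2|P∩G|/(|P|+|G|); one-vs-rest accuracy
(TP+TN)/total — true negatives count, which is the only reading under
which small classes can score higher accuracy than Dice; boundary F1 with
a configurable pixel tolerance (default 2 px), where boundaries are class
pixels 4-adjacent to any other class and matching uses exact Euclidean
distances; and average precision as the area under the
precision–recall curve of pixel scores pooled over the whole evaluation
set (tied scores form one threshold group, so constant scores give the
positive prevalence). Overall rows: mean DSC, reference-share-weighted
accuracy, mean bF1 and unweighted mean AP over the five classes.
Empty-versus-empty conventions reward correct absence: DSC and bF1 are 1
when the class is absent from both masks, 0 when absent from exactly one.
High-Dice/low-bF1 combinations are expected whenever area overlap is good
but contours are jittered.

Method agreement: Pearson correlation with the least-squares line;
Bland–Altman bias with limits of agreement at bias ± 1.96 sample SD of the
paired differences; an ANCOVA-style joint F-test of slope = 1 and
intercept = 0 realized as an extra-sum-of-squares test against the fixed
identity line (perfect identity returns p = 1 as a no-divergence
sentinel); and a Kolmogorov–Smirnov normality check against a normal with
plug-in mean and SD (Lilliefors-style caveat: the p-value is approximate).
Significance is read at p < 0.05. Subgroup rows (all / I-R / protected)
mirror the study design; statistics whose sample-size preconditions fail
on a small subgroup are reported as NA rather than aborting the report.

## Numerical choices and degenerate inputs

Probability ties in `maps_to_mask()` resolve to the lowest class index.
Soft-Dice and AP use an epsilon of 1e-7 / exact rational arithmetic
respectively; cross-entropy clips probabilities at 1e-12. Degenerate
inputs raise typed errors rather than producing numbers: slices with no
imaged face or zero LV area, experiments with zero AAR mass (IS undefined
without an AAR), all-background images, constant samples in the KS test,
zero-variance regressors. The quality report returns an infinite PSNR
sentinel for lossless resizing. All randomness flows through R's RNG —
including the compiled dropout, which draws from the R stream — so a
single `set.seed()`/config seed reproduces cohorts, training and reports
bit for bit on one machine.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely on generated
phantoms at desk scale: metric-oracle equivalence on 200 random masks up
to 16×16; quantification recovery on 50 hearts rendered at 256 px;
parameter recovery on 24 hearts at 96 px with threefold cross-validation
under the tiny profile; the full pipeline smoke tests on 6 hearts at
64 px. These sizes are the package's chosen desk-scale study conditions;
the `paper` profile documents the full-scale settings for users with the
data and hardware to run them.

## Known limitations

The phantom domain gap listed above; a compact network (the tiny profile
is sized for phantoms, not photographs); no no-reflow/thioflavin-S
support; no multi-GPU or GPU training — the compiled implementation is
single-threaded CPU code sized for small models; and the KS normality
p-value's plug-in approximation. Applying the package to real photographs
requires training under the `paper` profile on annotated data and, as for
any cross-centre deployment, re-validation on the target image
distribution.
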
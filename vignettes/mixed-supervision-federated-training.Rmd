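---
title: "Mixed histopathology supervision and federated training for prostate mpMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed histopathology supervision and federated training for prostate mpMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedlesion)
```

## The problem

Detecting clinically significant prostate cancer (csPCa, ISUP grade group
>= 2) from multi-parametric MRI is hard for one institution alone: exams are
expensive, annotation practice differs between hospitals, and the
histopathology ground truth attached to an exam comes at wildly different
granularities. One site may contour each MRI-identified lesion and biopsy it
under MR fusion (a *strong*, lesion-level label), sample six fixed sextants
systematically (a *weak*, region-level label), while another site only knows
the highest grade group in the whole exam, not which lesion produced it (a
*weak*, gland-level label). `fedlesion` implements a training system that
uses all of these at once, and a federated loop that lets two such sites
train one model without exchanging images.

## Data model

An exam is a registered 3-channel volume (T2WI, DWI, ADC) with a binary
prostate gland mask and a voxel spacing. Supervision is attached to
*regions*: binary masks of lesions, sextants or the whole gland, each
carrying a supervision signal `z` in {0 = ignore, 1 = strong, 2 = weak} and a
maximum ISUP grade group in {0, ..., 5}. For the binary csPCa task the grade
is binarized at grade group >= 2 (K = 2 classes).

## Preprocessing

MR amplitudes are relative, so each channel is normalized per exam:

1. **IQR99**: `(I - p1) / (p99 - p1)` with both percentiles computed over
   gland voxels only; by default the result is clamped to [0, 1] to remove
   artifact outliers. The clamp is a flag (`clip`) because the rescaling
   itself is what the definition states; percentiles use linear interpolation
   between order statistics (type-7 quantiles), a convention the definition
   leaves open.
2. **Z-score**: gland voxels are shifted/scaled to zero mean, unit standard
   deviation. Applied to all three channels by default; the narrower reading
   (T2WI and DWI only) is available via the `channels` argument. Out-of-gland
   voxels receive the same affine maps, since the network sees full volumes
   while statistics are defined in-gland.

Resampling to a common grid (e.g. `[0.66, 0.66, 2.24]` mm for clinical
volumes) uses trilinear interpolation for channels and nearest-neighbour for
masks, with a voxel-center coordinate convention.

## The multi-task objective

The model predicts a tanh-activated lesion segmentation map, a
softmax-activated K-channel grade-group map, the *soft region histogram*
`h[r] = mean over region voxels of the softmax vector` for every region, and
a per-region classification from a small perceptron head on those
histograms. The loss is dynamically populated from the supervision signals:

* `L_segmentation = L_dice + L_BCE` on the lesion mask union, through
  `p = (yhat + 1)/2`. The dice form is `1 - (y . p)/(|y| + |p| + eps)`; note
  the numerator carries no factor 2, so perfect overlap scores 0.5 — the
  conventional form is available via `dice_variant = "standard"`. With an
  empty target mask the form evaluates to exactly 1 with zero gradient, so
  negative exams are driven by the BCE term alone.
* `L_GGmap`: voxel-mean categorical cross-entropy of the grade map inside
  strongly supervised *lesion* regions (homogeneous tissue), averaged over
  those regions.
* `L_hist_strong`: cross-entropy between each signal-1 region's one-hot grade
  and its soft histogram.
* `L_hist_high`: for each signal-2 region, histogram bins *above* the
  labelled grade bin are pushed toward zero mass via `-log(1 - h[r, k])`.
  This implements the stated intent — suppress the proportion of voxels at
  grades the histopathology does not support — because the literal printed
  weighting (the one-hot label evaluated above its own bin) is identically
  zero; that literal form is kept behind `hist_high_variant = "as_printed"`
  and warns.
* `L_region_classifier`: cross-entropy of the classification head on all
  supervised regions (signal 1 or 2).

Terms are combined as `sum_i alpha_i * lambda_i * term_i` with defaults
`alpha = lambda = (1, 1, 1, 1)`; any term whose active-region set is empty
contributes exactly 0, so an exam with only an exam-level label trains
exactly the terms its data supports. Numerical choices: a stability floor
`delta = 1e-6` inside every logarithm (with zero subgradient in the clamped
region), voxel-mean reduction within regions and region-mean across regions,
and `eps = 1e-6` in the dice denominator.

Membership of the active sets is not fully pinned down by the objective's
printed form; the defaults are: strong voxel-wise grading uses signal-1
regions of kind *lesion*; the strong histogram term uses all signal-1
regions; suppression uses all signal-2 regions; the region classifier uses
their union. All four are overridable per call via `select`.

## The network

A small 3D residual encoder-decoder written for exact analytic
backpropagation (there is no automatic-differentiation framework among this
package's dependencies, so gradients are hand-derived and checked against
central finite differences in the test suite):

* stem convolution, then per level a residual block (two 3x3x3 convolutions
  with instance normalization, additive skip, ReLU);
* stride-2 convolution downsampling; factor-2 trilinear upsampling with a
  convolution and additive encoder skips on the way up;
* two 1x1x1 heads (tanh segmentation, softmax grading) on the full-resolution
  features, and a two-layer perceptron on the K-vector histograms for region
  classification.

At the defaults (`base_width = 8`, `depth = 2`, K = 2) the model has about
29k parameters, so the whole system trains in CPU minutes. Grid dimensions
must be divisible by `2^(depth - 1)`.

## Federated simulation

The federated loop implements FedSGD with a server-side optimizer: each
round the server broadcasts the global weights; every client computes the
gradient of the composite loss on one batch of its own data (mean-reduced)
and returns only that gradient plus its sample count; the server averages
the updates (sample-weighted by default) and applies one AdamW step
(decoupled weight decay; momentum state lives only on the server). With
mean-reduced client losses and sample weighting, one federated round over
any partition of a batch is *exactly* one centralized AdamW step on the
pooled batch — gradient linearity — which the tests assert to 1e-5 relative;
this equivalence is the core correctness oracle of the loop. The AdamW
defaults are lr 1e-3, betas (0.9, 0.999), decay 1e-2.

Validation stays private: each client scores every broadcast model on its
own validation split and keeps its own best round, so a two-site federation
ends with two — possibly different — best checkpoints. The private metrics
are computable at any supervision granularity from data every site owns:
exam-level class-balanced accuracy (an exam is called positive when any of
the site's own lesion contours is predicted clinically significant; the
exam-level maximum grade group is known everywhere, even where per-lesion
grades are not) and mean lesion IoU against the site's own contours. The
default selection metric is the class-balanced accuracy, with IoU as
fallback; metric ties prefer the later, more trained round. The experiment
runner instead selects by the `"overall"` metric — the geometric mean of
balanced accuracy and 100 x IoU — because at desk scale a site's exam-level
accuracy alone moves in coarse noisy steps, and a single early noise spike
would otherwise freeze that site's checkpoint on a barely trained model;
the geometric mean demands that a checkpoint perform on both tasks at once.
Training under the experiment defaults also anneals the learning rate
(constant for the first 60% of the run, cosine decay to 10% thereafter),
which damps the late-round oscillation of the multi-task trade-off so that
late checkpoints are uniformly usable. Only the sharable update ever
crosses the client-server boundary. One batch per client per round (pure
FedSGD); multi-step local epochs in the FedAvg style are out of scope.

## The synthetic two-site benchmark

No public cohort accompanies this problem, so the package ships a phantom
generator that reproduces the *statistical and annotation structure* the
training system assumes, at desk scale (default 32 x 32 x 16 voxel grids):

* an ellipsoidal gland with mild per-exam shape jitter;
* 0-N anisotropic Gaussian-blob lesions thresholded at half maximum, placed
  inside the gland with bounded retries;
* every MRI-identified lesion is T2-hypointense (that is what makes it an
  MRI-identified lesion, and what makes segmentation well-posed even for
  benign lesions); DWI hyper- and ADC hypo-intensity grow linearly with the
  grade *tier* (GG0, GG1, GG2, GG3-5) at 1.5 x noise sigma per tier — chosen
  so the easy benchmark is learnable by the small default model in under ten
  epochs; the hard preset halves it;
* exam maximum-grade categories are drawn from a configurable prevalence
  (default uniform over the four tiers, echoing the rough balance of
  grade-group tables in multi-site cohorts);
* sextants are a geometric division: left/right of the gland bounding box's
  midsagittal plane crossed with three axial thirds.

Two site presets create the heterogeneity a federation has to survive.
Site A emulates an endorectal-coil acquisition with strong annotations:
higher noise, a multiplicative posterior-anterior bias field, per-lesion
bounding-box regions (signal 1) plus six sextants (signal 2). Site B
emulates an external-coil 3D protocol with weak annotations: lower noise,
smooth anatomy-like background texture, contoured lesions used only as
segmentation labels, and one exam-level gland region (signal 2). The sites
also weight DWI vs ADC differently in their grade contrast
(`channel_effects`), emulating protocol differences such as acquisition
b-value; unlike the additive channel offsets (which the Z-score step
removes), these structural differences survive preprocessing and are what
makes locally trained models degrade across sites. All heterogeneity
magnitudes are free parameters of `site_config()`, since no quantitative
inter-site statistics are published for this setting; the preset values were
fixed once when the generator was designed.

One master seed drives named substreams (gland, grades, placement, texture,
noise, model init, batch order), so adding exams never perturbs earlier ones
and every artifact is bit-reproducible.

What the phantom does *not* emulate: prostate anatomy beyond an ellipsoid,
zonal structure, MR physics (k-space, partial volume), registration error
between channels, or realistic lesion morphology. Passing the benchmark
therefore demonstrates that the supervision machinery, optimization and
federation are correct and that the system can recover planted signal under
site shift — not clinical performance.

## Evaluation

* **Lesion IoU**: per-exam intersection-over-union of the thresholded
  segmentation map (threshold 0 on the tanh scale, i.e. 0.5 in probability),
  averaged over exams. An exam with no lesion predicted clean scores 1; if
  exactly one mask is empty, 0.
* **Class-balanced accuracy**: each row of the region-wise confusion matrix
  is normalized to recall rates and the diagonal averaged (occurrence
  normalization); for K = 2 this is exactly `100 * (TNR + TPR) / 2`. The
  headline classification metric uses lesion-kind regions only; sextant and
  gland regions feed training and the private validation metric but not the
  headline number.
* **Cross-site grid**: every checkpoint evaluated on every site's test split,
  with federated-minus-local deltas per test site.

## Experiment defaults and problem sizes

`run_experiment()` wires the full pipeline (synthesize, preprocess, local
training per site, federated training, cross-site grid). Its defaults —
60/10/15 train/val/test exams per site, batch size 4, 10 epochs, AdamW lr
3e-3 with weight decay 1e-2, loss weights `lambda = (2, 1, 2, 3)` — were
calibrated once on the easy benchmark so that within-site lesion IoU exceeds
0.5 and lesion balanced accuracy exceeds 80% inside the 20-epoch budget on a
single CPU. The extra weight on the segmentation term compensates for
lesions occupying well under 1% of the voxels; the extra weight on the
region-classifier and voxel-grading terms keeps classification learning at
pace with segmentation, which matters most in federated runs where the
weakly supervised site dilutes the classification gradient (a federated run
needs roughly twice as many rounds as a local run takes steps before
classification emerges). The acceptance checks in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` run reduced
problem sizes (24 x 24 x 12 grids and 40 train exams per site for the
three-seed cross-site comparison) so the whole suite stays inside
CPU-minutes; these sizes are recorded there explicitly.

## Known limitations

* The literal printed suppression term is unusable for one-hot labels (see
  above); the implemented form is the documented intent.
* The dice variant without the factor 2 bounds the achievable dice term at
  0.5 from below; both variants are provided.
* Balanced accuracy is undefined when a true class is absent from an
  evaluation set; small validation splits therefore fall back to IoU for
  checkpoint selection rather than skipping rounds.
* K > 2 grading is structurally supported (histograms, losses and heads are
  K-generic) but only exercised at K = 2, matching the binary csPCa task.
* The federated loop is a local simulation: no transport, serialization
  security, TLS, or asynchronous aggregation.
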
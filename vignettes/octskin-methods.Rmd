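---
title: "Measuring epidermal thickness in skin OCT with few labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring epidermal thickness in skin OCT with few labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octskin)
```

## The problem

Epidermal thickness is a clinically meaningful readout in wound healing and
many other dermatologic conditions, and optical coherence tomography (OCT)
can measure it noninvasively: in a B-scan the epidermis appears as a
relatively bright band between the skin surface and the dimmer dermis, and
its per-A-line extent converts directly to micrometres through the axial
pixel pitch. Segmenting that band automatically is easy when thousands of
expert-labelled B-scans are available and very hard when they are not —
which is the situation for patient data, where each volume may contribute
hundreds of B-scans but almost no annotations.

`octskin` implements a transfer strategy for exactly this regime. A
multitask U-Net is pretrained on a *source domain* where labels are
plentiful (rodent-like skin: a very thin epidermis, under ~25 µm, with
strong epidermis/dermis contrast) and then fine-tuned on a *target domain*
(human-like skin: an epidermis thicker than ~50 µm with weaker contrast,
especially in burn lesions) using only **one or three labelled B-scans per
volume**. Wound scabs are segmented jointly with the epidermis because a
scab sits directly on top of it and would otherwise corrupt the upper
boundary.

Because no public OCT volumes accompany this problem setting, the package
ships a speckle phantom generator with analytic ground truth. All
quantitative statements in the package's tests are statements about those
phantoms, not about clinical data.

## Model

The network is a U-Net with one shared down-sampling encoder and two
decoder heads:

* the **object head** ends in a 1×1 convolution and a 3-class softmax over
  (background/other, epidermis, scab), giving per-pixel probabilities
  $N_o(x, c)$;
* the **contour head** ends in a single sigmoid channel $N_c(x)$ trained on
  a binary band of width 5 px centred on every annotated interface.

Every scale applies two 3×3 convolutions, each followed by batch
normalisation and a leaky rectifier (negative slope 0.01); down-sampling is
2×2 max-pooling with stride 2 and up-sampling a 2×2 transposed convolution
with stride 2, with encoder features concatenated at the matching scale.
Because the encoder is shared, gradients from either head update it; the
two heads never receive each other's gradients. This wiring is asserted
bit-exactly in the test suite.

Pretraining minimises the total loss

$$L_\text{total}(\theta) = \lambda\,\psi(\theta)
  - \sum_{x} \log N_o(x, l_o(x))
  - \sum_{x} \log N_c(x, l_c(x)),$$

a pixel-summed cross-entropy of both heads plus an L2 penalty
$\psi(\theta)$ on all convolution weights (never on normalisation
parameters or biases), with $\lambda = 10^{-4}$ by default. The transfer
(fine-tuning) loss is the per-pixel *mean* three-class cross-entropy of the
object head only,

$$L_\text{transfer} = -\frac{1}{|X|}\sum_{x}\sum_{c=1}^{3} y_c(x) \log N_o(x, c),$$

so the contour head is untouched during transfer unless explicitly
included. The sum/mean scale difference between the two losses is absorbed
by the learning rates. Probabilities are clamped at $10^{-12}$ before any
logarithm.

## The three-step strategy

1. **Pretrain** on labelled source-domain B-scans (default: Adam, learning
   rate 3e-3, batch 4, 30 epochs at desk scale).
2. **Select** the labelled target subset: `baseline` uses none, `method1`
   one random B-scan per target volume, `method2` three. Selection is
   nested — for a fixed seed the method-1 image is the first of the
   method-2 triple — so strategy comparisons share labels.
3. **Fine-tune** with the transfer loss at a lowered learning rate (Adam,
   1e-4, 50 epochs), starting from the pretrained parameters; `baseline`
   skips this step entirely.

Two training defaults deviate from the obvious first choice, in both cases
after measurement:

* **Pretraining learning rate 3e-3** (not 1e-3). At desk scale the whole
  pretraining budget is ~240 Adam steps; at 1e-3 the total loss stalls an
  order of magnitude higher and the encoder features transfer poorly.
* **Fine-tuning batch size 1** (not 4). With one labelled image per volume
  the transfer set is tiny; single-image batches give four times as many
  Adam steps for the same 50-epoch schedule and measurably better target
  Dice. Batch statistics over a single image are spatial statistics, which
  is acceptable at these image sizes.
* **Base width 12** at depth 3. Width 8 underfits the pretraining set
  (final loss ~2.6× higher); width 16 doubles the cost for no accuracy
  gain at this scale.

Fine-tuning updates all parameters by default; `freezeEncoder = TRUE`
restricts updates to the heads. An option `includeContour = TRUE` adds the
contour binary cross-entropy to the transfer loss; it is off by default
because the transfer objective is a single task.

## Fusion of the two probability maps

The literal threshold rule combines a scalar object map and the contour
map per pixel:

$$s(x) = \begin{cases}
2 \text{ (scab)} & N_o(x) < t_{O1} \wedge N_c(x) < t_{C1} \\
1 \text{ (epidermis)} & t_{O1} \le N_o(x) < t_{O2} \wedge N_c(x) < t_{C2} \\
0 & \text{otherwise,}
\end{cases}$$

with all four thresholds defaulting to 0.5. At those defaults
$t_{O1} = t_{O2}$ makes the epidermis branch **empty** — `fuseEq2()` keeps
the rule exactly as printed, the package warns about the degeneracy at
construction, and the tests assert it against a brute-force per-pixel
oracle. The intended channel semantics of the scalar $N_o$ are not
recoverable, so the rule is retained as a testable operation rather than a
pipeline stage.

`fusePractical()` is the contour-aware alternative: argmax over the object
channels, with boundary-uncertain pixels ($N_c \ge t_{C1}$) reassigned to
the class of the nearest non-contour pixel along their A-line (distance
ties break toward the smaller class index). One guard was added after
measurement: reassignment reaches at most `maxShiftPx = 2` pixels — the
half-width of the 5-px training band — because a pixel farther than that
from every anchor cannot belong to a genuine band. Without the guard, the
bands around the two boundaries of any layer not much thicker than the
band merge, no interior anchor survives, and the rewrite erases the layer
(always for the ≤3 px source-domain epidermis; a loss of ~0.4 Dice even on
fine-tuned target phantoms).

Even with the guard, the rewrite erodes one to two boundary rows per
interface on layered phantoms, because the predicted band is wider than
the trained one and asymmetric about the true boundary. The pipeline
default in `segmentVolume()` is therefore the plain object-head **argmax**:
on this data the contour task earns its keep during training, by shaping
the shared encoder, not at fusion time. Both other modes remain
selectable.

Segmentation cleanup suppresses misclassified islands per foreground
class. Keeping only the largest connected component proved destructive on
fragmented predictions (it halves the Dice of a weak model and still costs
a well-trained one ~0.05); instead, components smaller than 1/8 of the
class's largest component are removed. The threshold is deliberately
permissive: it deletes speckle islands while keeping genuine fragments.

## Thickness mapping

For each A-line of each segmented B-scan, the epidermal thickness in
pixels is `bottom − top + 1` of the *largest* contiguous epidermis run
(ties go to the shallower run), which is robust to isolated residual
speckle labels. A-lines with no epidermis pixel are undefined; they are
rendered as 0 in exported maps but excluded from every statistic. The
micrometre view multiplies by the axial pitch, 8 µm/px by default, chosen
so that 80 px correspond to 640 µm. Volume-level agreement is reported as
the absolute difference of mean thickness per volume, aggregated as
mean ± sd across volumes.

## Metrics

IoU and Dice are computed by direct pixel counting; Dice is additionally
checked against the identity $\mathrm{DSC} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$
on every call. Surface points are foreground pixels with a background
4-neighbour, with the image border treated as background. ASSD is the
standard symmetric form
$(\sum_p d(p, S_{gt}) + \sum_q d(q, S_{pred}))/(n_1 + n_2)$ and the
Hausdorff distance the max of the two directed maxima; both use Euclidean
distances in isotropic pixel space scaled by the axial pitch, and both are
validated against an exhaustive $O(n_1 n_2)$ pairwise oracle in the tests.
Conventions for degenerate inputs are explicit: two empty masks are
perfect agreement (IoU = DSC = 1, ASSD = HD = 0); a single empty mask has
no defined surface distance and raises an error.

## The phantom generator

Each B-scan is built from analytic layer geometry:

* a skin **surface** row per A-line: a Gaussian-smoothed random profile
  (amplitude 3 px, correlation ~12 px) around a mean depth of one third of
  the image;
* an **epidermis** band below it whose thickness profile is smoothed noise
  clamped to the domain regime — source: mean 2.4 px, clamp [1, 3]
  (under 25 µm at 8 µm/px); target: mean 9 px, clamp [7, 12] (over 50 µm);
* an optional **scab cap** sitting directly on the epidermis in wound
  sessions S1–S3, with lateral extent 0.6/0.4/0.2 of the width shrinking
  as healing progresses; `control` has none;
* **dermis** filling the rest of the image.

Sampled surface profiles are clipped to the feasible imaging window (the
scab cap must stay inside the image and at least one dermis row must
remain below the epidermis); geometry that cannot fit at any surface
position — an epidermis thicker than the image, say — raises an error
naming the offending A-line. The image is a piecewise-constant
reflectivity field (air 0.02; source:
epidermis 0.85, dermis 0.35, scab 0.72; target: epidermis 0.55, dermis
0.38, scab 0.6) attenuated by $e^{-0.02 d}$ with $d$ the depth below the
tissue entry row (air above the skin is unattenuated), multiplied by
gamma-distributed speckle (shape 3, mean 1 — the standard OCT
envelope-statistics choice) and perturbed by additive Gaussian noise
(sd 0.02), then clipped to `[0, 1]`. The reduced target-domain
epidermis/dermis contrast (0.17 vs 0.50 reflectivity difference) is the
deliberate analogue of the low lesion contrast that makes direct transfer
fail. Equal parameters and seed give bit-identical output, and the truth
object carries boundaries, masks and the en-face thickness map exactly.

What the phantoms do **not** model: coherent point-spread physics,
refraction, vasculature, scab texture heterogeneity, motion and shadow
artefacts. Passing the phantom suite therefore demonstrates that the
method's machinery — losses, gradients, transfer, fusion, thickness
mapping, metrics — behaves as specified under a controlled domain shift;
it does not certify clinical accuracy on real data.

## Label conventions

Class masks use 0 = background/other, 1 = epidermis, 2 = scab. The contour
band marks every annotated interface (foreground against background and
the epidermis–scab interface): boundary pixels are foreground pixels with
a 4-neighbour of a different class, and the band is their Chebyshev
dilation of radius `(width − 1)/2`. Measured along an edge normal away
from corners the band is exactly `width` (default 5) pixels thick, and an
isolated pixel produces its full 5×5 neighbourhood. Whether the original
annotation tool drew its band inside, outside or centred on the boundary
is unknowable; anchoring on the outermost foreground ring is assumed, and
it is what makes the 5-px thickness exact. Even widths are rejected since
the band could not be centred.

## The desk-scale domain-shift experiment

`domainShiftExperiment()` packages the whole protocol: 32 source B-scans
(64×64 px, sessions cycling through control/S1/S2/S3), a depth-3 width-12
network pretrained for 30 epochs, 8 target volumes of 4 B-scans for
fine-tuning with one (or three) labelled B-scans each for 50 epochs at
learning rate 1e-4, and 8 held-out target volumes for evaluation by mean
epidermis Dice. These sizes were chosen so a full five-seed replicate runs
in minutes on one core while leaving a clear gap between strategies; the
acceptance suite asserts the orderings (baseline < method 1,
method 1 ≤ method 2 + 0.03) and the method-1 level (≥ 0.8 mean Dice over
five seeds) at exactly these sizes. They are orderings on phantoms; the
absolute clinical values of the original setting are out of reach by
construction.

## Numerical choices and degenerate inputs

* Probability clamp $10^{-12}$ before logarithms; batch-norm
  $\varepsilon = 10^{-5}$, running-statistics momentum 0.1 (inference uses
  running statistics).
* He-scaled normal initialisation, deterministic per seed; Adam with
  $\beta = (0.9, 0.999)$, $\varepsilon = 10^{-8}$. Parameters without
  gradients are never touched by the optimiser, which is what makes the
  head-isolation guarantees bit-exact.
* Forward passes require spatial sizes divisible by $2^\text{depth}$;
  `segmentVolume()` reflect-pads and crops back for other sizes.
* An A-line that is contour everywhere keeps its argmax classes; an
  all-background prediction yields an all-undefined thickness map, and
  asking for its mean raises an explicit error rather than returning NaN.
* Checkpoints store config, seed, parameters and running statistics; a
  JSON manifest carries an architecture hash and loading refuses a
  checkpoint whose hash disagrees.

## Known limitations

* The phantom's layer model is piecewise-constant; real dermal texture,
  vasculature and artefacts are absent, so the domain gap here is milder
  and better controlled than the real interspecies gap.
* The contour head's value is indirect (encoder shaping); on this data its
  fusion-time use is neutral at best.
* Cycle-GAN-style unsupervised augmentation (the third strategy of the
  original setting) is out of scope.
* Surface distances are 2-D per B-scan; no volumetric surface metrics.
* Training is single-threaded CPU code built for desk-scale problems, not
  a general-purpose deep-learning framework.
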
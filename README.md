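# octskin

Contour-aware, few-label segmentation of skin layers in optical coherence
tomography (OCT), for measuring epidermal thickness.

Epidermal thickness is a key readout in wound healing and other
dermatologic conditions, and OCT images it noninvasively: the epidermis is
a bright band between the skin surface and the dimmer dermis, and its
per-A-line extent converts to micrometres through the axial pixel pitch
(8 µm/px here; 80 px ↔ 640 µm). Supervised segmentation of that band needs
labels that patient data rarely has. `octskin` implements a transfer
strategy for that regime:

1. **Pretrain** a multitask U-Net — shared encoder, a 3-class object head
   (background / epidermis / scab) and an auxiliary contour head trained on
   5-px boundary bands — on a label-rich *source domain* (rodent-like skin:
   epidermis < 25 µm, high contrast), minimising
   `λ·ψ(θ) − Σ_x log N_o(x, l_o(x)) − Σ_x log N_c(x, l_c(x))`.
2. **Fine-tune** on a *target domain* (human-like skin: epidermis > 50 µm,
   low lesion contrast) with only **one** (`method1`) or **three**
   (`method2`) labelled B-scans per volume, minimising the per-pixel mean
   cross-entropy `−Σ_c y_c log p_c` of the object head at a lowered
   learning rate (1e-4, 50 epochs). `baseline` skips this step.
3. **Segment** whole volumes, fuse the probability maps into class masks,
   and map **en-face epidermal thickness** per A-line.

Evaluation uses IoU, Dice (`DSC = 2·IoU/(1+IoU)`), average symmetric
surface distance and Hausdorff distance (µm). Because no public data
accompany the setting, the package ships a speckle phantom generator
(layered reflectivity × exponential depth attenuation × gamma speckle)
with analytic ground truth; the two phantom domains reproduce the
interspecies thickness and contrast shift. The network and its training
(convolutions, batch norm, backprop, Adam) are implemented in the package
itself with RcppArmadillo kernels — no external deep-learning framework.

## Worked example

Generate a human-like wound phantom, segment it with a pretrained +
fine-tuned model, and measure thickness:

```r
library(octskin)

# a target-domain volume at wound stage S1 (scab cap present)
p <- domainPreset("target", "S1", height = 64, width = 64, seed = 42)
g <- makeVolume(p, nBScans = 4)

# the packaged desk-scale experiment: pretrain on 32 source B-scans,
# fine-tune with 1 labelled B-scan per target volume
ex <- domainShiftExperiment(seed = 1, strategies = c("baseline", "method1"))
round(ex$dice, 3)
#> baseline  method1
#>    0.317    0.833

model <- ex$models$method1
masks <- segmentVolume(model, g$volume)          # argmax + island cleanup
tm <- thicknessMap(masks, pitchUm = 8)
meanThickness(tm)
#>    meanUm      sdUm         n
#>  67.09375  17.22899 256.00000

# against the analytic truth
thicknessDeviation(tm, truthThicknessMap(g$truth))
#> meanUm   sdUm      n
#>    2.5    0.0    1.0
```

The Dice numbers are the headline behaviour: applying the source-pretrained
model directly to the shifted target domain fails (Dice ≈ 0.32, it finds
only a thin sliver of the thick epidermis), while fine-tuning on a single
labelled B-scan per volume restores Dice ≥ 0.8. The thickness map says the
segmented epidermis of this wound phantom averages ~67 µm over its 256
A-lines, and the volume-mean thickness is within 2.5 µm of the analytic
truth (the original protocol calls single-digit micrometre deviations
clinically acceptable).

A thin CLI wrapper over the same functions lives at
`inst/scripts/octskin.R` (`phantom`, `pretrain`, `finetune`, `segment`,
`thickness` subcommands).

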
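# raxseg

Weakly supervised segmentation of 2-D hand radiographs in R: a
dual-attention (CBAM + scSE) encoder–decoder network trained on CLAHE+Otsu
pseudo-masks, with a seeded synthetic phantom generator, boundary-aware
evaluation metrics, and a patient-level training/ablation harness. The
package targets the musculoskeletal-radiography setting — thin cortical
rims, overlapping bones, low-contrast joint spaces, scarce expert labels —
and is aimed at imaging researchers who want a reproducible, CPU-testable
reference implementation of this pipeline.

## What's inside

**Model.** A U-Net-style decoder over a pluggable four-stage feature-pyramid
encoder (taps at strides 4/8/16/32). Each of the three up blocks is
`upsample ×2 → concat skip → 2×(Conv–BN–SiLU)`; the first block gates the
encoder skip with scSE before fusion, the later blocks apply CBAM to the
concatenated tensor and scSE after the convolutions, then a bilinear ×4
upsample and a 1×1 sigmoid head. All layers (including backprop and AdamW)
are implemented natively in R and validated by finite-difference gradient
checks.

**Objective.**

    L = 0.45·L_Dice + 0.35·L_BCE + 0.20·L_Lovász

with the squared-denominator soft Dice on sigmoid(logits), logit-domain BCE,
and the per-image Lovász hinge (sorted hinge errors dotted with the discrete
Jaccard gradient, verified against an exhaustive prefix-Jaccard oracle).
Tversky and Focal-Dice losses are included for study.

**Weak supervision.** `make_pseudo_mask()`: CLAHE (clip 2.0, 8×8 tiles) →
global Otsu threshold relaxed by 0.95 → opening/closing (disk radius 2) →
largest 8-connected component.

**Evaluation.** Dice/IoU/accuracy/precision/recall, leakage rate
(1 − precision), boundary F1 and boundary pixel accuracy, ASSD / HD95 /
surface Dice (distance-transform based, oracle-verified), ROC/PR AUC,
seeded bootstrap CIs and paired Wilcoxon tests.

**Phantoms.** `generate_phantom()` draws seeded hand silhouettes (palm +
carpal block + finger capsules with joint gaps) with ~35% foreground
coverage, bimodal exposure (mean-intensity modes near 0.30 and 0.60), a
smooth multiplicative bias field and Gaussian noise — so the whole pipeline
is testable offline.

## Worked example

```r
library(raxseg)

## a phantom and its pseudo-mask
s  <- generate_phantom(phantom_config(seed = 5, noise_sigma = 0, bias_strength = 0))
pm <- make_pseudo_mask(s$image)
overlap_metrics(pm, s$mask)$dice
#> [1] 0.9801797

## profile the reference encoder backbones
profile_table()
#>          backbone  params_M     gmacs   fp32_mb input_size
#> 1   convnext-tiny 28.589128 4.4555313 114.35651        224
#> 2        resnet50 25.557032 4.0891843 102.22813        224
#> 3 efficientnet-b0  5.288548 0.3858148  21.15419        224
#> 4 efficientnet-b3 12.233232 1.7241014  48.93293        300

## patient-level splits at a typical collection size
man <- data.frame(image = sprintf("i%03d", 1:185),
                  patient_id = sprintf("p%03d", 1:185),
                  coverage = runif(185, 0.2, 0.5))
table(make_splits(man, seed = 1)$split)
#>  test train   val
#>    28   129    28

## end-to-end demo: phantoms -> pseudo-masks -> splits -> training -> report
report <- end_to_end_demo(seed = 5, out_dir = "demo_run")
jsonlite::read_json(file.path("demo_run", "test_summary.json"))$test_dice_fixed
#> [1] 0.8003247
```

`profile_table()` reports the trainable parameters and forward
multiply-accumulates of the standard ImageNet classification form of each
encoder (1000-class head, standard input resolution, MAC convention; FP32
size = 4 bytes/parameter). The demo's Dice is measured on held-out phantoms
against the *true* masks after training only on pseudo-masks — i.e. it
quantifies what the weak-supervision pipeline recovers end to end.

A thin command-line wrapper lives at `inst/cli/raxseg.R`
(`phantoms`, `pseudomask`, `train`, `eval`, `ablate`, `profile`, `demo`).

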
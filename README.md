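# kbfmgmt

Identifying MGMT promoter methylation — an epigenetic marker that
predicts glioblastoma response to alkylating chemotherapy — directly
from brain MRI, without tumor segmentation masks. The package implements
the full pipeline for radiologists' most routine sequences, FLAIR and
T1-weighted:

1. **Volume reconstruction** from DICOM series (slices ordered by the
   *Slice Location* tag; geometry from *Pixel Spacing*, *Spacing Between
   Slices* and *Image Orientation*), plus a minimal DICOM writer and
   NIfTI I/O for testing and interchange.
2. **Preparation**: trilinear resampling to 1 mm isotropic voxels,
   reorientation to a sagittal standard, 6-DOF rigid inter-modality
   registration by normalised mutual information, and skull stripping
   (external brain mask preferred, intensity-based fallback included).
3. **Knowledge-based filtering (KBF)** — the core idea. Tumor tissue is
   FLAIR-bright and T1-dark (above CSF): each modality is split at its
   intensity mode over in-brain voxels, the brightest 25% of supra-mode
   FLAIR voxels are intersected with the darkest 25% of sub-mode T1-w
   voxels, and the resulting unsupervised ROI mask multiplies the FLAIR
   volume point-wise. The product is cropped to a fixed cube around the
   brain (ROI voxels are never lost) and min-max normalised to [0, 1]
   per patient.
4. **Classification** by `MGMTClassifier`: seven depthwise-separable
   convolutional blocks (kernel 3, stride 2, padding 1; pointwise 1x1x1;
   batch norm; ReLU; 8 channels doubling to 512) and two fully connected
   layers on a single logit — in 2D (slice-averaged) or 3D form, trained
   with Adam (5e-4, batch 8) and binary cross-entropy.
5. **Evaluation** by stratified patient-level k-fold cross-validation
   (single-, cross- and merged-dataset modes) with ACC, SPE, SEN, PRE,
   F1 and rank-based AUC; **explainability** by integrated gradients and
   occlusion maps.
6. A seeded **phantom generator** that instantiates exactly the
   intensity assumptions the filter relies on, with ground-truth tumor
   masks and a methylation label carried by tumor texture — so the whole
   pipeline is testable without patient data.

## Worked example

```r
library(kbfmgmt)

# a synthetic patient: paired FLAIR/T1-w with a ground-truth tumor mask
ph <- make_phantom(phantom_params(), seed = 1, label = 1)
ph
#> <phantom> phantom000001: 64^3 voxels, label 1, 1162 tumor voxels

# unsupervised tumor-ROI preselection
kb <- kbf_pipeline(ph$flair, ph$t1, ph$brain_mask,
                   kbf_params(crop_side = 64))
kb$roi
#> <roi_mask> 1332 selected voxels of 262144 (0.51%)
dice_coefficient(kb$roi$grid, ph$tumor_mask)
#> [1] 0.8757017

# train on a small strong-signal cohort and score held-out patients
co <- make_cohort(16, prevalence = 0.5,
                  params = phantom_params(label_effect = 70), seed = 7)
ds <- cohort_inputs(co, kbf_params(crop_side = 64), dims = 3)
fit <- train_fold(ds$x[1:12], ds$y[1:12],
                  classifier_spec(dims = 3, input_side = 64),
                  train_config(max_epochs = 60, seed = 1,
                               weight_decay = 1e-3,
                               augmentation = augmentation_config(
                                 rotation_range = 0, flip_axes = 1:3,
                                 probability = 0.7,
                                 ortho_rotations = TRUE)))
fit
#> <mgmt_fit> 3D classifier, 12 training patients, 60 epochs
#>   final training loss 0.3724 (initial 0.9268)
#>   223292 trainable parameters

predict(fit, ds$x[13:16])     # per-patient methylation probabilities
#> [1] 0.1284 0.9865 0.9191 0.0763
ds$y[13:16]
#> [1] 0 1 1 1
evaluate_predictions(predict(fit, ds$x[13:16]), ds$y[13:16])
#> ACC 0.7500  SPE 1.0000  SEN 0.6667  PRE 1.0000  F1 0.8000  AUC 0.6667
#> TP 2  TN 1  FP 0  FN 1

# explain a prediction: most informative slice of the attribution map
summarize_slice(integrated_gradients(fit, ds$x[[13]], steps = 64))
#> <attribution_slice> slice 24 (integrated_gradients), |attribution| = 21.4
```

The numbers above come from the fixed seeds shown. The Dice of ~0.88
says the unsupervised filter localises the tumor well (the method aims
at localisation, not voxel-perfect segmentation); the 12-patient toy
training set misses one held-out positive — the full-scale experiment
behind `scripts/acceptance.R` uses 40 phantoms and 120 epochs and
separates the classes cleanly.

A thin command-line wrapper ships in `exec/kbfmgmt`
(`simulate`, `prep`, `kbf`, `describe` subcommands).

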
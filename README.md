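# oarclass

Image-based classification of radiotherapy organ-at-risk (OAR)
delineations by **delineation guideline**, plus the evaluation harness
showing why the distinction matters.

Radiotherapy structure archives mix contours drawn under different
guidelines (clinical protocols, commercial AI models, older
conventions), and the structure name says nothing reliable about which
one. Training a segmentation model on such a mixture degrades it.
`oarclass` implements, end to end and in pure R:

- **Preprocessing**: CT + structure set → two-channel classifier input
  (z-score-normalized CT + *AddMap*, the joint body/structure encoding
  `(body + structure)/2` with values 1 / 0.5 / 0 for overlap /
  body-only / background), via quadratic-B-spline / nearest-neighbor
  resampling, body masking and cropping, a 96-slice structure-centered
  window, and symmetric zero-fill to a fixed grid.
- **Training**: a compact 3D CNN backbone (pluggable contract) trained
  with balanced weighted cross entropy, learning-rate plateau halving,
  and early stopping on the **custom precision**
  `CP = Σ_{i≠j} P_i` — the sum of per-class precisions excluding the
  catch-all `"Other"` class — under 5-fold patient-level cross
  validation.
- **Inference**: per-fold prediction, majority voting (ties by summed
  probability, then vocabulary order), optional **structure-name
  exclusion** (lowercase substring keywords force `"Other"`), a CSV
  report and class-sorted file copies.
- **Evaluation**: per-class/macro/weighted precision, recall, F1,
  confusion matrices; DSC, HD95 and MSD (oracle-verified) with
  superior truncation; exact two-sided Wilcoxon signed-rank test.
- **Synthetic phantoms**: pelvic CT phantoms with every organ in two
  parametric guideline variants (dilation/extension, bladder-wall
  erosion) and keyword-named nuisance structures, so the whole
  pipeline is testable without clinical data.
- **Mixed-guideline demo**: a small segmentation learner trained
  coherently vs on a 50/50 guideline mixture, evaluated with
  DSC/HD95/MSD and Wilcoxon comparisons.

I/O is NIfTI (`image.nii.gz` + `mask_<Name>.nii.gz` per patient
folder) or a minimal DICOM CT + RT-STRUCT codec; see the methods
vignette (`vignettes/guideline-classification-methods.Rmd`) for every
modelling decision.

## Worked example

Generate a phantom patient, preprocess it, and inspect a sample:

```r
library(oarclass)

p   <- generate_phantom(phantom_spec("desk"), seed = 42, patient_id = "p001")
cfg <- preprocess_config("desk")
samples <- preprocess_patient(p$volume, p$structures, cfg, labels = p$labels)
length(samples)                        # 13 structures (body excluded)
samples[[1]]$name                      # "Bladder"
dim(samples[[1]]$ct)                   # 24 40 44  (slices, rows, cols)
sort(unique(as.vector(samples[[1]]$addmap)))   # 0.0 0.5 1.0
```

Train the 5-fold ensemble on a 25-patient cohort and score the pooled
validation predictions (about 2–3 min on one CPU):

```r
coh <- generate_cohort(25, phantom_spec("desk"), base_seed = 101)
samples <- unlist(lapply(coh$patients, function(p)
  preprocess_patient(p$volume, p$structures, preprocess_config("desk"),
                     labels = p$labels)), recursive = FALSE)
cfg <- train_config("desk", vocabulary = phantom_vocabulary(), seed = 1)
ens <- train_kfold(samples, cfg)
```

With seed 1 this prints fold summaries such as

```
<ensemble_model> 5 folds, 11 classes, input 40x44x24
  fold 1: best epoch 20, val CP 9.833
  fold 2: best epoch 14, val CP 9.714
  fold 3: best epoch 28, val CP 9.667
```

(CP ranges over [0, 10] for 11 classes) and the pooled validation
report gives `macro label accuracy 0.9685`, with the two bladder
variants — separated only by a 6 mm wall rule — as the weakest pair
(precision 0.815/0.957), mirroring where the method struggles on
clinical data. Classify a
folder tree and write a sorted copy tree:

```r
report <- classify_patients(ens, patient_dirs, preprocess_config("desk"),
                            exclusion = TRUE, out_dir = "classified")
```

Run the mixed-guideline demonstration (about 1.5 min):

```r
res <- run_demo(demo_config(seed = 5))
res$summary
```

```
     arm dsc_mean hd95_mean msd_mean
  A on A    0.872      9.12     3.41
  B on B    0.766     16.09     6.75
Mix on A    0.831     12.52     4.17
Mix on B    0.733     18.23     7.82
```

The mixture-trained model is worse on every metric for both
guidelines (DSC lower, HD95/MSD higher; two-sided Wilcoxon p ≤ 0.031
for all six comparisons at n = 8), the desk-scale analogue of the
published clinical finding.

Command-line entry points (after installing):

```sh
Rscript inst/cli/classify.R --model ckpt/ --input patients/ --profile pelvis --exclusion on --out sorted/
Rscript inst/cli/demo_mixed.R --seed 1 --out demo_out/
```

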
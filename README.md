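# heki67

Predicting Ki67/MIB1 immunohistochemical positivity of tumor cells
directly from H&E-stained histology images, via nuclear morphometry.

## The problem and the approach

The Ki67 labeling index — the fraction of tumor cells whose nuclei
stain for the proliferation marker Ki67/MIB1 — is a routine
immunohistochemical (IHC) readout in tumor pathology. Proliferating
nuclei are, however, also more hyperchromatic on an ordinary H&E
stain, so part of that information is already present in the slide
every laboratory makes anyway.

`heki67` implements a complete, tested pipeline that extracts this
signal:

1. **Stain separation.** Beer–Lambert optical density,
   OD = −log₁₀(I/I₀), and Ruifrok–Johnston color deconvolution
   OD = Mᵀc, giving per-pixel hematoxylin and eosin concentrations.
2. **Nucleus segmentation.** Gaussian smoothing, OD thresholding and
   distance-transform watershed on the hematoxylin map.
3. **Nuclear morphometry.** Per-nucleus area, Crofton perimeter,
   circularity 4πA/P², eccentricity, caliper diameters, and the
   hematoxylin OD statistics — centrally **NHMOD**, the nuclear
   hematoxylin mean optical density.
4. **Tumor/stroma classification.** A random forest (50 trees, ≥10
   samples per node, unlimited depth, stratified 80/20 validation
   split), with SVM / k-nearest / naive-Bayes comparison on the
   identical split.
5. **Ki67 calling.** Empirical ROC per feature (trapezoid AUC = the
   Mann–Whitney statistic with ties ½; DeLong CI), Youden-J threshold
   on NHMOD, per-cell calls, full diagnostic confusion metrics, and a
   core-level rule: positive if strictly more than 10% of tumor cells
   are at or above the "red" level of the color scale.
6. **False color map.** Each nucleus recolored by its NHMOD through a
   blue→cyan→green→red→yellow ramp and overlaid on the H&E image.

Because the original tissue-microarray cohort is not publicly
deposited, the package ships a first-class synthetic TMA-core
generator with complete ground truth (nucleus masks, tumor/stroma
class, latent Ki67 state shifting the hematoxylin OD distribution),
used to validate every stage; see the methods vignette
(`vignettes/predicting-ki67-from-he.Rmd`) for what it does and does
not emulate.

## Worked example

```r
library(heki67)

core <- generateCore(syntheticCoreSpec(seed = 1))
core
#> SyntheticCore: 512 x 512 px, 200 nuclei (120 tumor, 80 stroma)
#>   Ki67-positive fraction (tumor): 0.283

model  <- defaultHEModel()
stains <- deconvolve(rgbToOD(coreImage(core), model), model)
mask   <- detectNuclei(hematoxylinMap(stains))
max(mask)
#> [1] 199

records <- attachTruth(nucleusFeatures(mask, stains), mask, core)
tumor <- records[records$class_label == "tumor" &
                 records$ki67_truth != "unknown", ]

rocs <- rocRankFeatures(tumor)
rocs[[1]]
#> RocResult: nhmod  AUC = 0.939 (95% CI 0.897-0.982), 120 thresholds

thr <- chooseThreshold(rocs[[1]])
called <- callCells(tumor, thr)
confusionFromCalls(called$ki67_pred, called$ki67_truth)
#> ConfusionMetrics (counts: tp 29 fn 5 fp 5 tn 81 )
#>    statistic     value    ci_low   ci_high defined
#>  sensitivity 0.8529412 0.6894343 0.9504715    TRUE
#>  specificity 0.9418605 0.8695160 0.9808549    TRUE
#>          ppv 0.8529412 0.6918487 0.9374349    TRUE
#>          npv 0.9418605 0.8678224 0.9755932    TRUE
#>     accuracy 0.9166667 0.8520846 0.9593139    TRUE
#>           f1 0.8529412        NA        NA    TRUE
```

Reading the output: 199 of the 200 planted nuclei are segmented; NHMOD
is the top-ranked feature by ROC AUC against the Ki67 ground truth
(0.94 on this strongly separated default core); thresholding it with
Youden's J calls single cells with ~92% accuracy here. On generator
settings calibrated to a designed AUC of 0.688 — the regime reported
for real tissue — per-cell performance is correspondingly lower; the
acceptance script below measures exactly that.

The end-to-end driver wraps all stages, writes feature tables,
predictions, per-core calls, false-color overlays and a manifest with
per-stage output hashes (bit-identical across repeated seeded runs):

```r
man <- runPipeline(pipelineConfig(seed = 7, outDir = "run1"))
```

A thin command-line wrapper with `synth`, `deconvolve`, `fcm` and
`run` subcommands is installed at `inst/scripts/he2ki67.R`.

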
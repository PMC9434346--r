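# retquant

Quantification of SD-OCT imaging biomarkers in neovascular age-related
macular degeneration (nAMD), and random-forest prediction of one-year
disease activity from their longitudinal course.

## The problem

Anti-VEGF therapy fails to fully control roughly a third of nAMD eyes
("persistent disease activity", PDA).  On a spectral-domain OCT B-scan the
relevant anatomy splits into two families:

* **linear photoreceptor layers** — the ellipsoid zone (EZ) and the external
  limiting membrane (ELM), thin bright bands whose *integrity* (how much of
  the scan width they survive) reflects photoreceptor health;
* **blocky lesions** — intraretinal fluid (IRF), subretinal fluid (SRF),
  subretinal hyperreflective material (SHRM) and pigment epithelium
  detachment (PED), regions with area, extent and reflectivity.

`retquant` implements the full analysis chain:

1. **Preprocessing** — ROI crop, bilinear reshape to 256 × 1600, min-max
   normalisation, seeded flip/crop/shift augmentation.
2. **Layer detection** — each scan is sliced into vertical 256 × 16 clips; a
   small CNN (4 × [conv → batch-norm → ReLU → max-pool] → 2 fully connected
   layers) classifies per clip whether EZ (or ELM) is present; clip
   decisions are merged back in order.  The *length rate* of a layer is the
   fraction of positive clips.
3. **Lesion segmentation** — a small U-shaped fully convolutional network
   assigns each pixel one of {background, IRF, SRF, SHRM, PED} (softmax
   cross-entropy).
4. **Quantification** — the 12-feature biomarker vector per scan: EZ/ELM
   length rates; per-lesion area (mm²) and maximum basal diameter (mm);
   mean reflectivity of SHRM and PED.
5. **Evaluation** — dice `2|A∩B|/(|A|+|B|)`, accuracy, sensitivity,
   specificity, percentile-bootstrap 95% CIs, and the AVG (mean across
   biomarkers) aggregation.
6. **Prognosis** — a random forest (CART + bagging + majority vote,
   implemented in the package) predicts the 3-class one-year outcome
   {0 stable, 1 PDA, 2 cured} from longitudinal feature blocks
   (baseline / +month 1 / +month 3, with signed deltas), in two-metric
   (EZ+ELM), four-metric (lesions) and six-metric (all) variants, with
   stratified 10-fold CV and an in-fold grid search of the tree count over
   150…800.

Because no public dataset exists for this task, the package ships a seeded
**synthetic B-scan generator** (layered retina, bright RPE band, EZ/ELM
lines with contiguous gaps, elliptical/dome lesions, multiplicative
speckle) with *analytic ground truth*, plus a longitudinal cohort generator
whose outcome labels follow a planted, configurable rule.  Every stage is
tested end-to-end against that ground truth.

## Worked example

```r
library(retquant)

# a desk-scale noise-free scene with ground truth
spec  <- scene_spec(image_height = 128, image_width = 512, speckle_sigma = 0)
scene <- generate_scene(spec, seed = 7)
round(scene$features, 4)
#>       ez_length_rate      elm_length_rate         irf_area_mm2
#>               0.7188               0.8438               0.0129
#>  irf_max_diameter_mm         srf_area_mm2  srf_max_diameter_mm
#>               0.2550               0.0165               0.4100
#>        shrm_area_mm2 shrm_max_diameter_mm         ped_area_mm2
#>               0.0079               0.2550               0.0219
#>  ped_max_diameter_mm  shrm_mean_intensity   ped_mean_intensity
#>               0.4600               0.8200               0.7001

# quantification on the emitted annotation inverts the generator exactly
all.equal(quantify_annotation(scene), scene$features)
#> [1] TRUE
```

The EZ length rate 0.7188 means 23 of the 32 sixteen-pixel clips contain an
intact EZ line (the scene was configured with a 30% gap); the SRF pocket covers
0.0165 mm² with a 0.41 mm basal diameter at 0.005 mm/px; SHRM/PED mean
reflectivity are the painted intensities (0.82, 0.70).

A planted longitudinal cohort and the prognosis model:

```r
coh <- generate_cohort(150, seed = 11, signal = "ez_only", render = FALSE)
ft  <- cohort_feature_table(coh)
fm  <- build_feature_matrix(ft, "six_metric", "month3")
rep <- fit_predict_cv(fm$x, fm$y, forest_config(n_trees = 300, seed = 5),
                      fm$columns)
c(accuracy = rep$accuracy, auc = rep$auc_macro)
#>  accuracy       auc
#> 0.9666667 0.9962218
head(rank_feature_importance(rep), 3)
#>                  feature importance
#> 1  ez_length_rate@month3  0.2039797
#> 2 elm_length_rate@month3  0.1368288
#> 3 elm_length_rate@month1  0.1191918
```

Here the outcome was planted in the month-3 EZ length rate, and the forest
both recovers it (out-of-fold accuracy 0.97, macro one-vs-rest AUC 0.996)
and ranks the photoreceptor-integrity features first.

## Command line

```sh
inst/cli/retquant run-all --config demo.yaml --seed 1 --out-dir runs/demo
inst/cli/retquant segment --model runs/demo/segmenter.rds \
                          --in scan.png --out mask.png
```

The YAML config has per-stage blocks (`profile`, `synth`, `detector`,
`segmenter`, `evaluate`, `predict`); unknown keys are rejected by name, and
re-running an identical config reproduces every CSV bit-exactly
(`manifest.json` records the config hash and per-stage seeds).

## Vignette

`vignettes/retquant-methods.Rmd` documents the model assumptions, the
synthetic-data design (what it emulates and what it deliberately does not),
numerical choices, and known limitations.
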
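# ventmorph

Ventricular morphometry and MRI-based discrimination of Alzheimer's
disease (AD) and mild cognitive impairment (MCI) from normal controls
(NC), in R.

Enlargement of the lateral ventricles is a robust, easily measured
correlate of the cerebral atrophy that accompanies MCI and AD. This
package implements a complete, testable version of a classic
volume-plus-shape classification pipeline for structural T1 brain MRI:

1. **Tissue segmentation and volumetry.** A three-class intensity
   Gaussian mixture (CSF < GM < WM) fitted by EM yields posterior maps,
   and tissue volumes are counted by the thresholded-posterior rule
   `volume_tissue = #{i : P(C_tissue | f(i)) > 0.5} x voxel volume`,
   with the whole-brain variant using `P(C_GM v WM | f(i)) > 0.5`.
2. **Ventricle extraction.** Double-threshold region growing from an
   automatically chosen cavity seed region (band = CSF class mean +/- 2
   s.d.), morphological opening and closing with a 6-connected radius-1
   element, slice-wise Sobel boundary maps, and voxel-count ventricular
   volume.
3. **Shape features.** 3D: group probability maps `P_t = (1/N) sum I_t`,
   discriminate maps `D = P_patient - P_normal`, and the matching
   coefficient `MC = sum_xyz D(x,y,z) T(x,y,z)` of a held-out subject's
   mask `T`. 2D: seventeen descriptors on the *datum slice* (the axial
   slice of maximum ventricular area): area and its four centroid
   quadrants, traced-contour perimeter, circularity `100*4*pi*A/P^2`,
   second-moment elongation, minimum-area-rectangle rectangularity, six
   landmark distances (centroid G and extreme points A/B/C/D), minimum
   caliper thickness, and the mean centroid-distance signature.
4. **Feature reduction.** Per-feature Mann-Whitney screening with
   `Z_U = (U_obt - n1 n2 / 2) / sqrt(n1 n2 (n1 + n2 + 1) / 12)` at
   alpha = 0.05 (Route I), optionally followed by PCA on the correlation
   matrix retaining the components that explain 95% of total variance
   (Route II).
5. **Classification.** Three interchangeable classifiers written from
   their defining equations: a two-stage Kohonen self-organizing map
   (Gaussian neighborhood, ordering rate 0.9, tuning rate 0.5 with
   neighborhood 0.5 over 1000 epochs), a one-against-rest soft-margin
   RBF SVM solved by sequential minimal optimization, and a PSO-tuned
   SVM searching `(log2 C, log2 gamma)` with 30 particles, 200
   iterations, `c1 = c2 = 2`, `w = 0.8`, fitness = internal
   cross-validated accuracy.
6. **Evaluation.** Leave-one-out cross-validation with every
   data-dependent step refit inside each fold, 3x3 confusion matrices,
   and accuracy/sensitivity/specificity per
   `ACC = (TP + TN)/(P + N)`, `TPR = TP/(TP + FN)`,
   `TNR = TN/(FP + TN)`.

Because the original clinical cohort is not deposited, the package
ships a first-class synthetic phantom generator: seeded 3D brain
phantoms with a butterfly-shaped ventricular cavity whose size and horn
geometry differ by diagnostic group, so the whole pipeline is
exercised end to end without MRI data.

## Worked example

```r
library(ventmorph)

ph <- generate_phantom(phantom_spec(seed = 7))
sub <- extract_features(ph$image)
round(sub$features[c("V_GM", "V_CSF", "Area", "Perimeter", "Circularity",
                     "d_AC", "MeanSig")], 2)
#>        V_GM       V_CSF        Area   Perimeter Circularity        d_AC
#>   556156.25   175437.50     2175.00      269.96       37.50       60.21
#>     MeanSig
#>       24.50

dice(sub$mask, vm_mask(ph$truth$label_volume == 4, ph$image$voxel_size))
#> [1] 0.9306931
```

The segmented gray-matter volume (~556 cm^3), ventricular datum-slice
area (~2200 mm^2) and circularity (~38%) are of the magnitudes seen in
elderly cohorts, and the extracted mask overlaps the generator's ground
truth at Dice 0.93.

A full seeded study — 17 NC / 18 MCI / 17 AD phantoms, Route II
(Mann-Whitney + PCA) feature reduction and the PSO-SVM under LOOCV:

```r
cohort <- generate_cohort(seed = 1)                 # 52 subjects
feats <- cohort_features(cohort)
res <- loocv(feats$table, classifier = "pso_svm", route = "II",
             classifier_args = list(n_particles = 10, max_iter = 50),
             seed = 1)
summary(res)
#> Overall LOOCV accuracy: 98.08%
#>   NC: 94.12%
#>   MCI: 100.00%
#>   AD: 100.00%
```

`run_pipeline(run_config(...))` wraps the same chain and writes the
feature CSV, group statistics, results and confusion-matrix CSVs plus a
JSON manifest; `inst/cli/ventmorph.R` exposes `phantom` and `run-all`
subcommands for shell use.

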
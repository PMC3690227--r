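# pulleyQuant

Automated quantification of pulley histopathology in trigger finger.

Trigger finger (stenosing tenosynovitis) is graded from H&E-stained
microscopic sections of the A1 pulley, where the disease hallmark is
fibrocartilaginous (chondroid) metaplasia: normal collagenous tissue is
eosinophilic pink with elongated rod-like fibroblast nuclei, while
metaplastic tissue stains blue/purple and carries round chondrocyte-like
nuclei. Visual grading is slow and observer-dependent; `pulleyQuant`
extracts the color and shape evidence automatically and reduces each
specimen to two severity indices:

- **parameter 1** — the size ratio of abnormal tissue regions,

  `p1 = A_abnormal / (A_abnormal + A_normal)`

  with areas in pixels, summed over the analyzed images of a specimen;

- **parameter 2** — the number ratio of abnormal nuclei,

  `p2 = N_abnormal / (N_abnormal + N_normal)`.

The pipeline behind the indices:

1. **Color normalization** — Reinhard statistics transfer in the
   logarithmic lαβ space: RGB → LMS (3×3 cone-response matrix), natural
   log, decorrelating rotation to (l, α, β); each channel is shifted and
   rescaled so its mean/SD match a profile averaged over operator-chosen
   target images, then inverted back to 8-bit RGB.
2. **Tissue segmentation** — hue channel of the HSI model; three Otsu
   thresholding steps (hue → rough foreground; G channel of the rough
   background → recover residual purple; hue of the full foreground →
   normal vs abnormal), followed by a 9×9 majority rank filter.
3. **Nuclei analysis** — active double thresholding on the R channel
   (base = mean of the 10 darkest pixels; seeds at base+30; 8-connected
   growth restricted to base+45) and a rule-based shape classifier: a
   region is a normal rod iff circularity 4πA/P² < 0.95, centroid-to-
   boundary distance ratio d_max/d_min > 3 and area < 2000 px; other
   regions are abnormal (round singles below 2000 px, otherwise clusters
   whose nucleus count is area / mean single-round area).
4. **Quantification** — sum-then-ratio aggregation per specimen, stage
   discrimination by midpoints of adjacent H/M/L stage means (value at a
   cut goes to the higher stage), and Welch two-sample tests between
   stages.

A seeded synthetic slide generator (`simulateImage()`,
`simulateSpecimenSet()`) renders pink fiber fields, purple metaplastic
patches and planted rod/round nuclei with exact ground truth, so every
stage is testable without access to clinical slides.

## Worked example

The package bundles the per-specimen measurements of a 29-specimen
graded cohort (10 H, 10 M, 6 L, 3 N; summed pixel areas and nucleus
counts over 10 images each):

```r
library(pulleyQuant)
rc <- referenceCohort()
q  <- quantifyCohort(rc$tissue, rc$nuclei)
print(q$analysis1$groups, digits = 3)
#>   stage  n  mean     sd
#> 1     H 10 0.259 0.0139
#> 2     M 10 0.198 0.0126
#> 3     L  6 0.123 0.0388
#> 4     N  3 0.109 0.0148
print(q$analysis1$cuts, digits = 4)
#>  cutHM  cutML
#> 0.2286 0.1603
print(q$analysis1$comparisons, digits = 3)
#>     pair     t    df        p
#> 1 H vs M 10.29 17.82 6.39e-09
#> 2 M vs L  4.62  5.64 4.23e-03
print(q$analysis1$misclassified)
#>   from to n
#> 1    L  M 1
```

Reading the output: mean abnormal-area ratios fall monotonically from
High (0.259) through Middle (0.198) to Low (0.123) severity; the two
midpoint cuts (0.229, 0.160) classify 25 of the 26 diseased specimens
into their pathologist stage, with a single L specimen (ratio 0.176)
crossing into M; both between-stage differences are significant
(p < 0.05).

An imaging run on synthetic slides:

```r
set <- simulateSpecimenSet(3, 2, seed = 11)
man <- writeSpecimenSet(set, "slides")
writeRGB(simulateImage(syntheticConfig(seed = 99))$image, "target.png")
cfg <- pipelineConfig(manifest = data.frame(path = man$path,
                                            specimen = man$specimen,
                                            stage = man$stage),
                      targets = "target.png", outputDir = "reports")
res <- runPipeline(cfg)
res$specimens        # summed areas/counts, parameter1, parameter2
```

A thin command-line wrapper with subcommands `profile`, `normalize`,
`segment`, `nuclei`, `quantify`, `simulate` and `run` is installed at
`system.file("scripts", "pulleyquant", package = "pulleyQuant")`.

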
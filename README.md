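# adseg

Toolkit for region-of-interest analysis of 2-D grayscale brain MRI
slices, aimed at computer-aided screening of neurodegenerative disease
from structural MRI. Cohort studies in this area need three things the
package provides as reusable, separately testable stages:

1. **Segmentation** — Otsu thresholding, with the optimal threshold
   located either by an exhaustive sweep or by the Tunicate Swarm
   Algorithm (TSA), a population metaheuristic that searches the
   threshold space by jet-propulsion moves towards the best agent and
   neighbour-averaging swarm moves.
2. **Texture description** — local binary patterns (LBP) and local
   directional pattern variance (LDPv, Kirsch-mask directional codes
   weighted by response variance), computed block-wise over the segmented
   region and fused by concatenation into one descriptor per image.
3. **Classification** — a from-scratch deep belief network: stacked
   restricted Boltzmann machines pretrained by contrastive divergence
   (CD-1), topped with a softmax layer, fine-tuned end to end by
   backpropagation.

Segmentation quality is scored by Jaccard (JSC), Dice (DSC) and pixel
accuracy; classification by accuracy, sensitivity and specificity.
Because real sMRI cohorts (ADNI, AIBL) sit behind access agreements, the
package ships a seedable phantom generator — bright textured ellipse on a
dark background with exact ground-truth masks — so the whole chain is
verifiable at desk scale.

At the core, the segmentation objective is the within-class variance

    sigma_w^2(t) = w_b(t) sigma_b^2(t) + w_f(t) sigma_f^2(t)

minimised over thresholds t in [0, 254]; the DBN is the classic stack
h_l = sigmoid(h_{l-1} W_l + b_l) with hidden sizes [8, 6] trained by CD-1
(10 epochs/layer) and softmax cross-entropy fine-tuning (100 epochs,
batch 100, learning rate 0.01).

## Worked example

```r
library(adseg)

spec <- phantom_spec(seed = 7)                      # 128x128, 3 texture classes
s    <- generate_phantom(spec, class_label = 2, seed = 42)

h   <- compute_histogram(s$image)
thr <- otsu_tsa(h, tsa_config(seed = 1))            # swarm threshold search
thr
#> Otsu threshold (tsa): t = 110, within-class variance = 274.968

mask <- apply_threshold(s$image, thr$threshold)     # 1 = bright RoI
m <- segmentation_metrics(mask, s$mask)
sprintf("JSC %.3f, DSC %.3f, PA %.3f", m$jsc, m$dsc, m$pa)
#> "JSC 0.999, DSC 0.999, PA 1.000"

f <- extract_features(s$image, mask)                # fused LBP + LDPv
length(f)
#> 4992
```

The threshold 110 sits in the valley between the background mode (~40)
and the foreground mode (~180); the resulting mask recovers the
generating ellipse almost exactly, and the 4992-vector (16 blocks × 256
LBP bins + 16 × 56 LDPv bins, L1-normalised per block) is what the
classifier consumes.

The whole chain on a cohort:

```r
report <- run_pipeline(pipeline_config(seed = 7))   # 150 phantoms, 3 classes
report
#> adseg pipeline report (150 images, method tsa, seed 7)
#>   thresholds: mean 104.0 (range 79..117)
#>   segmentation: JSC 0.998, DSC 0.999, PA 0.999
#>   classification (held out, n=30): accuracy 100.0%, sensitivity 100.0%, specificity 100.0%
```

`dbn()` is also usable directly as a classifier for any feature matrix;
it returns an S3 model with `predict`, `print`, `summary`, `plot` and
`coef` methods and serialises to portable JSON via `write_dbn()` /
`read_dbn()`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/adseg.R simulate --out phantoms --n-per-class 50 --seed 7
Rscript inst/cli/adseg.R segment phantoms/phantom_001.png --method tsa
Rscript inst/cli/adseg.R run --out run_artifacts --seed 7
```

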
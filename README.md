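# ildseg

Automatic lung-field segmentation for HRCT slices of interstitial lung
disease (ILD), written for image-analysis researchers who want a fully
reproducible, dependency-light reference pipeline that fuses hand-crafted
texture features with a learned refinement stage.

ILD parenchyma shows reticular, nodular and ground-glass patterns that
defeat plain intensity thresholds. `ildseg` implements a two-stage
radiomics pipeline:

1. **Denoising.** Additive acquisition noise `S(x,y) = f(x,y) + G(x,y)`,
   `G ~ N(mu, sigma^2)`, is removed with a pixel-wise adaptive (MMSE)
   Wiener filter `W = m + max(v - nu, 0)/max(v, nu) * (S - m)` over local
   mean `m` and variance `v`, with a structure-robust MAD-of-Laplacian
   estimate of the noise floor `nu`.
2. **Texture stage (initial mask).** Gray-level co-occurrence matrices
   `q(i,j)` are counted at displacements `d` along 0/45/90/135 degrees,
   symmetrised, and normalised to `p(i,j) = q(i,j)/sum q`; the 14
   Haralick statistics (angular second moment, contrast, correlation,
   entropy, information measures of correlation, maximal correlation
   coefficient, ...) are computed per sliding window. Windows are
   clustered (seeded k-means) and dark texture classes inside the
   morphological body mask become the initial lung mask.
3. **Deep stage (refinement).** A compact U-Net (3 encoder and 3 decoder
   blocks of paired 3x3 conv + ReLU, 2x2 max pooling, 2x2
   up-convolutions with crop-and-concatenate skips, channel ladder
   16/32/64/128) refines the mask from a 2-channel input (denoised
   image + current mask), trained with weighted softmax cross-entropy
   `E = -(1/N) sum_x w(x) log softmax(alpha(x))_{l(x)}` under Adam. The
   refinement is iterated until the contour stabilises
   (`DSC(mask_t, mask_{t-1}) >= 0.999`).

Masks are scored with the Dice similarity coefficient
`DSC = 2|M∩A|/(|M|+|A|)` and sensitivity `SEN = TP/(TP+FN)`.

Because the real ILD HRCT databases cannot be redistributed, the package
ships a seeded **lung phantom generator** (bright thorax, two darker lung
ellipses carrying reticular / nodular / ground-glass procedural texture,
Gaussian noise, exact ground-truth masks), so the whole pipeline trains
and evaluates end-to-end on a laptop with no downloads.

## Worked example

```r
library(ildseg)

# one seeded phantom with ground truth
ph  <- generatePhantom(phantomParams(seed = 3))
den <- wienerDenoise(ph@image)

# texture stage: Haralick feature map -> initial mask
fmap <- textureFeatureMap(den, glcmMapConfig(window = 9, stride = 2))
init <- initialTextureSegmentation(fmap, den, seed = 7)
dice(init, ph@mask)
#> [1] 0.9300185

# the full desk-scale study: 60 phantoms, 40 train / 20 test, 30 epochs
out <- runDeskRecipe(seed = 7)     # ~10 min on one CPU core
out$record
#> EvalRecord: 20 samples, mean DSC 0.9513, mean SEN 0.9975 (0 skipped)
out$initialDSC
#> [1] 0.919318
```

`runDeskRecipe()` trains the U-Net on texture-stage masks of 40 phantoms
and evaluates the full iterative pipeline on 20 held-out phantoms: the
mean test Dice of 0.951 against 0.919 for the texture stage alone shows
what the learned refinement adds; sensitivity 0.998 means virtually all
lung pixels are recovered.

A small co-occurrence example is bundled:

```r
g <- computeGLCM(glcmExampleImage(), d = 1, theta = 0, Q = 5)
glcmCounts(g)[1, 3]   # the gray-level pair (0, 2) occurs twice
#> [1] 2
```

## Command line

```sh
Rscript inst/scripts/ildseg.R simulate --n 60 --size 64 --texture reticular --sigma 10 --seed 7 --out data/
Rscript inst/scripts/ildseg.R train    --manifest data/manifest.txt --out model.ckpt --epochs 30 --seed 7
Rscript inst/scripts/ildseg.R evaluate --manifest data/manifest.txt --model model.ckpt --report report.csv
Rscript inst/scripts/ildseg.R segment  --in slice.png --model model.ckpt --out mask.png --max-iter 5
```

Every subcommand writes a run-manifest YAML (config snapshot, seed,
package version) next to its outputs; a YAML config file can supply
defaults (`--config`), and explicit flags override it. See
`inst/extdata/config-full-scale.yaml` for the 512 px full-scale recipe
(batch 20, learning rate 1e-4, 500 epochs).

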
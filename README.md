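# mammoenhance

Contrast enhancement for digital mammograms, for people building
computer-aided breast-cancer detection pipelines.  Screening mammograms are
low-contrast, unevenly illuminated and noisy, and the mediolateral-oblique
(MLO) projection contains a bright pectoral-muscle wedge that wrecks any
intensity-based lesion analysis.  This package implements a five-stage
enhancement pipeline plus the quality metrics and baselines needed to
evaluate it — and a synthetic phantom generator so everything is testable
without clinical data.

**Pipeline** (in fixed order):

1. channel split of the RGB input (`read_image`);
2. per-channel morphological background uniformity
   `f + T_w(f) - T_b(f)` where `T_w(f) = f - (f ∘ b)` is the top-hat and
   `T_b(f) = (f • b) - f` the bottom-hat with structuring element `b`
   (`uniformize`);
3. PCA fusion of the YCbCr-transformed channels into one grayscale image,
   weights `w_i = λ_i / Σλ` from the 3×3 covariance eigenvalues
   (`pca_gray`);
4. pectoral muscle removal by seed-based region growing from the top
   chest-wall corner, adaptive running-mean acceptance (`grow_pectoral`,
   `remove_pectoral`; MLO views only);
5. Laplacian-of-Gaussian normalization and coherence-enhancing anisotropic
   diffusion `I ← I + Δt · div(D ∇I)` with entropy-based stopping
   (`log_filter`, `diffuse`).

**Metrics** (`metrics_report`): PSNR from MSE (both the published
`10·log10((L−1)/MSE)` form and the standard `10·log10(L²/MSE)`, with
`L = 2⁸ − 1 = 255`), log-contrast `10·log10(var(Y))` dB, and EME — the mean
over a `K1 × K2` block grid of `20·log10(Imax/Imin)`.

**Post-processing** (`kmeans_intensity`, `evaluate_mask`): 1-D k-means on
intensities (k ∈ [2, 8], deterministic quantile initialization) with
specificity / sensitivity / accuracy scoring against a ground-truth mask.

**Baselines** (`hist_equalize`, `clahe`, `bbhe`) and a benchmark harness
(`run_bench`) comparing them with the pipeline on randomized phantoms.

## Worked example

```r
library(mammoenhance)

# a 256x256 MLO phantom: breast 120, background 20, pectoral muscle 200,
# one lesion, illumination ramp + per-channel noise
ph  <- make_phantom(phantom_spec(view = "MLO", seed = 7L))

cfg <- pipeline_config(view = "MLO", skip_log = TRUE)
res <- enhance_image(ph$degraded, cfg)

dice(res$pectoral_mask, ph$pectoral_mask)
#> [1] 0.9989...                      # grown mask vs ground-truth triangle

metrics_report(to_ycbcr(ph$degraded)$Y, res$final, psnr_variant = "standard")
#>   psnr_db contrast_db_original contrast_db_enhanced eme_original eme_enhanced
#> 1   9.418                35.08                34.74        10.43        7.843
#>   psnr_variant k1 k2
#> 1     standard  8  8

kmeans_intensity(res$final, 4)$centroids
#> [1]   0.9 109.2 179.1 189.5
```

Reading the numbers: the Dice coefficient says the region grower recovered
99.9 % of the pectoral wedge.  In the metrics row, `psnr_db` compares the
*input* against the *output* (the paper's protocol), so a small value simply
means the output differs a lot from the input — here mostly because the
muscle was removed and the range re-stretched.  Contrast and EME are
before/after pairs; on this flat phantom the denoised output scores slightly
lower (see the vignette for why that reverses on textured data).  The four
k-means centroids split the enhanced image into muscle-free background
(0.9), breast tissue (109.2) and two bright strata containing the lesion.

Every stage artifact can be written to disk for a file input:

```r
run_pipeline("mammogram.png", "out/", cfg)   # uniformized channels, gray,
                                             # pectoral mask, LoG, final,
                                             # metrics.csv, manifest
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mammoenhance.R", package = "mammoenhance"))')
Rscript $CLI phantom --out phantom_dir --view MLO --seed 7
Rscript $CLI enhance --input phantom_dir/degraded_green.png --out out --view MLO
Rscript $CLI segment --input out/degraded_green_final.png --out seg --k 2,4,6,8
Rscript $CLI bench --n 20 --seed 1 --out bench.csv
```

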
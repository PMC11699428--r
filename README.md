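# abmff

Two-phase grayscale image segmentation, built for noisy data.

Clustering-based segmentation assigns every pixel to one of *k*
intensity classes, and breaks down exactly where it is most needed:
impulse ("salt-and-pepper") noise and random intensity scatter push
individual pixels across class boundaries even when the underlying
regions are perfectly distinct. `abmff` addresses this with a hybrid
method:

1. **Agent-based homogenization.** Every pixel is an agent holding one
   of 256 intensity states. Each sweep, an agent compares itself with
   its Moore neighborhood and computes the sign consensus
   S = sign(Σ_q sign(e_q − e_0)); it then moves by a fixed step Δ in
   the direction of the majority (S = ±1) or stays put (S = 0, i.e. a
   uniform patch or a balanced edge). Regions homogenize, isolated
   impulses are absorbed at Δ per sweep, and balanced boundaries stay.
2. **Firefly clustering with K-means refinement.** Candidate centroid
   sets ("fireflies") are scored by the regularized objective
   J(C) = Σᵢ Σ_{x∈Cᵢ} ‖x − μᵢ‖² − α Σ_{i<j} ‖μᵢ − μⱼ‖² (α = 0.6),
   move toward brighter (lower-J) solutions with distance-decaying
   attraction plus a decaying random walk, and the best solution seeds
   a weighted K-means on the intensity histogram. Every pixel gets the
   label of its nearest centroid.

The package also provides the evaluation apparatus: a ground-truthed
synthetic image generator (piecewise-Gaussian regions, impulse and
additive Gaussian noise), full-reference quality metrics (PSNR, global
SSIM, FSIM with a log-Gabor phase-congruency bank), an exact
multilevel Otsu baseline, permutation-matched pixel accuracy, and an
experiment driver. See the methods vignette
(`vignettes/abmff-methods.Rmd`) for the model details and design
rationale.

## Worked example

```r
library(abmff)

# a 100x100 image: regions N(50,20) and N(200,20), 10% salt-and-pepper
spec <- synth_spec(100, 100, region_means = c(50, 200),
                   region_stds = c(20, 20), sp_density = 0.1, seed = 7)
syn <- synth_image(spec)

seg <- segment(syn$image, k = 2, seed = 7)
print(seg)
#> segmentation: 100 x 100 image, k = 2
#> cluster solution (k = 2, via kmeans)
#>   centroids: 53.03, 197.42
#>   objective J = 678085.0663 (alpha = 0.6)

pixel_accuracy(seg$labels, syn$labels)
#> [1] 1
```

Despite 1000 corrupted pixels, the homogenization phase restores both
regions well enough that the recovered centroids sit within a few
intensity units of the true means (50 and 200) and every pixel is
labeled correctly. Comparing methods on the same input:

```r
run_experiment(spec, seed = 7)
#>    method     psnr     rmse      ssim      fsim accuracy
#> 1   abmff 21.96753 20.33123 0.9734990 0.3243409   0.9993
#> 2 cluster 15.97278 40.54161 0.9013963 0.4060709   0.9492
#> 3    otsu 15.97278 40.54161 0.9013963 0.4060709   0.9492
```

The `cluster` row is the ablation (clustering without homogenization)
and `otsu` is multilevel Otsu thresholding: both leave the ~5% of
impulses that fall on the wrong side of the class boundary
mislabeled, while the full pipeline absorbs them first. PSNR/SSIM/FSIM
score each method's centroid-rendered segmentation against the clean
reference; accuracy is against the ground-truth region map under the
best label matching.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/abmff.R", package="abmff"))')" \
    synth --out img.png --sp-density 0.1 --seed 7
```

with subcommands `synth`, `homogenize`, `cluster`, `segment`,
`evaluate`, and `experiment`.

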
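---
title: "Methods: agent-based homogenization and firefly clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agent-based homogenization and firefly clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Clustering-based segmentation of grayscale images assigns every pixel
to one of $k$ intensity classes. It fails in a characteristic way on
noisy data: impulse noise (dead or saturated sensor pixels) and random
intensity scatter move individual pixels across cluster boundaries even
when the regions they belong to are perfectly distinct. `abmff`
implements a two-phase remedy: a local, rule-based *homogenization*
phase that pulls each pixel toward its neighborhood consensus, followed
by a global *clustering* phase driven by a swarm metaheuristic.

# Phase 1: the agent-based model

Every pixel is an agent holding one of 256 intensity states. For agent
$e_0$ with neighbors $e_1,\dots,e_q$ (Moore neighborhood by default,
fewer at borders) the *sign consensus* is

$$S(e_0) = \operatorname{sign}\Big[\sum_q \operatorname{sign}\big(e_q - e_0\big)\Big].$$

The update rules are: $S=+1$ raises the agent by $\Delta$, $S=-1$
lowers it by $\Delta$, $S=0$ leaves it alone; states are clamped to
$[0,255]$. A uniform patch ($S=0$ everywhere) is a fixed point, and an
agent whose neighborhood is evenly split — a balanced edge — also has
$S=0$. An isolated impulse sees all neighbors on the far side of it,
so it moves a full $\Delta$ per sweep until it rejoins its region:
homogenization absorbs impulse noise at a known rate while flat
structure is preserved.

## Update scheme: why synchronous

Agents can be updated *in place* during a sweep (sequential,
Gauss–Seidel style) or all together from the pre-sweep grid
(synchronous). We make synchronous the default, and this is a
load-bearing choice. Under sequential updates, an agent lowered early
in a sweep is seen at its new value by every later agent in scan
order, so a single dark defect recruits its successors within the
*same* sweep: the perturbation travels at sweep speed, not at
$\Delta$ per sweep. Empirically a $100\times100$ two-region image
(levels 50/200) collapses to region means of roughly 105/150 after 100
sequential sweeps — the two regions drift into a common gray — while
synchronous sweeps keep the regions at their own levels and only blur
the boundary locally. The sequential variant (and both within-row scan
directions, which only matter sequentially) remains available in
`abm_config()` for sensitivity analysis.

## Step size and iteration budget

A defect of height $h$ needs $\lceil h/\Delta\rceil$ sweeps to be
absorbed. Full 8-bit impulses (salt at 255 inside a dark region) have
heights up to 255, so the phase can do its job within `iter1` sweeps
only if $\Delta\cdot\texttt{iter1} \ge 255$. With the conventional
budget of `iter1 = 100` sweeps, `delta = 3` is the smallest integer
step satisfying this with a margin, and it is the package default. A
unit step with a 100-sweep budget leaves every impulse of height
over 100 stranded mid-range, which measurably costs segmentation
accuracy at impulse densities as low as 0.1.

## Fine structure of the dynamics

Three second-order behaviors are worth knowing; all are consequences
of the rules, reproduced by the test suite:

* **Neighbor dip and parity stall.** The neighbors of an impulse see
  one discrepant value, so they dip $\Delta$ toward it and spring back
  the next sweep, oscillating with period 2. If $h/\Delta$ is an even
  integer, the climbing impulse meets the dipped ring exactly and
  stalls for one sweep: removal then takes $\lceil h/\Delta\rceil + 1$
  sweeps instead of $\lceil h/\Delta\rceil$. With a step that does not
  divide the height, the impulse can also be captured by the
  oscillating band just below the region level without ever crossing
  it exactly.
* **Persistent micro-oscillation.** After absorption, the impulse site
  and its ring settle into a 2-cycle of amplitude $\Delta$ around the
  region value rather than an exact fixed point. The residual is
  invisible at segmentation scale (it is within one step of the
  plateau) but means "convergence" should be read as convergence of
  regions, not of individual pixels.
* **Plateau creep.** Equal neighbors contribute zero to the consensus
  sum, so a perfectly flat plateau adjacent to a brighter one has
  $S=+1$ at its rim and creeps upward, one step per sweep. On *ideal*
  piecewise-constant images long homogenization budgets therefore
  carve the regions into staircases (labels are unaffected — each
  staircase stays on its own side of the midline). Real and
  synthetic-noisy regions are not exactly flat, and the within-region
  scatter pins the interior, which is why the effect is absent in the
  noisy experiments.

# Phase 2: firefly clustering

Candidate solutions are sets of $k$ centroid intensities
$\mu_1,\dots,\mu_k \in [0,255]$, scored by the regularized objective

$$J(C) = \sum_{i=1}^{k}\sum_{x\in C_i}\lVert x-\mu_i\rVert^2
  \;-\; \alpha \sum_{i<j}\lVert\mu_i-\mu_j\rVert^2,$$

with nearest-centroid assignment and $\alpha = 0.6$ by default: tight
clusters are rewarded, coincident centroids are penalized. Because the
data are 1-D intensities, $J$ is evaluated exactly on the 256-bin
histogram — identical to the per-pixel sum at a tiny fraction of the
cost (the equality is asserted in the tests).

Each *firefly* is one candidate solution; its brightness is $-J$ (any
strictly decreasing map gives the same pairwise comparisons). Per
iteration, every firefly moves toward every brighter one by
$\beta_0 e^{-\gamma r^2}(x_j - x_i)$ plus a uniform jitter of
amplitude `step_scale` $\times\,255$, decaying geometrically
(`step_decay = 0.97`). The distance $r$ is taken between *sorted*
centroid vectors so that attraction ignores label permutation. The
movement rule itself is the canonical firefly update; defaults
(`swarm_size = 20`, `beta0 = 1`, `gamma = 1/255^2`,
`step_scale = 0.2`, `iter2 = 100`) are conventional swarm settings on
the normalized intensity scale. The best solution ever visited is
retained, so the reported optimum is non-increasing in the iteration
count.

## K-means refinement and the better-of-two rule

The firefly optimum initializes a weighted K-means on the histogram
(assignment / mean-update until the largest centroid displacement is
below `kmeans_tol = 1e-4`; its within-cluster criterion $J_K$ is
non-increasing by construction; empty clusters are re-seeded at the
occupied intensity farthest from its nearest surviving centroid). One
subtlety: K-means minimizes the *pure* within-cluster criterion,
which is $J$ without the separation reward. On large images the intra
term dominates and the refined centroids also improve $J$; on small or
widely scattered data the refinement can trade away enough separation
to *worsen* $J$ by double-digit percentages. The clustering stage
therefore returns whichever of the two candidates — firefly best or
K-means refinement — has the lower $J$, making refinement a strict
improvement rather than a gamble.

Labels are assigned by nearest centroid, ties to the lower index;
centroids are reported in ascending order so label 1 is always the
darkest class.

# Quality metrics

* **RMSE / PSNR.** Standard root-mean-square error in intensity units
  and $\mathrm{PSNR} = 20\log_{10}(255/\mathrm{RMSE})$, with
  $+\infty$ for identical images.
* **SSIM (global).** The single-window form computed from whole-image
  statistics with both images rescaled to $[0,1]$ and stabilizers
  $C_1 = C_2 = 0.065$ on that scale. The contrast/structure factor
  uses the cross-covariance by default, which makes self-similarity
  exactly 1; a product-of-deviations variant is switchable for
  comparison. Sample moments use the $n-1$ denominator.
* **FSIM.** Per-pixel similarity of phase congruency
  ($S_{PC}$, stabilizer $T_1 = 0.85$) and Scharr gradient magnitude
  ($S_G$, stabilizer $T_2 = 160$ on the 8-bit gradient scale),
  averaged with phase-congruency salience weights
  $PC_m = \max(PC_1, PC_2)$. Phase congruency is computed from a
  log-Gabor bank (4 scales from wavelength 6 at multiplier 2,
  4 orientations, radial bandwidth 0.55) as total local energy over
  total amplitude with stabilizer $\varepsilon = 10^{-4}$; images must
  be at least $16\times16$ for the bank's support. No downsampling or
  noise-threshold correction is applied — the simple energy/amplitude
  form is used.

Metrics compare *images*, so segmentations are rendered by replacing
each label with its centroid intensity (`render_segmentation()`)
before scoring against the clean reference. Raw label indices would
make the formulas meaningless. Note the rendering is piecewise
constant: its FSIM against a textured reference is structurally low
even for a perfect segmentation, so FSIM values are comparable between
methods on the same image, not across images.

# The synthetic generator

`synth_spec()` emulates the controlled inputs used throughout:
piecewise-constant region layouts (vertical split, equal bands,
concentric square) with per-region Gaussian intensities
($N(50,20)$ and $N(200,20)$ being the canonical two-region setting),
salt-and-pepper impulses (count `Np` or density $d$ with
$N_p = M\cdot N\cdot d$; positions sampled without replacement,
$\lceil N_p/2\rceil$ pepper at 0, the rest salt at 255; odd counts
favor pepper), and additive $N(0,\sigma)$ noise ($\sigma = 1$ in the
additive-noise arm). Values are rounded half away from zero — a fixed
convention so images are bit-identical across platforms — then clamped
to $[0,255]$. Sub-seeds for the generation stages are derived from one
spec seed, so the clean image does not change when noise settings do.

What the generator does *not* emulate: texture, illumination
gradients, curved or soft boundaries, correlated noise, or anything
resembling natural-image statistics. Passing the recovery experiments
here demonstrates noise-robust recovery of well-separated intensity
classes, not performance on natural benchmarks.

# Experiment protocol and problem sizes

`run_experiment()` generates one spec'd image, runs any of the full
pipeline, the clustering-only ablation (`iter1 = 0`) and multilevel
Otsu (exact dynamic programming over the histogram), and scores each
with PSNR/SSIM/FSIM against the clean reference plus pixel accuracy
against the ground-truth map. Accuracy maximizes over label
permutations (exhaustive, $k \le 8$), since cluster indices are
arbitrary. The test suite exercises $100\times100$ two-region
recovery over 10 seeds (with and without $d=0.1$ impulses),
$90\times90$ three-band ablation pairs over 10 seeds, and 16-pixel
instances against an exhaustive integer-centroid oracle; these sizes
give stable pass/fail behavior while keeping the default suite in the
low minutes on one core.

# Known limitations

* Sequential sweeps are faithful to the "agents processed along a
  path" picture but unstable, as analyzed above; they are provided for
  study, not use.
* The impulse-removal time is exactly $\lceil h/\Delta\rceil$ only
  away from the parity/capture cases described above; the package
  documents the true behavior rather than the idealized one.
* Clustering is 1-D (intensity only); color or texture features,
  other metaheuristics, and automatic selection of $k$ are out of
  scope.
* Global SSIM is not the windowed SSIM of the image-quality
  literature, and FSIM here uses the plain energy/amplitude phase
  congruency without noise compensation; values are internally
  consistent but not interchangeable with other implementations.
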
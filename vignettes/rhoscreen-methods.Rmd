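---
title: "Models and methods behind rhoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models, the image-processing
choices, and the numerical decisions inside `rhoscreen`, and states what
the synthetic-data generators do and do not emulate.

## Screen scoring

A migration screen produces, for every gene and replicate, a *migration
index* (percentage of the initial cell-free wound area covered after
24 h) in two conditions, basal medium and HGF-supplemented medium, plus
fluorescence readings at 48 h and 72 h after transfection.

Replicates are averaged per gene before scoring, and the plate Z-score of
a gene is

$$Z_g = \frac{\bar x_g - \overline{x}_{\mathrm{plate}}}{s_{\mathrm{plate}}},$$

with the sample SD ($n-1$ denominator) over all genes on the plate.
Classification at threshold $t = 1$ uses strict inequalities:
*impaired* if $Z_{\mathrm{basal}} < -t$, *accelerated* if
$Z_{\mathrm{basal}} > t$; genes quiet in basal medium are *HGF-impaired*
or *HGF-accelerated* when only the HGF-condition Z crosses the threshold.
The HGF-accelerated rule is the symmetric extension of the HGF-impaired
one: the hit tables distinguish both directions, so the one-sided
definition alone would be incomplete.

The viability index is the 72 h/48 h fluorescence ratio, Z-scored per
replicate screen across genes; a gene is excluded (category forced to
`none`) only when its viability Z falls below $-1$ in *every* replicate
screen, reflecting that transient, single-screen viability dips should
not disqualify a reproducible migration phenotype.

No multiple-testing correction is applied: the screen's cutoff is a plain
$|Z| > 1$ rule, and the package keeps that contract.

## Wound-assay image processing

The scoring chain is `flatten_and_threshold()` →
`wound_mask_from_t0()` → `migration_index()`.

* **Flatten + threshold.** Intensities are min–max normalized, a
  grayscale morphological opening with a disc of radius `flatten_radius`
  (default 50 px, well above the cell size) estimates the slowly varying
  background, and Otsu's method thresholds the residual. Normalizing
  first makes the mask exactly invariant to uniform gain and to a
  constant offset; it also keeps grayscale morphology inside the [0, 1]
  range EBImage operates on. Per-cell differences in dye uptake are
  irrelevant after thresholding.
* **Wound detection.** The cell mask is closed (disc radius 5 px) to
  bridge gaps between touching cells; connected cell-free regions are
  labelled with 8-connectivity so diagonal pixel chains do not split a
  region. Regions touching the image border are discarded — the
  exclusion zone is interior by construction, so border-touching
  background is outside the monolayer, not the wound. The largest
  remaining region (minimum 1% of the image, a debris guard) is dilated
  back by the closing radius, minus actual cell pixels, to undo the
  boundary erosion that closing causes.
* **Migration index** is `100 * |cells(24h) ∩ wound| / |wound|`,
  monotone in the covered pixel set and invariant to image rotation.

The flatten filter and threshold algorithm are deliberate choices of a
standard, parameter-light pair; nothing in the scoring depends on their
fine detail as long as bright cells separate from background.

## The two-state persistent random walk

A cell's track is modelled per frame interval $\Delta t$ (minutes): given
the hidden state $k$, the step speed is $s \sim
\mathcal N(\mu_k, \sigma_k^2)$ truncated at 0, and the orientation is the
previous orientation plus wrapped-Normal noise with SD
$\sigma_{\theta,k}$ — "memory of orientation from the prior step".
Speeds are truncated rather than folded or log-transformed because the
state description is a mean speed with a variance and no support
statement; the truncation correction for the realized mean,
$\mathrm E[s] = \mu + \sigma\,\phi(-\mu/\sigma)/\Phi(\mu/\sigma)$, is
applied wherever empirical mean speeds are compared to parameters.

States switch by a first-order Markov chain parameterized by the
stationary occupancy $\alpha$ of state 1 and a dwell scale $d \ge 1$:
$p_{12} = (1-\alpha)/d$, $p_{21} = \alpha/d$. The stationary distribution
is $(\alpha, 1-\alpha)$ for every $d$, and $d = 1$ is the memoryless
mixture. Some temporal persistence ($d > 1$) is what makes states
decodable from a single track; the occupancy alone does not determine
the switching dynamics, so the dwell scale is reported explicitly.
States are always labelled by ascending mean speed, so state 1 is the
slow/paused mode.

### Marginal x-displacement density

At stationarity the orientation is uniform, so a step's x-displacement
is $s\,\Delta t \cos\theta$ with $\theta$ uniform, giving per state

$$f_k(\Delta x) = \int_{|\Delta x|/\Delta t}^{\infty}
  g_k(s)\,\frac{\mathrm ds}{\pi\sqrt{(s\Delta t)^2 - \Delta x^2}},$$

the arcsine projection of the truncated-Normal speed density $g_k$, and
the marginal is the $\alpha$-weighted mixture. Numerically the
substitution $s = a\cosh u$ (with $a = |\Delta x|/\Delta t$) removes the
square-root singularity; the CDF is the smooth integral
$\int g_k(s)\,[1 - \arccos(\Delta x/(s\Delta t))/\pi]\,\mathrm ds$. As
$\sigma_k \to 0$ the density collapses to the closed-form arcsine law
$1/(\pi\sqrt{(\mu\Delta t)^2 - \Delta x^2})$, which the implementation
switches to below $\sigma = 10^{-8}$; a zero-speed state degenerates to
a point mass at 0. The density has an integrable logarithmic singularity
at $\Delta x = 0$ whenever the speed density is positive at 0 — a
property of the model, not a numerical defect.

### Fitting

`fit_two_state()` is Baum–Welch EM: scaled forward–backward E-step; an
M-step that re-estimates the transition matrix and initial distribution
in closed form, the truncated-Normal parameters by bounded
quasi-Newton optimization of the weighted likelihood through its three
sufficient statistics ($\sum w$, $\sum w s$, $\sum w s^2$), and the
wrapped-Normal SD by a circular-moment start
($\hat\sigma = \sqrt{-2\log \bar R}$) refined by 1-D likelihood
optimization. Keeping every M-step an actual maximizer preserves the
monotone log-likelihood guarantee, which the tests assert. The
truncated-Normal mean is constrained to $\mu \ge 0$, its parameter
domain; the unconstrained MLE can drift negative on pooled bimodal
speeds.

Initialization splits steps at the median speed; a further 4 restarts
jitter that start multiplicatively (seed-controlled). Convergence is
declared at a relative log-likelihood change below `tol = 1e-6` within
`max_iter = 500`; starts that empty a state (posterior mass < 1e-3) are
discarded. Turning angles are missing at the first step of each track
and wherever a zero-length displacement leaves the angle undefined;
those steps contribute only their speed emission.

The first-step orientation is not modelled, so the likelihood depends on
the data only through speeds and turning angles — which makes every fit
exactly invariant to a global rotation of the field of view.

`fit_one_state()` is the closed-form/numerical MLE of the single-state
model and serves as the baseline for the model-adequacy comparison: on
two-state data the two-state log-likelihood should exceed it by far more
than the 6-parameter difference, and the fitted two-state displacement
density should match the empirical $\Delta x$ distribution at least as
well (KS statistic). Because EM stops on a relative tolerance, a
two-state fit of genuinely one-state data may sit a fraction of a nat
*below* the one-state MLE; the tests treat anything within one nat of
zero as "no improvement".

`decode_states()` provides the Viterbi path and forward–backward
posteriors. Zero transition probabilities (e.g. $\alpha = 1$) are kept
as exact zeros in log space so impossible states are never decoded.
`summarize_states()` reports posterior-weighted per-state mean speed,
directional variance over a lag (default two frames — an 8-minute window
at 4-minute frame intervals), and $\alpha$ as the posterior mean
occupancy.

### Directional variance

For orientation changes $\delta_i$ over a lag (an integer multiple of
$\Delta t$), the directional variance is the circular variance
$1 - |\,\mathrm{mean}\,e^{i\delta}\,|$: 0 for perfectly persistent
motion, 1 in the uncorrelated limit.

## Shape descriptors

`shape_factor = 4\pi A/P^2` (1 for a circle, near 0 for flattened
objects) and `elongation_factor` its reciprocal. A published variant of
the circularity formula without the square on the perimeter is
dimensionally inconsistent with "1.0 indicates a perfect circle" and is
treated as a typographical slip; only the $4\pi A/P^2$ form is
implemented. The perimeter uses the 4-direction Crofton estimate
$P = \pi\,\mathrm{mean}_\theta[\mathrm{chords}(\theta)\,d(\theta)]$
(axial spacing 1, diagonal $1/\sqrt2$); counting boundary pixels instead
overestimates $P$ by up to $\sim$20% and systematically deflates the
shape factor. On a rasterized disc of radius 50 px the Crofton shape
factor is within 0.4% of 1. The ellipse fixtures carry Ramanujan's
perimeter approximation
$P \approx \pi[3(a+b) - \sqrt{(3a+b)(a+3b)}]$, accurate to better than
0.01% for aspect ratios up to 5.

Binucleation assigns each nucleus to the cell containing its centroid
and reports the percentage of cells with two or more nuclei; centroids
outside every cell are warned about and left unassigned.

## Biosensor edge profiling

`distance_profile()` bins pixel activities by Euclidean distance to the
nearest edge (distance transform inside the mask) and reports per-bin
mean ± SEM. `edge_velocity()` defines the local protrusion/retraction
velocity as the difference of signed distance maps between consecutive
frames, evaluated at the edge pixels of the earlier frame and divided by
$\Delta t$ — positive outward (protrusion), negative inward
(retraction), exactly zero for a static edge, and antisymmetric under
time reversal. This signed-distance construction is a deliberate
methodological simplification of spline-window edge-tracking methods: it
meets the same sign semantics with one geometric primitive and no
tracking parameters. `activity_velocity_map()` samples every pixel
within `sample_depth` (default 5 μm) of the edge, attributes to it the
velocity of its nearest edge pixel, and accumulates (distance, velocity)
bin means and counts — every sampled pixel lands in exactly one bin, so
counts are conserved — plus category means for protruding
($v > 0.2$ μm/min), retracting ($v < -0.2$ μm/min) and static edges.
Per-cell and pooled averaging differ in principle; the implementation
pools samples, and per-cell curves can be had by calling
`distance_profile()` per movie.

## Synthetic data: what it emulates, and what it does not

* **Screen tables** (`make_screen_table`): per-gene, per-replicate
  migration indices as control mean × effect multiplier + additive
  Gaussian plate noise, clamped to [0, 100]. Defaults: control 55%
  basal (midpoint of a 50–60% control coverage range) and 70% under
  HGF (HGF stimulates migration; 1.4× effects stay inside the clamp);
  effects 0.6× (impaired) / 1.4× (accelerated); noise SD 3 index
  points; 3 replicates; hits assigned round-robin over the four
  categories. Additive Gaussian noise is the simplest model matching a
  mean ± SD description of replicate screens; there are no plate-edge,
  batch or carry-over effects.
* **Wound scenes** (`make_wound_scene`): a textured monolayer of
  touching dye-labelled cell dots with a dense rim flush against a
  circular exclusion zone; at t24, dots are added on uncovered wound
  pixels until the covered fraction is within 2% of target. A solid,
  untextured monolayer would be removed entirely by any
  rolling-ball-style flatten filter — real dye images show cell-scale
  texture, and so does the generator.
* **Tracks** delegate to `simulate_tracks()`, so track fixtures come
  from exactly the model being fitted. Parameter-recovery tests
  therefore validate the estimator, not the model's fidelity to real
  cells.
* **Biosensor movies** (`make_biosensor_movie`): a disc-like cell whose
  radius follows a per-frame (optionally per-sector) protrusion script,
  activity a known function of edge distance (optionally angle) plus
  Gaussian noise.

All generators are bit-reproducible under a fixed seed and restore the
caller's RNG state. None of them emulate photorealistic microscopy,
cell–cell collisions, division, uneven illumination or segmentation
errors — so passing tests demonstrate correctness of the *computations*
on well-posed inputs, not robustness to every pathology of real
microscopy.

## Problem sizes and numerical tolerances used by the test suite

The suite's statistical checks run at sizes chosen to keep Monte-Carlo
bands tight while staying desk-scale: parameter recovery at 100 tracks ×
180 steps (all six state parameters and α within 15%, decoding ≥ 90%);
the displacement-density KS check against 10⁵ simulated steps
(KS < 0.01) using weakly persistent generator settings
(σ_θ = 2.0/0.8, dwell 5, 1000 tracks × 100 steps) — the iid KS band is
only meaningful when step-to-step autocorrelation from persistent
headings and state dwell is weak, so strongly persistent settings would
fail the band even for a perfect density; forward-algorithm likelihoods
against brute-force path enumeration on 6-step tracks (10⁻¹⁰);
uncorrelated-walk mean-squared-displacement and convergence checks at
10⁴ samples with 3σ bands; density normalization to 10⁻⁶; plate
Z-score normalization to machine precision.

## Known limitations

* Two states only; no random-effects (per-cell) parameters, no
  interacting cells, no anisotropy.
* The EM fit assumes states switch *within* tracks; a population of
  cells fixed in different modes is the large-dwell limit and is
  estimated, but not distinguished from switching, on short tracks.
* Edge velocity by signed distance is robust but local: it does not
  track material points along the membrane, so tangential flow is
  invisible to it.
* The wound detector assumes one interior wound; multi-wound wells and
  time series beyond two time points are out of scope.
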
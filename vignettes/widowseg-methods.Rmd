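---
title: "Multilevel thresholding with black-widow metaheuristics: models and methods"
author: "widowseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel thresholding with black-widow metaheuristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(widowseg)
```

## The problem

Multilevel thresholding partitions a grayscale image into $k+1$ intensity
classes using $k$ cut points on its histogram.  In breast thermography and
similar biomedical imaging, the histogram of a region of interest is
multimodal — a hot core, warm surround, cool background — and the cut
points that separate those modes segment the anatomy without any spatial
model.  The entire problem reduces to maximizing a criterion over sorted
integer vectors $0 \le th_1 < \dots < th_k \le L-2$ for $L = 256$ gray
levels.

Two classical criteria are implemented, both driven solely by the
normalized histogram $p_i = n_i / N$:

* **Otsu's between-class variance.**  With class masses
  $\omega_j = \sum_{i \in C_j} p_i$ and means
  $\mu_j = \sum_{i \in C_j} i\,p_i / \omega_j$,
  $$\sigma_B^2(th) = \sum_{j=1}^{k+1} \omega_j (\mu_j - \mu_T)^2,$$
  where $\mu_T$ is the global mean.  Maximizing $\sigma_B^2$ is equivalent
  to minimizing the pooled within-class variance; the package's tests
  verify the decomposition
  $\sigma_B^2 + \sum_j \omega_j \sigma_{W,j}^2 = \sigma_{total}^2$
  to $10^{-9}$ on random histograms.

* **Kapur's entropy.**  Each class contributes the Shannon entropy of its
  normalized distribution,
  $H_j = -\sum_{i \in C_j} (p_i/\omega_j) \ln (p_i/\omega_j)$, and the
  criterion is $\sum_j H_j$.  The natural logarithm is used throughout;
  the base only rescales the objective and cannot change the maximizer.
  Terms with $p_i = 0$ contribute 0 (the $x \ln x \to 0$ limit), and an
  empty class contributes 0 rather than raising an error, so stochastic
  search may traverse degenerate candidates freely.

A single class-membership convention is used everywhere, in the
objectives, the segmenter and the oracle: gray level $g$ belongs to class
$j$ when $th_{j-1} < g \le th_j$ (sentinels $th_0 = -1$,
$th_{k+1} = L-1$), i.e. a threshold belongs to its lower class.

## Exact search and the exhaustive oracle

`exhaustiveOptimal()` enumerates all $\binom{L-1}{k}$ sorted vectors for
$k \le 3$.  Prefix sums of $p_i$, $i\,p_i$ and $p_i \ln p_i$ make every
class score an $O(1)$ lookup, and a precomputed $256 \times 256$
class-score table turns the $k = 3$ enumeration (2.7 million candidates)
into roughly a second of work.  Ties are broken toward the
lexicographically smallest vector, which makes oracle output reproducible
and comparisons with the metaheuristics exact.  Beyond $k = 3$
enumeration grows combinatorially and the function refuses, pointing to
the metaheuristic.

## The Black Widow Optimization Algorithm

BWOA is a population metaheuristic whose generation cycle mimics the
mating biology of *Latrodectus* spiders:

1. **Procreation.**  The best $\mathrm{round}(PP \cdot N_{pop})$ widows
   form the breeding pool and are paired disjointly at random.  Each pair
   draws a mixing vector $\alpha \sim U[0,1]^k$ per brood pair and
   produces $V_1 = \alpha \odot x_1 + (1-\alpha) \odot x_2$,
   $V_2 = \alpha \odot x_2 + (1-\alpha) \odot x_1$.
2. **Cannibalism.**  The fitter parent (the female) survives and eats the
   other; among $n$ offspring only the $\lceil CR \cdot n \rceil$ best
   survive their siblings.
3. **Mutation.**  $\mathrm{round}(PM \cdot N_{pop})$ members of the
   survivor pool are perturbed.  The default strategy redraws one
   component uniformly within bounds ("reset"); the classical
   two-component swap is retained as an option but is fitness-neutral
   here, because positions are sorted at decode time.  The pool's best
   member is exempt: a just-discovered optimum exists only in the
   survivor pool until replacement, and mutating it in place would
   destroy it before elitism can record it.  (Instrumented runs showed
   exactly this failure — the exact optimum evaluated mid-run, then
   lost — before the exemption was added.)
4. **Replacement.**  The next generation is the $N_{pop}$ best of the
   survivor pool plus the current best widow.  At the default rates this
   pool can be smaller than $N_{pop}$; the shortfall is topped up with
   freshly drawn random widows.  These immigrants keep the population
   size invariant and supply a steady trickle of exploration, which
   proved decisive on rugged entropy landscapes (see below).  With
   procreation disabled ($PP = 0$) there is no offspring pool and the
   generation is carried over unchanged, so the algorithm degenerates to
   returning the best initial widow.

Elitism is structural: the current best always enters the replacement
pool, so the best-so-far fitness is non-decreasing — every test run
audits its trace for monotonicity.

Defaults follow the standard protocol for this problem family:
$N_{pop} = 50$, 350 iterations, $PP = 0.8$, $CR = 0.5$, $PM = 0.4$,
with $\max(2, 2\lceil k/2 \rceil)$ offspring per pair.  Box bounds for
thresholding are $[0, L-2]$ per dimension; candidate positions are real
valued and are decoded (clamp, round, sort) before evaluation, so every
evaluation sees a valid sorted integer vector and duplicate thresholds
simply produce an empty class.

## The improved algorithm (IBWOA)

Two modifications are layered on the same engine.

**Lévy-driven procreation.**  Step lengths follow Mantegna's algorithm:
$\mathrm{Levy} = s \cdot R_6 / |R_7|^{1/\beta}$ with
$R_6 \sim N(0, \sigma^2)$,
$$\sigma = \left[\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
  {\Gamma\!\left(\tfrac{1+\beta}{2}\right)\beta\,2^{(\beta-1)/2}}\right]^{1/\beta},$$
$R_7 \sim N(0,1)$, $\beta = 1.5$ ($\sigma \approx 0.6966$) and scale
$s = 0.01$.  How the step enters procreation is genuinely open — the
defining equation introduces a perturbed mixing weight $\alpha'$ without
defining it — and the choice matters.  Three readings were implemented
and compared on the package's synthetic corpus by their exact-optimum
hit rates against the exhaustive oracle:

* $\alpha' = \mathrm{clamp}(\alpha + \mathrm{Levy}, 0, 1)$ keeps
  offspring convex combinations of their parents.  It is the most
  conservative reading but is provably inert once the population
  contracts: offspring can never leave the parents' componentwise
  interval, so the heavy tail does nothing exactly when exploration is
  scarcest.
* $\alpha' = \alpha + \mathrm{Levy}$ unclamped lets offspring
  extrapolate slightly past a parent along the line joining the pair —
  useful terminal polish, but still confined to that line.
* A Lévy flight in position space, scaled by the box width, moves
  offspring off the recombination line entirely and escapes correlated
  traps where two thresholds must move together.

The shipped `levyProcreate()` splits each brood pair between the last
two: the first child uses the unclamped $\alpha'$ (exploitation along
the parental line), its sibling takes the complementary plain mixture
plus a position-space flight (exploration off the line).  This mirrors
the stated intent of the design — Lévy flights for exploration,
balanced against exploitation — and measurably dominates each single
reading on both objectives.  With scale 0 no Lévy numbers are drawn and
the operator is bit-identical to plain procreation.

**Quasi-opposition-based learning.**  The quasi-opposite of $x$ in a box
$[l, u]$ is uniform between the box midpoint and the full opposite
$u + l - x$.  At initialization the quasi-opposite of every widow is
evaluated and the best $N_{pop}$ of the $2 N_{pop}$ candidates are kept.
During the run, with probability 0.3 per generation, the same keep-best
sweep is applied — but over the population's *current* per-dimension
interval, the convention of quasi-oppositional differential evolution.
Early on that interval is the whole box and jumps are global; as the
swarm contracts the jumps contract with it and become local
refinements.  Because QOBL at rate 0 would still reshape the initial
population, the initialization sweep is tied to the jump rate: at
`qoblJumpRate = 0` no QOBL step runs at all.  Together with the
draw-free disabled Lévy path this makes
`ibwoaOptimize(levy = levyConfig(scale = 0), qoblJumpRate = 0)`
consume exactly the baseline's random stream — the reduction is
bit-identical, and a test asserts it.

**Reproducibility.**  Each run seeds R's RNG once from the
configuration and all operators draw from that single stream in a fixed
order; disabled operators draw nothing.  Studies run seeds
$s_0, s_0+1, \dots$ so paired algorithm comparisons reuse identical
seeds.

## Quality metrics

Segmented images for metric purposes are class-mean reconstructions:
each pixel is replaced by the rounded mean gray level of its class
(metrics against raw class labels would be meaningless; a class-midpoint
mode is provided for comparison).

* **RMSE / PSNR.**  $\mathrm{PSNR} = 20 \log_{10}(255/\mathrm{RMSE})$
  dB, with RMSE the standard squared-difference root mean.  Identical
  images carry an infinity flag.
* **SSIM.**  Computed exactly as the single-statistic formula with
  whole-image moments and the 8-bit stabilizers $C_1 = (0.01 \cdot
  255)^2 = 6.5025$, $C_2 = (0.03 \cdot 255)^2 = 58.5225$; a windowed
  mean-SSIM mode (11×11 Gaussian, sd 1.5) is available for
  cross-checking against sliding-window implementations.
* **FSIM.**  Combines phase-congruency similarity ($T_1 = 0.85$) and
  gradient-magnitude similarity ($T_2 = 160$, Scharr operator) weighted
  by $PC_m = \max(PC_1, PC_2)$.  Phase congruency is computed from a
  log-Gabor filter bank — 4 scales, 4 orientations, minimum wavelength
  6 px, scale multiplier 2, $\sigma/f$ ratio 0.55 — with
  Rayleigh-statistics noise compensation ($k = 2$ standard deviations)
  and a sigmoid weighting of filter-response spread.  All constants are
  arguments.  Two constant images have no phase structure anywhere, and
  FSIM is refused as undefined rather than silently returned.

## The synthetic thermogram generator

Real thermograms are unavailable to an offline test suite, so the
package generates its own: a `MixtureSpec` lists 1–6 Gaussian intensity
modes (mean, sd, weight) and a seed.  `generateImage()` renders the
mixture as nested, mildly lobed elliptical regions — the mode farthest
from the background level forms the core, the nearest forms the
surround — with region areas exactly proportional to the weights.  Each
region fills with stratified draws from its mode's Gaussian (jittered
quantiles, shuffled spatially), rounded and clamped to $[0, 255]$.
`generateHistogram()` returns the same distribution analytically
(rounding bins, tails absorbed into levels 0 and 255); stratification
makes the sampled histogram track it at $O(1/n)$ rather than the
$O(1/\sqrt{n})$ of independent draws, and a test checks total variation
below 0.02 at $128^2$ pixels.

What the generator emulates: the multimodal gray-level structure of
thermogram regions, spatially coherent blobs with genuine edges and
phase structure (so FSIM has something to measure), and exact control
of mode masses.  What it does not emulate: thermal physics, sensor
noise correlation, vignetting, or the irregular anatomy of real breasts
— passing tests demonstrate correctness of the algorithms on controlled
multimodal inputs, not clinical performance.

`fixtureSuite()` builds the standing 20-image corpus used by the
acceptance experiments: equal-weight well-separated modes (2, 3 and 4
modes cycling; means jittered around an even grid over $[45, 215]$, sds
8–14, adjacent means at least ~3 sds apart), 128×128 pixels, with
exhaustive-oracle answers cached for $k \in \{1,2,3\}$ and both
objectives.  128×128 keeps the full suite at desk scale while leaving
histogram noise realistic enough to make the entropy landscape genuinely
rugged.

## Numerical choices and degenerate inputs

* Decoding clamps before rounding, so out-of-box positions repair to the
  nearest valid threshold; sorting happens at decode time only, leaving
  operators free in an unconstrained box.
* Duplicate thresholds after rounding produce an empty class worth 0 —
  legal, never fatal.
* Oracle ties break lexicographically; `which.max` order makes this
  deterministic.
* $R_7 = 0$ in a Lévy draw (probability zero, but finite-precision
  possible) is redrawn.
* Empty-class means are reported as 0 with an `empty` flag rather than
  NaN.
* Color inputs are converted with Rec.601 luminance weights and rounded
  half-up; image writes are lossless (PNG, ASCII PGM) so round-trips are
  bit-exact.

## Study protocol and problem sizes

`runStudy()` executes `runs` independent runs (default 35) with seeds
`baseSeed + 0 ... baseSeed + runs - 1`, reports per-run fitness,
thresholds and quality metrics, aggregates means and standard
deviations, and flags oracle hits when $k \le 3$.  The acceptance
experiments use the 20-image corpus with 5 seeds per image — 100 runs
per (objective, $k$, algorithm) cell — which keeps the complete suite
within desk-scale runtime while leaving each rate estimate a resolution
of one percentage point.

## Known limitations

* The exhaustive oracle stops at $k = 3$; no dynamic-programming exact
  solver is provided for larger $k$.
* Kapur's entropy on sampled (noisy) histograms has near-ties separated
  by $10^{-5}$ and correlated optima; the metaheuristic's exact-hit rate
  at $k = 3$ is high but not unity, and studies report it honestly.
* SSIM's global-statistics form and FSIM's phase-congruency constants
  follow the published defaults; other implementations that window SSIM
  or tune the filter bank will produce different absolute values.
* No DICOM or temperature-calibrated thermogram input; 8-bit grayscale
  only.
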
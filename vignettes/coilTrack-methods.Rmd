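---
title: "Tracking coiled worm postures by inverting a generative model"
author: "coilTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking coiled worm postures by inverting a generative model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilTrack)
```

## The model

A crawling nematode's 2-D posture is represented intrinsically by the
directions $\theta(s)$ of the body tangent at 100 equidistant arc-length
points, head first. Subtracting the mean orientation
$\langle\theta\rangle$ makes the description rotation-free; principal
component analysis of such profiles shows that a handful of eigenvectors of
the shape covariance — *eigenworms* $\hat e_i$ — capture nearly all
postural variance, so that

$$\theta_F(s) \;=\; \langle\theta\rangle + \sum_{i=1}^{5} a_i\,\hat e_i(s).$$

The first two modes form a quadrature pair whose phase
$\varphi = -\mathrm{atan2}(a_2, a_1)$ advances during forward crawling and
retreats during reversals; the third mode is an overall body bend whose
large excursions are deep turns; the fourth and fifth carry end-localized
curvature (head swings).

The tracker works by *inverting* this map. Given a body model (arc length
$l$ and half-thickness $r_j$ at each backbone point), any posture
$p = (a_1,\dots,a_5,\langle\theta\rangle)$ renders into a binary image: the
backbone is integrated from the tangent angles (each of the 99 segments
along the mean of its endpoint angles) and a filled disc of radius $r_j$ is
drawn at each point. A movie frame is tracked by finding the posture whose
render best matches it under

$$f_{err} = f_{outline}\cdot f_{pixel},$$

* $f_{outline}$: the outer boundary of each shape is traced, smoothed, and
  resampled into 201 equal-arc segments; the 201 inter-segment turning
  angles $\psi$ and the perimeter $\ell$ give
  $C_0\lVert\psi_1-\psi_2\rVert^2 + C_1(\ell_1-\ell_2)^2$, minimized over
  all cyclic starting offsets and both trace directions (the faithful
  version of the starting-point ambiguity after equal-arc resampling).
* $f_{pixel}$: after aligning centroids by a nearest-integer shift, both
  images are divided into 10×10-px blocks over their union bounding box
  (anchored at its top-left corner) and the mean squared difference of the
  per-block foreground fractions is taken. Always in $[0,1]$.

The product is zero on identical images and insensitive to translation by
construction. It is minimized by generalized pattern search from many
random starting points, under per-mode bounds $(18,18,34,12,6)$ and a
local-curvature cap: no two tangent angles 10 indices apart may differ by
more than 1.95 rad (curvature-infeasible polls score $+\infty$). Minima
with error below 1.0 are retained, and candidates within the merge box
$(3,3,3,3,2.5)$ in modes and 0.5 rad (circular) in orientation are merged,
keeping each cluster's best member.

Coiled silhouettes are fundamentally ambiguous — several postures can
produce one image, and every worm is pixel-identical to its head/tail
reversal — so frames yield zero, one or several candidates. A
dynamic-programming (Viterbi) pass then selects one candidate per frame
minimizing the total sequence error subject to per-frame velocity limits
(modes: $(3,3,4,3,2)$ units/frame; orientation: $\pi$ rad/s), bridges
gap frames with interpolating cubic splines, offers every uncrossed frame
both its thinning solution and the swapped version, and finally compares
the selected trajectory with its globally swapped twin by total rendered
image error, flagging near-ties (margin < 5%) for review — a reversal is
silhouette-invisible, so near-ties are expected and external information
(or the synthetic ground truth) settles them.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| mode bounds | (18, 18, 34, 12, 6) | mode units | tails of naturally occurring amplitudes |
| curvature limit | 1.95 over 10 indices | rad | rules out unnaturally tight coils |
| keep threshold | 1.0 | error units | retention cut for candidate minima |
| merge box | (3, 3, 3, 3, 2.5) + 0.5 | mode units, rad | cluster radius for duplicate minima |
| $C_0$, $C_1$ | 1.0, 1/100 | rad$^{-2}$, px$^{-2}$ | calibrated so matched renders score $\ll 1$ and mismatched coils $> 1$ at the default scale, making the keep threshold meaningful |
| restarts | 300 (tests/validation: 40–60) | — | budget vs. reliability of the global search |
| mesh init/tol, expand/contract, cap | 4.0 / 0.05, ×2 / ×0.5, cap 4.0 | mode units | GPS schedule scaled to the bounds; capping growth at the initial mesh measurably improves recovery per evaluation |
| block size | 10 | px | coarse-graining scale of $f_{pixel}$ |
| outline segments | 201 | — | equal-arc resolution of the boundary signature |
| boundary smoothing $\sigma$ | 3 | px arc | removes the pixel staircase; a rasterized disc then shows near-uniform turning angles while its perimeter stays within 5% |
| straightness threshold | 0.8 over 10 indices | rad | crawl frames pass, $|a_3|\gtrsim 11$ coils fail; orientation is only read off straight shapes |
| turn bands | $[10,20]$ / $>20$ | $a_3$ units | omega vs. delta amplitude classes |
| rate windows | 600 s window, 300 s step, 200 s discard | s | turn-frequency adaptation curves |
| MI bins / shifts | {2, 4, 10, 20} s, ±60 s | s | event-series independence analysis |

The weights $C_0, C_1$ deserve a note: they are free constants of the
method. We set them so that, at the package's default synthetic scale
(120-px worm on a 160×160 canvas), renders of the correct posture score
around $10^{-3}$–$10^{-2}$ while renders of a *different* coil score above
1.0. Only then does the fixed keep-threshold of 1.0 separate plausible from
implausible candidates. Exact numeric equality with any other
implementation's error values is not meaningful — only the induced ranking
is.

## The synthetic generator

Every claim in the test suite is validated against generated ground truth;
no recordings are required. The generator emulates:

* a posture ensemble of travelling body waves (~1.5 body wavelengths,
  quadrature pair, per-profile wavelength jitter), an overall-bend
  component with occasional deep-turn excursions, end-curvature bumps, and
  white angle noise (SD 0.12 rad/point). PCA of 5,000 such profiles gives
  the default basis: ensemble variances (35.2, 35.1, 31.9, 8.9, 2.2), top
  four modes capturing ≈96.5% of the variance;
* forward crawl as phase-locked sinusoids in $(a_1, a_2)$ of amplitude 4.5
  (≈0.64 rad tangent undulations) at 0.5 Hz, with $d\varphi/dt > 0$;
* the escape response: crawl, phase-reversed reversal after the 10-s
  stimulus, a bimodal $a_4$ head swing, a raised-cosine $a_3$ pulse (peak
  15, 7 s), and an imposed orientation profile whose segments sum to
  $-0.9\pi$ by default;
* foraging: independent inhomogeneous Poisson streams of omega
  ($a_3 \sim N(15,1)$ clipped to $[10,20]$) and delta ($N(23,1)$, clipped
  to $(20,30]$) turns with rate
  $r(t) = r_\infty + (r_0 - r_\infty)e^{-t/\tau}$ ($r_0 = 0.6$,
  $r_\infty = 0.15$ events/min, $\tau = 600$ s), ventral-only deep events,
  optional symmetric deep-dorsal background, and sub-threshold shallow
  wiggles. Conflicting events (closer than one pulse duration) are redrawn
  from the same process, preserving the adaptation profile;
* rendered movies with Bernoulli pixel-flip noise (default 0.01).

One deliberate geometric property: the basis is computed from the
reversal-symmetrized covariance $(C + PCP)/2$ ($P$ = body-index flip), so
every eigenworm is exactly symmetric or antisymmetric under head/tail
reversal. The 5-mode subspace is then closed under reversal, the head/tail
swap is an exact involution on coordinates, and a posture and its swap
render to bit-identical images (this also requires the mean-angle backbone
integration rule and centering by the backbone centroid; integrating each
segment along its *starting* angle, or centering by integer pixel shifts,
breaks the identity at the one-segment / sub-pixel level).

The generator's amplitude scale reproduces the method's phenomenology: a
pure $a_3$ bend first touches its own body at $a_3 \approx 15$–16 and
fully crosses by $a_3 \approx 23$, so the omega/delta bands fall exactly at
the touching and crossing regimes.

What the synthetic movies do **not** emulate: grayscale optics, motion
blur, illumination gradients, substrate debris, multi-worm contact, and
real residual posture structure beyond a white-noise/harmonic approximation
of the out-of-subspace content. Passing tests therefore establish the
correctness of the algorithms and their closed-loop consistency — they do
not certify performance on any particular microscope's footage.

## Numerical choices and degenerate inputs

* Image convention: x right, y down, origin at the top-left pixel center;
  angles from +x toward +y. Rasterization is inclusive (dist ≤ r) at pixel
  centers, matching the brute-force oracle bit-for-bit.
* Boundary tracing is Moore-neighbour with Jacob's stopping criterion; the
  smoothing kernel weights each boundary pixel by its local arc-length
  measure (pixel steps alternate between 1 and $\sqrt2$, which would
  otherwise bias the smoothed curve), and a short second kernel over the
  uniformly resampled points distributes the residual per-vertex turning.
* Rendered worms may touch only diagonally at the tapered tips, so
  component counting is 8-connected; tip radii are floored at 0.9 px to
  keep renders connected.
* The error landscape is multimodal by nature. Mode perturbations of a
  rendered posture increase $f_{err}$ monotonically near the optimum, but
  *orientation* perturbations need not: deep coils are nearly
  rotation-symmetric, so a rotated copy can score almost as well — this is
  precisely why multiple restarts and multiple retained candidates are
  essential, and why orientation is disambiguated at the sequence level.
* Gap interpolation uses Forsythe–Malcolm–Moler end conditions, which
  reproduce cubic trajectories exactly (natural end conditions would zero
  the end curvature and cannot).
* Peak detection uses MATLAB-style topographic prominence with a 0.5
  floor; shoulder sub-peaks are merged by the excursion rule (two same-sign
  extrema never separated by a drop below the $a_3 = 3$ straightness level
  are one turn).
* Holes smaller than 5 px are treated as pixel noise: they never flag a
  frame as crossed and are filled before skeleton analysis (a 2-px hole
  otherwise creates an irreducible skeleton loop). Genuine coil holes are
  orders of magnitude larger. Segmentation itself records all holes
  without filling.
* Empty candidate sets are legal per frame; a gap at a segment edge with
  fewer than two supporting frames is an error rather than an
  extrapolation.
* All stochastic components run off R's RNG; identical seeds give
  bit-identical ensembles, trajectories, candidate sets and movies.

## Problem sizes used in validation

The shipped validation uses desk-scale problem sizes chosen to exercise
every code path with comfortable statistics: 20 rendered coils × 48
restarts for the tracking-error bound (largest per-mode median error
≈3% of the mode range, against a 10% bound), 5,000-profile ensembles for
the variance-capture check (≈96.9% in four modes, against a 95% bound),
32-frame rendered escape movies for the end-to-end pipeline, 6–12 worm ×
35-min foraging batches for rates and mutual information, and 20-trial
escape batches for the reorientation mean. Restart budgets for production
tracking default to 300 per frame.

## Known limitations

* Head/tail identity is unobservable from silhouettes; the package
  resolves it by continuity and flags global near-ties instead of
  guessing. Real deployments should anchor the head once per segment from
  external cues (intensity, motion history).
* The per-frame search is stochastic; rare frames (≈1 in 20 at 48
  restarts on deep coils) retain only candidates outside the round-trip
  tolerance. The sequence filter usually rescues these via continuity, and
  larger restart budgets shrink the failure rate.
* Orientation attribution *within* an escape response depends on where the
  straight-shape reference frames fall relative to the turn bounds; the
  total reorientation is robust, the per-segment split is
  definition-dependent.
* The generator's orientation–curvature coupling
  ($d\langle\theta\rangle/dt = -\kappa a_3\,\mathrm{sign}(d\varphi/dt)$,
  $\kappa$ calibrated so a peak-15, 7-s pulse yields $-0.9\pi$) is a
  deliberately simple stand-in for the real, data-derived relationship.
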
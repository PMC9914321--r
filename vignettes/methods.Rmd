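---
title: "Methods: optimized S-curve enhancement and wavelet fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimized S-curve enhancement and wavelet fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammofuse)
```

`mammofuse` enhances the contrast of breast images (mammograms,
tomosynthesis slices) and then restores detail the enhancement may have
suppressed, by fusing the enhanced image with the original in the
wavelet domain. This vignette explains the model behind each stage, the
parameters that matter, the numerical decisions, and what the test
suite does and does not establish.

## The enhancement model

A raw 8-bit image is first mapped linearly onto $[0,1]$
(`normalize()`; the display range $[L_{\min}, L_{\max}]$ is carried
along so the map is exactly invertible). Each normalized pixel $r$ is
then remapped by the sigmoid gray-level ("S-curve") transform

$$ s(r) = \alpha + \frac{\beta - \alpha}{1 + e^{-(r-\gamma)/\delta}} $$

- $\gamma \in [0,1]$ (default 0.4962) is the center of the stretch on
  the normalized gray axis;
- $\delta > 0$ (default 0.07598) is the width: the slope at the center
  is $(\beta-\alpha)/(4\delta)$, so the default width concentrates a
  very steep stretch in roughly the central third of the gray range;
- $\alpha$ and $\beta$ (defaults 0.9642 and $8.594\times 10^{-4}$) are
  the two asymptote-side constants. The map runs from
  $s(0)\approx 0.9628$ down to $s(1)\approx 0.0021$ with the defaults:
  **the default transform is decreasing**, i.e. it inverts intensity
  while stretching mid-tone contrast. We keep that orientation as the
  reference operating point and expose `scurve_invert()` (swap
  $\alpha \leftrightarrow \beta$) as the escape hatch, rather than
  silently "fixing" the orientation; the quality metrics used for
  tuning (EME in particular) are insensitive to which orientation is
  chosen, so tuning behaves identically either way.

Useful identities (all verified to $10^{-12}$ in the tests):
$s(\gamma) = (\alpha+\beta)/2$, and point symmetry
$s(\gamma+d) + s(\gamma-d) = \alpha+\beta$.

### Local (tiled) application

Global application over-brightens regions that carry no diagnostic
content. `scurve_local()` therefore divides the image into a
$k \times k$ **grid** of tiles (default $k = 8$; ceiling division, so
edge tiles absorb the remainder). Grid semantics — rather than tiles of
$k \times k$ pixels — keeps the number of tiles independent of image
size, the convention adaptive histogram equalization uses.

Within each tile the pixels are renormalized (tile min $\to$ 0, tile
max $\to$ 1), pushed through the sigmoid, and mapped back onto the
tile's original span. Renormalization gives every tile the full
mid-tone stretch regardless of how narrow its local range is; it is the
default but switchable (`renormalize = FALSE` applies the sigmoid to
the tile's raw normalized values, in which case $k=1$ without blending
reproduces `scurve_global()` exactly). A constant tile is passed
through unchanged — there is no contrast to stretch and the
renormalization would be $0/0$.

With `blend = TRUE` (default) each pixel's output is bilinearly
interpolated between the mappings of the four nearest tile centers.
Because the per-tile mapping is parametric (tile min/max plus the
sigmoid), blending costs four vectorized sigmoid evaluations over the
image, and the seam-freedom property holds: on a smooth ramp the
largest jump across a tile boundary does not exceed the largest
within-tile gradient.

Outputs are clamped to $[0,1]$ after the sigmoid. With the default
constants the clamp is inert (range $\approx (0.0021, 0.9628)$), but
tuned or user-supplied parameters may exceed the unit interval.

## The fitness and the swarm

Contrast is scored with the block-based enhancement measure

$$ \mathrm{EME} = \frac{1}{b_1 b_2} \sum_{\text{blocks}}
   20\,\log_{10}\!\frac{I_{\max}}{I_{\min}} $$

over non-overlapping $3\times3$ blocks on the raw 0–255 scale
(decibel convention, hence base-10 logarithm). Three numerical guards:
$I_{\min}$ is floored at $\varepsilon = 1$ gray level (a block
containing a true zero would otherwise be infinite); a block whose
maximum falls below $\varepsilon$ contributes 0; and trailing partial
blocks are dropped, not padded — padding would fabricate contrast at
the borders. A constant image scores exactly 0.

`optimize_scurve()` tunes $(\alpha, \beta)$ — optionally all four
parameters — by particle swarm optimization with the canonical
inertia-weight rules

$$ v' = w v + c_1 r_1 (x_\mathrm{Best} - x) + c_2 r_2 (g_\mathrm{Best} - x),
   \qquad x' = x + v' $$

with $r_1, r_2 \sim U[0,1]$ drawn per component per iteration.
Defaults: swarm 30, 10 update iterations after the initial evaluation,
$w = 0.7$, $c_1 = c_2 = 1.5$ (a standard convergent setting), search
bounds $\alpha \in [0.5, 1]$, $\beta \in [0, 0.5]$, velocity capped at
$0.2\times$ the bound span. Velocities start at zero; positions are
drawn uniformly in the bounds. Boundary handling is absorbing: a
clipped component has its velocity zeroed. The global best is updated
greedily, so its fitness trace is non-decreasing by construction — an
exact invariant the tests assert on every run.

Two design choices that bear on reproducibility:

- **Elitist seeding** (default on): one particle starts at the fixed
  default constants, which guarantees the tuned EME is never below the
  fixed-parameter EME.
- **Seeding**: all draws come from a single seeded stream
  (`pso_config(seed = ...)`); the global RNG state is saved and
  restored, so library calls do not perturb a caller's session.

The search bounds are a design choice of this package (the natural
ranges on either side of the midpoint 0.5); nothing forces the optimum
into the interior, and on strongly low-contrast inputs the swarm
typically rides to $\alpha = 1$, $\beta = 0$ — the maximum-amplitude
sigmoid, which is what EME rewards.

## Wavelet fusion

Enhancement trades detail for contrast; fusion restores it. Both the
original and enhanced raw images are decomposed with a one-level
separable 2-D DWT into an approximate sub-band (LL) and three detail
sub-bands (LH, HL, HH); corresponding coefficients are merged and the
inverse transform reconstructs the fused image, clamped to the display
range.

- **Fusion rule**: the literal elementwise maximum on every sub-band is
  the default. On signed detail coefficients a plain maximum discards
  strong negative edges, so a sign-preserving `abs_max` variant (larger
  magnitude wins, detail bands only) is provided — flagged, not
  default, since the plain rule is the reference behavior.
- **Wavelet family**: `haar` by default — it makes hand-checkable
  fixtures possible (a $2\times2$ block's LL is $(a+b+c+d)/2$) — with
  `db2`, `db4`, `sym4` selectable; `level` is configurable, default 1.
- **Boundary handling**: odd sides are replicate-padded by one sample
  (a half-sample symmetric extension) to even length, and the
  orthonormal filter bank is applied with periodic indexing. This
  combination makes the analysis matrix exactly orthogonal for *every*
  image size, so forward + inverse reconstruction is exact to machine
  precision (the tests demand $<10^{-8}$ max error on sizes
  $8\times8$, $5\times7$, $33\times31$, $64\times64$); the recorded
  pre-pad shapes let `idwt_reconstruct()` restore odd dimensions
  exactly. Level-1 sub-bands measure $\lceil n/2 \rceil$ per side.

Fusing an image with itself is the identity up to reconstruction
round-off, and the rule is symmetric in its inputs — both are tested.

## Metrics

All metrics operate on the raw 0–255 scale (a normalized image is
de-normalized first; computing them on $[0,1]$ data would silently
rescale EME, SD and AMBE). Entropy requantizes to the 256-level grid
(round half up) before building its histogram, so it reports the
entropy of the image *as it would be displayed or saved*. AMBE is
$|\bar{x}_\mathrm{ref} - \bar{x}_\mathrm{proc}|$ with the original
source as reference by convention, including for fused outputs. The
universal image quality index is computed over $8\times8$ sliding
windows (stride 1) as
$Q = 4\sigma_{xy}\bar{x}\bar{y} / ((\sigma_x^2+\sigma_y^2)(\bar{x}^2+\bar{y}^2))$,
averaged over windows with a nonzero denominator; a fully constant pair
has no defined window anywhere and raises an error from `iqi()` itself,
which `metrics_report()` converts to `NA` so a degenerate image cannot
abort a batch. Note $Q$ is invariant to the $1/N$ vs $1/(N-1)$ variance
convention, since the covariance and variance sum scale together.

## The phantom generator

`generate_phantom()` builds mammogram-like scenes: a smooth tissue
background (white noise low-passed by a Gaussian transfer function with
correlation length `tissue_smoothness`, default 12 px), additive
Gaussian-profile lesions (default 3, peak contrast 20 gray levels,
radius ~8 px), 1–3 px microcalcification specks (default 10, +80 gray
levels), and pixelwise Gaussian noise (default sd 3). The
`low_contrast` preset dims every component and then rescales the scene
into $[90, 140]$, imitating the narrow-band, low-entropy inputs the
enhancement is aimed at. Scenes are bitwise-reproducible from the seed.

What the phantom does **not** emulate: anatomical structure (ducts,
pectoral muscle, skin line), X-ray physics (scatter, beam hardening),
detector noise statistics (quantum noise is signal-dependent, not
additive Gaussian), or the label distributions of clinical databases.
Passing tests therefore establish that the pipeline implements its
stated mathematics and improves its stated objectives on controlled
inputs — not that the enhancement is diagnostically adequate on
clinical images, which requires reader studies outside this package's
scope.

## Problem sizes and budgets in the test suite

The suite exercises the optimizer at its reference settings (swarm 30,
10 iterations) on $32\times32$ phantoms — large enough for a
$10\times10$ grid of EME blocks and an $8\times8$ tile grid, small
enough that a hundred seeded runs complete in about a minute — and the
end-to-end pipeline on $64\times64$ and $128\times128$ low-contrast
phantoms. Oracle comparisons (brute-force EME, sliding-window IQI,
per-tile S-curve chains) run on $12\times12$–$16\times16$ images where
the naive double loops are instant.

## Known limitations

- Only single-channel processing; color inputs are reduced to BT.601
  luminance at load.
- No DICOM reader — PGM/PNG/TIFF/JPEG only.
- The EME objective rewards amplitude, so unconstrained tuning tends to
  the bound corner ($\alpha=1, \beta=0$); if brightness preservation
  matters, narrow the bounds or penalize AMBE in a custom objective
  passed to `pso_maximize()`.
- Plain-max fusion of an inverting enhancement with its original mixes
  two opposite-polarity images; the fused IQI against the original is
  accordingly modest. The `abs_max` detail rule mitigates but does not
  remove this.
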
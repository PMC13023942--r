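---
title: "Frequency-aware self-supervised denoising of MEMS-OCT B-scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-aware self-supervised denoising of MEMS-OCT B-scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Optical coherence tomography (OCT) images tissue in depth-resolved
cross-sections (B-scans). When the beam is steered by a MEMS micromirror —
the standard route to handheld and endoscopic probes — three degradations
dominate:

1. **multiplicative speckle**, the granular interference pattern of
   coherent backscatter, signal-dependent and high-frequency;
2. **periodic low-frequency background**, a smooth intensity bias from
   swept-source instability, detector nonuniformity and mirror vibration;
3. **coherent stripes**, full-length line artifacts from parasitic Fresnel
   reflections, spatially consistent across consecutive B-scans.

No clean reference image exists for in-vivo data, which rules out
supervised training. `fenoct` implements a self-supervised pipeline:
classical preprocessing for the structured artifacts (2, 3), then a
neural denoiser for speckle trained only on noisy images via
Neighbor2Neighbor-style subsampling, with frequency-domain structure built
into both the network and the objective.

# The phantom generator

Real MEMS-OCT datasets of this kind are not publicly deposited, so the
package carries a first-class simulator (`phantom_config()`,
`make_phantom()`, `make_dataset()`) that produces layered-tissue phantoms
with all three degradations and keeps every component field:

$$y = \mathrm{clip}\big(x \cdot s + b + a_\mathrm{st} m\big),$$

where $x$ is the clean piecewise-smooth layer image, $s$ the speckle
field, $b$ the background field, $m$ the stripe mask. Clipping into the
representable range happens exactly once, after all corruptions, so the
stored fields reproduce the noisy image exactly (a property the tests
assert to machine precision).

Choices, and why:

* **Speckle**: i.i.d. unit-mean Gamma, $s \sim \Gamma(k, 1/k)$, so
  $E[s]=1$ and $\mathrm{Var}[s]=1/k$. Gamma intensity statistics are the
  standard model of fully developed speckle; a single shape parameter
  controls the strength. Default $k = 4$ (strong speckle,
  $\mathrm{Var}=0.25$).
* **Background**: a sum of 2-D cosines with random phase, amplitude 10%
  of the dynamic range, default periods (32 px axial, and 48 px lateral
  as a second component). The defaults are chosen long enough to be
  "low-frequency" relative to tissue texture but far enough from DC that
  a notch filter can address them without touching the image mean.
* **Stripes**: `count` full-length lines of width 1–2 px with a fixed
  additive amplitude; re-using a seed reproduces the positions, which is
  how consecutive B-scans of a simulated volume share one stripe pattern.
* **Geometry**: `n_layers` horizontal bands with smoothly curved
  interfaces (two lateral sinusoids per interface, ~3% of the height in
  amplitude). The darkest drawn intensity is assigned to the top band so
  every phantom has an air-like region above the tissue; the default SNR
  regions of interest (signal = first tissue band, background = air) rely
  on this convention.

What the phantom does *not* emulate: interferometric image formation,
depth-dependent attenuation and roll-off, axial point-spread structure,
motion. Tests passing on phantoms therefore certify the pipeline's
mechanics and its behavior under the stated noise model — not clinical
image quality.

# Classical preprocessing

**Stripes** (`remove_stripes()`): stripes are consistent across a stack
of consecutive B-scans while speckle decorrelates, so the per-pixel stack
mean concentrates them. Line profiles (row and column means of the stack
mean) are compared against a running-median baseline; lines deviating by
more than a threshold (default: $3\times$ the MAD-based scale of the
deviations) are flagged and replaced in every scan by linear interpolation
from the nearest unflagged lines along the perpendicular axis.

**Periodic background** (`detect_dominant_frequencies()`,
`notch_filter()`): peaks of the centered log-magnitude spectrum outside a
small DC-exclusion disk identify the interference frequencies; each is
attenuated by a Gaussian-profile notch $(1 - d\,e^{-r^2/2\sigma_b^2})$
applied symmetrically to the conjugate bin, which keeps the mask
conjugate-symmetric and the output real. Gaussian-profile notches are used
instead of ideal binary notches because smooth spectral edits ring far
less; a configurable spatial Gaussian blur remains as a second defense
against residual ringing. Frequencies are always reported in centered
coordinates (DC at the array center).

# Neighbor subsampling

`subsample_pair()` partitions the image into non-overlapping 2×2 cells
and picks one fixed position per cell for each half-image. The mapping is
a pure function of the shape and the pattern identifier — there is no
randomness anywhere, and the same mapping is used for training,
validation, testing and evaluation. Pattern A (default) takes top-left /
top-right: the two pixels feeding any output position are *laterally*
adjacent, so axial layer boundaries — where OCT anatomy lives — are never
split between the two half-images. Pattern B (top-left / bottom-left) is
available for ablation. The empirical noise-consistency gap
$|\bar g_2 - \bar g_1|$ shrinks as $n^{-1/2}$ for i.i.d. noise, which the
tests check across 64²–256² images.

Odd-sized inputs are rejected with instructions to crop; the CLI
center-crops with a message rather than padding silently.

# The network

A 4-level encoder/decoder with skip connections (`net_config()`,
`build_feunet()`), built on two blocks:

* **WSPM** (wavelet-guided spectral pooling): orthonormal single-level
  Haar split into LL/LH/HL/HH; the LL band passes through a learnable 1×1
  channel-mixing map (initialized to the identity); the three detail bands
  are scaled by $(1-\lambda)$; inverse Haar reconstructs. $\lambda = 0.65$
  by default. The module is linear for fixed parameters, the property that
  makes "spectral pooling" interpretable — so no normalization layer is
  ever placed inside it. With $\lambda = 0$ it is the identity; with
  $\lambda = 1$ it is exact 2×2 block averaging; on white noise it
  attenuates detail-band energy by $(1-\lambda)^2$. All three limits are
  asserted in the tests.
* **FE-RFB** (frequency-enhanced receptive-field block): four parallel
  branches, each a 1×1 channel reduction (to ¼ of the block width), a 3×3
  convolution with dilation rate {1, 2, 3, 5}, leaky-ReLU activations,
  and an embedded WSPM; branch outputs are concatenated, fused by a 1×1
  convolution and added residually to the input. The branch count, rates
  and channel fraction follow the receptive-field-block convention and are
  exposed in `ferfb_config()` for sensitivity runs.

Architecture choices that were genuinely open, and the decisions taken:

* Channels 32/64/128/256 (`base_channels = 32`, doubling per level) —
  sized so CPU-scale training is practical.
* Downsampling by 2×2 max pooling after each encoder block: the plainest
  operator, keeping WSPM the only frequency-selective element.
* Decoder upsampling = bilinear interpolation + 3×3 convolution (avoiding
  transposed-convolution grid artifacts), preceded by a 1×1 channel
  reduction; after concatenation with the skip tensor, a 1×1 fusion and
  an FE-RFB.
* Branch fusion happens before the skip connection is taken.
* Group normalization (8 groups) and leaky-ReLU after the level-entry,
  upsampling and fusion convolutions only — never in the spectral path.
* Fan-in-scaled (He) random initialization under a recorded seed; the
  WSPM LL refiners start as exact identities.

Ablation switches reproduce the structural variants: `use_wspm = FALSE`
removes the spectral refinement inside branches; `use_ferfb = FALSE`
replaces each block with a plain two-layer 3×3 convolution block (which,
since WSPM lives inside the branches, removes WSPM as well).

The package ships its own reverse-mode training engine: a tape over dense
(H, W, C, N) arrays with conv2d / max-pool / bilinear-upsample / group-norm
/ Haar kernels in C++ and Adam in R. Every kernel's gradient is checked
against central finite differences in the test suite.

# The objective

For a noisy patch $y$ with halves $(g_1, g_2)$ and network $f$:

$$\mathcal{L} = \lambda_1\,\|f(g_1) - g_2\|_1
  + \lambda_2\,\|f(g_1) - f(g_2)\|_2^2
  + \lambda_3\,\|\mathcal{F}(f(y)) - \mathcal{F}(x_\mathrm{pseudo})\|_2^2
  + \gamma\,\mathcal{R},$$

with defaults $\lambda_1 = 0.8$, $\lambda_2 = 0.1$, $\lambda_3 = 0.1$
(selected by grid search on validation SSIM; `grid_search_loss_weights()`
provides the harness) and $\gamma = 0.01$.

* The prediction term is an L1 norm (mean-reduced), the consistency term a
  mean squared difference.
* $x_\mathrm{pseudo}$ is the nearest-neighbor upsampling of
  $(g_1 + g_2)/2$: averaging the complementary halves halves the variance
  of independent per-pixel noise and matches the full-size output shape.
  Comparing against either half alone would reintroduce the noise of that
  half; the average is the lowest-variance pseudo-reference available
  without a model.
* $\mathcal{F}$ is the orthonormal 2-D FFT, and the loss is normalized by
  pixel count, making it resolution-independent. Under this convention
  Parseval's theorem makes the frequency loss *exactly* equal to the
  spatial MSE against $x_\mathrm{pseudo}$; the training engine therefore
  differentiates the spatial form while `frequency_consistency_loss()`
  computes the spectral form, and a test asserts their equality to 1e-6
  relative.
* $\mathcal{R} = \|(f(g_1) - g_2) - (g_1(f(y)) - g_2(f(y)))\|_2^2$ is the
  retained Neighbor2Neighbor regularizer: it vanishes for the identity
  model and pushes the denoiser to commute with subsampling, which
  counteracts over-smoothing. No path is gradient-detached.
* The `n2n_baseline` ablation trains the plain network with the plain
  objective $\|f(g_1) - g_2\|_2^2 + \gamma \mathcal{R}$.

The recorded total is always the exact weighted sum of the recorded parts
(an identity the tests assert on the per-step CSV log).

# Training and evaluation protocols

Two presets (`full_preset()`, `desk_preset()`):

| setting | full-scale preset | desk preset |
|---|---|---|
| epochs | 100 | 5 |
| batch | 4 | 1 |
| learning rate | 1e-4 | 1e-3 |
| halved every | 20 epochs | 2 epochs |
| patch | 64 px | 64 px |

The desk preset is the package's own scaled-down condition set, used by
the test suite and the acceptance script: 88 phantoms of 64×64 pixels
split 8:1:1-style into 64 training, 8 validation and 16 held-out test
images, 5 × 64 = 320 Adam steps. Patches are randomly chosen with
even-aligned offsets (so subsampling cells never straddle a crop);
validation uses the pseudo-clean protocol and the best-validation
parameters are retained, mirroring the SSIM-based selection used for the
loss weights. A seed fully determines the data, the initialization, the
patch order and every logged number; two runs with the same seed are
bit-identical.

Evaluation (`evaluate_pseudo_clean()`, `evaluate_true_clean()`):

* **Pseudo-clean**: each noisy scan is split with the fixed pattern; the
  network denoises $g_1$ and is scored against $g_2$. This is the only
  protocol available on real data.
* **True-clean**: phantoms carry their clean image, so the full denoised
  output is scored against it — the oracle protocol, and the package's
  primary success criterion at desk scale: PSNR(denoised, clean) must
  exceed PSNR(noisy, clean).

Metrics: PSNR on the *declared* value range (never recomputed from pixel
extremes, so scores are comparable across images; identical images return
an infinite sentinel rather than an error); SSIM with the canonical 11×11
Gaussian window, $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, population
local moments and border cropping (verified against an independent
reference implementation to 1e-10); ROI SNR
$20\log_{10}(\mathrm{mean}(\mathrm{signal})/\mathrm{sd}(\mathrm{background}))$
with explicit masks, since no universal SNR protocol exists — phantoms get
default masks from their known layer geometry.

# Numerical choices and degenerate inputs

* Even dimensions are required everywhere the 2×2 cell structure appears
  (subsampling, Haar); the network needs multiples of 16 (four halvings)
  and `denoise()` reflect-pads and crops back automatically.
* Notch masks are conjugate-symmetric by construction, so the filtered
  image is real to numerical noise; depth-0 notches with zero blur are the
  identity to better than 1e-6.
* Peak detection treats a spectrum with no candidate exceeding 10× the
  median off-peak magnitude (and a 1e-12 total-power floor) as "no
  dominant frequency" — a constant image yields an empty peak list, not an
  error.
* Stripe replacement at image borders falls back to the nearest unflagged
  line; ties in max pooling resolve to the first maximum in column-major
  order, deterministically.
* A non-finite loss aborts training immediately with the offending step's
  loss breakdown.

# Known limitations

* At desk scale (320 steps, 2.8M parameters) none of the model variants
  is near convergence, and margins between them are small. On the default
  seeded run the full model beats both single-module ablations — against
  the no-receptive-field-block variant only by a sliver — while the plain
  baseline (plain network, pure MSE objective) is still *ahead* of the
  full model by ~0.3 dB true-clean PSNR. That is expected at this
  horizon: a pure MSE prediction loss converges fastest toward the
  conditional mean, which under unit-mean multiplicative speckle is close
  to the clean phantom, whereas the L1 + consistency + frequency
  objective trades early MSE convergence for structure preservation and
  pays off over long schedules (100 epochs on thousands of images in the
  reference regime). Desk-scale ablation orderings should therefore be
  read as a smoke test of the machinery, not as a reproduction of
  full-scale margins.
* With strong speckle ($k = 4$) on a unit range, noisy-vs-clean PSNR sits
  near 13–16 dB on these phantoms; the pipeline's measured gains should be
  read relative to that operating point.
* The phantom's layered geometry is far simpler than finger tissue; the
  preprocessing stage's measured SNR gains on phantoms (where the injected
  artifacts are exactly removable) are not predictions for clinical scans.
* The training engine is CPU-oriented and single-threaded apart from BLAS;
  full-preset training at full image sizes is out of its intended scope.
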
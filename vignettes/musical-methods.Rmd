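---
title: "Methods: subspace super-resolution from blinking fluorophores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subspace super-resolution from blinking fluorophores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musical)
```

## The problem and the model

Wide-field fluorescence microscopy cannot resolve structures closer than
roughly $\lambda / 2\mathrm{NA}$ (about 200 nm for visible light and a high-NA
objective). When fluorophores blink — switch stochastically between bright and
dark states, independently of one another — a movie of the sample carries more
information than any single frame: different frames sample different random
subsets of emitters. MUSICAL (multiple signal classification) turns that
temporal diversity into spatial resolution without requiring sparse blinking,
special dyes or switching buffers.

Consider a small window of $N = N_w^2$ pixels observed over $K$ frames,
arranged as an $N \times K$ matrix $G$ (each column one vectorized frame of
the window). Its singular value decomposition

$$G = U \Sigma V^\top$$

yields *eigenimages* (columns of $U$): orthonormal spatial patterns ordered by
their singular values. Patterns that recur across frames — the structures
carrying the emitters, in all their blinking combinations — have large
singular values; patterns arising from shot noise have small ones. A threshold
$\sigma_0$ splits the eigenimages into a **signal subspace** (the range,
$\sigma_i \ge \sigma_0$) and a **null subspace** (the rest).

The PSF ties the subspaces to physical locations. For a *test point* $\mathbf{r}$
on a sub-pixel grid, the steering vector $a(\mathbf{r})$ is the unit-normalized
PSF of a hypothetical emitter at $\mathbf{r}$, sampled at the window's pixel
centers. Its projection norms onto the two subspaces,

$$d_{PR}(\mathbf{r}) = \lVert P_S\, a(\mathbf{r}) \rVert, \qquad
  d_{PN}(\mathbf{r}) = \lVert P_N\, a(\mathbf{r}) \rVert,$$

measure compatibility with the observed structure: if an emitter (or the
structure formed by emitters) truly occupies $\mathbf{r}$, its PSF lies in the
range and $d_{PN} \approx 0$. The per-point indicator

$$f(\mathbf{r}) = \left(\frac{d_{PR}(\mathbf{r})}{d_{PN}(\mathbf{r})}\right)^{\alpha}$$

is therefore very large at emitter locations and small elsewhere. The
$d_{PR}$ numerator (absent in classic MUSIC, which uses $1/d_{PN}$) weighs
each window by how much signal it actually contains, which is what makes
plain summation a valid stitching rule: the full image is scanned with the
window at stride one pixel, and the output at every test point is the sum of
the indicators of all windows covering it. The classic pseudospectrum remains
available via `traditional = TRUE`.

Because the rank of $G$ is at most $\min(N, K)$, a meaningful null subspace
needs enough frames; $K \ge N$ is desirable. With the default $N_w = 7$, i.e.
$N = 49$ pixels, 49 frames suffice — `run_musical()` warns (but proceeds)
below that. $N_w$ itself is set by the PSF extent: a 7-pixel window at 65
nm/pixel spans ~2 PSF FWHMs, large enough to contain an emitter's region of
confidence and small enough to keep the local emitter count well below the
frame count.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `N_w` | 7 | pixels | soft-window side; fixed by the PSF extent |
| `alpha` | 4 | — | indicator exponent; sharpens peaks non-linearly |
| `sigma0` | `rel:0.02` | — | subspace split at $0.02\,\sigma_1$ per window |
| `subpixel` | 10 | — | test-point grid density; output cell = pixel/`subpixel` |
| `eps` | $10^{-12}$ | — | floor on $d_{PN}$ against exact-null blowup |
| `na`, `wavelength`, `pixel_size` | — | —, nm, nm | optics; no defaults, must describe the instrument |

The relative $\sigma_0$ rule (signal = components with $\sigma_i \ge
\tau\sigma_1$, $\tau = 0.02$) adapts to local brightness and makes the map
exactly invariant under global intensity rescaling, since both the
decomposition and the threshold scale together. An absolute threshold
(`sigma0_absolute()`, CLI `abs:<v>`) is accepted for users who inspect a
window's singular-value spectrum by hand. When the threshold falls below all
singular values of a window the null subspace is empty; such a window carries
no localization information and contributes zero (with a warning) rather than
dividing by the floor everywhere.

## Conventions and numerical choices

- **Coordinates.** Positions are continuous, 0-based, in pixel units, with
  pixel centers at integer coordinates; nm enter only through `pixel_size`
  inside the PSF. One convention everywhere — emitters, windows, test
  points, profiles.
- **Sampling.** The PSF is point-sampled at pixel centers for both the
  steering vectors and the simulator default; the simulator additionally
  offers pixel-area integration on an odd `oversample` sub-grid for checking
  sensitivity to this choice.
- **Raw frames enter the SVD.** The temporal mean is not subtracted by
  default (`mean_subtract = FALSE` is exposed): the DC pattern then occupies
  one signal component and the split is applied to the raw spectrum.
- **Soft-window taper.** Uniform weights by default; a radial cosine taper
  (`taper = "cosine"`) is available. Whatever weights multiply the data also
  multiply the steering vector before renormalization, so data and steering
  live in the same weighted space.
- **Edges.** Windows are placed only where their full footprint fits; a
  border of $(N_w-1)/2$ pixels receives contributions only from interior
  windows, and test points covered by no window are 0.
- **Degenerate inputs.** All-zero windows are skipped; an all-zero stack
  yields an all-zero map without error. Exact-null test points are kept
  finite by the $d_{PN}$ floor.
- **Test grid.** $s \times s$ points per pixel at sub-pixel cell centers;
  output cell $(i,j)$ sits at input position $((i+0.5)/s-0.5,\,(j+0.5)/s-0.5)$.
- **Implementation.** Steering vectors depend only on the offset between
  test point and window center, so one steering dictionary of
  $(N_w s)^2$ unit vectors is precomputed and shared by all windows; each
  window then costs one thin SVD and one matrix product. Singular-value
  thresholding, not rank truncation, decides the split, and the projections
  are computed in the eigenbasis (no explicit projector matrices). The test
  suite cross-checks this fast path against a from-first-principles
  reference using dense covariance eigendecomposition and explicit
  projectors.

## What the simulator emulates — and what it does not

`simulate_stack()` generates stacks of independently blinking point emitters:
per frame, each emitter is bright with probability `p_on` (i.i.d. Bernoulli —
the minimal model satisfying the statistical-independence requirement; a
two-state Markov chain with the same stationary on-fraction is available for
dwell-time realism), the noise-free pixel expectation is background plus the
sum of bright emitters' PSFs, and Poisson shot noise is applied at unit
camera gain. Scene builders cover the standard validation geometries: an
isolated pair at a set separation (two-point resolution), rings, and a
Y-shaped fork (junction fidelity).

Defaults represent a realistic blinking movie: 1000 expected photons per
bright frame per emitter, on-fraction 0.2, 10 background photons per pixel
per frame. The signal-to-background ratio is *declared* here as peak expected
single-emitter pixel signal over mean background (`scene_sbr()`); published
SBR figures may use other conventions, so comparisons should check the
definition first.

Not modelled: photobleaching, dye dark-state kinetics beyond two states,
camera read noise and sCMOS pixel-dependent noise (a gain-1 photon-counting
camera is assumed), dipole orientation, 3D/defocus PSFs (a 2D in-focus PSF is
appropriate for TIRF-like imaging with ~100 nm penetration), and sample
drift. Passing tests on these simulations therefore demonstrate the
algorithm's statistical and geometric correctness, not robustness to every
instrumental artifact of real data.

## Quantification conventions

- `measure_fwhm()` interpolates the half-maximum crossings linearly on the
  raw profile; no baseline is subtracted by default (an explicit `baseline`
  argument exists). Whether published widths subtract background or fit a
  model is often unstated; the raw half-max crossing is the assumption-free
  choice.
- `average_aligned_profiles()` aligns maxima at integer-sample resolution
  before averaging — the plain reading of aligning profile maxima, without
  introducing a sub-sample registration model.
- `two_peak_contrast()` uses the symmetric Michelson form
  $(\bar p - d)/(\bar p + d)$ over the two largest local maxima and the dip
  between them. Two-peak "contrast" has no single standard definition, so
  the convention is declared and isolated in this one function; 1 means a
  dip to zero, 0 means no dip, and an unresolved profile reports 0 with
  `resolved = FALSE`.
- `profile_periodogram()` reports the dominant period at bin resolution
  (`1/span`) without zero padding — stated resolution rather than
  interpolated precision.

## Problem sizes used in validation

The test-suite and acceptance reconstructions run on small fields chosen to
exercise every code path at desk scale: 21 x 21 px stacks of 500 frames for
the two-point resolution study (5 seeds per separation, upsampling 20), 2000
frames for simulator statistics, and single-window stacks for the
oracle-equivalence checks. A full-frame experimental reconstruction is the
same computation with more windows; nothing in the implementation depends on
field size beyond linear cost in window count.

```{r example, eval = FALSE}
psf <- psf_model("airy", na = 1.49, wavelength = 593, pixel_size = 65)
scene <- make_pair_scene(50, psf, image_shape = c(21, 21),
                         brightness = 1040, p_on = 0.2, background = 100)
sim <- simulate_stack(scene, 500, noise = "poisson", seed = 1)
map <- run_musical(sim$stack, psf, N_w = 7, alpha = 4, subpixel = 20)
prof <- sample_line_profile(map, c(10, 8), c(10, 12), 301)
two_peak_contrast(prof)
```

## Known limitations

- Sub-diffraction performance degrades with SBR; no compensation for side
  lobes or camera noise is implemented (hooks for taper and thresholding
  exist, and `threshold_map()` provides the heuristic intensity floor — 0.4
  of the 99.9th percentile — useful against diffuse background in live-cell
  data).
- $\sigma_0$ selection is left to the user beyond the relative default; the
  CSV spectrum dump in the CLI supports manual choice.
- Single-threaded by design; window loops are embarrassingly parallel if
  ever needed.
- The indicator is not a photometric quantity: its scale depends on
  $\alpha$, $\sigma_0$ and window coverage, so only ratios and geometry
  (peak positions, widths, contrasts) should be interpreted.
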
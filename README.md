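# musical

Statistical super-resolution for wide-field fluorescence microscopy from
blinking-fluorophore image stacks, by multiple signal classification
(MUSICAL).

## Who this is for, and what it does

Microscopists and image analysts who have a movie of a fluorescent sample in
which the emitters blink — organic dyes, fluorescent proteins, anything with
intensity fluctuations that are statistically independent between emitters —
and want structure below the diffraction limit (~λ/2NA ≈ 200 nm) without
sparse single-molecule blinking, switching buffers or special hardware.

The method works per small *soft window* of the stack. The window's
pixels-by-frames matrix `G` is decomposed by SVD into orthonormal
*eigenimages* `U` with singular values `σ₁ ≥ σ₂ ≥ …`; eigenimages with
`σᵢ ≥ σ₀` span the **signal subspace** (recurring structure), the rest the
**null subspace** (noise). For every sub-pixel test point **r**, the
unit-norm PSF sampled over the window (the steering vector `a(r)`) is
projected onto both subspaces, giving `d_PR(r)` and `d_PN(r)`, and the
indicator

```
f(r) = ( d_PR(r) / d_PN(r) )^α
```

is huge where a real emitter sits (its PSF lies in the range, `d_PN → 0`)
and small elsewhere. Sliding the window across the image at stride 1 and
**summing** the indicators of all windows covering each test point yields
the super-resolved map — the `d_PR` numerator makes each window
self-weighting so plain summation is the correct stitching rule.

The package provides:

- `psf_model()`, `evaluate_psf()`, `psf_fwhm()`, `sample_psf_vector()` —
  Airy / matched-Gaussian PSF models;
- `make_pair_scene()`, `make_ring_scene()`, `make_fork_scene()`,
  `simulate_stack()`, `scene_sbr()` — a blinking-emitter simulator with
  Poisson shot noise and known ground truth;
- `run_musical()` plus the building blocks `extract_window_matrix()`,
  `compute_eigenimages()`, `split_subspaces()`, `project_psf()`,
  `indicator()`, and `threshold_map()`;
- `sample_line_profile()`, `measure_fwhm()`, `average_aligned_profiles()`,
  `two_peak_contrast()`, `profile_periodogram()`,
  `closest_maxima_distance()` — quantification;
- multi-page TIFF I/O with JSON provenance sidecars (`read_stack()`,
  `write_map()`, …) and a CLI (`exec/musical`) with `run`, `simulate`,
  `analyze` and `psf` subcommands.

## Worked example: resolving a 50 nm pair

Two emitters 50 nm apart — a quarter of the diffraction FWHM, less than one
camera pixel — blinking independently with on-fraction 0.2 at
signal-to-background 10, imaged for 500 noisy frames:

```r
library(musical)

psf <- psf_model("airy", na = 1.49, wavelength = 593, pixel_size = 65)
#> <psf_model> airy | NA = 1.49, lambda = 593 nm, pixel = 65 nm, FWHM = 204.8 nm

scene <- make_pair_scene(50, psf, image_shape = c(21, 21),
                         brightness = 1040, p_on = 0.2, background = 100)
#> <synthetic_scene> 2 emitters in 21 x 21 px, background 100, SBR 10.00

sim <- simulate_stack(scene, 500, noise = "poisson", seed = 1)
map <- run_musical(sim$stack, psf, N_w = 7, alpha = 4, subpixel = 20)
#> <indicator_map> 420 x 420 cells (3.25 nm/cell), range [0.016, 1.84e+09]; 225 windows

prof <- sample_line_profile(map, c(10, 8.5), c(10, 11.5), 301)
ct <- two_peak_contrast(prof)
round(as.numeric(ct), 3)
#> 0.808
round(attr(ct, "peak_positions"), 1)        # nm along the profile
#> 72.8 121.6
round((scene$emitters$col - 8.5) * 65, 1)   # ground truth
#> 72.5 122.5
```

The mean image of the same stack shows a single blob; the reconstructed map
shows two peaks with a deep dip (contrast 0.81) within ~1 nm of the true
positions. The map's absolute intensity scale is not photometric — interpret
geometry (positions, widths, contrasts), not raw values.

The same run from the shell:

```sh
exec/musical simulate --output stack.tif --scene pair --separation-nm 50 \
    --shape 21,21 --brightness 1040 --p-on 0.2 --background 100 --frames 500 --seed 1
exec/musical run --input stack.tif --output map.tif --pixel-size-nm 65 \
    --na 1.49 --wavelength-nm 593 --window 7 --alpha 4 --sigma0 rel:0.02 --subpixel 20
exec/musical analyze --input map.tif --op contrast --from 10,8.5 --to 10,11.5
```

See `vignette("musical-methods")` for the model, the σ₀ and taper choices,
the simulator's scope, and all declared conventions (SBR, two-peak contrast,
FWHM baseline handling).

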
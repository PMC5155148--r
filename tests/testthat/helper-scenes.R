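# standard optics used across tests: 100x/1.49 NA objective, 6.5 um camera
# pixels (65 nm at the sample plane)
test_psf <- function(wavelength = 593, model = "airy", pixel_size = 65) {
  psf_model(model, na = 1.49, wavelength = wavelength, pixel_size = pixel_size)
}

# small single-emitter scene, emitter centered on the central pixel
single_emitter_scene <- function(psf = test_psf(), shape = c(13L, 13L),
                                 brightness = 1000, p_on = 0.5, background = 5) {
  ctr <- (shape - 1) / 2
  synthetic_scene(
    data.frame(row = ctr[1], col = ctr[2], brightness = brightness, p_on = p_on),
    shape, background, psf
  )
}

# random positive single-window stack (H = W = N_w) for oracle comparisons
random_window_stack <- function(N_w, K, seed, pixel_size = 65) {
  set.seed(seed)
  arr <- array(rgamma(N_w * N_w * K, shape = 2, scale = 10), c(N_w, N_w, K))
  image_stack(arr, pixel_size)
}
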
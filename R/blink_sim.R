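#' Synthetic blinking-emitter scene
#'
#' Ground-truth description of a field of independently blinking point
#' emitters: continuous sub-pixel positions, per-frame brightness, on-state
#' probability, a uniform fluorescent background and the optical PSF.
#' Positions are 0-based `(row, col)` pixel units; pixel centers sit at
#' integer coordinates.
#'
#' Default photophysics are typical of organic-dye / fluorescent-protein
#' blinking movies: 1000 expected photons per bright frame per emitter,
#' on-fraction 0.2, 10 background photons per pixel per frame.
#'
#' @param emitters Data frame with columns `row`, `col` (pixel units),
#'   `brightness` (expected photons per bright frame, > 0) and `p_on`
#'   (per-frame on probability in (0, 1]).
#' @param image_shape Integer `(H, W)`.
#' @param background Expected background photons per pixel per frame (>= 0).
#' @param psf A [psf_model()].
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(emitters, image_shape, background, psf) {
  stopifnot(inherits(psf, "psf_model"))
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L))
    stop("'image_shape' must be two positive integers (H, W)", call. = FALSE)
  em <- as.data.frame(emitters)
  req <- c("row", "col", "brightness", "p_on")
  if (!all(req %in% names(em)))
    stop("'emitters' needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(em) > 0) {
    if (any(em$brightness <= 0)) stop("brightness must be > 0", call. = FALSE)
    if (any(em$p_on <= 0 | em$p_on > 1)) stop("p_on must be in (0, 1]", call. = FALSE)
    if (any(em$row < 0 | em$row > image_shape[1] - 1) ||
        any(em$col < 0 | em$col > image_shape[2] - 1))
      stop("emitter positions must lie inside the image bounds", call. = FALSE)
  }
  if (!is.numeric(background) || length(background) != 1L || background < 0)
    stop("'background' must be a single number >= 0", call. = FALSE)
  structure(list(emitters = em, image_shape = image_shape,
                 background = background, psf = psf),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d emitters in %d x %d px, background %g, SBR %s\n",
              nrow(x$emitters), x$image_shape[1], x$image_shape[2], x$background,
              if (x$background > 0) sprintf("%.2f", scene_sbr(x)) else "Inf"))
  invisible(x)
}

#' Two-emitter scene at a given separation
#'
#' The canonical two-point resolution phantom: two identical emitters
#' centered in the field, separated by `separation` nm along the horizontal
#' (column) axis.
#'
#' @param separation Center-to-center distance in nm (> 0, must fit in the
#'   field of view).
#' @param psf A [psf_model()] (its `pixel_size` sets the nm/pixel scale).
#' @param image_shape `(H, W)` in pixels; default 25 x 25.
#' @param brightness Expected photons per bright frame per emitter.
#' @param p_on Per-frame on probability.
#' @param background Background photons per pixel per frame.
#' @return A `synthetic_scene` with two emitters.
#' @export
make_pair_scene <- function(separation, psf, image_shape = c(25L, 25L),
                            brightness = 1000, p_on = 0.2, background = 10) {
  stopifnot(inherits(psf, "psf_model"))
  if (!is.numeric(separation) || length(separation) != 1L || separation <= 0)
    stop("'separation' must be a single positive number (nm)", call. = FALSE)
  sep_px <- separation / psf$pixel_size
  if (sep_px >= min(image_shape))
    stop("separation exceeds the field of view", call. = FALSE)
  ctr <- (image_shape - 1) / 2
  em <- data.frame(
    row = rep(ctr[1], 2),
    col = ctr[2] + c(-sep_px / 2, sep_px / 2),
    brightness = brightness, p_on = p_on
  )
  synthetic_scene(em, image_shape, background, psf)
}

#' Ring scene: emitters equally spaced on circles
#'
#' @param ring_centers Matrix with one `(row, col)` center per row, pixel
#'   units.
#' @param ring_radius Ring radius in nm.
#' @param emitters_per_ring Number of emitters equally spaced in angle on
#'   each ring.
#' @param psf A [psf_model()].
#' @param image_shape `(H, W)` in pixels.
#' @param brightness,p_on,background Photophysics as in [make_pair_scene()].
#' @return A `synthetic_scene`.
#' @export
make_ring_scene <- function(ring_centers, ring_radius, emitters_per_ring, psf,
                            image_shape = c(40L, 40L), brightness = 1000,
                            p_on = 0.2, background = 10) {
  stopifnot(inherits(psf, "psf_model"))
  rc <- as.matrix(ring_centers)
  if (ncol(rc) != 2L) stop("'ring_centers' must have 2 columns", call. = FALSE)
  if (ring_radius <= 0 || emitters_per_ring < 1)
    stop("invalid ring radius or emitter count", call. = FALSE)
  r_px <- ring_radius / psf$pixel_size
  ang <- 2 * pi * (seq_len(emitters_per_ring) - 1) / emitters_per_ring
  pos <- do.call(rbind, lapply(seq_len(nrow(rc)), function(i) {
    cbind(row = rc[i, 1] + r_px * sin(ang), col = rc[i, 2] + r_px * cos(ang))
  }))
  if (any(pos < 0) || any(pos[, 1] > image_shape[1] - 1) ||
      any(pos[, 2] > image_shape[2] - 1))
    stop("rings overlap the image boundary", call. = FALSE)
  em <- data.frame(row = pos[, 1], col = pos[, 2],
                   brightness = brightness, p_on = p_on)
  synthetic_scene(em, image_shape, background, psf)
}

#' Fork ("Y") scene: a stem splitting into two arms
#'
#' Emitters are laid every `emitter_spacing` nm along a vertical stem that
#' splits at its top into two straight arms, each deviating by
#' `arm_angle / 2` from the stem direction. The junction carries one emitter;
#' each arm then contributes `floor(arm_length / emitter_spacing)` more, so
#' the total count is
#' `floor(stem_length/spacing) + 1 + 2 * floor(arm_length/spacing)`.
#'
#' @param arm_angle Full opening angle between the two arms, radians.
#' @param arm_length Arm length in nm.
#' @param emitter_spacing Spacing between consecutive emitters in nm.
#' @param psf A [psf_model()].
#' @param stem_length Stem length in nm.
#' @param image_shape `(H, W)` in pixels.
#' @param brightness,p_on,background Photophysics as in [make_pair_scene()].
#' @return A `synthetic_scene`.
#' @export
make_fork_scene <- function(arm_angle, arm_length, emitter_spacing, psf,
                            stem_length = 2 * arm_length,
                            image_shape = c(40L, 40L), brightness = 1000,
                            p_on = 0.2, background = 10) {
  stopifnot(inherits(psf, "psf_model"))
  if (arm_length <= 0 || emitter_spacing <= 0 || stem_length <= 0)
    stop("lengths and spacing must be positive", call. = FALSE)
  px <- psf$pixel_size
  ctr <- (image_shape - 1) / 2
  n_stem <- floor(stem_length / emitter_spacing)
  n_arm <- floor(arm_length / emitter_spacing)
  # stem grows upward (decreasing row) ending at the junction near the center
  junction <- c(ctr[1] - (stem_length / px) / 4, ctr[2])
  stem_t <- seq(0, n_stem) * emitter_spacing / px
  stem <- cbind(row = junction[1] + stem_t, col = rep(junction[2], n_stem + 1))
  arms <- do.call(rbind, lapply(c(-1, 1), function(s) {
    th <- s * arm_angle / 2
    t <- seq_len(n_arm) * emitter_spacing / px
    cbind(row = junction[1] - t * cos(th), col = junction[2] + t * sin(th))
  }))
  pos <- rbind(stem, arms)
  if (any(pos < 0) || any(pos[, 1] > image_shape[1] - 1) ||
      any(pos[, 2] > image_shape[2] - 1))
    stop("fork does not fit inside the image bounds", call. = FALSE)
  em <- data.frame(row = pos[, 1], col = pos[, 2],
                   brightness = brightness, p_on = p_on)
  synthetic_scene(em, image_shape, background, psf)
}

# expected photon image of each emitter when bright: (H*W) x n matrix,
# column-major over (row, col). oversample > 1 averages the PSF over an
# oversample^2 sub-grid of each pixel (area integration); 1 = point sampling.
emitter_psf_matrix <- function(scene, oversample = 1L) {
  H <- scene$image_shape[1]; W <- scene$image_shape[2]
  em <- scene$emitters
  n <- nrow(em)
  P <- matrix(0, H * W, max(n, 1L))
  if (n == 0L) return(P[, 0, drop = FALSE])
  oversample <- as.integer(oversample)
  if (oversample < 1L || oversample %% 2L == 0L)
    stop("'oversample' must be a positive odd integer", call. = FALSE)
  offs <- (seq_len(oversample) - (oversample + 1) / 2) / oversample
  rows <- rep(seq_len(H) - 1, times = W)
  cols <- rep(seq_len(W) - 1, each = H)
  for (j in seq_len(n)) {
    acc <- 0
    for (dr in offs) for (dc in offs) {
      d <- sqrt((rows + dr - em$row[j])^2 + (cols + dc - em$col[j])^2) *
        scene$psf$pixel_size
      acc <- acc + evaluate_psf(scene$psf, d)
    }
    P[, j] <- em$brightness[j] * acc / oversample^2
  }
  P
}

#' Simulate a blinking image stack from a scene
#'
#' Per frame, each emitter is independently bright (recorded in the returned
#' `blink` matrix). The noise-free expectation of a pixel is
#' `background + sum over bright emitters of brightness * PSF(distance)`;
#' with `noise = "poisson"` each pixel is an independent Poisson draw with
#' that mean (photon shot noise at unit camera gain). Identical
#' `(scene, n_frames, noise, seed)` reproduce the stack bit-exactly; blinking
#' variates are drawn emitter-major (emitter 1 frames 1..K, then emitter 2,
#' ...) followed by the pixel noise, so random streams are stable across
#' runs. The caller's RNG state is restored on exit.
#'
#' @param scene A [synthetic_scene()].
#' @param n_frames Number of frames K (>= 1).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param seed Integer seed.
#' @param blink_model `"bernoulli"` (i.i.d. per frame, the minimal model of
#'   statistically independent blinking) or `"markov"` (two-state chain with
#'   the same stationary on-fraction `p_on`; dwell controlled by
#'   `p_off_given_on`, the per-frame probability of leaving the on state).
#' @param p_off_given_on Markov off-switching probability per frame (only
#'   used for `blink_model = "markov"`).
#' @param oversample Odd integer; >1 integrates the PSF over each pixel area
#'   on an `oversample^2` sub-grid instead of point-sampling pixel centers.
#' @return An object of class `simulated_stack`: list with `stack`
#'   ([image_stack()]), `blink` (emitters x frames 0/1 matrix), `scene`,
#'   `seed`.
#' @export
simulate_stack <- function(scene, n_frames, noise = c("poisson", "none"),
                           seed = 1L, blink_model = c("bernoulli", "markov"),
                           p_off_given_on = 0.5, oversample = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  noise <- match.arg(noise)
  blink_model <- match.arg(blink_model)
  K <- as.integer(n_frames)
  if (K < 1L) stop("'n_frames' must be >= 1", call. = FALSE)
  H <- scene$image_shape[1]; W <- scene$image_shape[2]
  n_em <- nrow(scene$emitters)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  blink <- matrix(0L, n_em, K)
  for (j in seq_len(n_em)) {
    p <- scene$emitters$p_on[j]
    if (blink_model == "bernoulli") {
      blink[j, ] <- rbinom(K, 1L, p)
    } else {
      # stationary start; p_on_given_off chosen to keep stationary p_on
      p_on_off <- min(1, p_off_given_on * p / (1 - p + 1e-300))
      s <- rbinom(1L, 1L, p)
      for (k in seq_len(K)) {
        blink[j, k] <- s
        s <- if (s == 1L) rbinom(1L, 1L, 1 - p_off_given_on)
             else rbinom(1L, 1L, p_on_off)
      }
    }
  }

  P <- emitter_psf_matrix(scene, oversample)
  expect <- matrix(scene$background, H * W, K)
  if (n_em > 0) expect <- expect + P %*% blink
  if (noise == "poisson") {
    vals <- rpois(length(expect), lambda = expect)
  } else {
    vals <- expect
  }
  arr <- array(as.numeric(vals), dim = c(H, W, K))
  structure(
    list(stack = image_stack(arr, scene$psf$pixel_size), blink = blink,
         scene = scene, seed = as.integer(seed)),
    class = "simulated_stack"
  )
}

#' Signal-to-background ratio of a scene
#'
#' Declared convention: SBR = (peak expected photon count contributed by the
#' brightest isolated emitter at its brightest pixel) / (mean background per
#' pixel). For a point-sampled PSF and an emitter sitting exactly on a pixel
#' center this reduces to `brightness / background`.
#'
#' @param scene A [synthetic_scene()] with `background > 0`.
#' @return Dimensionless SBR.
#' @export
scene_sbr <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (scene$background <= 0)
    stop("SBR undefined for zero background", call. = FALSE)
  if (nrow(scene$emitters) == 0L) return(0)
  P <- emitter_psf_matrix(scene)
  max(apply(P, 2, max)) / scene$background
}
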
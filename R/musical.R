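#' Sliding-window coordinates
#'
#' Pixel-center coordinates of an `N_w x N_w` window centered at an integer
#' pixel, in the vectorization order used throughout the package
#' (column-major: row index varies fastest).
#'
#' @param center Integer `(row, col)` center, 0-based pixel units.
#' @param N_w Odd window side in pixels.
#' @return `N_w^2 x 2` matrix of `(row, col)` pixel centers.
#' @export
window_pixels <- function(center, N_w) {
  h <- check_window_side(N_w)
  rows <- (center[1] - h):(center[1] + h)
  cols <- (center[2] - h):(center[2] + h)
  cbind(row = rep(rows, times = N_w), col = rep(cols, each = N_w))
}

check_window_side <- function(N_w) {
  if (length(N_w) != 1L || N_w < 3L || N_w %% 2L == 0L)
    stop("'N_w' must be an odd integer >= 3", call. = FALSE)
  (as.integer(N_w) - 1L) %/% 2L
}

# taper weights in pixel_list order; "uniform" (all 1) or a radial raised
# cosine falling to cos(pi/2 * r/r_max) at the window corner
window_taper <- function(N_w, taper = c("uniform", "cosine")) {
  taper <- match.arg(taper)
  h <- (N_w - 1) / 2
  if (taper == "uniform") return(rep(1, N_w^2))
  wp <- window_pixels(c(0, 0), N_w)
  r <- sqrt(wp[, 1]^2 + wp[, 2]^2)
  w <- cos(pi / 2 * r / (sqrt(2) * h + 1))
  pmax(w, 1e-3)
}

#' Extract a weighted window data matrix
#'
#' Column `k` holds the window's pixels from frame `k` (vectorized
#' column-major, rows fastest), each multiplied by its taper weight. This
#' `N x K` matrix is the input of the per-window eigenimage decomposition.
#'
#' @param stack An [image_stack()].
#' @param center Integer `(row, col)` window center, 0-based; the full
#'   footprint must lie inside the image.
#' @param N_w Odd window side (pixels).
#' @param frame_range Optional 1-based frame indices.
#' @param weights Optional length-`N_w^2` positive taper; default uniform.
#' @return `N_w^2 x K` numeric matrix.
#' @export
extract_window_matrix <- function(stack, center, N_w, frame_range = NULL,
                                  weights = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  h <- check_window_side(N_w)
  d <- dim(stack$data)
  if (center[1] - h < 0 || center[1] + h > d[1] - 1 ||
      center[2] - h < 0 || center[2] + h > d[2] - 1)
    stop("window footprint extends outside the image", call. = FALSE)
  fr <- resolve_frame_range(stack, frame_range)
  sub <- stack$data[(center[1] - h):(center[1] + h) + 1L,
                    (center[2] - h):(center[2] + h) + 1L, fr, drop = FALSE]
  M <- matrix(sub, nrow = N_w * N_w, ncol = length(fr))
  if (!is.null(weights)) {
    if (length(weights) != N_w^2 || any(weights <= 0))
      stop("'weights' must be ", N_w^2, " positive values", call. = FALSE)
    M <- M * weights
  }
  M
}

#' Eigenimages of a window data matrix
#'
#' Singular value decomposition of the `N x K` window matrix. The left
#' singular vectors are the window's eigenimages: orthonormal spatial
#' patterns ordered by how prominently they recur across frames (their
#' singular values). At most `min(N, K)` singular values are nonzero.
#'
#' @param window_matrix Finite `N x K` numeric matrix.
#' @return An object of class `window_decomposition`: list with
#'   `singular_values` (descending), `eigenimages` (`N x min(N, K)`
#'   orthonormal columns), `right_vectors`, and (after
#'   [split_subspaces()]) `sigma0`, `signal_indices`, `null_indices`.
#' @export
compute_eigenimages <- function(window_matrix) {
  M <- as.matrix(window_matrix)
  if (any(!is.finite(M))) stop("window matrix must be finite", call. = FALSE)
  q <- min(dim(M))
  sv <- svd(M, nu = q, nv = q)
  structure(
    list(singular_values = sv$d, eigenimages = sv$u, right_vectors = sv$v,
         sigma0 = NA_real_, signal_indices = integer(0),
         null_indices = integer(0)),
    class = "window_decomposition"
  )
}

#' @export
print.window_decomposition <- function(x, ...) {
  cat(sprintf("<window_decomposition> %d eigenimages of %d px; sigma1 = %.4g; signal dim %s\n",
              ncol(x$eigenimages), nrow(x$eigenimages), x$singular_values[1],
              if (is.na(x$sigma0)) "(not split)" else length(x$signal_indices)))
  invisible(x)
}

#' Singular-value threshold rules
#'
#' `sigma0_relative(tau)` thresholds each window at `tau * sigma_1` (its own
#' largest singular value), so the split adapts to local brightness and the
#' resulting map is invariant to a global intensity rescaling.
#' `sigma0_absolute(value)` applies one fixed threshold to every window.
#' [parse_sigma0()] converts the CLI spellings `"rel:0.02"` / `"abs:12.5"`
#' (or a bare number, taken as absolute).
#'
#' @param tau Relative threshold in (0, 1).
#' @param value Absolute singular-value threshold (>= 0).
#' @return A `sigma0_rule` object.
#' @export
sigma0_relative <- function(tau = 0.02) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("'tau' must be a single number in (0, 1)", call. = FALSE)
  structure(list(type = "relative", tau = tau), class = "sigma0_rule")
}

#' @rdname sigma0_relative
#' @export
sigma0_absolute <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || value < 0)
    stop("'value' must be a single number >= 0", call. = FALSE)
  structure(list(type = "absolute", value = value), class = "sigma0_rule")
}

#' @rdname sigma0_relative
#' @param x A `sigma0_rule`, a number (absolute threshold), or a string
#'   `"rel:<tau>"` / `"abs:<value>"`.
#' @export
parse_sigma0 <- function(x) {
  if (inherits(x, "sigma0_rule")) return(x)
  if (is.numeric(x)) return(sigma0_absolute(x))
  if (is.character(x) && length(x) == 1L) {
    if (grepl("^rel:", x)) return(sigma0_relative(as.numeric(sub("^rel:", "", x))))
    if (grepl("^abs:", x)) return(sigma0_absolute(as.numeric(sub("^abs:", "", x))))
    v <- suppressWarnings(as.numeric(x))
    if (!is.na(v)) return(sigma0_absolute(v))
  }
  stop("cannot interpret sigma0 rule: ", deparse(x), call. = FALSE)
}

#' Split eigenimages into signal and null subspaces
#'
#' Eigenimages with singular values `>= sigma0` form the signal subspace
#' (range); the rest form the null subspace. With a relative rule, `sigma0`
#' is resolved per window as `tau * sigma_1`.
#'
#' @param decomposition A [compute_eigenimages()] result.
#' @param sigma0_rule A [sigma0_relative()]/[sigma0_absolute()] rule (or
#'   anything [parse_sigma0()] accepts).
#' @return The decomposition with `sigma0`, `signal_indices` and
#'   `null_indices` filled in.
#' @export
split_subspaces <- function(decomposition, sigma0_rule = sigma0_relative(0.02)) {
  stopifnot(inherits(decomposition, "window_decomposition"))
  rule <- parse_sigma0(sigma0_rule)
  d <- decomposition$singular_values
  s0 <- if (rule$type == "relative") rule$tau * d[1] else rule$value
  q <- ncol(decomposition$eigenimages)
  sig <- which(d[seq_len(q)] >= s0)
  decomposition$sigma0 <- s0
  decomposition$signal_indices <- sig
  decomposition$null_indices <- setdiff(seq_len(q), sig)
  decomposition
}

#' Project a steering vector onto the signal and null subspaces
#'
#' Returns `d_PR`, the norm of the projection of the unit steering vector
#' onto the signal subspace (range), and `d_PN`, its projection norm onto
#' the null subspace. At a true emitter position the steering vector lies
#' (up to noise) in the range, so `d_PN` is close to zero there. With a
#' complete retained basis `d_PR^2 + d_PN^2 = 1`.
#'
#' @param decomposition A split [window_decomposition][compute_eigenimages()].
#' @param steering Unit-norm numeric vector of length N (taper weights, if
#'   any, must already be applied and the vector renormalized — see
#'   [run_musical()]).
#' @return List with elements `d_PR` and `d_PN` (class `projection_pair`).
#' @export
project_psf <- function(decomposition, steering) {
  stopifnot(inherits(decomposition, "window_decomposition"))
  U <- decomposition$eigenimages
  if (length(steering) != nrow(U))
    stop("steering vector length must equal the window pixel count", call. = FALSE)
  co <- drop(crossprod(U, steering))
  structure(
    list(d_PR = sqrt(sum(co[decomposition$signal_indices]^2)),
         d_PN = sqrt(sum(co[decomposition$null_indices]^2))),
    class = "projection_pair"
  )
}

#' MUSICAL indicator value
#'
#' `f = (d_PR / max(d_PN, eps))^alpha`: large where the test-point PSF is
#' consistent with the signal subspace and orthogonal to the null subspace.
#' The `d_PR` numerator weighs each window's contribution so overlapping
#' windows can be stitched by plain summation; `alpha` sharpens the peaks by
#' non-linear scaling. `traditional = TRUE` gives the classic MUSIC
#' pseudospectrum `(1 / max(d_PN, eps))^alpha` (use `alpha = 1` for its
#' textbook form).
#'
#' @param projection A [project_psf()] result (or any list with `d_PR`,
#'   `d_PN`).
#' @param alpha Positive exponent (default 4).
#' @param eps Floor applied to `d_PN` to avoid division by zero at exact
#'   null points; default `1e-12` (steering vectors are unit norm).
#' @param traditional Logical; drop the `d_PR` numerator.
#' @return Non-negative scalar.
#' @export
indicator <- function(projection, alpha = 4, eps = 1e-12, traditional = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  num <- if (traditional) 1 else projection$d_PR
  (num / max(projection$d_PN, eps))^alpha
}

# steering-vector dictionary shared by all windows: unit-norm PSF vectors for
# every sub-pixel offset of a test point relative to the window center.
# Returns N x (N_w*s)^2 matrix; column (tr, tc) [tr fastest] is the steering
# vector for the test point at row offset off[tr], col offset off[tc], with
# entries in window_pixels order (row fastest).
steering_dictionary <- function(psf, N_w, s, weights = NULL) {
  h <- (N_w - 1) / 2
  Tn <- N_w * s
  off <- -h - 0.5 + (seq_len(Tn) - 0.5) / s
  pix <- (-h):h
  A <- outer(pix, off, "-")^2            # N_w x Tn
  term_r <- A[rep(seq_len(N_w), times = N_w), rep(seq_len(Tn), times = Tn)]
  term_c <- A[rep(seq_len(N_w), each = N_w), rep(seq_len(Tn), each = Tn)]
  r_nm <- sqrt(term_r + term_c) * psf$pixel_size
  S <- matrix(evaluate_psf(psf, as.vector(r_nm)), nrow = N_w^2)
  if (!is.null(weights)) S <- S * weights
  nrm <- sqrt(colSums(S^2))
  if (any(nrm <= 0)) stop("degenerate steering vector in dictionary", call. = FALSE)
  sweep(S, 2, nrm, "/")
}

#' Run the MUSICAL reconstruction
#'
#' Slides an `N_w x N_w` soft window over every position where its full
#' footprint fits (stride 1 pixel). For each window the data matrix is
#' decomposed into eigenimages, the signal/null split is applied at
#' `sigma0`, and the indicator is evaluated at every test point of the
#' `subpixel`-times upsampled grid covered by the window. The output at each
#' test point is the sum of the indicator values of all windows covering it.
#'
#' Test points sit at sub-pixel cell centers: output cell `(i, j)` (0-based)
#' corresponds to input-pixel position `((i + 0.5)/s - 0.5, (j + 0.5)/s - 0.5)`.
#' Border cells covered by no complete window are 0.
#'
#' A warning is issued when `K < N = N_w^2`, the desirable minimum number of
#' frames for a full-rank window decomposition. Windows whose null subspace
#' comes out empty (threshold below every singular value) carry no
#' localization information and contribute 0; all-zero windows are skipped.
#'
#' @param stack An [image_stack()].
#' @param psf A [psf_model()]; its `pixel_size` must describe the stack.
#' @param N_w Odd window side in pixels (default 7).
#' @param alpha Indicator exponent (default 4).
#' @param sigma0 Threshold rule; see [sigma0_relative()]. Default
#'   `sigma0_relative(0.02)`.
#' @param subpixel Upsampling factor s >= 1 (default 10); the output grid is
#'   `(H*s) x (W*s)` with `pixel_size/s` nm per cell.
#' @param frame_range Optional 1-based frame indices.
#' @param taper `"uniform"` (default) or `"cosine"` soft-window weighting;
#'   the same weights multiply data and steering vectors.
#' @param mean_subtract Subtract each window's temporal mean image before
#'   the decomposition (default FALSE: raw frames enter the matrix).
#' @param traditional Use the classic MUSIC pseudospectrum `1/d_PN` instead
#'   of `d_PR/d_PN`.
#' @param eps Floor on `d_PN` (default 1e-12).
#' @return An object of class `indicator_map`: list with `values`
#'   (`(H*s) x (W*s)` matrix), `pixel_size` (nm per output cell),
#'   `subpixel`, and `params` (full provenance, including window counts).
#' @export
run_musical <- function(stack, psf, N_w = 7L, alpha = 4, sigma0 = sigma0_relative(0.02),
                        subpixel = 10L, frame_range = NULL,
                        taper = c("uniform", "cosine"), mean_subtract = FALSE,
                        traditional = FALSE, eps = 1e-12) {
  stopifnot(inherits(stack, "image_stack"), inherits(psf, "psf_model"))
  taper <- match.arg(taper)
  h <- check_window_side(N_w)
  N_w <- as.integer(N_w)
  s <- as.integer(subpixel)
  if (s < 1L) stop("'subpixel' must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  rule <- parse_sigma0(sigma0)
  d <- dim(stack$data)
  H <- d[1]; W <- d[2]
  if (H < N_w || W < N_w)
    stop("stack (", H, " x ", W, ") is smaller than the window", call. = FALSE)
  fr <- resolve_frame_range(stack, frame_range)
  K <- length(fr)
  N <- N_w^2
  if (K < N)
    warning("K = ", K, " frames < N = ", N,
            " window pixels; the decomposition is rank-limited (K >= N is desirable)",
            call. = FALSE)

  w <- window_taper(N_w, taper)
  if (taper == "uniform") w <- NULL
  S <- steering_dictionary(psf, N_w, s, weights = w)
  Tn <- N_w * s

  out <- matrix(0, H * s, W * s)
  n_used <- 0L; n_empty_null <- 0L; n_zero <- 0L
  centers_r <- h:(H - 1L - h)
  centers_c <- h:(W - 1L - h)
  for (cr in centers_r) {
    for (cc in centers_c) {
      M <- extract_window_matrix(stack, c(cr, cc), N_w, fr, weights = w)
      if (mean_subtract) M <- M - rowMeans(M)
      if (all(M == 0)) { n_zero <- n_zero + 1L; next }
      q <- min(N, K)
      sv <- svd(M, nu = q, nv = 0)
      s0 <- if (rule$type == "relative") rule$tau * sv$d[1] else rule$value
      sig <- sv$d[seq_len(q)] >= s0
      if (all(sig)) { n_empty_null <- n_empty_null + 1L; next }
      co <- crossprod(sv$u, S)                       # q x Tn^2
      dPR2 <- colSums(co[sig, , drop = FALSE]^2)
      dPN2 <- colSums(co[!sig, , drop = FALSE]^2)
      num <- if (traditional) 1 else sqrt(dPR2)
      ind <- (num / pmax(sqrt(dPN2), eps))^alpha
      ridx <- (cr - h) * s + seq_len(Tn)
      cidx <- (cc - h) * s + seq_len(Tn)
      out[ridx, cidx] <- out[ridx, cidx] + matrix(ind, Tn, Tn)
      n_used <- n_used + 1L
    }
  }
  if (n_empty_null > 0L)
    warning(n_empty_null, " window(s) had an empty null subspace and contributed 0",
            call. = FALSE)
  structure(
    list(values = out, pixel_size = stack$pixel_size / s, subpixel = s,
         params = list(N_w = N_w, alpha = alpha,
                       sigma0 = unclass(rule), subpixel = s, taper = taper,
                       mean_subtract = mean_subtract, traditional = traditional,
                       eps = eps, n_frames = K, frame_range = range(fr),
                       input_pixel_size = stack$pixel_size,
                       psf = unclass(psf),
                       windows_used = n_used, windows_empty_null = n_empty_null,
                       windows_all_zero = n_zero)),
    class = "indicator_map"
  )
}

#' @export
print.indicator_map <- function(x, ...) {
  cat(sprintf("<indicator_map> %d x %d cells (%g nm/cell), range [%.3g, %.3g]; %d windows\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values), x$params$windows_used))
  invisible(x)
}

#' Floor an indicator map at a fraction of a high percentile
#'
#' Suppresses diffuse background in the reconstruction: values below
#' `fraction` times the `percentile`-th percentile of the map's intensity
#' histogram are set to 0. The defaults (0.4 of the 99.9th percentile)
#' reproduce the heuristic floor used for live-cell reconstructions where
#' freely diffusing labelled molecules contribute a large diffuse background.
#'
#' @param map An `indicator_map`.
#' @param fraction Non-negative multiplier (default 0.4; 0 leaves the map
#'   unchanged).
#' @param percentile Percentile in (0, 100] (default 99.9).
#' @return The thresholded `indicator_map`.
#' @export
threshold_map <- function(map, fraction = 0.4, percentile = 99.9) {
  stopifnot(inherits(map, "indicator_map"))
  if (fraction < 0) stop("'fraction' must be >= 0", call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("'percentile' must be in (0, 100]", call. = FALSE)
  cut <- fraction * stats::quantile(map$values, percentile / 100, names = FALSE)
  map$values[map$values < cut] <- 0
  map$params$threshold <- list(fraction = fraction, percentile = percentile,
                               cutoff = cut)
  map
}
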
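#' Line profile container
#'
#' Intensity samples along a straight line, at uniformly spaced positions in
#' nm.
#'
#' @param positions Numeric vector of nm positions, uniformly spaced
#'   (within 1e-9 relative), length >= 3.
#' @param values Intensities, same length.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(positions, values) {
  if (length(positions) < 3L || length(positions) != length(values))
    stop("need >= 3 samples with matching positions/values", call. = FALSE)
  dp <- diff(positions)
  if (any(dp <= 0) || diff(range(dp)) > 1e-9 * max(abs(dp)) + 1e-12)
    stop("positions must be strictly increasing and uniformly spaced", call. = FALSE)
  structure(list(positions = as.numeric(positions), values = as.numeric(values)),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.1f nm (spacing %.3g nm)\n",
              length(x$values), diff(range(x$positions)), diff(x$positions[1:2])))
  invisible(x)
}

# bilinear interpolation of matrix `m` at continuous 0-based (row, col)
# coordinates; coordinates must lie in [0, nrow-1] x [0, ncol-1]
bilinear <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r0 <- pmin(floor(r), H - 2); c0 <- pmin(floor(c), W - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i <- function(rr, cc) m[cbind(rr + 1, cc + 1)]
  (1 - fr) * (1 - fc) * i(r0, c0) + (1 - fr) * fc * i(r0, c0 + 1) +
    fr * (1 - fc) * i(r0 + 1, c0) + fr * fc * i(r0 + 1, c0 + 1)
}

# input-pixel coordinates -> output-grid coordinates of an indicator map
map_grid_coord <- function(map, p) (p + 0.5) * map$subpixel - 0.5

#' Sample a line profile from an indicator map
#'
#' Bilinear interpolation of the map at `n_samples` equally spaced points
#' between two endpoints given in input-pixel coordinates (same continuous
#' 0-based frame as emitter positions). Profile positions are nm along the
#' line from `p_start`.
#'
#' @param map An `indicator_map` from [run_musical()].
#' @param p_start,p_end Length-2 `(row, col)` endpoints, input-pixel units.
#' @param n_samples Number of samples (>= 3).
#' @return A [line_profile()].
#' @export
sample_line_profile <- function(map, p_start, p_end, n_samples = 200L) {
  stopifnot(inherits(map, "indicator_map"))
  if (n_samples < 3L) stop("'n_samples' must be >= 3", call. = FALSE)
  g1 <- map_grid_coord(map, as.numeric(p_start))
  g2 <- map_grid_coord(map, as.numeric(p_end))
  dgrid <- dim(map$values)
  for (g in list(g1, g2))
    if (any(g < 0) || g[1] > dgrid[1] - 1 || g[2] > dgrid[2] - 1)
      stop("profile endpoint outside the map", call. = FALSE)
  t <- seq(0, 1, length.out = n_samples)
  rr <- g1[1] + t * (g2[1] - g1[1])
  cc <- g1[2] + t * (g2[2] - g1[2])
  vals <- bilinear(map$values, rr, cc)
  len_nm <- sqrt(sum((g2 - g1)^2)) * map$pixel_size
  line_profile(t * len_nm, vals)
}

#' Full width at half maximum of a line profile
#'
#' Finds the global maximum (which must be interior), locates the half-max
#' crossing on each side by linear interpolation between samples, and
#' returns their distance. No baseline is subtracted by default; an optional
#' `baseline` (intensity units) is subtracted before measuring.
#'
#' @param profile A [line_profile()].
#' @param baseline Intensity subtracted before measuring (default 0).
#' @return List of class `fwhm_result` with `fwhm` (nm), `peak_position`
#'   (nm) and `peak_value`.
#' @export
measure_fwhm <- function(profile, baseline = 0) {
  stopifnot(inherits(profile, "line_profile"))
  v <- profile$values - baseline
  p <- profile$positions
  im <- which.max(v)
  if (im == 1L || im == length(v))
    stop("profile maximum lies on the boundary; FWHM unresolvable", call. = FALSE)
  half <- v[im] / 2
  cross <- function(idx_seq) {
    # first sample at or below half, walking away from the peak
    for (i in idx_seq) {
      if (v[i] <= half) {
        j <- i + sign(im - i)  # neighbor towards the peak (above half)
        frac <- (half - v[i]) / (v[j] - v[i])
        return(p[i] + frac * (p[j] - p[i]))
      }
    }
    NA_real_
  }
  left <- cross((im - 1L):1L)
  right <- cross((im + 1L):length(v))
  if (is.na(left) || is.na(right))
    stop("no half-maximum crossing on one side; FWHM unresolvable", call. = FALSE)
  structure(list(fwhm = right - left, peak_position = p[im], peak_value = v[im]),
            class = "fwhm_result")
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("<fwhm_result> FWHM %.2f nm at %.2f nm (peak %.4g)\n",
              x$fwhm, x$peak_position, x$peak_value))
  invisible(x)
}

#' Average line profiles after aligning their maxima
#'
#' Each profile is shifted so that its maximum sits at position 0 (alignment
#' at integer-sample resolution), then the pointwise mean is taken over the
#' aligned indices where every profile has support. This is the procedure
#' used to build an average effective-PSF profile from a group of parallel
#' cross-sections.
#'
#' @param profiles List of [line_profile()] objects with a common sample
#'   spacing.
#' @return A [line_profile()]; position 0 is the aligned maximum.
#' @export
average_aligned_profiles <- function(profiles) {
  if (length(profiles) < 1L) stop("need at least one profile", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, TRUE, "line_profile")))
  sp <- vapply(profiles, function(p) diff(p$positions[1:2]), 0)
  if (diff(range(sp)) > 1e-9 * max(sp))
    stop("profiles must share one sample spacing", call. = FALSE)
  spacing <- sp[1]
  im <- vapply(profiles, function(p) which.max(p$values), 0L)
  n <- vapply(profiles, function(p) length(p$values), 0L)
  lo <- max(1L - im)          # most restrictive left extent (relative index)
  hi <- min(n - im)
  if (hi - lo + 1L < 3L)
    stop("aligned profiles share fewer than 3 samples", call. = FALSE)
  rel <- lo:hi
  avg <- rowMeans(vapply(seq_along(profiles),
                         function(i) profiles[[i]]$values[rel + im[i]],
                         numeric(length(rel))))
  line_profile(rel * spacing, avg)
}

# indices of strict local maxima of a numeric vector (plateau-safe: a run of
# equal values counts once, at its first index, if its neighbors are lower)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  d <- diff(v)
  sgn <- sign(d)
  # carry the last nonzero slope through plateaus
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  which(diff(sgn) < 0) + 1L
}

#' Two-peak contrast of a profile
#'
#' For a profile crossing two nearby structures: takes the two largest local
#' maxima and the minimum ("dip") between them, and returns the
#' Michelson-type contrast
#' \deqn{C = \frac{\bar{p} - d}{\bar{p} + d}, \quad \bar{p} = (p_1 + p_2)/2.}
#' `C = 1` when the dip reaches zero and `C = 0` when there is no dip. This
#' symmetric definition is the package's declared convention for two-peak
#' contrast. If the profile has fewer than two local maxima the structures
#' are unresolved: the value 0 is returned with attribute `resolved = FALSE`.
#'
#' @param profile A [line_profile()].
#' @return Contrast in `[0, 1]`, with attributes `resolved` (logical),
#'   `peak_positions`, `peak_values`, `dip_value`, `dip_position`.
#' @export
two_peak_contrast <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  v <- profile$values; p <- profile$positions
  lm <- local_maxima(v)
  if (length(lm) < 2L)
    return(structure(0, resolved = FALSE, peak_positions = p[lm],
                     peak_values = v[lm], dip_value = NA_real_,
                     dip_position = NA_real_))
  top2 <- lm[order(v[lm], decreasing = TRUE)[1:2]]
  top2 <- sort(top2)
  between <- top2[1]:top2[2]
  dip_i <- between[which.min(v[between])]
  pk <- mean(v[top2])
  dip <- v[dip_i]
  ctr <- (pk - dip) / (pk + dip)
  structure(ctr, resolved = TRUE, peak_positions = p[top2],
            peak_values = v[top2], dip_value = dip, dip_position = p[dip_i])
}

#' Power spectrum of a line profile
#'
#' Discrete Fourier power spectrum of the mean-removed profile; used to read
#' off spatial periodicities (e.g. along a filament). No zero padding is
#' applied, so the frequency resolution is `1/span`; the dominant peak is
#' reported at bin resolution.
#'
#' @param profile A [line_profile()] with >= 8 samples.
#' @return List with `frequency` (cycles per nm, positive frequencies),
#'   `power`, `peak_frequency`, `peak_period` (nm; `NA` if no power above
#'   1e-12 of the total).
#' @export
profile_periodogram <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  v <- profile$values
  n <- length(v)
  if (n < 8L) stop("need >= 8 samples for a periodogram", call. = FALSE)
  spacing <- diff(profile$positions[1:2])
  x <- v - mean(v)
  pw <- Mod(stats::fft(x))^2 / n
  nf <- floor(n / 2)
  freq <- (1:nf) / (n * spacing)
  pw <- pw[2:(nf + 1)]
  if (max(pw) <= 1e-12 * max(sum(pw), 1e-300) || max(pw) <= 1e-300) {
    pkf <- NA_real_
  } else {
    pkf <- freq[which.max(pw)]
  }
  list(frequency = freq, power = pw, peak_frequency = pkf,
       peak_period = if (is.na(pkf)) NA_real_ else 1 / pkf)
}

#' Distance to the closest indicator maximum along a direction
#'
#' For each query point, samples the map along the line through the point in
#' direction `direction` (both ways, out to the map border), finds the local
#' maxima of the 1D profile, and returns the distance (nm, unsigned) from
#' the point to the nearest one. Used to trace how far the nearest
#' reconstructed structure lies from a reference line.
#'
#' @param map An `indicator_map`.
#' @param points Matrix with one `(row, col)` point per row, input-pixel
#'   units.
#' @param direction Length-2 direction vector (normalized internally).
#' @param step Sampling step along the line in output-grid cells
#'   (default 0.5).
#' @return Numeric vector of nm distances; `NA` where no local maximum is
#'   found.
#' @export
closest_maxima_distance <- function(map, points, direction, step = 0.5) {
  stopifnot(inherits(map, "indicator_map"))
  pts <- matrix(as.numeric(points), ncol = 2)
  dir <- as.numeric(direction)
  nd <- sqrt(sum(dir^2))
  if (nd <= 0) stop("'direction' must be nonzero", call. = FALSE)
  dir <- dir / nd
  dgrid <- dim(map$values)
  vapply(seq_len(nrow(pts)), function(i) {
    g0 <- map_grid_coord(map, pts[i, ])
    # max parametric extents (grid cells) staying inside the map
    lim <- function(sgn) {
      t <- Inf
      for (k in 1:2) {
        dk <- sgn * dir[k]
        if (dk > 0) t <- min(t, (dgrid[k] - 1 - g0[k]) / dk)
        if (dk < 0) t <- min(t, (0 - g0[k]) / dk)
      }
      max(t, 0)
    }
    tpos <- lim(1); tneg <- lim(-1)
    tt <- seq(-floor(tneg / step) * step, floor(tpos / step) * step, by = step)
    if (length(tt) < 3L) return(NA_real_)
    vals <- bilinear(map$values,
                     pmin(pmax(g0[1] + tt * dir[1], 0), dgrid[1] - 1),
                     pmin(pmax(g0[2] + tt * dir[2], 0), dgrid[2] - 1))
    lm <- local_maxima(vals)
    if (length(lm) == 0L) return(NA_real_)
    min(abs(tt[lm])) * map$pixel_size
  }, numeric(1))
}
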
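#' Image stack container
#'
#' A stack of K frames of H x W non-negative pixel intensities with the
#' sample-plane pixel size attached. Data are stored as an `H x W x K` array;
#' frame `k` is `x$data[, , k]`.
#'
#' @param data Numeric `H x W x K` array (a single matrix is treated as one
#'   frame), finite and non-negative.
#' @param pixel_size Sample-plane pixel size in nm (> 0).
#' @return An object of class `image_stack` with elements `data` and
#'   `pixel_size`.
#' @export
image_stack <- function(data, pixel_size) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be an H x W x K array", call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0))
    stop("stack intensities must be finite and non-negative", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number", call. = FALSE)
  structure(list(data = data, pixel_size = pixel_size), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames of %d x %d px (%g nm/px), range [%g, %g]\n",
              d[3], d[1], d[2], x$pixel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer frame count K.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Temporal mean image of a stack
#'
#' The diffraction-limited reference image: the pixelwise mean over frames.
#'
#' @param stack An [image_stack()].
#' @param frame_range Optional integer vector of frame indices (1-based).
#' @return H x W matrix.
#' @export
mean_image <- function(stack, frame_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- resolve_frame_range(stack, frame_range)
  rowMeans(stack$data[, , fr, drop = FALSE], dims = 2)
}

resolve_frame_range <- function(stack, frame_range) {
  K <- dim(stack$data)[3]
  if (is.null(frame_range)) return(seq_len(K))
  fr <- as.integer(frame_range)
  if (length(fr) == 0L) stop("empty frame range", call. = FALSE)
  if (any(fr < 1L) || any(fr > K))
    stop("frame range outside 1..", K, call. = FALSE)
  fr
}
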
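#' Read a multi-page grayscale TIFF as an image stack
#'
#' Frames are taken in file order. Following the common convention for
#' microscopy TIFFs, 8- and 16-bit samples are treated as integer photon
#' counts and read as stored, while 32-bit samples are treated as
#' floating-point and returned as written. The sample-plane pixel size is
#' always supplied by the caller — TIFF resolution tags are notoriously
#' unreliable and the steering vectors depend critically on this value.
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param pixel_size Sample-plane pixel size in nm.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  probe <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(probe, "bits.per.sample")
  is_int <- !is.null(bits) && bits %in% c(8L, 16L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = is_int)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) > 2L && dim(p)[3] > 1L)
      stop("multi-channel/RGB TIFF is not supported; supply a grayscale stack",
           call. = FALSE)
  }
  pages <- lapply(pages, function(p) { dim(p) <- dim(p)[1:2]; p })
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), TRUE)))
    stop("inconsistent page shapes in ", path, call. = FALSE)
  arr <- array(0, dim = c(d1, length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  image_stack(arr, pixel_size)
}

#' Write an image stack as a multi-page float TIFF
#'
#' Values are stored as 32-bit floats scaled to `[0, 1]` by the stack
#' maximum (the TIFF writer's value range); the scale factor is recorded in
#' a JSON sidecar (`<path>.json`) so [read_stack_scaled()] restores original
#' intensities.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  K <- dim(stack$data)[3]
  pages <- lapply(seq_len(K), function(k) stack$data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(kind = "image_stack", scale = scale,
                            pixel_size = stack$pixel_size, n_frames = K,
                            package_version = as.character(utils::packageVersion("musical"))),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read back a stack written by [write_stack()]
#' @param path TIFF path (its `.json` sidecar must sit next to it).
#' @return An [image_stack()].
#' @export
read_stack_scaled <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  st <- read_stack(path, meta$pixel_size)
  st$data <- st$data * meta$scale
  st
}

#' Write an indicator map as a 32-bit float TIFF with provenance
#'
#' The map is stored scaled to `[0, 1]` by its maximum; the scale, the
#' output pixel size and the full reconstruction parameters go into a JSON
#' sidecar (`<path>.json`). With `log_scale = TRUE` a display copy holding
#' `log10(1 + values)` (same scaling convention) is written next to the map
#' as `<path base>_log10.tif`.
#'
#' @param map An `indicator_map` from [run_musical()].
#' @param path Output TIFF path.
#' @param log_scale Also write a log-transformed display copy.
#' @return Invisibly, the sidecar path.
#' @export
write_map <- function(map, path, log_scale = FALSE) {
  stopifnot(inherits(map, "indicator_map"))
  if (any(!is.finite(map$values))) stop("map contains non-finite values", call. = FALSE)
  write_one <- function(vals, p) {
    mx <- max(vals)
    scale <- if (mx > 0) mx else 1
    tiff::writeTIFF(vals / scale, p, bits.per.sample = 32L, compression = "none")
    scale
  }
  scale <- write_one(map$values, path)
  meta <- list(kind = "indicator_map", scale = scale,
               pixel_size_out = map$pixel_size, subpixel = map$subpixel,
               params = map$params,
               package_version = as.character(utils::packageVersion("musical")))
  if (log_scale) {
    logpath <- sub("(\\.tiff?)?$", "_log10.tif", path)
    meta$log10_copy <- basename(logpath)
    meta$log10_scale <- write_one(log10(1 + map$values), logpath)
  }
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read back an indicator map written by [write_map()]
#' @param path TIFF path (with its `.json` sidecar).
#' @return An `indicator_map`.
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- tiff::readTIFF(path)
  if (length(dim(vals)) > 2L) dim(vals) <- dim(vals)[1:2]
  structure(list(values = vals * meta$scale, pixel_size = meta$pixel_size_out,
                 subpixel = meta$subpixel, params = meta$params),
            class = "indicator_map")
}

#' Write a scene's ground truth next to a simulated stack
#'
#' CSV of emitter positions/photophysics, CSV of the blink matrix and a JSON
#' parameter record, for downstream validation of reconstructions.
#'
#' @param sim A `simulated_stack` from [simulate_stack()].
#' @param base Base path (without extension) for
#'   `<base>_emitters.csv`, `<base>_blink.csv`, `<base>_params.json`.
#' @return Invisibly, the written paths.
#' @export
write_ground_truth <- function(sim, base) {
  stopifnot(inherits(sim, "simulated_stack"))
  paths <- c(emitters = paste0(base, "_emitters.csv"),
             blink = paste0(base, "_blink.csv"),
             params = paste0(base, "_params.json"))
  utils::write.csv(sim$scene$emitters, paths["emitters"], row.names = FALSE)
  utils::write.csv(as.data.frame(sim$blink), paths["blink"], row.names = FALSE)
  sc <- sim$scene
  jsonlite::write_json(
    list(image_shape = sc$image_shape, background = sc$background,
         psf = unclass(sc$psf), n_frames = ncol(sim$blink), seed = sim$seed,
         sbr = if (sc$background > 0) scene_sbr(sc) else NULL),
    paths["params"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
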
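#' Assemble and validate a reconstruction run configuration
#'
#' Merges, in increasing precedence: package defaults, a YAML config file,
#' and explicit overrides (e.g. CLI flags). Every physical parameter is
#' validated before any computation, and every effective value — including
#' untouched defaults — is recorded so output sidecars carry complete
#' provenance.
#'
#' Defaults: `psf_model = "airy"`, `window = 7`, `alpha = 4`,
#' `sigma0 = "rel:0.02"`, `subpixel = 10`, no frame restriction, no
#' threshold. `pixel_size_nm`, `na` and `wavelength_nm` have no defaults:
#' they describe the microscope and must be supplied.
#'
#' @param file Optional YAML file path.
#' @param overrides Named list of values overriding file/defaults.
#' @return Validated named list of class `run_config`.
#' @export
load_config <- function(file = NULL, overrides = list()) {
  cfg <- list(input = NULL, output = NULL,
              pixel_size_nm = NULL, na = NULL, wavelength_nm = NULL,
              psf_model = "airy", window = 7L, alpha = 4,
              sigma0 = "rel:0.02", subpixel = 10L, frames = NULL,
              threshold = NULL, seed = 1L, log_level = "info")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    fromfile <- yaml::read_yaml(file)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(fromfile)] <- fromfile
  }
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(overrides)] <- overrides

  need_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0))
      stop("config key '", key, "' must be a single positive number", call. = FALSE)
  }
  for (k in c("pixel_size_nm", "na", "wavelength_nm", "alpha")) need_pos(k)
  if (!cfg$psf_model %in% c("airy", "gaussian"))
    stop("config key 'psf_model' must be \"airy\" or \"gaussian\"", call. = FALSE)
  w <- cfg$window
  if (!is.numeric(w) || length(w) != 1L || w < 3 || w %% 2 == 0)
    stop("config key 'window' must be an odd integer >= 3", call. = FALSE)
  cfg$window <- as.integer(w)
  if (!is.numeric(cfg$subpixel) || cfg$subpixel < 1)
    stop("config key 'subpixel' must be >= 1", call. = FALSE)
  cfg$subpixel <- as.integer(cfg$subpixel)
  parse_sigma0(cfg$sigma0)  # validates; keep original spelling for provenance
  if (!is.null(cfg$frames)) {
    fr <- parse_frames(cfg$frames)
    cfg$frames <- fr
  }
  if (!is.null(cfg$threshold)) {
    th <- cfg$threshold
    if (is.character(th)) th <- as.numeric(strsplit(th, ":")[[1]])
    th <- as.numeric(unlist(th))
    if (length(th) != 2L || th[1] < 0 || th[2] <= 0 || th[2] > 100)
      stop("config key 'threshold' must be fraction:percentile", call. = FALSE)
    cfg$threshold <- list(fraction = th[1], percentile = th[2])
  }
  structure(cfg, class = "run_config")
}

# "a:b" (1-based, inclusive) or numeric vector -> integer frame indices
parse_frames <- function(x) {
  if (is.character(x)) {
    ab <- as.integer(strsplit(x, ":")[[1]])
    if (length(ab) != 2L || any(is.na(ab))) stop("bad frame range: ", x, call. = FALSE)
    return(ab[1]:ab[2])
  }
  as.integer(x)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.null(v)) v <- "(unset)"
    cat(sprintf("  %-14s %s\n", k, paste(format(unlist(v)), collapse = " ")))
  }
  invisible(x)
}
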
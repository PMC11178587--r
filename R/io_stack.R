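## Stack file I/O and run configuration.
##
## Two stack formats are supported:
##  * ".rds"  - R native serialisation: lossless for 64-bit floats,
##    carries layout and metadata inline. The package's primary format.
##  * ".tif"  - multi-page float TIFF (pages = the 16 channels) for
##    exchange with other tools. The TIFF library stores unit-range
##    samples, so values are affinely mapped to [0, 1] on write with the
##    bounds recorded in a JSON sidecar (<path>.json); round trip is exact
##    to 32-bit float precision of the mapped values.
## Channel order is row-major over (generator, analyser) states; see
## [state_channel()].

stack_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "rds") "rds"
  else stop("unsupported stack extension '.", ext, "' (use .rds or .tif)")
}

#' Write an intensity or Mueller stack to disk
#'
#' @param x an [intensity_tensor()], [mueller_image()] or plain
#'   H x W x 16 array.
#' @param path output path; the extension selects the format (`.rds` or
#'   `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  kind <- if (inherits(x, "mueller_image")) "mueller" else "intensity"
  data <- unclass(x)
  if (kind == "mueller") {
    d <- dim(data)
    data <- array(data, c(d[1], d[2], 16L))  # 4 x 4 unrolled column-major
  }
  meta <- attr(x, "meta") %||% list()
  meta$kind <- kind
  meta$layout <- "channels-last"
  meta$state_order <- "row-major (generator, analyser)"
  if (kind == "intensity") meta$shots <- attr(x, "shots") %||% 1L
  if (kind == "mueller") meta$normalised <- attr(x, "normalised") %||% FALSE
  fmt <- stack_format(path)
  if (fmt == "rds") {
    saveRDS(list(data = data, meta = meta), path)
  } else {
    lo <- min(data); hi <- max(data)
    scl <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(data)[3]),
                    function(k) (data[, , k] - lo) / scl)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta$tiff_min <- lo; meta$tiff_scale <- scl
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an intensity or Mueller stack from disk
#'
#' Validates the channel count (16) and finiteness; multi-page and
#' channels-last layouts yield identical tensors.
#'
#' @param path file written by [write_stack()] (or any 16-page float
#'   TIFF with a JSON sidecar).
#' @return an [intensity_tensor()] or [mueller_image()] according to the
#'   recorded kind.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  fmt <- stack_format(path)
  if (fmt == "rds") {
    obj <- readRDS(path)
    data <- obj$data; meta <- obj$meta
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sidecar <- paste0(path, ".json")
    meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
    data <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (k in seq_along(pages)) {
      pg <- pages[[k]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      data[, , k] <- pg
    }
    if (!is.null(meta$tiff_min)) {
      data <- data * meta$tiff_scale + meta$tiff_min
    }
  }
  nch <- dim(data)[3]
  if (is.na(nch) || nch != 16L) {
    stop("expected 16 channels, found ", nch, " in ", path)
  }
  for (k in seq_len(16L)) {
    if (!all(is.finite(data[, , k]))) {
      stop("non-finite values in channel ", k, " of ", path)
    }
  }
  kind <- meta$kind %||% "intensity"
  if (kind == "mueller") {
    d <- dim(data)
    mueller_image(array(data, c(d[1], d[2], 4L, 4L)),
                  normalised = isTRUE(meta$normalised))
  } else {
    intensity_tensor(data, shots = meta$shots %||% 1L,
                     meta = meta[setdiff(names(meta),
                                         c("kind", "layout", "state_order",
                                           "shots", "tiff_min", "tiff_scale"))])
  }
}

#' Read / write a binary region-of-interest mask
#'
#' PNG or TIFF images; nonzero pixels are inside the ROI.
#'
#' @param path image path (.png, .tif, .tiff).
#' @param mask logical matrix (for writing).
#' @return `read_roi`: logical matrix.
#' @export
read_roi <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' @rdname read_roi
#' @export
write_roi <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (ext == "png") png::writePNG(img, path) else tiff::writeTIFF(img, path)
  invisible(path)
}

#' Write Lu-Chipman parameter maps as a multi-page TIFF
#'
#' Pages: D, Delta, R, phi, validity mask, with a JSON sidecar recording
#' units and conventions.
#'
#' @param p a `parameter_maps` object.
#' @param path output `.tif` path.
#' @export
write_parameter_maps <- function(p, path) {
  maps <- list(D = p$D, Delta = p$Delta, R = p$R, phi = p$phi,
               valid = matrix(as.numeric(p$valid), nrow(p$valid)))
  lo <- sapply(maps, min); hi <- sapply(maps, max)
  pages <- lapply(seq_along(maps), function(i) {
    s <- if (hi[i] > lo[i]) hi[i] - lo[i] else 1
    (maps[[i]] - lo[i]) / s
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pages = names(maps), page_min = as.list(lo),
         page_scale = as.list(ifelse(hi > lo, hi - lo, 1)),
         units = list(D = "dimensionless [0,1]",
                      Delta = "dimensionless [0,1]",
                      R = "degrees [0,180]", phi = "degrees [0,180) axial"),
         conventions = "phi = fast-axis azimuth; axial wrap at 180 degrees"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- run configuration ----------------------------------------------

#' Default run configuration
#'
#' Flat, serialisable key/value document of every tunable of the
#' pipeline. Unknown keys are rejected on load so silent typos cannot
#' change behaviour.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    input_stack = NULL,          # path to a measured stack (else phantom)
    calib = NULL,                # path to an .rds with G and A
    roi = NULL,                  # path to a mask image
    phantom_h = 64L, phantom_w = 64L,
    phantom_sigma = 0.08, phantom_kappa = 0.05, phantom_wmult = 3,
    phantom_lesion_frac = 0.18,
    method = "none",             # none | pddn | MEDF | GBLR | GRAD
    model = NULL,                # path to a trained model (.rds), for pddn
    t_star = "auto",
    preset = "desk",             # desk | paper (training preset)
    train_frames = 3L,           # phantoms used as HQ training set
    normalise = TRUE,            # M11 normalisation before decomposition
    delta_trace = "sub3",        # sub3 | full4
    csd_window = 5L,
    ssim_window = 7L,
    reflection_quantile = 0.999,
    reflection_dilate = 1L
  )
}

#' Load a run configuration from a YAML document
#'
#' Values in the file override defaults; `overrides` (e.g. parsed CLI
#' flags) override both. Unknown keys raise an error.
#'
#' @param path YAML file or `NULL` for pure defaults.
#' @param overrides named list applied last.
#' @return complete configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  apply_over <- function(cfg, vals, src) {
    bad <- setdiff(names(vals), names(cfg))
    if (length(bad)) {
      stop("unknown configuration key(s) in ", src, ": ",
           paste(bad, collapse = ", "))
    }
    utils::modifyList(cfg, vals)
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  if (length(overrides)) cfg <- apply_over(cfg, overrides, "overrides")
  cfg
}

#' @rdname load_config
#' @param cfg configuration list to serialise.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!sapply(cfg, is.null)], path)
  invisible(path)
}
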
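## Lightweight S3 containers for the pipeline's domain objects.

#' Construct an intensity tensor
#'
#' A polarimetric intensity acquisition: an H x W x 16 array of real-valued
#' intensities, one channel per (generator, analyser) polarisation-state
#' pair (see [state_channel()] for the channel ordering).
#'
#' @param data numeric H x W x 16 array (channels-last).
#' @param shots number of averaged camera shots this tensor represents
#'   (1 = single-shot low quality).
#' @param meta named list of free-form metadata (wavelength, seed, ...).
#' @return an object of class `intensity_tensor`.
#' @export
intensity_tensor <- function(data, shots = 1L, meta = list()) {
  d <- dim(data)
  if (length(d) != 3L || d[3] != 16L) {
    stop("expected 16 channels (H x W x 16 array), got ",
         paste(d, collapse = " x "))
  }
  if (!all(is.finite(data))) {
    bad <- which(apply(!is.finite(data), 3, any))
    stop("non-finite values in intensity channel(s) ",
         paste(bad, collapse = ", "))
  }
  structure(data, shots = as.integer(shots), meta = meta,
            class = "intensity_tensor")
}

#' Construct a Mueller image
#'
#' Per-pixel 4 x 4 Mueller matrices stored as an H x W x 4 x 4 array.
#'
#' @param data numeric H x W x 4 x 4 array.
#' @param normalised logical; `TRUE` if each block has been divided by its
#'   M11 element.
#' @param valid optional H x W logical matrix of pixels where the matrix is
#'   meaningful; defaults to all finite blocks.
#' @return an object of class `mueller_image`.
#' @export
mueller_image <- function(data, normalised = FALSE, valid = NULL) {
  d <- dim(data)
  if (length(d) != 4L || d[3] != 4L || d[4] != 4L) {
    stop("expected an H x W x 4 x 4 array")
  }
  if (is.null(valid)) {
    valid <- matrix(apply(is.finite(data), c(1, 2), all), d[1], d[2])
  }
  structure(data, normalised = isTRUE(normalised), valid = valid,
            class = "mueller_image")
}

#' Construct a calibration pair
#'
#' The polarisation state generator matrix G and analyser matrix A of the
#' instrument, determined at calibration. Either global (one 4 x 4 each) or
#' per-pixel (H x W x 4 x 4).
#'
#' @param G,A numeric 4 x 4 matrices, or H x W x 4 x 4 arrays for per-pixel
#'   calibration.
#' @param max_cond maximal accepted Frobenius condition number of any block.
#' @return an object of class `calibration_pair` with a `mode` field of
#'   `"global"` or `"per-pixel"`.
#' @export
calibration_pair <- function(G, A, max_cond = 1e8) {
  chk <- function(x, name) {
    d <- dim(x)
    if (identical(d, c(4L, 4L))) return("global")
    if (length(d) == 4L && d[3] == 4L && d[4] == 4L) return("per-pixel")
    stop(name, " must be 4x4 or H x W x 4 x 4")
  }
  mg <- chk(G, "G"); ma <- chk(A, "A")
  if (mg != ma) stop("G and A must share the same calibration mode")
  for (nm in c("G", "A")) {
    x <- if (nm == "G") G else A
    blocks <- if (mg == "global") array(x, c(1, 4, 4)) else
      array(x, c(prod(dim(x)[1:2]), 4, 4))
    kap <- cond44(blocks)
    if (any(!is.finite(kap)) || any(kap > max_cond)) {
      off <- which(!is.finite(kap) | kap > max_cond)[1]
      if (mg == "global") {
        stop("singular ", if (nm == "G") "generator" else "analyser",
             " matrix (condition number ",
             format(kap[off], digits = 3), " exceeds ", max_cond, ")")
      }
      stop("ill-conditioned ", nm, " calibration block at pixel ", off)
    }
  }
  structure(list(G = G, A = A, mode = mg, max_cond = max_cond),
            class = "calibration_pair")
}

#' @export
print.intensity_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<intensity_tensor %d x %d x 16, shots = %d>\n",
              d[1], d[2], attr(x, "shots")))
  invisible(x)
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<mueller_image %d x %d x 4 x 4, normalised = %s, %d/%d valid>\n",
              d[1], d[2], attr(x, "normalised"),
              sum(attr(x, "valid")), d[1] * d[2]))
  invisible(x)
}

## Internal: view a mueller_image as an N x 4 x 4 pixel stack.
mueller_pix <- function(M) {
  d <- dim(M)
  array(unclass(M), c(d[1] * d[2], 4L, 4L))
}

## Internal: rebuild a mueller_image from a pixel stack.
pix_to_mueller <- function(p, h, w, normalised = FALSE, valid = NULL) {
  mueller_image(array(p, c(h, w, 4L, 4L)), normalised = normalised,
                valid = valid)
}
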
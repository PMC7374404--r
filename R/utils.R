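# shared helpers: classed conditions, rounding, bilinear resize

pupilloc_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pupilloc_error"), call = call))
}

# round-half-up (base round() is ties-to-even, used only where stated)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_intensity_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && nrow(m) >= 1 && ncol(m) >= 1 &&
    all(is.finite(m))
}

#' Resize an intensity matrix by bilinear interpolation
#'
#' Thin wrapper around [EBImage::resize()] operating in the package's
#' row = y, column = x matrix convention. Resizing a matrix to its own size
#' is the identity.
#'
#' @param m numeric matrix (rows = height, columns = width).
#' @param height,width target dimensions, each >= 1.
#' @return numeric matrix of dimension `height` x `width`.
#' @keywords internal
resize_bilinear <- function(m, height, width) {
  stopifnot(is_intensity_matrix(m), height >= 1, width >= 1)
  if (nrow(m) == height && ncol(m) == width) return(m)
  # EBImage stores dim1 = x, so transpose in and out
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(t(m)), w = width, h = height,
                    filter = "bilinear")
  )
  matrix(t(out), nrow = height, ncol = width)
}
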
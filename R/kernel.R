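# iris kernel construction and adaptive per-pass resizing
#
# The kernel is a greyscale template of a generic iris: dark, approximately
# circular, on a lighter field. It must be non-constant, since normalised
# correlation is undefined for a zero-variance template. Before each
# matching pass the kernel is resized (bilinear) to the dimensions the pass
# requires: full eye-frame height and 0.4 x frame width for the horizontal
# pass, then 0.4 x iris-rectangle height at unchanged width for the
# vertical pass.

new_kernel <- function(pixels) {
  if (!is_intensity_matrix(pixels))
    pupilloc_error("kernel must be a non-empty finite numeric matrix",
                   "pupilloc_validation_error")
  if (stats::var(as.vector(pixels)) == 0)
    pupilloc_error("kernel is constant: normalised matching needs a non-constant template",
                   "pupilloc_degenerate_kernel_error")
  structure(list(pixels = pixels), class = "pupil_kernel")
}

#' @export
print.pupil_kernel <- function(x, ...) {
  cat(sprintf("<pupil_kernel: %d x %d px, range [%g, %g]>\n",
              ncol(x$pixels), nrow(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Build a custom iris kernel from example iris patches
#'
#' Combines cropped iris patches into a single generalising template: every
#' patch is resized (bilinear) to the element-wise median patch dimensions,
#' the resized patches are averaged pixel-wise, and the mean is rounded
#' (half up) to integer intensities. A single patch yields itself.
#'
#' @param iris_patches non-empty list of greyscale intensity matrices.
#' @return a kernel object.
#' @export
build_custom_kernel <- function(iris_patches) {
  if (!is.list(iris_patches) || length(iris_patches) == 0)
    pupilloc_error("need at least one iris patch", "pupilloc_validation_error")
  for (p in iris_patches)
    if (!is_intensity_matrix(p))
      pupilloc_error("each iris patch must be a non-empty numeric matrix",
                     "pupilloc_validation_error")
  hs <- vapply(iris_patches, nrow, 0L)
  ws <- vapply(iris_patches, ncol, 0L)
  h <- round_half_up(stats::median(hs))
  w <- round_half_up(stats::median(ws))
  acc <- matrix(0, nrow = h, ncol = w)
  for (p in iris_patches) acc <- acc + resize_bilinear(p, h, w)
  new_kernel(round_half_up(acc / length(iris_patches)))
}

#' Analytic dark-disc kernel
#'
#' The bundled default template when no iris patches are supplied: a dark
#' disc (intensity 20) of diameter 0.9 x min(width, height), centred on a
#' light field (intensity 235). Captures the geometric signature the method
#' relies on — an approximately circular dark iris on a lighter sclera.
#'
#' @param width,height kernel size in pixels, each >= 3.
#' @return a kernel object.
#' @export
default_disc_kernel <- function(width = 21L, height = 21L) {
  stopifnot(width >= 3, height >= 3)
  r <- 0.9 * min(width, height) / 2
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1), times = width), nrow = height)
  px <- matrix(235, nrow = height, ncol = width)
  px[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 20
  new_kernel(px)
}

#' Adapt the kernel for the horizontal pass
#'
#' Resizes the kernel to the eye frame's full height and to
#' `width_fraction` of the eye frame's width (rounded half up, clamped to
#' >= 1), so that sliding it horizontally with a 1-px stride scans every
#' iris x-position with no vertical strides.
#'
#' @param kernel a kernel object.
#' @param eye an [eye_frame()] or intensity matrix.
#' @param width_fraction kernel width as a fraction of eye-frame width
#'   (default 0.4).
#' @return the resized kernel.
#' @export
adapt_kernel_horizontal <- function(kernel, eye, width_fraction = 0.4) {
  stopifnot(inherits(kernel, "pupil_kernel"),
            width_fraction > 0, width_fraction < 1)
  px <- if (inherits(eye, "eye_frame")) eye$pixels else eye
  h <- nrow(px)
  w <- max(1L, round_half_up(width_fraction * ncol(px)))
  new_kernel(resize_bilinear(kernel$pixels, h, w))
}

#' Adapt the kernel for the vertical pass
#'
#' Resizes the kernel height to `height_fraction` of the iris-rectangle
#' height (rounded half up, clamped to >= 1) while keeping the width
#' unchanged, so the vertical pass scans pupil y-positions within the
#' iris rectangle.
#'
#' @param kernel the horizontal-pass kernel.
#' @param iris_rect_height height of the iris rectangle in pixels, or the
#'   iris-rectangle matrix itself; in the latter case the kernel width also
#'   follows the rectangle (a rim match clipped at the frame edge leaves
#'   the rectangle narrower than the kernel).
#' @param height_fraction kernel height as a fraction of the rectangle
#'   height (default 0.4).
#' @return the resized kernel.
#' @export
adapt_kernel_vertical <- function(kernel, iris_rect_height,
                                  height_fraction = 0.4) {
  stopifnot(inherits(kernel, "pupil_kernel"))
  w <- ncol(kernel$pixels)
  if (is.matrix(iris_rect_height)) {
    w <- ncol(iris_rect_height)
    iris_rect_height <- nrow(iris_rect_height)
  }
  stopifnot(iris_rect_height >= 1)
  h <- max(1L, round_half_up(height_fraction * iris_rect_height))
  new_kernel(resize_bilinear(kernel$pixels, h, w))
}

#' Save or load a kernel as an image with a JSON provenance sidecar
#'
#' The kernel is written as a PGM image; `<path>.json` records provenance
#' (patch count and content hash) so a saved kernel's origin is auditable.
#'
#' @param kernel a kernel object.
#' @param path output image path (`.pgm`).
#' @param provenance optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
save_kernel <- function(kernel, path, provenance = list()) {
  stopifnot(inherits(kernel, "pupil_kernel"))
  write_pgm(kernel$pixels, path)
  side <- c(list(width = ncol(kernel$pixels), height = nrow(kernel$pixels),
                 sha1 = digest_matrix(kernel$pixels)), provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_kernel
#' @export
load_kernel <- function(path) {
  new_kernel(read_pgm(path))
}

digest_matrix <- function(m) {
  # small content fingerprint without extra deps: dims + value checksum
  v <- as.vector(m)
  sprintf("%dx%d-%.6f-%.6f", nrow(m), ncol(m), sum(v), sum(v * seq_along(v)))
}
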
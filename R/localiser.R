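# the core method: white-rim padding, horizontal matching cascade for the
# iris x-position, vertical cascade within the iris rectangle for the pupil
# y-position, and the centre computation
#
# Both passes slide the kernel with a 1-pixel stride along ONE axis only
# (no nested 2D sliding). At each stride the normalised correlation
# coefficient between the mean-centred kernel and the mean-centred
# eye-frame patch scores the overlap; positions scoring above the dynamic
# 90th-percentile threshold form the candidate set, whose mean coordinate
# gives the matched rectangle corner.

#' Localiser configuration
#'
#' @param width_fraction horizontal-pass kernel width as a fraction of the
#'   eye-frame width (default 0.4).
#' @param height_fraction vertical-pass kernel height as a fraction of the
#'   iris-rectangle height (default 0.4).
#' @param quantile candidate-selection percentile of the score vector
#'   (default 90).
#' @param centred use the mean-centred (true correlation-coefficient) form
#'   of the matching score (default TRUE); FALSE gives the un-centred
#'   normalised cross-correlation variant.
#' @return a named list of settings.
#' @export
localiser_config <- function(width_fraction = 0.4, height_fraction = 0.4,
                             quantile = 90, centred = TRUE) {
  stopifnot(width_fraction > 0, width_fraction < 1,
            height_fraction > 0, height_fraction < 1,
            quantile > 0, quantile < 100)
  list(width_fraction = width_fraction, height_fraction = height_fraction,
       quantile = quantile, centred = isTRUE(centred))
}

#' Pad an intensity matrix with a white rim
#'
#' Adds `pad_x` columns of 255 on the left and right and `pad_y` rows on
#' the top and bottom. The white rim lets the kernel overlap frame-edge
#' positions, so an iris sitting at an extreme left/right gaze position is
#' still reachable by the sliding match.
#'
#' @param frame intensity matrix.
#' @param pad_x,pad_y non-negative padding in pixels.
#' @return padded matrix of size `(h + 2 pad_y) x (w + 2 pad_x)`.
#' @export
pad_white <- function(frame, pad_x = 0L, pad_y = 0L) {
  stopifnot(is_intensity_matrix(frame), pad_x >= 0, pad_y >= 0)
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(255, nrow = h + 2 * pad_y, ncol = w + 2 * pad_x)
  out[(pad_y + 1):(pad_y + h), (pad_x + 1):(pad_x + w)] <- frame
  out
}

#' Normalised correlation matching score
#'
#' Scores the agreement between a kernel and an equally sized image patch:
#' `sum(K' E') / sqrt(sum(K'^2) sum(E'^2))` where `K'` and `E'` are the
#' mean-centred kernel and patch. The result lies in [-1, 1] and is
#' invariant to positive affine rescaling of either input. A zero-variance
#' patch or kernel is degenerate and scores 0 (never an error: rim-padding
#' produces constant all-white patches by construction).
#'
#' @param kernel a kernel object or intensity matrix.
#' @param patch intensity matrix with the kernel's dimensions.
#' @param centred mean-centre both inputs first (default TRUE).
#' @return scalar score in [-1, 1].
#' @export
match_score <- function(kernel, patch, centred = TRUE) {
  k <- if (inherits(kernel, "pupil_kernel")) kernel$pixels else kernel
  if (!all(dim(k) == dim(patch)))
    pupilloc_error("patch dimensions must equal kernel dimensions",
                   "pupilloc_sizing_error")
  if (centred) {
    k <- k - mean(k)
    patch <- patch - mean(patch)
  }
  den <- sqrt(sum(k^2) * sum(patch^2))
  if (den == 0) return(0)
  sum(k * patch) / den
}

# shared single-axis matching cascade: pad along the stride axis, slide the
# kernel with a 1-px stride, score each overlap; positions are reported in
# unpadded coordinates (negative and >= extent - kernel positions occur at
# the rims)
slide_scores <- function(frame, kernel_px, axis = c("x", "y"), centred = TRUE) {
  axis <- match.arg(axis)
  kh <- nrow(kernel_px); kw <- ncol(kernel_px)
  if (axis == "x") {
    pad <- kw %/% 2
    padded <- pad_white(frame, pad_x = pad, pad_y = 0L)
    if (kw > ncol(padded) || kh != nrow(padded))
      pupilloc_error("kernel does not fit the padded frame",
                     "pupilloc_sizing_error")
    n_pos <- ncol(padded) - kw + 1L
    positions <- seq_len(n_pos) - 1L - pad
    scores <- vapply(seq_len(n_pos), function(i)
      match_score(kernel_px, padded[, i:(i + kw - 1), drop = FALSE],
                  centred = centred), 0)
  } else {
    pad <- kh %/% 2
    padded <- pad_white(frame, pad_x = 0L, pad_y = pad)
    if (kh > nrow(padded) || kw != ncol(padded))
      pupilloc_error("kernel does not fit the padded frame",
                     "pupilloc_sizing_error")
    n_pos <- nrow(padded) - kh + 1L
    positions <- seq_len(n_pos) - 1L - pad
    scores <- vapply(seq_len(n_pos), function(i)
      match_score(kernel_px, padded[i:(i + kh - 1), , drop = FALSE],
                  centred = centred), 0)
  }
  list(scores = scores, positions = positions, axis = axis)
}

#' Horizontal matching pass
#'
#' Pads the eye frame horizontally with a white rim of half the kernel
#' width, then slides the (full-height) kernel along x with a 1-px stride,
#' scoring each overlap with [match_score()]. No vertical strides occur.
#'
#' @param eye an [eye_frame()] or intensity matrix.
#' @param kernel kernel already adapted via [adapt_kernel_horizontal()]
#'   (its height must equal the frame height).
#' @param config a [localiser_config()].
#' @return list with `scores`, `positions` (kernel top-left x in unpadded
#'   frame coordinates, strictly increasing) and `axis = "x"`.
#' @export
horizontal_pass <- function(eye, kernel, config = localiser_config()) {
  px <- if (inherits(eye, "eye_frame")) eye$pixels else eye
  slide_scores(px, kernel$pixels, axis = "x", centred = config$centred)
}

#' Vertical matching pass
#'
#' The vertical analogue of [horizontal_pass()], run within the iris
#' rectangle: pads vertically by half the kernel height and slides along y
#' with a 1-px stride.
#'
#' @param iris iris-rectangle intensity matrix from [iris_rectangle()].
#' @param kernel kernel adapted via [adapt_kernel_vertical()] (its width
#'   must equal the rectangle width).
#' @param config a [localiser_config()].
#' @return list with `scores`, `positions` (kernel top-left y) and
#'   `axis = "y"`.
#' @export
vertical_pass <- function(iris, kernel, config = localiser_config()) {
  slide_scores(iris, kernel$pixels, axis = "y", centred = config$centred)
}

#' Select candidate positions above the dynamic threshold
#'
#' The threshold is the `quantile`-th percentile (linear interpolation
#' between order statistics) of the pass's score vector; candidates are the
#' positions scoring strictly above it. If no score exceeds the threshold
#' (all ties), the fallback is every position attaining the maximum score,
#' so the set is never empty.
#'
#' @param match a pass result (`scores` + `positions`).
#' @param quantile percentile in (0, 100), default 90.
#' @return list with `coordinates` (candidate positions), `m_or_n` (count)
#'   and the `threshold` used.
#' @export
select_candidates <- function(match, quantile = 90) {
  stopifnot(length(match$scores) >= 1,
            length(match$scores) == length(match$positions))
  thr <- stats::quantile(match$scores, quantile / 100, names = FALSE,
                         type = 7)
  keep <- match$scores > thr
  if (!any(keep)) keep <- match$scores == max(match$scores)
  list(coordinates = match$positions[keep], m_or_n = sum(keep),
       threshold = thr)
}

#' Aggregate candidate coordinates into a rectangle corner
#'
#' The matched rectangle's top-left coordinate along the pass axis is the
#' arithmetic mean of the candidate coordinates, rounded half-to-even to an
#' integer pixel.
#'
#' @param candidates result of [select_candidates()].
#' @return integer coordinate (`R_x` for the horizontal pass, `R_y` for the
#'   vertical).
#' @export
aggregate_position <- function(candidates) {
  if (length(candidates$coordinates) == 0)
    pupilloc_error("candidate set is empty", "pupilloc_localisation_error")
  as.integer(round(mean(candidates$coordinates)))
}

#' Extract the iris rectangle selected by the horizontal pass
#'
#' The iris rectangle is the vertical strip of kernel width starting at
#' column `R_x`, over the full eye-frame height, clipped to the frame
#' bounds (rim matches can place `R_x` outside the frame).
#'
#' @param R_x top-left x from the horizontal pass.
#' @param eye an [eye_frame()] or intensity matrix.
#' @param kernel the horizontal-pass kernel (provides the width).
#' @return list with `pixels` (the strip), `x0` (first column kept) and
#'   `R_x`.
#' @export
iris_rectangle <- function(R_x, eye, kernel) {
  px <- if (inherits(eye, "eye_frame")) eye$pixels else eye
  wk <- ncol(kernel$pixels)
  x0 <- max(0L, R_x)
  x1 <- min(ncol(px) - 1L, R_x + wk - 1L)
  if (x1 < x0)
    pupilloc_error("iris rectangle lies fully outside the eye frame",
                   "pupilloc_localisation_error")
  list(pixels = px[, (x0 + 1):(x1 + 1), drop = FALSE], x0 = x0, R_x = R_x)
}

#' Pupil centre from the matched rectangle
#'
#' `C_x = R_x + floor(w_k / 2)`, `C_y = R_y + floor(h_k / 2)` where `h_k`
#' is the vertical-pass kernel height, clamped to the eye-frame bounds.
#'
#' @param R_x,R_y rectangle top-left coordinates from the two passes.
#' @param w_k horizontal-pass kernel width.
#' @param h_k_vertical vertical-pass kernel height.
#' @param frame_width,frame_height eye-frame bounds for clamping.
#' @return integer `c(C_x, C_y)` in eye-frame coordinates.
#' @export
centre_from_rect <- function(R_x, R_y, w_k, h_k_vertical,
                             frame_width = Inf, frame_height = Inf) {
  cx <- R_x + w_k %/% 2
  cy <- R_y + h_k_vertical %/% 2
  c(clamp(cx, 0, frame_width - 1), clamp(cy, 0, frame_height - 1))
}

#' Locate the pupil centre within an eye frame
#'
#' Runs the full coarse-to-fine cascade: greyscale conversion, horizontal
#' kernel adaptation and matching pass, dynamic-threshold candidate
#' selection and aggregation to `R_x`, iris-rectangle extraction, vertical
#' kernel adaptation and matching pass to `R_y`, and the centre
#' computation. Deterministic for fixed inputs and config.
#'
#' @param eye an [eye_frame()] or greyscale matrix (a 3-channel array is
#'   converted).
#' @param kernel an iris kernel; defaults to the analytic dark disc.
#' @param config a [localiser_config()].
#' @return a `pupil_estimate`: `iris_rect` (`c(R_x, R_y, w_k, h_k)`),
#'   `centre` (`c(C_x, C_y)` in eye-frame pixels), `centre_parent` (parent
#'   image pixels) and `side`.
#' @export
locate_pupil <- function(eye, kernel = default_disc_kernel(),
                         config = localiser_config()) {
  if (!inherits(eye, "eye_frame")) {
    eye <- eye_frame(to_greyscale(eye))
  }
  px <- eye$pixels
  if (stats::var(as.vector(px)) == 0)
    pupilloc_error("degenerate eye frame: constant intensities",
                   "pupilloc_localisation_error")
  kh <- adapt_kernel_horizontal(kernel, eye, config$width_fraction)
  hp <- horizontal_pass(eye, kh, config)
  R_x <- aggregate_position(select_candidates(hp, config$quantile))
  iris <- iris_rectangle(R_x, eye, kh)
  kv <- adapt_kernel_vertical(kh, iris$pixels, config$height_fraction)
  vp <- vertical_pass(iris$pixels, kv, config)
  R_y <- aggregate_position(select_candidates(vp, config$quantile))
  centre <- centre_from_rect(R_x, R_y, ncol(kh$pixels), nrow(kv$pixels),
                             frame_width = ncol(px), frame_height = nrow(px))
  structure(list(
    iris_rect = c(R_x = R_x, R_y = R_y, w_k = ncol(kh$pixels),
                  h_k = nrow(kv$pixels)),
    centre = centre,
    centre_parent = to_parent_coords(eye, centre),
    side = eye$side
  ), class = "pupil_estimate")
}

#' @export
print.pupil_estimate <- function(x, ...) {
  cat(sprintf("<pupil_estimate %s: centre (%d, %d), parent (%d, %d)>\n",
              x$side, x$centre[1], x$centre[2],
              x$centre_parent[1], x$centre_parent[2]))
  invisible(x)
}
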
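# eye-region extraction: frame validity gate, landmark-based cropping,
# greyscale conversion

#' Construct an eye frame
#'
#' An eye frame is the cropped sub-image containing one eye, carrying the
#' offset of its top-left corner in the parent image so estimates can be
#' mapped back to parent-image coordinates.
#'
#' @param pixels greyscale intensity matrix (rows = y, columns = x).
#' @param offset integer vector `c(x, y)`, 0-based position of the frame's
#'   top-left pixel in the parent image.
#' @param side `"left"` or `"right"`. Sides are named by image position;
#'   note that in a photograph the image-left eye is the subject's
#'   anatomical right eye.
#' @return an object of class `eye_frame`.
#' @export
eye_frame <- function(pixels, offset = c(0L, 0L), side = "left") {
  if (!is_intensity_matrix(pixels))
    pupilloc_error("eye frame pixels must be a non-empty finite numeric matrix",
                   "pupilloc_validation_error")
  side <- match.arg(side, c("left", "right"))
  structure(
    list(pixels = pixels, offset = as.integer(offset[1:2]), side = side),
    class = "eye_frame"
  )
}

#' @export
print.eye_frame <- function(x, ...) {
  cat(sprintf("<eye_frame %s: %d x %d px at offset (%d, %d)>\n",
              x$side, ncol(x$pixels), nrow(x$pixels),
              x$offset[1], x$offset[2]))
  invisible(x)
}

#' Map an eye-frame coordinate to parent-image coordinates
#'
#' @param eye an [eye_frame()].
#' @param xy numeric vector `c(x, y)` in eye-frame coordinates.
#' @return `c(x, y)` in parent-image coordinates.
#' @export
to_parent_coords <- function(eye, xy) {
  stopifnot(inherits(eye, "eye_frame"))
  c(xy[1] + eye$offset[1], xy[2] + eye$offset[2])
}

#' Frame validity gate
#'
#' A frame is processed only when the detector found exactly one face and
#' exactly two eyes within it. The score counts how many of the two checks
#' pass: +1 for exactly one face, and (only then) +1 for exactly two eyes.
#' Invalidity is a result, never an error.
#'
#' @param faces number of detected face rectangles.
#' @param eyes number of detected eye frames within the face.
#' @return list with `score` (0-2), `valid` (TRUE iff score is 2) and a
#'   human-readable `reason`.
#' @export
validate_frame <- function(faces, eyes) {
  stopifnot(length(faces) == 1, length(eyes) == 1, faces >= 0, eyes >= 0)
  score <- 0L
  reason <- "valid"
  if (faces == 1L) {
    score <- score + 1L
    if (eyes == 2L) {
      score <- score + 1L
    } else {
      reason <- sprintf("expected exactly 2 eyes, found %d", eyes)
    }
  } else {
    reason <- sprintf("expected exactly 1 face, found %d", faces)
  }
  list(score = score, valid = score == 2L, reason = reason)
}

#' Convert an image to greyscale
#'
#' Three-channel images are converted with fixed ITU-R BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to integer intensities;
#' single-channel input passes through unchanged.
#'
#' @param image a numeric matrix (already grey) or an h x w x 3 array with
#'   channels in R, G, B order, intensities 0-255.
#' @return greyscale intensity matrix.
#' @export
to_greyscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3) {
    g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    return(round_half_up(g))
  }
  pupilloc_error("image must have 1 or 3 channels", "pupilloc_format_error")
}

#' Crop left and right eye frames from facial landmarks
#'
#' Each eye frame is the axis-aligned bounding box of that eye's landmark
#' points (eye corners and eyelid extremes), expanded by `margin` pixels on
#' all sides and clipped to the face rectangle. Bounds are inclusive: points
#' spanning columns 10..30 give a frame 21 px wide.
#'
#' @param image greyscale matrix or 3-channel array (converted internally).
#' @param landmarks list with `face_rect = c(x, y, w, h)` and per-eye point
#'   matrices `left_eye`, `right_eye` (n x 2, columns x and y, 0-based).
#' @param margin non-negative expansion in pixels (default 0: the exact
#'   extreme-point bounding box).
#' @return list with elements `left` and `right`, each an [eye_frame()].
#' @export
crop_eye_frames <- function(image, landmarks, margin = 0L) {
  stopifnot(margin >= 0)
  img <- to_greyscale(image)
  fr <- landmarks$face_rect
  if (is.null(fr)) fr <- c(0L, 0L, ncol(img), nrow(img))
  crop_one <- function(pts, side) {
    if (is.null(pts) || nrow(pts) == 0)
      pupilloc_error(sprintf("no landmark points for %s eye", side),
                     "pupilloc_extraction_error")
    x0 <- min(pts[, 1]) - margin
    x1 <- max(pts[, 1]) + margin
    y0 <- min(pts[, 2]) - margin
    y1 <- max(pts[, 2]) + margin
    # clip to the face rectangle, then to the image
    x0 <- max(x0, fr[1], 0); y0 <- max(y0, fr[2], 0)
    x1 <- min(x1, fr[1] + fr[3] - 1, ncol(img) - 1)
    y1 <- min(y1, fr[2] + fr[4] - 1, nrow(img) - 1)
    if (x1 < x0 || y1 < y0)
      pupilloc_error(sprintf("degenerate bounding box for %s eye", side),
                     "pupilloc_extraction_error")
    eye_frame(img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE],
              offset = c(x0, y0), side = side)
  }
  list(left  = crop_one(landmarks$left_eye, "left"),
       right = crop_one(landmarks$right_eye, "right"))
}
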
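# eye-centre evaluation metrics
#
# wec / bec: the per-frame worst (max) and best (min) of the two per-eye
# centre errors, normalised by the interocular distance so the error is
# independent of image scale; wec <= 0.05 corresponds roughly to an
# estimate within the pupil diameter, <= 0.1 within the iris.
#
# S_ED: the single-eye alternative — the centre error as a percentage of
# the eye frame's diagonal, so it needs no second eye and is invariant to
# image size and resolution.

euclid <- function(a, b) sqrt(sum((a - b)^2))

check_pair <- function(truth, est) {
  stopifnot(is.list(truth), is.list(est))
  if (!all(is.finite(c(truth$C_l, truth$C_r, est$C_l, est$C_r))))
    pupilloc_error("eye centres must be finite", "pupilloc_validation_error")
  iod <- euclid(truth$C_l, truth$C_r)
  if (iod == 0)
    pupilloc_error("interocular distance is zero", "pupilloc_validation_error")
  iod
}

#' Worst eye centre error (wec)
#'
#' `max(||est_l - true_l||, ||est_r - true_r||) / ||true_l - true_r||`:
#' the larger of the two per-eye Euclidean errors, normalised by the
#' interocular distance.
#'
#' @param truth list with actual centres `C_l`, `C_r` (each `c(x, y)`).
#' @param est list with estimated centres `C_l`, `C_r`.
#' @return scalar relative error.
#' @export
wec <- function(truth, est) {
  iod <- check_pair(truth, est)
  max(euclid(est$C_l, truth$C_l), euclid(est$C_r, truth$C_r)) / iod
}

#' Best eye centre error (bec)
#'
#' The minimum of the two normalised per-eye errors; `bec <= wec` always.
#'
#' @inheritParams wec
#' @return scalar relative error.
#' @export
bec <- function(truth, est) {
  iod <- check_pair(truth, est)
  min(euclid(est$C_l, truth$C_l), euclid(est$C_r, truth$C_r)) / iod
}

#' Standardised Euclidean distance (percent of the frame diagonal)
#'
#' `100 * ||estimate - actual|| / ||(x_max, y_max) - (x_min, y_min)||`:
#' the centre error as a percentage of the maximum possible error within
#' the eye frame (its corner-to-corner diagonal). Needs only the single
#' eye frame — no second eye or interocular distance — and is invariant
#' under uniform scaling and translation of all coordinates.
#'
#' @param actual,estimate centre coordinates `c(x, y)`.
#' @param geometry list with the frame's nearest corner `x_min`, `y_min`
#'   and farthest corner `x_max`, `y_max` (requires `x_max > x_min` and
#'   `y_max > y_min`).
#' @return percentage in [0, 100].
#' @export
s_ed <- function(actual, estimate, geometry) {
  g <- geometry
  if (!(g$x_max > g$x_min && g$y_max > g$y_min))
    pupilloc_error("degenerate frame geometry", "pupilloc_validation_error")
  diag <- sqrt((g$x_max - g$x_min)^2 + (g$y_max - g$y_min)^2)
  100 * euclid(estimate, actual) / diag
}

#' Frame geometry for [s_ed()] from an eye frame
#'
#' Uses the crop produced for that same eye: nearest corner at the frame's
#' top-left pixel, farthest at its bottom-right pixel (parent coordinates).
#'
#' @param eye an [eye_frame()].
#' @return list with `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
frame_geometry <- function(eye) {
  stopifnot(inherits(eye, "eye_frame"))
  list(x_min = eye$offset[1], y_min = eye$offset[2],
       x_max = eye$offset[1] + ncol(eye$pixels) - 1,
       y_max = eye$offset[2] + nrow(eye$pixels) - 1)
}

#' Accuracy at error thresholds
#'
#' For each threshold `t`, the percentage of frames whose relative error is
#' `<= t` (inclusive). The resulting curve is non-decreasing in `t`.
#'
#' @param errors non-empty numeric vector of per-frame relative errors
#'   (wec or bec values).
#' @param thresholds numeric vector of thresholds (default 0.01-0.25 in
#'   steps of 0.01).
#' @return data.frame with columns `threshold` and `accuracy` (percent).
#' @export
accuracy_at_thresholds <- function(errors, thresholds = seq(0.01, 0.25, 0.01)) {
  stopifnot(length(errors) >= 1)
  acc <- vapply(thresholds,
                function(t) 100 * mean(errors <= t), 0)
  data.frame(threshold = thresholds, accuracy = acc)
}

#' Per-axis mean absolute error and R-squared
#'
#' `MAE = mean |a_i - e_i|`; `R2 = 1 - SS_res / SS_tot` with
#' `SS_res = sum (a_i - e_i)^2` and `SS_tot = sum (a_i - mean(a))^2`, i.e.
#' the estimates scored directly against the actual series. A
#' zero-variance actual series leaves R-squared undefined (`NA`).
#'
#' @param actual,estimated equal-length numeric series, `n >= 2`.
#' @return list with `mae` and `r_squared`.
#' @export
regression_fit_stats <- function(actual, estimated) {
  stopifnot(length(actual) == length(estimated), length(actual) >= 2)
  mae <- mean(abs(actual - estimated))
  ss_tot <- sum((actual - mean(actual))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((actual - estimated)^2) / ss_tot
  list(mae = mae, r_squared = r2)
}

#' Evaluate detections against annotations
#'
#' Joins per-image detections with ground-truth annotations on the image
#' identifier and computes the full report: per-frame wec/bec, per-eye
#' S_ED when frame geometry is supplied, wec/bec accuracy at thresholds,
#' and Table-style per-axis aggregates (MAE and R-squared per axis,
#' pooling both eyes, plus mean Euclidean distance and mean S_ED).
#'
#' @param detections data.frame with columns `image`, `left_x`, `left_y`,
#'   `right_x`, `right_y` (invalid frames, with NA coordinates, are
#'   dropped with a message).
#' @param annotations data.frame in the same generic layout with actual
#'   centres.
#' @param geometries optional named list (by image) of [s_ed()] geometry
#'   lists; when NULL, S_ED values are omitted.
#' @param thresholds accuracy thresholds (default 0.01-0.25 step 0.01).
#' @return an `eval_report` list: `per_frame` data.frame, `curve`
#'   data.frame (wec and bec accuracy per threshold), and `aggregates`.
#' @export
evaluate_detections <- function(detections, annotations, geometries = NULL,
                                thresholds = seq(0.01, 0.25, 0.01)) {
  need <- c("image", "left_x", "left_y", "right_x", "right_y")
  stopifnot(all(need %in% names(detections)), all(need %in% names(annotations)))
  missing_ids <- setdiff(detections$image, annotations$image)
  if (length(missing_ids) > 0)
    pupilloc_error(
      sprintf("detections without annotations: %s",
              paste(utils::head(missing_ids, 3), collapse = ", ")),
      "pupilloc_validation_error")
  det <- detections[stats::complete.cases(detections[, need]), , drop = FALSE]
  if (nrow(det) < nrow(detections))
    message(nrow(detections) - nrow(det), " invalid frame(s) dropped")
  ann <- annotations[match(det$image, annotations$image), ]
  per <- data.frame(image = det$image, wec = NA_real_, bec = NA_real_,
                    s_ed_left = NA_real_, s_ed_right = NA_real_)
  for (i in seq_len(nrow(det))) {
    truth <- list(C_l = c(ann$left_x[i], ann$left_y[i]),
                  C_r = c(ann$right_x[i], ann$right_y[i]))
    est <- list(C_l = c(det$left_x[i], det$left_y[i]),
                C_r = c(det$right_x[i], det$right_y[i]))
    per$wec[i] <- wec(truth, est)
    per$bec[i] <- bec(truth, est)
    g <- geometries[[det$image[i]]]
    if (!is.null(g)) {
      per$s_ed_left[i] <- s_ed(truth$C_l, est$C_l, g$left)
      per$s_ed_right[i] <- s_ed(truth$C_r, est$C_r, g$right)
    }
  }
  curve <- accuracy_at_thresholds(per$wec, thresholds)
  names(curve)[2] <- "wec_accuracy"
  curve$bec_accuracy <- accuracy_at_thresholds(per$bec, thresholds)$accuracy
  # per-axis stats pool both eyes
  ax <- regression_fit_stats(c(ann$left_x, ann$right_x),
                             c(det$left_x, det$right_x))
  ay <- regression_fit_stats(c(ann$left_y, ann$right_y),
                             c(det$left_y, det$right_y))
  ed <- (vapply(seq_len(nrow(det)), function(i)
    euclid(c(det$left_x[i], det$left_y[i]),
           c(ann$left_x[i], ann$left_y[i])), 0) +
    vapply(seq_len(nrow(det)), function(i)
      euclid(c(det$right_x[i], det$right_y[i]),
             c(ann$right_x[i], ann$right_y[i])), 0)) / 2
  aggregates <- list(
    n_frames = nrow(per),
    mae_x = ax$mae, mae_y = ay$mae,
    r_squared_x = ax$r_squared, r_squared_y = ay$r_squared,
    mean_ed = mean(ed),
    mean_s_ed = if (is.null(geometries)) NA_real_ else
      mean(c(per$s_ed_left, per$s_ed_right)),
    pooling = "per-axis stats pool both eyes; wec/bec are per frame"
  )
  structure(list(per_frame = per, curve = curve, aggregates = aggregates),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$aggregates
  w05 <- x$curve$wec_accuracy[abs(x$curve$threshold - 0.05) < 1e-9]
  cat(sprintf(
    "<eval_report: %d frames | wec<=0.05: %s%% | MAE x %.2f y %.2f px | mean ED %.2f px>\n",
    a$n_frames,
    if (length(w05)) sprintf("%.2f", w05) else "-",
    a$mae_x, a$mae_y, a$mean_ed))
  invisible(x)
}
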
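# synthetic eye-frame renderer with exact ground truth
#
# Emulates the regime the localiser targets: a dark, approximately circular
# iris with a darker concentric pupil on a lighter sclera, at eye-frame
# resolutions of roughly 24-80 px width, with variable gaze (including
# extreme left/right where the disc is clipped by the frame edge), optional
# eyelid occlusion from the top, an additive illumination gradient, and
# Gaussian sensor noise clipped to [0, 255].

#' Specify a synthetic eye frame
#'
#' Discs are rasterised by centre-of-pixel inclusion: a pixel belongs to a
#' disc iff its centre lies within the radius. Rendering order is sclera
#' background, iris disc, pupil disc, eyelid band, horizontal gradient, then
#' Gaussian noise clipped to [0, 255] (noise is applied last and clipped,
#' mimicking sensor saturation).
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param iris_radius,pupil_radius disc radii in pixels; the pupil must not
#'   exceed the iris.
#' @param centre_x,centre_y true pupil centre (0-based pixels); must lie
#'   inside the frame, though the iris disc may be clipped at the edges
#'   (extreme gaze).
#' @param sclera_intensity,iris_intensity,pupil_intensity intensities 0-255;
#'   the pupil is the darkest region: `pupil <= iris < sclera`.
#' @param eyelid_occlusion fraction in [0, 1] of the iris height covered by
#'   an eyelid band from the top of the frame (painted at sclera intensity).
#' @param gradient_amplitude additive horizontal linear ramp, 0 at the left
#'   edge up to this many intensity units at the right edge.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed for the noise.
#' @return a validated `synthetic_eye_spec` list.
#' @export
synthetic_eye_spec <- function(frame_width = 60L, frame_height = 24L,
                               iris_radius = 8, pupil_radius = 3,
                               centre_x = 30, centre_y = 12,
                               sclera_intensity = 200, iris_intensity = 80,
                               pupil_intensity = 20,
                               eyelid_occlusion = 0, gradient_amplitude = 0,
                               noise_sigma = 0, seed = 1L) {
  spec <- list(frame_width = as.integer(frame_width),
               frame_height = as.integer(frame_height),
               iris_radius = iris_radius, pupil_radius = pupil_radius,
               centre_x = centre_x, centre_y = centre_y,
               sclera_intensity = sclera_intensity,
               iris_intensity = iris_intensity,
               pupil_intensity = pupil_intensity,
               eyelid_occlusion = eyelid_occlusion,
               gradient_amplitude = gradient_amplitude,
               noise_sigma = noise_sigma, seed = as.integer(seed))
  validate_eye_spec(spec)
  structure(spec, class = "synthetic_eye_spec")
}

validate_eye_spec <- function(s) {
  ok <- function(cond, msg)
    if (!cond) pupilloc_error(msg, "pupilloc_validation_error")
  ok(s$frame_width >= 1 && s$frame_height >= 1, "frame must be non-empty")
  ok(s$pupil_radius <= s$iris_radius, "pupil radius must not exceed iris radius")
  ok(s$pupil_intensity <= s$iris_intensity,
     "pupil must be at least as dark as the iris")
  ok(s$iris_intensity < s$sclera_intensity,
     "iris must be darker than the sclera")
  ok(s$centre_x >= 0 && s$centre_x <= s$frame_width - 1 &&
       s$centre_y >= 0 && s$centre_y <= s$frame_height - 1,
     "centre must lie inside the frame")
  ok(s$eyelid_occlusion >= 0 && s$eyelid_occlusion <= 1,
     "eyelid_occlusion must be in [0, 1]")
  ok(s$noise_sigma >= 0, "noise_sigma must be non-negative")
  invisible(s)
}

#' Render a synthetic eye frame
#'
#' Deterministic for a fixed spec (the seed lives in the spec): rendering
#' the same spec twice gives bit-identical images.
#'
#' @param spec a [synthetic_eye_spec()].
#' @return list with `image` (intensity matrix), `truth_centre` (`c(x, y)`,
#'   equal to the spec centre exactly) and `spec`.
#' @export
render_eye <- function(spec) {
  validate_eye_spec(spec)
  w <- spec$frame_width; h <- spec$frame_height
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)   # x of each pixel centre
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)  # y of each pixel centre
  d2 <- (xs - spec$centre_x)^2 + (ys - spec$centre_y)^2
  img <- matrix(spec$sclera_intensity, nrow = h, ncol = w)
  img[d2 <= spec$iris_radius^2] <- spec$iris_intensity
  img[d2 <= spec$pupil_radius^2] <- spec$pupil_intensity
  if (spec$eyelid_occlusion > 0) {
    # band from the frame top down to iris_top + occlusion * iris height
    iris_top <- spec$centre_y - spec$iris_radius
    lid_to <- iris_top + spec$eyelid_occlusion * 2 * spec$iris_radius
    img[ys <= lid_to] <- spec$sclera_intensity
  }
  if (spec$gradient_amplitude != 0 && w > 1)
    img <- img + spec$gradient_amplitude * xs / (w - 1)
  if (spec$noise_sigma > 0) {
    img <- withr::with_seed(spec$seed,
                            img + stats::rnorm(length(img), 0, spec$noise_sigma))
  }
  img <- clamp(img, 0, 255)
  list(image = img, truth_centre = c(spec$centre_x, spec$centre_y),
       spec = spec)
}

#' Render a mock face with 0, 1 or 2 eye regions
#'
#' Builds a larger skin-toned frame containing `n_eyes` rendered eye regions
#' at known offsets, together with the facial-landmark structure
#' ([crop_eye_frames()] input) and exact truth centres, so the validity gate
#' and the full detection pipeline can be exercised end to end. The face
#' count is 1 whenever at least one eye is present.
#'
#' @param n_eyes 0, 1 or 2.
#' @param seed integer seed controlling eye geometry and noise.
#' @param noise_sigma per-eye Gaussian noise level (default 0).
#' @return list with `image`, `landmarks`, `truth` (data.frame of side/x/y
#'   in parent coordinates), `n_faces` and `n_eyes`.
#' @export
render_face_mock <- function(n_eyes = 2L, seed = 1L, noise_sigma = 0) {
  stopifnot(n_eyes %in% 0:2)
  W <- 220L; H <- 140L
  img <- matrix(185, nrow = H, ncol = W)
  # head position varies from frame to frame: both eye regions share a
  # rigid per-face translation, keeping the interocular distance fixed
  jitter <- withr::with_seed(seed + 7919L,
                             round(stats::runif(2, -15, 15)))
  offsets <- list(left = c(30L + jitter[1], 55L + jitter[2]),
                  right = c(130L + jitter[1], 55L + jitter[2]))
  sides <- c("left", "right")[seq_len(n_eyes)]
  truth <- data.frame(side = character(0), x = numeric(0), y = numeric(0))
  landmarks <- list(face_rect = c(10L, 20L, 200L, 110L))
  ew <- 60L; eh <- 24L
  for (i in seq_along(sides)) {
    side <- sides[i]
    # iris radius follows the generator's default range (0.12-0.22 x width);
    # gaze spans the visible range for that radius, vertically near-centred
    par <- withr::with_seed(seed + i, {
      r <- round(stats::runif(1, 0.12 * ew, 0.22 * ew))
      list(r = r,
           cx = round(stats::runif(1, r, ew - 1 - r)),
           cy = round(stats::runif(1, 10, 13)))
    })
    spec <- synthetic_eye_spec(
      frame_width = ew, frame_height = eh,
      iris_radius = par$r, pupil_radius = max(1, round(0.4 * par$r)),
      centre_x = par$cx, centre_y = par$cy,
      noise_sigma = noise_sigma, seed = seed + 100L + i
    )
    eye <- render_eye(spec)
    off <- offsets[[side]]
    img[(off[2] + 1):(off[2] + eh), (off[1] + 1):(off[1] + ew)] <- eye$image
    # 6-point outline in the 68-point style: two corners, two upper-lid and
    # two lower-lid points spanning the region extremes
    pts <- rbind(c(off[1], off[2] + eh %/% 2),
                 c(off[1] + ew - 1, off[2] + eh %/% 2),
                 c(off[1] + ew %/% 3, off[2]),
                 c(off[1] + 2 * ew %/% 3, off[2]),
                 c(off[1] + ew %/% 3, off[2] + eh - 1),
                 c(off[1] + 2 * ew %/% 3, off[2] + eh - 1))
    landmarks[[paste0(side, "_eye")]] <- pts
    truth <- rbind(truth, data.frame(
      side = side, x = off[1] + par$cx, y = off[2] + par$cy))
  }
  list(image = img, landmarks = landmarks, truth = truth,
       n_faces = if (n_eyes >= 1) 1L else 0L, n_eyes = n_eyes)
}

#' Default sampling distribution for synthetic eye specs
#'
#' Spans the low-resolution regime the method targets: frame width uniform
#' on 24-80 px at a 2.5:1 aspect ratio, iris radius 0.12-0.22 of the frame
#' width, gaze offset uniform over the visible span (so extreme left/right
#' positions occur), pupil radius 0.4 of the iris radius, noise sigma
#' uniform 0-10 and gradient amplitude uniform 0-20 intensity units.
#'
#' @return a list of sampling ranges understood by [generate_dataset()].
#' @export
default_spec_distribution <- function() {
  list(frame_width = c(24, 80), aspect_ratio = 2.5,
       iris_radius_frac = c(0.12, 0.22), pupil_radius_frac = 0.4,
       centre_y_frac = c(0.35, 0.65),
       sclera = c(150, 230), iris = c(40, 100), pupil = c(0, 35),
       eyelid_occlusion = c(0, 0), gradient = c(0, 20), noise = c(0, 10))
}

sample_spec <- function(dist, seed) {
  withr::with_seed(seed, {
    w <- round(stats::runif(1, dist$frame_width[1], dist$frame_width[2]))
    h <- max(8, round(w / dist$aspect_ratio))
    r <- stats::runif(1, dist$iris_radius_frac[1], dist$iris_radius_frac[2]) * w
    pr <- max(1, dist$pupil_radius_frac * r)
    cx <- round(stats::runif(1, r, w - 1 - r))
    cy <- round(stats::runif(1, dist$centre_y_frac[1] * (h - 1),
                             dist$centre_y_frac[2] * (h - 1)))
    sc <- stats::runif(1, dist$sclera[1], dist$sclera[2])
    ir <- stats::runif(1, dist$iris[1], dist$iris[2])
    pu <- stats::runif(1, dist$pupil[1], min(dist$pupil[2], ir))
    synthetic_eye_spec(
      frame_width = w, frame_height = h,
      iris_radius = round(r), pupil_radius = round(pr),
      centre_x = cx, centre_y = cy,
      sclera_intensity = round(sc), iris_intensity = round(ir),
      pupil_intensity = round(pu),
      eyelid_occlusion = stats::runif(1, dist$eyelid_occlusion[1],
                                      dist$eyelid_occlusion[2]),
      gradient_amplitude = stats::runif(1, dist$gradient[1], dist$gradient[2]),
      noise_sigma = stats::runif(1, dist$noise[1], dist$noise[2]),
      seed = seed
    )
  })
}

#' Generate a dataset of synthetic eye frames
#'
#' Samples `n` specs with independently perturbed gaze, size, intensity and
#' noise parameters, renders each, and (optionally) writes the images plus a
#' generic-CSV annotation file recording the exact truth centres. Runs with
#' the same `n` and `seed` produce identical datasets and annotation files.
#'
#' Single-eye frames carry one centre; the generic CSV dialect has left and
#' right slots, so the centre is recorded in both.
#'
#' @param n number of samples (>= 1).
#' @param spec_distribution sampling ranges, see [default_spec_distribution()].
#' @param seed integer master seed; sample i uses `seed * 10000 + i`.
#' @param out_dir if non-NULL, write `eye_*.pgm` images and `annotations.csv`
#'   there.
#' @return invisible list of rendered samples (each as from [render_eye()]).
#' @export
generate_dataset <- function(n, spec_distribution = default_spec_distribution(),
                             seed = 1L, out_dir = NULL) {
  stopifnot(n >= 1)
  samples <- lapply(seq_len(n), function(i)
    render_eye(sample_spec(spec_distribution, seed = seed * 10000L + i)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ids <- sprintf("eye_%04d.pgm", seq_len(n))
    for (i in seq_len(n))
      write_pgm(samples[[i]]$image, file.path(out_dir, ids[i]))
    ann <- data.frame(
      image = ids,
      left_x = vapply(samples, function(s) s$truth_centre[1], 0),
      left_y = vapply(samples, function(s) s$truth_centre[2], 0),
      right_x = vapply(samples, function(s) s$truth_centre[1], 0),
      right_y = vapply(samples, function(s) s$truth_centre[2], 0)
    )
    write_annotations(ann, file.path(out_dir, "annotations.csv"))
  }
  invisible(samples)
}
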
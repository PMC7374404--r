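test_that("noiseless renders place exact intensities and are deterministic", {
  spec <- synthetic_eye_spec(frame_width = 60, frame_height = 24,
                             iris_radius = 8, pupil_radius = 3,
                             centre_x = 30, centre_y = 12, seed = 7)
  s1 <- render_eye(spec)
  expect_identical(s1$truth_centre, c(30, 12))
  expect_equal(s1$image[13, 31], spec$pupil_intensity)   # pixel at (30, 12)
  expect_equal(s1$image[13, 31 + 8], spec$iris_intensity)
  expect_equal(s1$image[1, 1], spec$sclera_intensity)
  # pupil pixel is the global minimum without noise or gradient
  expect_equal(min(s1$image), spec$pupil_intensity)
  # bit-identical re-render, including with noise
  noisy <- synthetic_eye_spec(noise_sigma = 6, seed = 7)
  expect_identical(render_eye(noisy)$image, render_eye(noisy)$image)
})

test_that("full eyelid occlusion hides every iris and pupil pixel", {
  spec <- synthetic_eye_spec(eyelid_occlusion = 1)
  img <- render_eye(spec)$image
  expect_false(any(img == spec$iris_intensity))
  expect_false(any(img == spec$pupil_intensity))
})

test_that("disc rasterisation uses centre-of-pixel inclusion", {
  spec <- synthetic_eye_spec(frame_width = 21, frame_height = 21,
                             iris_radius = 5, pupil_radius = 0,
                             centre_x = 10, centre_y = 10,
                             pupil_intensity = 80)  # pupil invisible
  img <- render_eye(spec)$image
  # pixel exactly at distance 5 is inside (<=), at sqrt(26) outside
  expect_equal(img[11, 16], spec$iris_intensity)  # (15, 10), d = 5
  expect_equal(img[12, 16], spec$sclera_intensity)  # (15, 11), d = sqrt(26)
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_eye_spec(pupil_intensity = 90, iris_intensity = 80),
               class = "pupilloc_validation_error")
  expect_error(synthetic_eye_spec(iris_intensity = 210,
                                  sclera_intensity = 200),
               class = "pupilloc_validation_error")
  expect_error(synthetic_eye_spec(centre_x = 60),
               class = "pupilloc_validation_error")
  expect_error(synthetic_eye_spec(pupil_radius = 9, iris_radius = 8),
               class = "pupilloc_validation_error")
})

test_that("mock faces feed the validity gate and round-trip annotations", {
  m2 <- render_face_mock(2, seed = 3)
  expect_true(validate_frame(m2$n_faces, m2$n_eyes)$valid)
  m1 <- render_face_mock(1, seed = 3)
  expect_false(validate_frame(m1$n_faces, m1$n_eyes)$valid)
  m0 <- render_face_mock(0, seed = 3)
  expect_equal(validate_frame(m0$n_faces, m0$n_eyes)$score, 0)

  # truth centres round-trip through the annotation writer/reader
  ann <- data.frame(image = "mock",
                    left_x = m2$truth$x[1], left_y = m2$truth$y[1],
                    right_x = m2$truth$x[2], right_y = m2$truth$y[2])
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back[, names(ann)], ann)
})

test_that("generated datasets are deterministic and satisfy spec invariants", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(10, seed = 1, out_dir = d1)
  generate_dataset(10, seed = 1, out_dir = d2)
  expect_identical(readLines(file.path(d1, "annotations.csv")),
                   readLines(file.path(d2, "annotations.csv")))
  expect_identical(readLines(file.path(d1, "eye_0003.pgm")),
                   readLines(file.path(d2, "eye_0003.pgm")))

  samples <- generate_dataset(200, seed = 4)
  for (s in samples) {
    sp <- s$spec
    expect_true(sp$pupil_intensity <= sp$iris_intensity)
    expect_true(sp$iris_intensity < sp$sclera_intensity)
    expect_true(sp$pupil_radius <= sp$iris_radius)
    expect_true(sp$centre_x >= 0 && sp$centre_x <= sp$frame_width - 1)
    expect_true(sp$centre_y >= 0 && sp$centre_y <= sp$frame_height - 1)
    expect_true(all(s$image >= 0 & s$image <= 255))
  }
})

test_that("sampled parameters match the requested distribution moments", {
  dist <- default_spec_distribution()
  samples <- generate_dataset(200, dist, seed = 11)
  widths <- vapply(samples, function(s) s$spec$frame_width, 0)
  # frame width ~ U(24, 80): mean 52, sd 56/sqrt(12)
  se <- 56 / sqrt(12) / sqrt(length(widths))
  expect_lt(abs(mean(widths) - 52), 3 * se)
  # gaze offset (relative position of centre in the visible span) ~ U(0, 1)
  rel <- vapply(samples, function(s) {
    sp <- s$spec
    (sp$centre_x - sp$iris_radius) /
      (sp$frame_width - 1 - 2 * sp$iris_radius)
  }, 0)
  expect_lt(abs(mean(rel) - 0.5), 3 * sqrt(1 / 12) / sqrt(length(rel)))
  # noise sigma ~ U(0, 10)
  ns <- vapply(samples, function(s) s$spec$noise_sigma, 0)
  expect_lt(abs(mean(ns) - 5), 3 * (10 / sqrt(12)) / sqrt(length(ns)))
})
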
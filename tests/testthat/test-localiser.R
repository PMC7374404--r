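test_that("white padding adds a 255 rim and keeps the interior intact", {
  f <- matrix(c(1, 2, 3, 4), 2, 2)
  p <- pad_white(f, 1, 1)
  expect_equal(dim(p), c(4, 4))
  expect_equal(p[2:3, 2:3], f)
  expect_true(all(p[c(1, 4), ] == 255) && all(p[, c(1, 4)] == 255))
  expect_identical(pad_white(f, 0, 0), f)
  expect_gte(mean(pad_white(f, 3, 2)), mean(f))
})

test_that("match score is the mean-centred normalised correlation", {
  k <- default_disc_kernel(9, 9)
  expect_equal(match_score(k, k$pixels), 1.0)
  # positive affine rescaling of the patch leaves the score at 1
  expect_equal(match_score(k, 0.5 * k$pixels + 40), 1.0)
  # hand-evaluated small case
  expect_equal(match_score(matrix(c(1, 0, 0, 1), 2, 2),
                           matrix(c(1, 0, 0, 0), 2, 2)),
               0.5774, tolerance = 1e-4)
  # degenerate inputs score 0, never crash
  expect_equal(match_score(k, matrix(7, 9, 9)), 0)
  expect_error(match_score(k, matrix(0, 3, 3)),
               class = "pupilloc_sizing_error")
})

test_that("match score agrees with the double-loop oracle on random inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    h <- sample(2:9, 1); w <- sample(2:9, 1)
    k <- matrix(runif(h * w, 0, 255), h, w)
    p <- matrix(runif(h * w, 0, 255), h, w)
    expect_equal(match_score(k, p), oracle_ncc(k, p), tolerance = 1e-12)
    expect_equal(match_score(k, p, centred = FALSE),
                 oracle_ncc(k, p, centred = FALSE), tolerance = 1e-12)
    expect_true(abs(match_score(k, p)) <= 1)
  }
})

test_that("both passes reproduce the literal stride-by-stride oracle", {
  for (seed in 1:6) {
    spec <- random_eye_spec(seed)
    img <- render_eye(spec)$image
    kh <- adapt_kernel_horizontal(default_disc_kernel(), img)
    hp <- horizontal_pass(img, kh)
    oh <- oracle_pass(img, kh$pixels, "x")
    expect_equal(hp$positions, oh$positions)
    expect_lt(max(abs(hp$scores - oh$scores)), 1e-6)
    expect_true(all(abs(hp$scores) <= 1))
    expect_true(all(diff(hp$positions) > 0))

    R_x <- aggregate_position(select_candidates(hp))
    iris <- iris_rectangle(R_x, img, kh)
    kv <- adapt_kernel_vertical(kh, iris$pixels)
    vp <- vertical_pass(iris$pixels, kv)
    ov <- oracle_pass(iris$pixels, kv$pixels, "y")
    expect_lt(max(abs(vp$scores - ov$scores)), 1e-6)
  }
})

test_that("a noiseless disc is found by the horizontal pass argmax", {
  spec <- synthetic_eye_spec(frame_width = 60, frame_height = 24,
                             iris_radius = 8, pupil_radius = 3,
                             centre_x = 30, centre_y = 12)
  img <- render_eye(spec)$image
  kh <- adapt_kernel_horizontal(default_disc_kernel(), img)
  hp <- horizontal_pass(img, kh)
  best <- hp$positions[which.max(hp$scores)]
  expect_lte(abs(best - (30 - ncol(kh$pixels) / 2)), 1)

  iris <- iris_rectangle(30 - ncol(kh$pixels) %/% 2, img, kh)
  kv <- adapt_kernel_vertical(kh, iris$pixels)
  vp <- vertical_pass(iris$pixels, kv)
  expect_lte(abs(vp$positions[which.max(vp$scores)] -
                   (12 - nrow(kv$pixels) / 2)), 1)
})

test_that("uniform frames give all-zero scores via the degenerate rule", {
  kh <- adapt_kernel_horizontal(default_disc_kernel(), matrix(255, 20, 50))
  expect_true(all(horizontal_pass(matrix(255, 20, 50), kh)$scores == 0))
})

test_that("candidate selection uses interpolated percentiles with > and a tie fallback", {
  ms <- list(scores = 1:10, positions = 0:9)
  sel <- select_candidates(ms, 90)
  expect_equal(sel$threshold, 9.1)  # linear-interpolation percentile
  expect_equal(sel$coordinates, 9)
  expect_equal(sel$m_or_n, 1)

  ms2 <- list(scores = 0:99, positions = 0:99)
  expect_equal(select_candidates(ms2, 90)$coordinates, 90:99)

  ties <- list(scores = rep(0.5, 8), positions = 0:7)
  fall <- select_candidates(ties, 90)
  expect_equal(fall$coordinates, 0:7)
  expect_equal(fall$m_or_n, 8)
})

test_that("aggregation takes the ties-to-even rounded mean", {
  expect_equal(aggregate_position(list(coordinates = c(10, 12, 14))), 12L)
  expect_equal(aggregate_position(list(coordinates = 7)), 7L)
  expect_equal(aggregate_position(list(coordinates = c(10, 11))), 10L)
  expect_equal(aggregate_position(list(coordinates = c(11, 12))), 12L)
  expect_error(aggregate_position(list(coordinates = numeric(0))),
               class = "pupilloc_localisation_error")
})

test_that("the iris rectangle is the kernel-width strip clipped to the frame", {
  img <- matrix(runif(60 * 24, 0, 255), 24, 60)
  k <- adapt_kernel_horizontal(default_disc_kernel(), img)  # 24 wide
  strip <- iris_rectangle(10, img, k)
  expect_equal(strip$x0, 10)
  expect_equal(dim(strip$pixels), c(24, ncol(k$pixels)))
  clipped <- iris_rectangle(-3, img, k)
  expect_equal(clipped$x0, 0)
  expect_equal(ncol(clipped$pixels), ncol(k$pixels) - 3)
  expect_equal(nrow(clipped$pixels), nrow(img))  # always full height
  expect_error(iris_rectangle(-100, img, k),
               class = "pupilloc_localisation_error")
})

test_that("centre computation floors the half-sizes and clamps to the frame", {
  expect_equal(centre_from_rect(10, 5, 20, 8), c(20, 9))
  expect_equal(centre_from_rect(3, 4, 1, 1), c(3, 4))
  expect_equal(centre_from_rect(58, 22, 20, 8, frame_width = 60,
                                frame_height = 24), c(59, 23))
})

test_that("locate_pupil recovers noiseless and extreme-gaze centres", {
  spec <- synthetic_eye_spec(frame_width = 60, frame_height = 24,
                             iris_radius = 8, pupil_radius = 3,
                             centre_x = 30, centre_y = 12)
  est <- locate_pupil(eye_frame(render_eye(spec)$image))
  expect_lte(sqrt(sum((est$centre - c(30, 12))^2)), 1)

  left <- synthetic_eye_spec(frame_width = 60, frame_height = 24,
                             iris_radius = 8, pupil_radius = 3,
                             centre_x = 8, centre_y = 12)
  est_l <- locate_pupil(eye_frame(render_eye(left)$image))
  expect_lte(sqrt(sum((est_l$centre - c(8, 12))^2)), 2)

  expect_error(locate_pupil(eye_frame(matrix(128, 24, 60))),
               class = "pupilloc_localisation_error")
})

test_that("estimates are translation-equivariant within rounding", {
  base <- synthetic_eye_spec(frame_width = 70, frame_height = 28,
                             iris_radius = 9, pupil_radius = 4,
                             centre_x = 30, centre_y = 13)
  shifted <- synthetic_eye_spec(frame_width = 70, frame_height = 28,
                                iris_radius = 9, pupil_radius = 4,
                                centre_x = 35, centre_y = 16)
  e1 <- locate_pupil(eye_frame(render_eye(base)$image))$centre
  e2 <- locate_pupil(eye_frame(render_eye(shifted)$image))$centre
  expect_lte(abs((e2[1] - e1[1]) - 5), 1)
  expect_lte(abs((e2[2] - e1[2]) - 3), 1)
})

test_that("estimates are invariant to positive affine intensity changes", {
  spec <- random_eye_spec(41, noiseless = TRUE)
  img <- render_eye(spec)$image
  e1 <- locate_pupil(eye_frame(img))$centre
  e2 <- locate_pupil(eye_frame(img * 0.6 + 30))$centre
  expect_equal(e1, e2)
})

test_that("estimates always lie inside the eye frame", {
  for (seed in 1:12) {
    spec <- random_eye_spec(seed + 300)
    img <- render_eye(spec)$image
    est <- locate_pupil(eye_frame(img))
    expect_true(est$centre[1] >= 0 && est$centre[1] <= ncol(img) - 1)
    expect_true(est$centre[2] >= 0 && est$centre[2] <= nrow(img) - 1)
  }
})
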
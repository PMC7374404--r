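# independent oracles and fixture helpers, kept deliberately literal so they
# stay independent of the implementation paths they check

# scalar normalised-correlation oracle: explicit double loop over pixels
oracle_ncc <- function(kernel, patch, centred = TRUE) {
  stopifnot(all(dim(kernel) == dim(patch)))
  if (centred) {
    kernel <- kernel - mean(kernel)
    patch <- patch - mean(patch)
  }
  num <- 0; kk <- 0; ee <- 0
  for (r in seq_len(nrow(kernel))) {
    for (c in seq_len(ncol(kernel))) {
      num <- num + kernel[r, c] * patch[r, c]
      kk <- kk + kernel[r, c]^2
      ee <- ee + patch[r, c]^2
    }
  }
  if (kk == 0 || ee == 0) return(0)
  num / sqrt(kk * ee)
}

# literal single-axis sliding-match oracle over a white-padded frame
oracle_pass <- function(frame, kernel_px, axis = "x") {
  kh <- nrow(kernel_px); kw <- ncol(kernel_px)
  if (axis == "x") {
    pad <- kw %/% 2
    padded <- cbind(matrix(255, nrow(frame), pad), frame,
                    matrix(255, nrow(frame), pad))
    n <- ncol(padded) - kw + 1
    scores <- vapply(seq_len(n), function(i)
      oracle_ncc(kernel_px, padded[, i:(i + kw - 1), drop = FALSE]), 0)
    list(scores = scores, positions = seq_len(n) - 1 - pad)
  } else {
    pad <- kh %/% 2
    padded <- rbind(matrix(255, pad, ncol(frame)), frame,
                    matrix(255, pad, ncol(frame)))
    n <- nrow(padded) - kh + 1
    scores <- vapply(seq_len(n), function(i)
      oracle_ncc(kernel_px, padded[i:(i + kh - 1), , drop = FALSE]), 0)
    list(scores = scores, positions = seq_len(n) - 1 - pad)
  }
}

# random small eye-frame spec for property tests
random_eye_spec <- function(seed, noiseless = FALSE, max_w = 64, max_h = 32) {
  withr::with_seed(seed, {
    w <- round(runif(1, 24, max_w))
    h <- max(8, min(max_h, round(w / 2.5)))
    r <- round(runif(1, 0.12, 0.22) * w)
    synthetic_eye_spec(
      frame_width = w, frame_height = h,
      iris_radius = r, pupil_radius = max(1, round(0.4 * r)),
      centre_x = round(runif(1, r, w - 1 - r)),
      centre_y = round(runif(1, 0.35 * (h - 1), 0.65 * (h - 1))),
      noise_sigma = if (noiseless) 0 else runif(1, 0, 8),
      gradient_amplitude = if (noiseless) 0 else runif(1, 0, 15),
      seed = seed
    )
  })
}
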
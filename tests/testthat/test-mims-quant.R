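mk_frame <- function(n15, n14, s32 = NULL) {
  ch <- list(N15 = n15, N14 = n14)
  if (!is.null(s32)) ch$S32 <- s32
  mims_frame(ch)
}

test_that("frame accumulation sums counts channel-wise", {
  one <- mk_frame(matrix(1L, 4, 4), matrix(2L, 4, 4))
  expect_identical(accumulate_frames(list(one)), one)

  two <- accumulate_frames(list(mk_frame(matrix(1L, 4, 4), matrix(1L, 4, 4)),
                                mk_frame(matrix(1L, 4, 4), matrix(1L, 4, 4))))
  expect_true(all(two$channels$N15 == 2L))
  expect_equal(two$n_frames_accumulated, 2L)

  # pooled-count ratio differs from the mean of per-frame ratios
  f1 <- mk_frame(matrix(1L, 1, 1), matrix(10L, 1, 1))
  f2 <- mk_frame(matrix(9L, 1, 1), matrix(20L, 1, 1))
  acc <- accumulate_frames(list(f1, f2))
  pooled <- measure_nucleus(acc, matrix(TRUE, 1, 1))$ratio
  per_frame_mean <- mean(c(1 / 10, 9 / 20))
  expect_equal(pooled, 10 / 30)
  expect_equal(per_frame_mean, 0.275)
  expect_false(isTRUE(all.equal(pooled, per_frame_mean)))

  expect_error(accumulate_frames(list(one, mk_frame(matrix(1L, 3, 3),
                                                    matrix(1L, 3, 3)))),
               "shapes differ")
})

test_that("frame construction validates counts and shapes", {
  expect_error(mims_frame(list(N15 = matrix(-1L, 2, 2))), "non-negative")
  expect_error(mims_frame(list(N15 = matrix(1.5, 2, 2))), "integer")
  expect_error(mims_frame(list(N15 = matrix(1L, 2, 2),
                               N14 = matrix(1L, 3, 3))), "share one shape")
})

test_that("segmentation finds disks and ignores blanks", {
  blank <- mk_frame(matrix(0L, 64, 64), matrix(0L, 64, 64))
  expect_true(all(segment_nuclei(blank) == 0L))

  # one bright disk, radius 10: one mask with area close to pi * 100
  img <- matrix(0L, 64, 64)
  for (r in 1:64) for (cc in 1:64)
    if ((r - 32)^2 + (cc - 32)^2 <= 100) img[r, cc] <- 500L
  lab <- segment_nuclei(mk_frame(img, img), min_area_px = 50)
  expect_equal(max(lab), 1L)
  expect_lt(abs(sum(lab == 1L) - pi * 100) / (pi * 100), 0.05)

  # two disks separated by background: two masks
  img2 <- matrix(0L, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    if ((r - 16)^2 + (cc - 16)^2 <= 36) img2[r, cc] <- 500L
    if ((r - 48)^2 + (cc - 48)^2 <= 36) img2[r, cc] <- 500L
  }
  expect_equal(max(segment_nuclei(mk_frame(img2, img2), min_area_px = 20)), 2L)
})

test_that("segmentation labels 8-connected components", {
  # two pixels touching only diagonally belong to one component
  img <- matrix(0L, 16, 16)
  img[5, 5] <- 500L
  img[6, 6] <- 500L
  lab <- segment_nuclei(mk_frame(img, img), min_area_px = 1)
  expect_equal(max(lab), 1L)
  expect_equal(lab[5, 5], lab[6, 6])
})

test_that("nucleus measurement uses summed-count ratios", {
  m <- nucleus_measurement(1L, sum15 = 300, sum14 = 1200)
  expect_equal(m$ratio, 0.25)
  expect_equal(m$atom_fraction, 0.2)
  expect_equal(m$excess, 0.1963)

  # single pixel (5, 20)
  n15 <- matrix(0L, 4, 4); n14 <- matrix(0L, 4, 4)
  n15[2, 2] <- 5L; n14[2, 2] <- 20L
  mask <- matrix(FALSE, 4, 4); mask[2, 2] <- TRUE
  expect_equal(measure_nucleus(mk_frame(n15, n14), mask)$ratio, 0.25)

  # sum14 = 0 is unmeasurable
  n14[2, 2] <- 0L
  expect_error(measure_nucleus(mk_frame(n15, n14), mask), "unmeasurable")
})

test_that("ratio estimator is consistent on synthetic nuclei", {
  # known f, total dose >= 1e5: |f_hat - f| within 3 binomial SE in >= 99%
  # of seeded replicates (scaled-down version; full sweep in acceptance)
  f <- 0.2
  dose <- 2e5
  hits <- sapply(1:200, function(i) {
    set.seed(3000 + i)
    s15 <- rpois(1, dose * f)
    s14 <- rpois(1, dose * (1 - f))
    m <- nucleus_measurement(1L, s15, s14)
    total <- s15 + s14
    abs(m$atom_fraction - f) <= 3 * sqrt(f * (1 - f) / total)
  })
  expect_gte(mean(hits), 0.97)
})

test_that("accumulation before ratio beats per-frame ratio averaging", {
  f <- 0.2; dose_per_frame <- 300; n_frames <- 4
  res <- t(sapply(1:500, function(i) {
    set.seed(4000 + i)
    s15 <- rpois(n_frames, dose_per_frame * f)
    s14 <- rpois(n_frames, dose_per_frame * (1 - f))
    c(pooled = sum(s15) / sum(s14), meaned = mean(s15 / s14))
  }))
  true_ratio <- f / (1 - f)
  expect_lt(mean((res[, "pooled"] - true_ratio)^2),
            mean((res[, "meaned"] - true_ratio)^2))
})

test_that("segmentation recovers ground-truth masks with Jaccard >= 0.9", {
  protocol <- labeling_protocol()
  # divided cells so nuclei are bright on the 14N channel
  cells <- data.frame(cell_id = paste0("c", 1:6), cell_type = "beta",
                      group = "AL", true_divisions = 2L,
                      true_excess = label_after_divisions(
                        protocol$initial_excess, 2))
  cfg <- mims_sim_config(raster_dim = c(256, 256), fiducials = 0)
  sim <- synthesize_mims_frames(cells, cfg, seed = 21)
  acc <- accumulate_frames(sim$frames)
  lab <- segment_nuclei(acc)
  expect_equal(max(lab), 6L)
  for (i in 1:6) {
    truth_px <- which(sim$masks == i)
    hits <- table(lab[truth_px])
    match_lab <- as.integer(names(which.max(hits[names(hits) != "0"])))
    seg_px <- which(lab == match_lab)
    jacc <- length(intersect(truth_px, seg_px)) /
      length(union(truth_px, seg_px))
    expect_gte(jacc, 0.9)
  }
})

test_that("fiducial affine fitting recovers planted transforms", {
  set.seed(31)
  src <- cbind(runif(10, 0, 100), runif(10, 0, 100))

  # identity
  tr <- fit_fiducial_affine(src, src)
  expect_equal(tr$A, diag(2), tolerance = 1e-9)
  expect_equal(tr$b, c(0, 0), tolerance = 1e-9)
  expect_lt(attr(tr, "rms_residual"), 1e-9)

  # pure translation (+5, +7)
  tr2 <- fit_fiducial_affine(src, sweep(src, 2, c(5, 7), "+"))
  expect_equal(tr2$A, diag(2), tolerance = 1e-9)
  expect_equal(tr2$b, c(5, 7), tolerance = 1e-9)

  # known affine + noise: parameters within 3 SE from least-squares theory
  A <- matrix(c(1.02, 0.05, -0.04, 0.98), 2, 2)
  b <- c(3, -2)
  noise_sd <- 0.5
  dst <- sweep(src %*% t(A), 2, b, "+") + matrix(rnorm(20, 0, noise_sd), 10)
  tr3 <- fit_fiducial_affine(src, dst)
  X <- cbind(1, src)
  cov_unscaled <- solve(crossprod(X))
  se <- noise_sd * sqrt(diag(cov_unscaled))  # intercept, x, y
  expect_lt(abs(tr3$b[1] - b[1]), 3 * se[1])
  expect_lt(abs(tr3$b[2] - b[2]), 3 * se[1])
  expect_lt(abs(tr3$A[1, 1] - A[1, 1]), 3 * se[2])
  expect_lt(abs(tr3$A[2, 2] - A[2, 2]), 3 * se[3])

  expect_error(fit_fiducial_affine(src[1:2, ], src[1:2, ]), "at least 3")
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(fit_fiducial_affine(coll, coll), "collinear")
})

test_that("transforms apply and invert consistently", {
  tr <- affine_transform(matrix(c(0.9, 0.1, -0.1, 1.1), 2, 2), c(5, 7))
  pts <- cbind(c(0, 3, 10), c(0, 4, -2))
  expect_equal(apply_transform(affine_transform(diag(2)), pts), pts)
  expect_equal(apply_transform(affine_transform(diag(2), c(5, 7)),
                               cbind(0, 0)),
               cbind(5, 7))
  roundtrip <- apply_transform(invert_transform(tr),
                               apply_transform(tr, pts))
  expect_equal(roundtrip, pts, tolerance = 1e-9)

  expect_error(affine_transform(matrix(c(1, 2, 2, 4), 2, 2)), "singular")
})

test_that("registration round-trip reproduces fiducials within noise", {
  set.seed(32)
  src <- cbind(runif(12, 0, 512), runif(12, 0, 512))
  A <- matrix(c(0.98, 0.02, -0.03, 1.01), 2, 2)
  noise_sd <- 0.3
  dst <- sweep(src %*% t(A), 2, c(10, -4), "+") +
    matrix(rnorm(24, 0, noise_sd), 12)
  tr <- fit_fiducial_affine(src, dst)
  rms <- sqrt(mean((apply_transform(tr, src) - dst)^2))
  expect_lte(rms, 2 * noise_sd)
})

test_that("mask transform maps labelled pixels with rounding", {
  lab <- matrix(0L, 16, 16)
  lab[4:6, 4:6] <- 2L
  shifted <- apply_transform_mask(affine_transform(diag(2), c(3, 2)), lab)
  expect_equal(sum(shifted == 2L), 9)
  expect_equal(shifted[7, 6], 2L)
})
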
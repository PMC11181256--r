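test_that("Sobel magnitude matches direct kernel application", {
  # flat field: zero gradient everywhere
  const <- lesion(matrix(90L, 6, 6))
  gf <- sobel_gradient(const)
  expect_true(all(gf$magnitude == 0))

  # unit horizontal ramp g(r, c) = c: |Gx| = 8, Gy = 0 at every interior pixel
  ramp <- lesion(matrix(0:9, 10, 10, byrow = TRUE))
  gr <- sobel_gradient(ramp)
  expect_true(all(gr$magnitude[2:9, 2:9] == 8))

  # vertical step edge: pixels adjacent to the step see |Gx| = 4 * 255
  step <- lesion(cbind(matrix(0L, 8, 4), matrix(255L, 8, 4)))
  gs <- sobel_gradient(step)
  expect_true(all(gs$magnitude[2:7, 4:5] == 4 * 255))
  expect_true(all(gs$magnitude[2:7, c(2, 7)] == 0))
})

test_that("gradient quantization spreads, clips and degenerates correctly", {
  les <- lesion(matrix(0L, 10, 10))
  gf <- sobel_gradient(les)

  # all-zero magnitudes map to level 0
  q0 <- quantize_gradient(gf, 32)
  expect_true(all(q0$quantized[q0$support] == 0))

  # endpoints {0, gmax} map to {0, 31}
  gf2 <- gf
  gf2$magnitude[gf2$support][1:2] <- c(0, 17.3)
  q2 <- quantize_gradient(gf2, 32)
  expect_equal(sort(unique(q2$quantized[q2$support])), c(0L, 31L))

  # 64 uniformly spaced magnitudes 0..gmax on the 8x8 interior:
  # each of the 32 levels gets exactly 2 pixels
  gf3 <- gf
  gf3$magnitude[gf3$support] <- seq(0, 5, length.out = 64)
  q3 <- quantize_gradient(gf3, 32)
  expect_equal(unname(table(q3$quantized[q3$support])), rep(2L, 32),
               ignore_attr = TRUE)
})

test_that("the GGCM counts gray/gradient pairs over the interior mask", {
  # constant image at gray 50: all mass at (50, 0)
  const <- lesion(matrix(50L, 8, 8))
  H <- compute_ggcm(const)
  expect_equal(H$counts[51, 1], 36L)  # 6x6 interior
  expect_equal(sum(H$counts), H$n_pixels)

  # horizontal ramp: every interior pixel has the same (maximal) gradient,
  # so all mass sits in the top gradient column
  ramp <- lesion(matrix(seq(40L, 130L, by = 10L), 10, 10, byrow = TRUE))
  Hr <- compute_ggcm(ramp)
  expect_equal(sum(Hr$counts[, 32]), Hr$n_pixels)
  expect_equal(sum(Hr$counts), sum(ramp$interior))

  set.seed(101)
  for (rep in 1:4) {
    les <- random_lesion(14, 14, p_mask = 0.85)
    expect_equal(compute_ggcm(les)$n_pixels, sum(les$interior))
  }
})

test_that("GGCM features match hand-computed single- and four-cell cases", {
  # all mass at one cell (i0, j0)
  H <- matrix(0L, 256, 32); H[41, 6] <- 17L  # i0 = 40, j0 = 5
  f <- ggcm_features(H)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["gray_entropy"]], 0)
  expect_equal(f[["gradient_entropy"]], 0)
  expect_equal(f[["hybrid_entropy"]], 0)
  expect_equal(f[["gray_mean_square_error"]], 0)
  expect_equal(f[["gradient_mean_square_error"]], 0)
  expect_equal(f[["correlation"]], 0)
  expect_equal(f[["small_gradient_dominance"]], 1 / 36)
  expect_equal(f[["inertia"]], (40 - 5)^2)

  # uniform mass on {0,1} x {0,1}
  H2 <- matrix(0L, 256, 32); H2[1:2, 1:2] <- 1L
  f2 <- ggcm_features(H2)
  expect_equal(f2[["energy"]], 0.25)
  expect_equal(f2[["hybrid_entropy"]], log(4))
  expect_equal(f2[["gray_average"]], 0.5)
  expect_equal(f2[["gradient_average"]], 0.5)
  expect_equal(f2[["correlation"]], 0)
  expect_equal(f2[["gray_heterogeneity"]], 2)

  # constant-image lesion: gradient marginal entirely at level 0
  fc <- ggcm_features(compute_ggcm(lesion(matrix(80L, 8, 8))))
  expect_equal(fc[["small_gradient_dominance"]], 1)
  expect_equal(fc[["large_gradient_dominance"]], 0)
  expect_equal(fc[["gradient_entropy"]], 0)
})

test_that("GGCM features agree with the direct-loop oracle on random matrices", {
  set.seed(111)
  for (rep in 1:4) {
    H <- matrix(rpois(256 * 32, 0.05), 256, 32)
    H[1, 1] <- H[1, 1] + 1L  # non-empty
    got <- ggcm_features(H)
    want <- oracle_ggcm_features(H)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
  set.seed(112)
  les <- random_lesion(20, 20, p_mask = 0.9)
  H <- compute_ggcm(les)
  expect_equal(ggcm_features(H), oracle_ggcm_features(H$counts),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GGCM feature vectors are finite with the expected analytic bounds", {
  set.seed(121)
  for (rep in 1:6) {
    les <- random_lesion(16, 16, p_mask = 0.85)
    f <- ggcm_features(compute_ggcm(les))
    expect_length(f, 15)
    expect_true(all(is.finite(f)))
    expect_gt(f[["energy"]], 0); expect_lte(f[["energy"]], 1)
    expect_gt(f[["inverse_difference_moment"]], 0)
    expect_lte(f[["inverse_difference_moment"]], 1)
    expect_gte(f[["gray_entropy"]], 0)
    expect_gte(f[["gradient_entropy"]], 0)
    # joint entropy dominates both marginals (up to float error)
    expect_gte(f[["hybrid_entropy"]],
               max(f[["gray_entropy"]], f[["gradient_entropy"]]) - 1e-9)
  }
})

test_that("small-gradient dominance decreases as mass moves to higher levels", {
  # two-column GGCMs: move mass from column j = 1 to column j = 20
  vals <- sapply(seq(0, 1, by = 0.1), function(w) {
    H <- matrix(0, 256, 32)
    H[10, 2] <- round(100 * (1 - w)); H[10, 21] <- round(100 * w)
    if (sum(H) == 0) return(NA_real_)
    ggcm_features(H)[["small_gradient_dominance"]]
  })
  expect_true(all(diff(vals[!is.na(vals)]) <= 0))
})

test_that("degenerate gradient inputs are rejected", {
  expect_error(sobel_gradient(lesion(matrix(1L, 2, 5))), "at least 3x3")
  # mask with empty interior (a thin diagonal)
  m <- matrix(FALSE, 6, 6); diag(m) <- TRUE
  expect_error(sobel_gradient(lesion(matrix(0L, 6, 6), m)), "empty interior")
  expect_error(ggcm_features(matrix(0, 4, 4)), "empty")
})
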
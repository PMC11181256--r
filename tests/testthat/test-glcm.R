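test_that("co-occurrence counts match hand-enumerated pairs on tiny images", {
  # two horizontal pairs: (0,0) and (1,1) at 2 levels
  les <- lesion(matrix(c(0, 0, 255, 255), 2, 2, byrow = TRUE))
  m <- compute_glcm(les, d = 1, theta = 0, levels = 2)
  expect_equal(m$counts, matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(m$n_pairs, 2)

  # 3x3 ramp 0,1,2 per row at 3 levels: 3 (0->1) and 3 (1->2) pairs
  ramp <- lesion(matrix(rep(c(0, 86, 172), 3), 3, 3, byrow = TRUE))
  m2 <- compute_glcm(ramp, d = 1, theta = 0, levels = 3)
  expect_equal(m2$counts[1, 2], 3L)
  expect_equal(m2$counts[2, 3], 3L)
  expect_equal(m2$n_pairs, 6)

  # constant image: all mass on the diagonal for every direction
  const <- lesion(matrix(70L, 5, 5))
  for (th in c(0, 45, 90, 135)) {
    m3 <- compute_glcm(const, d = 2, theta = th)
    expect_equal(m3$counts[71, 71], m3$n_pairs)
  }
})

test_that("co-occurrence counts equal brute-force enumeration on random masks", {
  set.seed(51)
  for (rep in 1:4) {
    h <- sample(10:24, 1); w <- sample(10:24, 1)
    les <- random_lesion(h, w)
    for (d in 1:3) for (th in c(0, 45, 90, 135)) {
      want <- oracle_glcm_counts(les$pixels, les$mask, d, th, levels = 256)
      if (sum(want) == 0) {
        expect_error(compute_glcm(les, d, th), "no valid pixel pairs")
      } else {
        got <- compute_glcm(les, d, th)
        expect_identical(got$counts, want)
        expect_identical(got$n_pairs, sum(want))
      }
    }
  }
})

test_that("descriptors match their definitions", {
  # constant image: degenerate-variance correlation rule
  const <- lesion(matrix(100L, 4, 4))
  d <- glcm_descriptors(compute_glcm(const, 1, 0))
  expect_equal(unname(d), c(0, 0, 1, 1))

  # 2x2 checkerboard at 2 levels: pairs (0,1) and (1,0), p = 0.5 each
  chk <- lesion(matrix(c(0, 255, 255, 0), 2, 2))
  dc <- glcm_descriptors(compute_glcm(chk, 1, 0, levels = 2))
  expect_equal(dc[["contrast"]], 1)
  expect_equal(dc[["energy"]], 0.5)

  set.seed(61)
  for (rep in 1:5) {
    les <- random_lesion(12, 12)
    m <- compute_glcm(les, 1, 45, levels = 16)
    got <- glcm_descriptors(m)
    want <- oracle_glcm_descriptors(m$counts)
    expect_equal(got, want, tolerance = 1e-12)
    expect_lte(got[["energy"]], 1)
    expect_lte(got[["homogeneity"]], 1)
  }
})

test_that("glcm48 concatenates the 12 per-configuration quadruples in order", {
  set.seed(71)
  les <- random_lesion(16, 16, p_mask = 0.9)
  v <- glcm48(les)
  expect_length(v, 48)
  expect_identical(attr(v, "combination_id"), "GLCM48")
  expect_equal(names(v)[1:4],
               c("d1_a0_contrast", "d1_a0_correlation", "d1_a0_energy",
                 "d1_a0_homogeneity"))
  expect_equal(names(v)[45], "d3_a135_contrast")
  for (d in 1:3) for (th in c(0, 45, 90, 135)) {
    want <- oracle_glcm_descriptors(oracle_glcm_counts(les$pixels, les$mask,
                                                       d, th))
    idx <- sprintf("d%d_a%d_%s", d, th, names(want))
    expect_equal(unname(v[idx]), unname(want), tolerance = 1e-12)
  }
})

test_that("global gray features follow the first-order definitions", {
  const <- lesion(matrix(100L, 10, 10))
  expect_equal(unname(global_gray_features(const)), c(0, 100, 0))

  two <- lesion(matrix(c(0L, 255L), 1, 2), matrix(TRUE, 1, 2))
  g <- global_gray_features(two)
  expect_equal(g[["entropy"]], log(2))
  expect_equal(g[["mean"]], 127.5)
  expect_equal(g[["sd"]], 127.5)

  # uniform histogram over all 256 levels: maximum entropy log(256)
  uni <- lesion(matrix(0:255, 16, 16))
  expect_equal(global_gray_features(uni)[["entropy"]], log(256))
})

test_that("glcm51 is glcm48 plus the three global features", {
  set.seed(81)
  les <- random_lesion(14, 14, p_mask = 0.85)
  v51 <- glcm51(les)
  expect_length(v51, 51)
  expect_identical(attr(v51, "combination_id"), "GLCM48_PLUS_GLOBAL3")
  expect_equal(unname(v51[1:48]), unname(glcm48(les)), ignore_attr = TRUE)
  expect_equal(unname(v51[49:51]), unname(global_gray_features(les)),
               ignore_attr = TRUE)
})

test_that("features are invariant under gray inversion and ROI translation", {
  set.seed(91)
  les <- random_lesion(15, 15, p_mask = 0.8)

  inv <- lesion(255L - les$pixels, les$mask)
  expect_equal(glcm48(inv), glcm48(les), tolerance = 1e-10)

  # translate the same masked pixels inside a larger canvas
  big_px <- matrix(0L, 25, 25); big_m <- matrix(FALSE, 25, 25)
  big_px[6:20, 8:22] <- les$pixels; big_m[6:20, 8:22] <- les$mask
  moved <- lesion(big_px, big_m)
  expect_equal(glcm51(moved), glcm51(les), tolerance = 1e-12)
})

test_that("gray quantization is order-preserving for coarser level counts", {
  g <- 0:255
  for (L in c(8, 16, 32, 64, 128)) {
    q <- floor(g * L / 256)
    expect_true(all(diff(q) >= 0))
    expect_equal(range(q), c(0, L - 1))
  }
  les <- lesion(matrix(c(10L, 200L, 10L, 200L), 2, 2))
  m <- compute_glcm(les, 1, 90, levels = 8)
  expect_equal(sum(m$counts), m$n_pairs)
})

test_that("overlong displacements are rejected with a named configuration", {
  thin <- lesion(matrix(5L, 2, 10))
  expect_error(compute_glcm(thin, d = 3, theta = 90), "d=3, theta=90")
})
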
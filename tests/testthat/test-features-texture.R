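test_that("GLCM reproduces hand-enumerated small cases", {
  # single constant column: one co-occurring pair value
  v <- hr_volume(array(1, c(1, 5, 1)))
  q <- quantize(v, hr_mask(array(1, c(1, 5, 1))), 4)
  g <- glcm(q, 1, 0)
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1)

  # 2x2 slice [[1,2],[2,1]]: horizontal pairs (1,2) and (2,1)
  v2 <- hr_volume(array(c(1, 2, 2, 1), c(2, 2, 1)))
  q2 <- quantize(v2, hr_mask(array(1, c(2, 2, 1))), 2)
  g2 <- glcm(q2, 1, 0)
  expect_equal(g2$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- glcm_features(g2)
  expect_equal(f[["Inverse Difference Moment"]], 0.5)
  expect_equal(f[["Inertia"]], 1)
  expect_equal(f[["Energy"]], 0.5)
})

test_that("GLCM features at the constant-image limit", {
  q <- quantize(hr_volume(array(2, c(4, 4, 2))), hr_mask(array(1, c(4, 4, 2))), 64)
  f <- glcm_features(glcm(q, 1, 0))
  expect_equal(f[["Energy"]], 1)
  expect_equal(f[["GLCMEntropy"]], 0)
  expect_equal(f[["Inverse Difference Moment"]], 1)
  expect_equal(f[["Inertia"]], 0)
  expect_equal(f[["Correlation"]], 0)  # degenerate-by-convention
})

test_that("Haralick sum statistics match hand-computed distributions", {
  # constant image: p(1,1) = 1 so p_{x+y}(2) = 1
  q <- quantize(hr_volume(array(2, c(3, 3, 1))), hr_mask(array(1, c(3, 3, 1))), 8)
  hb <- haralick_block(q)
  expect_equal(hb[["Sum Average"]], 2)
  expect_equal(hb[["Sum Entropy"]], 0)
  expect_equal(hb[["Difference Entropy"]], 0)
  expect_equal(hb[["Maximum Probability"]], 1)

  # checkerboard pairs: p(1,2) = p(2,1) = 0.5 -> p_{x+y}(3) = 1
  v2 <- hr_volume(array(c(1, 2, 2, 1), c(2, 2, 1)))
  q2 <- quantize(v2, hr_mask(array(1, c(2, 2, 1))), 2)
  g2 <- glcm(q2, 1, 0)
  hb2 <- haralick_block(q2, list(g2))
  expect_equal(hb2[["Sum Average"]], 3)
  expect_equal(hb2[["Sum Entropy"]], 0)
  expect_equal(hb2[["Difference Average"]], 1)
})

test_that("RLM reproduces hand-enumerated runs", {
  # row [1,1,1,2,2]: runs (1,3) and (2,2); LRE = (9+4)/2
  v <- hr_volume(array(c(1, 1, 1, 2, 2), c(1, 5, 1)))
  q <- quantize(v, hr_mask(array(1, c(1, 5, 1))), 2)
  r <- rlm(q, 1, 0)
  expect_equal(r$n_runs, 2)
  expect_equal(r$r[1, 3], 1)
  expect_equal(r$r[2, 2], 1)
  f <- rlm_features(r)
  expect_equal(f[["Long Run Emphasis"]], 6.5)
  expect_equal(f[["Run Percentage"]], 2 / 5)

  # constant row of N: single run, LRE = N^2, LGLRE = 1
  vc <- hr_volume(array(1, c(1, 6, 1)))
  qc <- quantize(vc, hr_mask(array(1, c(1, 6, 1))), 4)
  fc <- rlm_features(rlm(qc, 1, 0))
  expect_equal(fc[["Long Run Emphasis"]], 36)
  expect_equal(fc[["Low Gray Level Run Emphasis"]], 1)
  expect_equal(fc[["Run Percentage"]], 1 / 6)
})

test_that("direction aggregation is the mean and population SD", {
  expect_equal(aggregate_directions(c(2, 2, 2, 2)), c(mean = 2, SD = 0))
  expect_equal(aggregate_directions(c(1, 2, 3, 4)),
               c(mean = 2.5, SD = sqrt(1.25)))
  expect_equal(aggregate_directions(c(5, NA, NA, NA)), c(mean = 5, SD = 0))
  expect_true(all(is.na(aggregate_directions(rep(NA_real_, 4)))))
})

test_that("GLCM and RLM match brute-force oracles on random grids", {
  set.seed(20)
  n_grids <- 40
  for (k in seq_len(n_grids)) {
    G <- sample(2:8, 1)
    dims <- c(sample(2:8, 1), sample(2:8, 1), sample(1:4, 1))
    q <- random_qroi(dims, G, p_mask = runif(1, 0.5, 1))
    for (d in c(1L, 4L, 7L)) for (a in c(0, 45, 90, 135)) {
      g <- glcm(q, d, a)
      bp <- brute_glcm(q$levels, G, d, a)
      if (is.null(bp)) {
        expect_true(g$empty)
      } else {
        expect_equal(g$p, bp, tolerance = 1e-12)
        expect_equal(glcm_features(g), brute_glcm_stats(bp), tolerance = 1e-12)
      }
      r <- rlm(q, d, a)
      br <- brute_rlm(q$levels, G, d, a)
      if (is.null(br)) {
        expect_true(r$empty)
      } else {
        expect_equal(unname(r$r[, seq_len(ncol(br)), drop = FALSE]),
                     unname(br), tolerance = 1e-12)
        expect_equal(rlm_features(r), brute_rlm_stats(br, q$n_voxels),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("GLCM is symmetric, normalized, and invariant to 180-degree reversal", {
  set.seed(21)
  for (k in 1:10) {
    q <- random_qroi(c(6, 6, 3), 6)
    for (d in c(1L, 2L)) for (a in c(0, 45, 90, 135)) {
      g <- glcm(q, d, a)
      if (g$empty) next
      expect_equal(g$p, t(g$p), tolerance = 1e-14)
      expect_equal(sum(g$p), 1, tolerance = 1e-14)
      # reversing the direction (flip the slice both ways) leaves p unchanged
      lev_rev <- q$levels[rev(seq_len(dim(q$levels)[1])),
                          rev(seq_len(dim(q$levels)[2])), , drop = FALSE]
      q_rev <- q; q_rev$levels <- lev_rev
      expect_equal(glcm(q_rev, d, a)$p, g$p, tolerance = 1e-14)
    }
  }
})
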
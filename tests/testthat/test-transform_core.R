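test_that("alpha factor takes the 1/sqrt(2) branch only at DC", {
  expect_equal(dct_alpha(0), 1 / sqrt(2))
  expect_equal(dct_alpha(1), 1)
  expect_equal(dct_alpha(7), 1)
  expect_equal(dct_alpha(c(0, 3, 0)), c(1 / sqrt(2), 1, 1 / sqrt(2)))
  expect_error(dct_alpha(-1), "non-negative")
})

test_that("forward DCT matches direct evaluation and handles constants", {
  expect_equal(forward_dct(c(1, 0)), c(1, 1) / sqrt(2), tolerance = 1e-12)
  for (n in c(1, 3, 16)) {
    expect_equal(forward_dct(rep(2.5, n)), c(2.5 * sqrt(n), rep(0, n - 1)),
                 tolerance = 1e-10)
  }
  # against the independently built basis
  x <- withr::with_seed(1, stats::rnorm(13))
  expect_equal(forward_dct(x), drop(ref_dct_basis(13) %*% x),
               tolerance = 1e-12)
  expect_error(forward_dct(numeric(0)), "empty")
})

test_that("standard pair round-trips and preserves energy (orthonormality)", {
  withr::with_seed(42, {
    for (n in 1:64) {
      x <- stats::rnorm(n, sd = 50)
      y <- forward_dct(x)
      expect_equal(inverse_dct(y), x, tolerance = 1e-10)
      expect_equal(forward_dct(inverse_dct(y)), y, tolerance = 1e-10)
      expect_equal(sum(y^2), sum(x^2), tolerance = 1e-10)
    }
  })
  expect_equal(inverse_dct(c(3 * sqrt(4), 0, 0, 0)), rep(3, 4),
               tolerance = 1e-12)
  expect_equal(inverse_dct(c(1, 1) / sqrt(2)), c(1, 0), tolerance = 1e-12)
  expect_error(inverse_dct(numeric(0)), "empty")
})

test_that("weighted forward transform scales coefficient k by N/(N+k)", {
  expect_equal(forward_dre_dct(c(1, 0)), c(1 / sqrt(2), sqrt(2) / 3),
               tolerance = 1e-8)
  expect_equal(forward_dre_dct(rep(4, 8)), c(4 * sqrt(8), rep(0, 7)),
               tolerance = 1e-10)
  withr::with_seed(7, {
    for (n in c(2, 5, 16, 31)) {
      x <- stats::rnorm(n)
      y0 <- forward_dct(x)
      y1 <- forward_dre_dct(x)
      k <- 0:(n - 1)
      nz <- abs(y0) > 1e-8
      expect_equal(y1[nz] / y0[nz], (n / (n + k))[nz], tolerance = 1e-10)
    }
  })
})

test_that("weighted inverse equals standard inverse of N/(N-k)-scaled input", {
  expect_equal(inverse_dre_dct(c(7 * sqrt(3), 0, 0)), rep(7, 3),
               tolerance = 1e-10)
  expect_equal(inverse_dre_dct(c(0.70710678, 0.47140452)),
               c(7 / 6, -1 / 6), tolerance = 1e-7)
  withr::with_seed(8, {
    for (n in c(2, 9, 16)) {
      y <- stats::rnorm(n)
      k <- 0:(n - 1)
      expect_equal(inverse_dre_dct(y), inverse_dct(y * n / (n - k)),
                   tolerance = 1e-10)
    }
  })
})

test_that("composite gain matches the impulse-response oracle", {
  for (n in c(2, 4, 8, 14, 15, 16)) {
    g <- composite_gain(n)
    expect_equal(g[1], 1)
    # oracle: push each unit impulse through the weighted round trip and
    # read the per-coefficient amplification in the standard DCT domain
    measured <- matrix(NA_real_, n, n)
    for (j in 1:n) {
      e <- numeric(n); e[j] <- 1
      y0 <- forward_dct(e)
      y1 <- forward_dct(enhance_1d(e))
      nz <- abs(y0) > 1e-8
      measured[j, nz] <- y1[nz] / y0[nz]
    }
    for (k in 1:n) {
      vals <- measured[, k][!is.na(measured[, k])]
      expect_gt(length(vals), 0)
      expect_equal(vals, rep(n^2 / (n^2 - (k - 1)^2), length(vals)),
                   tolerance = 1e-9)
    }
  }
  expect_equal(composite_gain(2), c(1, 4 / 3))
  expect_equal(composite_gain(16)[16], 256 / 31)
  expect_error(composite_gain(0), ">= 1")
})

test_that("gain profile is >= 1, 1 at DC, and strictly increasing", {
  for (n in c(2, 14, 15, 16, 32)) {
    g <- composite_gain(n)
    expect_equal(g[1], 1)
    expect_true(all(g >= 1))
    if (n > 1) expect_true(all(diff(g) > 0))
  }
})

test_that("1D enhancement: fixed points, linearity, mean and energy laws", {
  expect_equal(enhance_1d(c(5, 5, 5, 5)), c(5, 5, 5, 5), tolerance = 1e-12)
  expect_equal(enhance_1d(c(1, 0)), c(7 / 6, -1 / 6), tolerance = 1e-10)
  expect_equal(enhance_1d(3.7), 3.7)  # N = 1 passes through
  withr::with_seed(99, {
    for (n in c(2, 4, 8, 14, 15, 16)) {
      x <- stats::rnorm(n, sd = 10)
      z <- stats::rnorm(n, sd = 10)
      g <- composite_gain(n)
      # oracle equivalence in the standard DCT domain
      expect_equal(enhance_1d(x), inverse_dct(g * forward_dct(x)),
                   tolerance = 1e-9)
      expect_equal(enhance_1d(2.5 * x - 1.25 * z),
                   2.5 * enhance_1d(x) - 1.25 * enhance_1d(z),
                   tolerance = 1e-9)
      expect_equal(mean(enhance_1d(x)), mean(x), tolerance = 1e-10)
      expect_equal(sum(enhance_1d(x)), sum(x), tolerance = 1e-9)
      if (n > 1) expect_gt(sum(enhance_1d(x)^2), sum(x^2))
      expect_equal(sum(enhance_1d(rep(2, n))^2), sum(rep(2, n)^2),
                   tolerance = 1e-10)
    }
  })
})
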
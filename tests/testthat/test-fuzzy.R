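test_that("upper_confidence_limit reproduces the published limits", {
  expect_equal(upper_confidence_limit(4.03, 10, 0.05), 6.178,
               tolerance = 0.001 / 6.178)
  expect_equal(upper_confidence_limit(6.09, 10, 0.05), 9.019,
               tolerance = 0.001 / 9.019)
  # zero estimate: only the normal-quantile term survives
  expect_equal(upper_confidence_limit(0, 10, 0.05),
               qnorm(0.975) / sqrt(10), tolerance = 1e-12)
  expect_error(upper_confidence_limit(4, 1, 0.05),
               class = "pf_parameter_error")
  expect_error(upper_confidence_limit(4, 10, 0),
               class = "pf_parameter_error")
  expect_error(upper_confidence_limit(4, 10, 1),
               class = "pf_parameter_error")
})

test_that("build_fuzzy_index reproduces the published apex/endpoint pairs", {
  fz1 <- build_fuzzy_index(4.03, n = 10)
  expect_equal(fz1$pf_m, 3.681, tolerance = 0.001 / 3.681)
  expect_equal(fz1$pf_r, 6.178, tolerance = 0.001 / 6.178)
  expect_identical(fz1$ucl, fz1$pf_r)
  fz4 <- build_fuzzy_index(5.93, n = 10)
  expect_equal(fz4$pf_m, 5.416, tolerance = 0.001 / 5.416)
  expect_equal(fz4$pf_r, 8.799, tolerance = 0.001 / 8.799)
  # apex scales with the estimate
  expect_equal(build_fuzzy_index(0, n = 10)$pf_m, 0)
  # chi-square median correction pulls the apex below a positive estimate
  expect_lt(fz1$pf_m, fz1$pf_star)
  # accepts an index_estimate and carries its metadata
  est <- estimate_index(summary_sample("cardio", 10, 590.6, 1.838),
                        fitness_spec("cardio", 598, "smaller_better"))
  fz <- build_fuzzy_index(est)
  expect_identical(fz$item_id, "cardio")
  expect_identical(fz$n, 10L)
})

test_that("pf_m, pf_r and the test ratio increase strictly with pf_star", {
  # grid restricted to where d_t > 0 (strongly negative estimates flip
  # the endpoint ordering and are a documented error path)
  pf_grid <- seq(-1, 8, by = 0.5)
  sp <- fitness_spec("x", 0, "larger_better", k = 6)
  fzs <- lapply(pf_grid, build_fuzzy_index, n = 10, alpha = 0.05)
  pf_m <- vapply(fzs, `[[`, numeric(1), "pf_m")
  pf_r <- vapply(fzs, `[[`, numeric(1), "pf_r")
  ratio <- vapply(fzs, function(fz) fuzzy_test(fz, sp)$ratio, numeric(1))
  expect_true(all(diff(pf_m) > 0))
  expect_true(all(diff(pf_r) > 0))
  expect_true(all(diff(ratio) > 0))
})

test_that("pf_m < pf_r for nonnegative estimates across n and alpha", {
  for (n in c(2, 5, 10, 30, 100))
    for (alpha in c(0.01, 0.05, 0.2, 0.49))
      for (pf in c(0, 0.5, 2, 10)) {
        fz <- build_fuzzy_index(pf, n = n, alpha = alpha)
        expect_lt(fz$pf_m, fz$pf_r)
      }
})

test_that("membership is 1 at the apex, 0 outside, monotone between", {
  fz <- build_fuzzy_index(4.03, n = 10)
  expect_equal(membership(fz, fz$pf_m), 1)
  expect_equal(membership(fz, fz$pf_m - 0.001), 0)
  expect_equal(membership(fz, fz$pf_r), 0)       # discontinuity at PF_R
  expect_equal(membership(fz, fz$pf_r + 1), 0)
  xs <- seq(fz$pf_m + 1e-6, fz$pf_r - 1e-6, length.out = 50)
  grades <- membership(fz, xs)
  expect_true(all(grades > 0 & grades <= 1))
  expect_true(all(diff(grades) < 0))
  # interior grades never drop below the 0.05 cut floor
  expect_true(all(grades >= 0.05 - 1e-9))
})

test_that("membership inverts the alpha-cut map to 1e-6 (round trip)", {
  set.seed(123)
  for (pf_star in c(4.03, 6.09, 1.2)) {
    fz <- build_fuzzy_index(pf_star, n = 10)
    xs <- runif(100, fz$pf_m + 1e-9, fz$pf_r - 1e-9)
    a <- membership(fz, xs)
    x_back <- vapply(a, fwd_cut, numeric(1), pf_star = pf_star, n = 10)
    expect_equal(x_back, xs, tolerance = 1e-6)
  }
})

test_that("alpha below the 0.05 floor caps interior membership at 0.05", {
  fz <- build_fuzzy_index(4.03, n = 10, alpha = 0.01)
  x_floor <- fwd_cut(0.05, 4.03, 10)
  expect_lt(x_floor, fz$pf_r)
  x_in_cap <- (x_floor + fz$pf_r) / 2
  expect_equal(membership(fz, x_in_cap), 0.05)
  expect_gt(membership(fz, x_floor - 0.01), 0.05)
})

test_that("fuzzy_test reproduces the published decisions and ratios", {
  sp <- fitness_spec("x", 0, "larger_better", k = 6, phi1 = 0.4,
                     phi2 = 0.8)
  dec1 <- fuzzy_test(build_fuzzy_index(4.03, n = 10), sp)
  expect_equal(dec1$d_r, 0.178, tolerance = 0.005 / 0.178)
  expect_equal(dec1$d_t, 2.497, tolerance = 0.002 / 2.497)
  expect_equal(dec1$ratio, 0.071, tolerance = 0.002 / 0.071)
  expect_identical(dec1$outcome, "improve")
  dec2 <- fuzzy_test(build_fuzzy_index(6.09, n = 10), sp)
  expect_equal(dec2$ratio, 0.874, tolerance = 0.002 / 0.874)
  expect_identical(dec2$outcome, "maintain")
})

test_that("fuzzy_test boundary, unclamped and degenerate behavior", {
  fz <- build_fuzzy_index(4.03, n = 10)
  # k at the right endpoint: ratio exactly 0, reject
  sp0 <- fitness_spec("x", 0, "larger_better", k = fz$pf_r)
  dec0 <- fuzzy_test(fz, sp0)
  expect_equal(dec0$ratio, 0)
  expect_identical(dec0$outcome, "improve")
  # k beyond the endpoint: negative ratio, not clamped
  sp_neg <- fitness_spec("x", 0, "larger_better", k = fz$pf_r + 1)
  expect_lt(fuzzy_test(fz, sp_neg)$ratio, 0)
  # k below the apex: ratio above 1, not clamped
  sp_hi <- fitness_spec("x", 0, "larger_better", k = fz$pf_m - 1)
  expect_gt(fuzzy_test(fz, sp_hi)$ratio, 1)
  # degenerate fuzzy number (negative estimate can invert the ordering
  # only artificially; force it via a handcrafted object)
  fz_bad <- fz
  fz_bad$pf_m <- fz$pf_r
  expect_error(fuzzy_test(fz_bad, sp0), class = "pf_degenerate_fuzzy")
})

test_that("maintain implies the classical UCL test also retains H0", {
  # ratio >= phi2 > 0 forces d_r = ratio * d_t > 0, i.e. pf_r > k
  set.seed(99)
  sp <- fitness_spec("x", 0, "larger_better", k = 6)
  for (pf in runif(50, -1, 12)) {
    dec <- fuzzy_test(build_fuzzy_index(pf, n = 10), sp)
    if (dec$outcome == "maintain")
      expect_gt(upper_confidence_limit(pf, 10, 0.05), sp$k)
  }
})

test_that("negative estimates keep all formulas defined", {
  fz <- build_fuzzy_index(-1, n = 10)
  expect_lt(fz$pf_m, 0)
  expect_true(is.finite(fz$pf_r))
  # the z-term keeps pf_r above pf_m for mildly negative estimates
  expect_gt(fz$pf_r, fz$pf_m)
  dec <- fuzzy_test(fz, fitness_spec("x", 0, "larger_better", k = 6))
  expect_true(is.finite(dec$ratio))
  expect_identical(dec$outcome, "improve")
  # strongly negative estimates invert the endpoints: explicit error
  fz2 <- build_fuzzy_index(-2, n = 10)
  expect_error(fuzzy_test(fz2, fitness_spec("x", 0, "larger_better")),
               class = "pf_degenerate_fuzzy")
})
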
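test_that("biased autocorrelation matches direct evaluation of the estimator", {
  expect_equal(autocorrelation(c(1, 2, 3, 4), 2)$values, c(7.5, 5.0, 2.75))
  expect_equal(autocorrelation(c(1, 0, 0, 0), 2)$values, c(0.25, 0, 0))
  expect_equal(autocorrelation(rep(0, 8), 3)$values, rep(0, 4))
  expect_error(autocorrelation(numeric(0), 1), "empty")
  expect_error(autocorrelation(1:4, 4), "smaller")
})

test_that("biased ACF is positive-semidefinite in the lag-0 dominance sense", {
  withr::local_seed(77)
  for (i in 1:25) {
    x <- rnorm(sample(20:200, 1))
    r <- autocorrelation(x, 10)$values
    expect_gte(r[1], 0)
    expect_true(all(abs(r[-1]) <= r[1] + 1e-12))
  }
})

test_that("Levinson-Durbin reproduces the closed-form first two orders", {
  expect_equal(levinson_reflection(c(1, 0.5, 0.25), 2)$k, c(0.5, 0))
  expect_equal(levinson_reflection(c(1, 0, 0), 2)$k, c(0, 0))
  # closed forms k1 = r1/r0, k2 = (r2 - k1 r1)/((1 - k1^2) r0) on random ACFs
  withr::local_seed(5)
  for (i in 1:20) {
    r <- reflection_to_acf(random_stable_k(2), max_lag = 2)$values
    k <- levinson_reflection(r, 2)$k
    k1 <- r[2] / r[1]
    expect_equal(k[1], k1, tolerance = 1e-12)
    expect_equal(k[2], (r[3] - k1 * r[2]) / ((1 - k1^2) * r[1]),
                 tolerance = 1e-12)
  }
  expect_error(levinson_reflection(c(0, 0, 0), 2), "positive")
  expect_error(levinson_reflection(c(1, 0.5), 2), "exceeds")
})

test_that("degenerate (perfectly predictable) ACFs are rejected", {
  # ACF of a pure cosine is cos(w m): predictable -> E collapses at order 2
  r <- cos(0.3 * (0:4))
  expect_error(levinson_reflection(r, 4), "degenerate")
})

test_that("step-up and step-down are mutual inverses on random stable models", {
  expect_equal(ar_to_reflection(ar_spec(-0.5))$k, 0.5)
  expect_error(ar_to_reflection(ar_spec(-2)), "unstable")
  withr::local_seed(19)
  for (i in 1:200) {
    p <- sample(1:6, 1)
    k <- random_stable_k(p)
    spec <- reflection_to_ar(k)
    expect_equal(ar_to_reflection(spec)$k, k, tolerance = 1e-12)
  }
})

test_that("recursion matches a direct Yule-Walker Toeplitz solve", {
  withr::local_seed(23)
  for (i in 1:200) {
    p <- sample(1:6, 1)
    r <- reflection_to_acf(random_stable_k(p), max_lag = p)$values
    refl <- levinson_reflection(r, p)
    d_direct <- solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
    expect_equal(refl$predictor, d_direct, tolerance = 1e-10)
  }
})

test_that("raising the order changes only the newest coefficient", {
  withr::local_seed(29)
  for (i in 1:100) {
    p <- sample(1:5, 1)
    r <- reflection_to_acf(random_stable_k(p + 1), max_lag = p + 1)$values
    expect_equal(levinson_reflection(r, p + 1)$k[1:p],
                 levinson_reflection(r, p)$k, tolerance = 1e-12)
  }
})

test_that("reflection coefficients stay bounded with monotone residual energies", {
  withr::local_seed(31)
  for (i in 1:100) {
    x <- rnorm(250)
    refl <- levinson_reflection(autocorrelation(x, 6), 6)
    expect_true(all(abs(refl$k) < 1))
    E <- refl$residual_energies
    expect_true(all(E >= 0))
    expect_true(all(diff(E) <= 1e-12))
    expect_equal(E[1], autocorrelation(x, 1)$values[1])
    expect_equal(E[-1], (1 - refl$k^2) * E[-length(E)], tolerance = 1e-12)
  }
})

test_that("theoretical ACF of a model matches its long-run sample ACF", {
  k <- c(0.5, -0.3, 0.2)
  r_theory <- reflection_to_acf(k, max_lag = 6)$values
  x <- simulate_ar_process(reflection_to_ar(k), 2e5, seed = 91)
  r_sample <- autocorrelation(x, 6)$values
  expect_equal(r_sample / r_sample[1], r_theory / r_theory[1],
               tolerance = 0.02)
  expect_equal(r_sample[1], r_theory[1], tolerance = 0.03)
})

test_that("feature matrix has channel-major layout and bounded entries", {
  pair <- separable_model_pair()
  fset <- preprocess_sessions(list(simulate_recording(pair$a, seed = 6)))
  feats <- extract_reflection_features(fset, n_coeffs = 2)
  expect_identical(dim(feats), c(19L, 12L))
  expect_identical(colnames(feats)[1:4], c("C3_k1", "C3_k2", "P3_k1", "P3_k2"))
  expect_true(all(abs(feats) < 1))
  feats4 <- extract_reflection_features(fset, n_coeffs = 4)
  expect_identical(dim(feats4), c(19L, 24L))
  # feature values equal a per-frame, per-channel manual computation
  manual <- levinson_reflection(autocorrelation(fset$frames[7, 3, ], 2), 2)$k
  expect_equal(unname(feats[7, 5:6]), manual)
})

test_that("white-noise frames give near-zero reflection coefficients", {
  white <- class_model("B", list(0, 0, 0, 0, 0, 0)[1:6])
  # order-1 spec with k = 0 on every channel is white noise
  fset <- preprocess_sessions(
    lapply(1:4, function(s) simulate_recording(white, seed = 100 + s)),
    line_freq = NULL)
  feats <- extract_reflection_features(fset, n_coeffs = 2)
  # under whiteness each coefficient is ~N(0, 1/N): essentially all of the
  # 912 entries fall within 3/sqrt(N), and none approaches a real signature
  expect_gte(mean(abs(feats) < 3 / sqrt(250)), 0.99)
  expect_lt(max(abs(feats)), 0.3)
})

test_that("feature CSV round trip keeps values and labels", {
  pair <- separable_model_pair()
  fset <- preprocess_sessions(list(simulate_recording(pair$a, seed = 8,
                                                      session_id = "s1")))
  feats <- extract_reflection_features(fset)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(feats, path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), 19L)
  expect_true(all(c("C3_k1", "label", "session") %in% names(tab)))
  expect_equal(tab$C3_k1, unname(feats[, "C3_k1"]), tolerance = 1e-12)
  expect_identical(unique(tab$label), "M")
})
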
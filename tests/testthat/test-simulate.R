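test_that("white-noise AR simulation has unit variance and null reflection", {
  spec <- ar_spec(coeffs = 0, noise_var = 1)
  x <- simulate_ar_process(spec, 1e5, seed = 97)
  expect_equal(var(x), 1, tolerance = 0.02)
  k <- levinson_reflection(autocorrelation(x, 2), 2)$k
  expect_lt(max(abs(k)), 0.02)
})

test_that("simulated AR processes recover their reflection signature", {
  target <- c(0.6, -0.4)
  x <- simulate_ar_process(reflection_to_ar(target), 1e5, seed = 101)
  k <- levinson_reflection(autocorrelation(x, 2), 2)$k
  expect_lt(max(abs(k - target)), 0.02)
  expect_error(simulate_ar_process(ar_spec(-2), 100, seed = 1), "unstable")
})

test_that("simulation is deterministic and leaves the global RNG untouched", {
  spec <- reflection_to_ar(c(0.3, 0.2))
  set.seed(999)
  before <- .Random.seed
  x1 <- simulate_ar_process(spec, 500, seed = 103)
  expect_identical(.Random.seed, before)
  x2 <- simulate_ar_process(spec, 500, seed = 103)
  expect_identical(x1, x2)
  expect_false(identical(x1, simulate_ar_process(spec, 500, seed = 104)))
})

test_that("simulated recordings match the acquisition geometry", {
  model <- separable_model_pair()$a
  rec <- simulate_recording(model, seed = 107)
  expect_identical(dim(rec$data), c(6L, 2500L))
  expect_equal(rec$fs, 250)
  expect_identical(rec$task_label, "M")
  expect_identical(rec$channel_labels, c("C3", "P3", "O1", "C4", "P4", "O2"))
  expect_identical(simulate_recording(model, seed = 107)$data, rec$data)
  # channels are independent streams, not copies
  expect_gt(min(apply(rec$data, 1, sd)), 0)
  expect_lt(abs(cor(rec$data[1, ], rec$data[4, ])), 0.1)
})

test_that("line interference appears at 60 Hz and the notch removes it", {
  model <- class_model("M", c(0.6, -0.4), line_amp = 2)
  rec <- simulate_recording(model, seed = 109)
  pg60 <- function(r) {
    n <- ncol(r$data)
    bin <- 60 * n / r$fs + 1
    vapply(seq_len(nrow(r$data)), function(i) {
      p <- Mod(stats::fft(r$data[i, ]))^2 / n
      p[bin] / sum(p[2:(n %/% 2)])
    }, numeric(1))
  }
  expect_gt(min(pg60(rec)), 0.2)          # dominant line peak on every channel
  cleaned <- notch_filter(rec, 60)
  expect_lt(max(pg60(cleaned)), 1e-4)
})

test_that("two-class datasets are labeled, sized and seeded correctly", {
  pair <- separable_model_pair()
  recs <- make_two_class_dataset(pair$a, pair$b, 10, seed = 113, duration = 1)
  expect_length(recs, 20)
  labs <- vapply(recs, `[[`, character(1), "task_label")
  expect_identical(sum(labs == "M"), 10L)
  expect_identical(sum(labs == "C"), 10L)
  expect_identical(anyDuplicated(vapply(recs, `[[`, character(1),
                                        "subject_id")), 0L)
  again <- make_two_class_dataset(pair$a, pair$b, 10, seed = 113,
                                  duration = 1)
  expect_identical(recs[[3]]$data, again[[3]]$data)
  # distinct sessions of one class are different realizations
  expect_false(identical(recs[[1]]$data, recs[[2]]$data))
})

test_that("theoretical Yule-Walker ACF matches the long-run sample ACF", {
  k <- c(-0.5, 0.3, -0.1)
  spec <- reflection_to_ar(k, noise_var = 2)
  r_theory <- reflection_to_acf(k, max_lag = 5, noise_var = 2)$values
  x <- simulate_ar_process(spec, 2e5, seed = 127)
  r_sample <- autocorrelation(x, 5)$values
  expect_equal(r_sample, r_theory, tolerance = 0.03)
  # and the theoretical sequence satisfies the Yule-Walker relation itself
  d <- levinson_reflection(r_theory, 3)$predictor
  expect_equal(unname(solve(stats::toeplitz(r_theory[1:3]), r_theory[2:4])),
               d, tolerance = 1e-10)
})

test_that("class models read back from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "task_m:",
    "  label: M",
    "  k:",
    "  - [0.6, -0.4]",
    "  - [0.6, -0.4]",
    "  channel_labels: [C3, C4]",
    "  noise_var: 1.5",
    "  line_amp: 0.5"), path)
  models <- read_class_models_yaml(path)
  expect_length(models, 1)
  m <- models$task_m
  expect_s3_class(m, "class_model")
  expect_identical(m$label, "M")
  expect_identical(m$channel_labels, c("C3", "C4"))
  expect_equal(m$line_amp, 0.5)
  expect_equal(m$k[[1]], c(0.6, -0.4))
})

test_that("unstable class models are rejected", {
  expect_error(class_model("M", c(1.2, 0)), "unstable|\\|k\\|")
  expect_error(class_model("M", list(0.5)), "per channel")
})
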
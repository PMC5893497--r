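test_that("band power concentrates where a pure tone lives", {
  fs <- 250
  t <- (0:249) / fs
  x <- sin(2 * pi * 10 * t)                    # exactly on a DFT bin
  bands <- eeg_bands()
  total <- band_power(x, band_definition("all", 0, fs / 2), fs)
  expect_gte(band_power(x, bands$alpha, fs), 0.95 * total)
  expect_lte(band_power(x, bands$delta, fs), 0.01 * total)
  expect_identical(band_power(rep(0, 250), bands$alpha, fs), 0)
  expect_error(band_power(x, band_definition("bad", 40, 130), fs), "Nyquist")
})

test_that("band powers over a disjoint partition conserve total power", {
  withr::local_seed(41)
  fs <- 250
  edges <- c(0, 4, 7, 13, 20, 37, fs / 2)
  parts <- lapply(seq_len(length(edges) - 1), function(i)
    band_definition(paste0("b", i), edges[i], edges[i + 1]))
  for (rep in 1:10) {
    x <- rnorm(250)
    pg <- Mod(stats::fft(x))^2 / 250
    total <- sum(pg[1:126])
    # interior edges fall between bins (non-integer Hz offsets avoided by
    # construction: bin spacing is 1 Hz, edges at integers are counted once
    # in the lower band via strict/inclusive pairing below)
    covered <- band_power(x, parts[[1]], fs) +
      sum(vapply(parts[-1], function(b)
        band_power(x, band_definition(b$name, b$f_lo + 0.5, b$f_hi), fs),
        numeric(1)))
    expect_equal(covered, total, tolerance = 1e-9)
  }
})

test_that("white-noise band power is proportional to bandwidth", {
  withr::local_seed(43)
  wide <- band_definition("w", 40, 100)
  narrow <- band_definition("n", 8, 13)
  pw <- replicate(200, {
    x <- rnorm(250)
    c(band_power(x, wide, 250), band_power(x, narrow, 250))
  })
  # expected power scales with bin count: 61 bins vs 6 bins
  expect_equal(mean(pw[1, ]) / mean(pw[2, ]), 61 / 6,
               tolerance = 0.15 * 61 / 6)
})

test_that("asymmetry ratio matches its definition and is antisymmetric", {
  expect_identical(asymmetry_ratio(2, 2), 0)
  expect_identical(asymmetry_ratio(1, 0), 1)
  expect_equal(asymmetry_ratio(3, 1), 0.5)
  expect_error(asymmetry_ratio(0, 0), "undefined")
  expect_error(asymmetry_ratio(-1, 1), "nonnegative")
  withr::local_seed(47)
  for (i in 1:20) {
    p <- runif(2, 0, 5)
    a <- asymmetry_ratio(p[1], p[2])
    expect_equal(a, -asymmetry_ratio(p[2], p[1]))
    expect_true(a >= -1 && a <= 1)
  }
})

test_that("PAR feature sets have the documented dimensions and layout", {
  pair <- separable_model_pair()
  fset <- preprocess_sessions(list(simulate_recording(pair$a, seed = 15)))
  p4 <- assemble_par_features(fset, "PAR4")
  p5 <- assemble_par_features(fset, "PAR5")
  p6 <- assemble_par_features(fset, "PAR6")
  expect_identical(ncol(p4), 60L)   # 4*6 + 4*3*3
  expect_identical(ncol(p5), 75L)   # 5*6 + 5*3*3
  expect_identical(ncol(p6), 90L)   # 6*6 + 6*3*3
  expect_identical(nrow(p4), 19L)
  expect_identical(colnames(p4)[1], "pow_delta_C3")
  expect_identical(colnames(p4)[25], "asym_delta_C3_C4")
  # powers nonnegative, ratios bounded
  expect_true(all(p4[, 1:24] >= 0))
  expect_true(all(abs(p4[, 25:60]) <= 1))
  # an asymmetry column equals Eq.-style recomputation from power columns
  a_manual <- (p4[, "pow_alpha_C3"] - p4[, "pow_alpha_P4"]) /
    (p4[, "pow_alpha_C3"] + p4[, "pow_alpha_P4"])
  expect_equal(unname(p4[, "asym_alpha_C3_P4"]), unname(a_manual),
               tolerance = 1e-12)
})

test_that("hemisphere coverage is required for PAR features", {
  rec <- toy_recording(nch = 2)                 # C3, P3: both left
  rec$hemisphere_map[] <- "left"
  fset <- frame_signal(normalize_recording(rec))
  expect_error(assemble_par_features(fset, "PAR4"), "hemisphere")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 250
  t <- (0:(4 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  alpha <- eeg_bands()$alpha
  tone10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), nrow = 1,
                                 dimnames = list("C3", NULL)), fs = fs)
  tone50 <- eeg_recording(matrix(sin(2 * pi * 50 * t), nrow = 1,
                                 dimnames = list("C3", NULL)), fs = fs)
  # avoid filtfilt edge transients in the RMS comparison
  mid <- 200:800
  in_band <- bandpass(tone10, alpha)
  expect_lt(abs(rms(in_band$data[1, mid]) / rms(tone10$data[1, mid]) - 1),
            0.05)
  out_band <- bandpass(tone50, alpha)
  atten_db <- 20 * log10(rms(tone50$data[1, mid]) / rms(out_band$data[1, mid]))
  expect_gt(atten_db, 30)
  expect_error(bandpass(tone10, band_definition("bad", 40, 130)), "Nyquist")
})
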
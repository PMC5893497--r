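#' EEG frequency-band definitions
#'
#' `band_definition()` builds a single named band; `eeg_bands()` returns the
#' conventional set used throughout: delta (0.1-4 Hz, the lower edge
#' matching a typical 0.1-100 Hz acquisition passband), theta (4-7 Hz),
#' alpha (8-13 Hz), beta (14-20 Hz), gamma (24-37 Hz) and a high band
#' (40-100 Hz).
#'
#' @param name Band name.
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi`.
#' @return `band_definition()`: a `band_definition` object; `eeg_bands()`:
#'   a named list of them.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || length(f_lo) != 1L ||
      length(f_hi) != 1L || f_lo < 0 || f_lo >= f_hi)
    stop("band edges must satisfy 0 <= f_lo < f_hi")
  structure(list(name = as.character(name), f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
eeg_bands <- function() {
  list(
    delta = band_definition("delta", 0.1, 4),
    theta = band_definition("theta", 4, 7),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 14, 20),
    gamma = band_definition("gamma", 24, 37),
    high  = band_definition("high", 40, 100)
  )
}

check_band <- function(band, fs) {
  stopifnot(inherits(band, "band_definition"))
  if (band$f_hi > fs / 2)
    stop("band ", band$name, " (", band$f_lo, "-", band$f_hi,
         " Hz) exceeds the Nyquist frequency ", fs / 2, " Hz")
  invisible(band)
}

#' Spectral power of a frame in a frequency band
#'
#' Sums the raw one-sided periodogram ordinates (squared DFT magnitudes
#' divided by the frame length) over the bins whose frequencies fall inside
#' `[f_lo, f_hi]`, edges inclusive. Band powers taken over a disjoint
#' partition of `[0, fs/2]` therefore add up exactly to the total
#' periodogram power of the frame.
#'
#' @param x Numeric vector, one frame of one channel.
#' @param band A [band_definition()].
#' @param fs Sampling rate in Hz.
#' @return Nonnegative power (signal-power units).
#' @export
band_power <- function(x, band, fs) {
  check_band(band, fs)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1L) stop("empty frame")
  pg <- Mod(stats::fft(x))^2 / n
  nyq <- n %/% 2L
  freqs <- (0:nyq) * fs / n
  keep <- freqs >= band$f_lo & freqs <= band$f_hi
  sum(pg[seq_len(nyq + 1L)][keep])
}

#' Inter-hemispheric asymmetry ratio
#'
#' The normalized power difference between a left-hemisphere electrode i
#' and a right-hemisphere electrode j within one band:
#' \deqn{A(i, j) = \frac{P(i) - P(j)}{P(i) + P(j)},}
#' bounded in \[-1, 1\] and antisymmetric in its arguments.
#'
#' @param p_i Band power at the left electrode (nonnegative).
#' @param p_j Band power at the right electrode (nonnegative).
#' @return The ratio in \[-1, 1\].
#' @examples
#' asymmetry_ratio(3, 1)  # 0.5
#' @export
asymmetry_ratio <- function(p_i, p_j) {
  if (!is.numeric(p_i) || !is.numeric(p_j) || p_i < 0 || p_j < 0)
    stop("band powers must be nonnegative")
  if (p_i + p_j <= 0)
    stop("asymmetry ratio undefined: both powers are zero")
  (p_i - p_j) / (p_i + p_j)
}

#' Band-power + asymmetry-ratio feature sets (PAR4/PAR5/PAR6)
#'
#' Assembles the baseline feature families built from per-band spectral
#' power and inter-hemispheric asymmetry ratios. PAR4 uses the four bands
#' delta/theta/alpha/beta; PAR5 adds gamma; PAR6 adds the 40-100 Hz high
#' band. Per frame the features are, in order: band powers (band-major,
#' channel-minor: `pow_<band>_<ch>`), then every left x right electrode
#' pair's asymmetry ratio per band (band-major, left-electrode-major:
#' `asym_<band>_<chL>_<chR>`). With N_b bands, l channels split into N_i
#' left and N_j right, the dimension is N_b x l + N_b x N_i x N_j — for a
#' six-channel montage 60, 75 and 90 columns for PAR4, PAR5 and PAR6,
#' against 12 for two reflection coefficients per channel.
#'
#' @param fset An `eeg_frameset` whose hemisphere map covers both sides.
#' @param variant `"PAR4"`, `"PAR5"` or `"PAR6"`.
#' @param bands Band set to draw from; defaults to [eeg_bands()].
#' @return A [feature_matrix()].
#' @export
assemble_par_features <- function(fset, variant = c("PAR4", "PAR5", "PAR6"),
                                  bands = eeg_bands()) {
  stopifnot(inherits(fset, "eeg_frameset"))
  variant <- match.arg(variant)
  band_names <- switch(variant,
    PAR4 = c("delta", "theta", "alpha", "beta"),
    PAR5 = c("delta", "theta", "alpha", "beta", "gamma"),
    PAR6 = c("delta", "theta", "alpha", "beta", "gamma", "high"))
  missing_b <- setdiff(band_names, names(bands))
  if (length(missing_b))
    stop("band set lacks definition(s): ", paste(missing_b, collapse = ", "))
  use <- bands[band_names]
  for (b in use) check_band(b, fset$fs)

  side <- fset$hemisphere_map[fset$channel_labels]
  left <- fset$channel_labels[side == "left"]
  right <- fset$channel_labels[side == "right"]
  if (length(left) == 0L || length(right) == 0L)
    stop("hemisphere map must place at least one channel on each side")

  d <- dim(fset$frames)
  nf <- d[1]; nch <- d[2]
  labels <- fset$channel_labels
  nb <- length(use)
  n_pow <- nb * nch
  n_asym <- nb * length(left) * length(right)
  X <- matrix(NA_real_, nrow = nf, ncol = n_pow + n_asym)

  pow_names <- as.vector(vapply(band_names, function(b)
    paste0("pow_", b, "_", labels), character(nch)))
  asym_names <- unlist(lapply(band_names, function(b)
    unlist(lapply(left, function(li) paste0("asym_", b, "_", li, "_", right)))),
    use.names = FALSE)
  colnames(X) <- c(pow_names, asym_names)

  li_idx <- match(left, labels)
  ri_idx <- match(right, labels)
  for (f in seq_len(nf)) {
    P <- matrix(NA_real_, nrow = nb, ncol = nch)
    for (b in seq_len(nb))
      for (c in seq_len(nch))
        P[b, c] <- band_power(fset$frames[f, c, ], use[[b]], fset$fs)
    X[f, seq_len(n_pow)] <- as.vector(t(P))
    at <- n_pow
    for (b in seq_len(nb))
      for (li in li_idx)
        for (ri in ri_idx) {
          at <- at + 1L
          X[f, at] <- asymmetry_ratio(P[b, li], P[b, ri])
        }
  }
  prov <- data.frame(
    kind = c(rep("power", n_pow), rep("asymmetry", n_asym)),
    band = c(rep(band_names, each = nch),
             rep(band_names, each = length(left) * length(right))),
    stringsAsFactors = FALSE
  )
  feature_matrix(X, labels = fset$frame_labels, sessions = fset$session_ids,
                 provenance = prov)
}

#' Zero-phase band-pass filtering of a recording
#'
#' Band-limits every channel with a 4th-order Butterworth band-pass design
#' ([signal::butter()]), applied with exactly zero phase by multiplying the
#' channel spectrum with the filter's squared magnitude response — the same
#' net response as a forward-backward pass, without edge transients,
#' matching the notch-filter convention. Used to study how restricting the
#' analysis to a single conventional band affects downstream
#' classification.
#'
#' @param rec An [eeg_recording()].
#' @param band A [band_definition()] valid for the recording's `fs`.
#' @return The band-limited recording.
#' @export
bandpass <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_band(band, rec$fs)
  lo <- max(band$f_lo, 1e-4 * rec$fs / 2)
  w <- c(lo, band$f_hi) / (rec$fs / 2)
  if (w[2] >= 1) w[2] <- 1 - 1e-6
  bf <- signal::butter(2, w, type = "pass")
  out <- rec
  for (i in seq_len(nrow(rec$data)))
    out$data[i, ] <- zerophase_filter(bf$b, bf$a, rec$data[i, ])
  out
}
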
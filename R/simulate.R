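#' Class model for synthetic EEG generation
#'
#' Describes one mental-task class as a set of per-channel stable
#' autoregressive models plus an optional common 60 Hz line-interference
#' component. Channel dynamics are specified in reflection-coefficient
#' space and converted through the step-up recursion, which guarantees
#' stability by construction (every `|k| < 1` maps to a stable AR model).
#'
#' @param label Task letter attached to generated recordings (`"M"`, `"C"`,
#'   `"L"`, `"B"`, `"R"` in the five-task protocol, but any string works).
#' @param k Per-channel reflection coefficients: either a single numeric
#'   vector (shared by all channels) or a list with one vector per channel.
#'   All entries must satisfy `|k| < 1`.
#' @param channel_labels Channel names; default the six-electrode montage
#'   C3, P3, O1, C4, P4, O2.
#' @param noise_var Excitation variance \eqn{\sigma_u^2} of the white
#'   Gaussian drive, shared by all channels.
#' @param line_amp Amplitude of an additive 60 Hz sinusoid injected into
#'   every channel (0 = none).
#' @param line_freq Line-interference frequency, Hz.
#' @return A `class_model` object.
#' @export
class_model <- function(label, k,
                        channel_labels = c("C3", "P3", "O1",
                                           "C4", "P4", "O2"),
                        noise_var = 1, line_amp = 0, line_freq = 60) {
  if (!is.list(k)) k <- rep(list(as.numeric(k)), length(channel_labels))
  if (length(k) != length(channel_labels))
    stop("`k` must give one coefficient vector per channel")
  specs <- lapply(k, function(kc) {
    kc <- as.numeric(kc)
    if (length(kc) < 1L || length(kc) > 6L)
      stop("per-channel model order must be between 1 and 6")
    if (any(abs(kc) >= 1))
      stop("unstable channel model: all reflection coefficients need |k| < 1")
    reflection_to_ar(kc, noise_var = noise_var)
  })
  if (!is.numeric(line_amp) || line_amp < 0)
    stop("`line_amp` must be nonnegative")
  structure(list(label = as.character(label), specs = specs, k = k,
                 channel_labels = channel_labels, noise_var = noise_var,
                 line_amp = line_amp, line_freq = line_freq),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat("<class_model> task ", x$label, ", ", length(x$specs),
      " channel(s), sigma_u^2 = ", x$noise_var,
      if (x$line_amp > 0) paste0(", ", x$line_freq, " Hz line amp ",
                                 x$line_amp) else "", "\n", sep = "")
  invisible(x)
}

#' Load class models from a YAML file
#'
#' The file maps model names to entries with fields `label`, `k` (a list of
#' per-channel coefficient vectors or one shared vector), and optional
#' `channel_labels`, `noise_var`, `line_amp`, `line_freq`.
#'
#' @param path Path to the YAML file.
#' @return A named list of [class_model()] objects.
#' @export
read_class_models_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(entry) {
    do.call(class_model, entry[intersect(names(entry),
      c("label", "k", "channel_labels", "noise_var", "line_amp",
        "line_freq"))])
  })
}

#' Simulate a stable AR process
#'
#' Draws a realization of \eqn{x(n) = -\sum_k a_k x(n-k) + u(n)} with
#' zero-mean Gaussian excitation of variance `noise_var`, discards a
#' burn-in prefix so the retained samples are effectively stationary, and
#' is fully reproducible for a fixed seed. The global random state is left
#' untouched.
#'
#' @param spec An [ar_spec()]; rejected if unstable.
#' @param n_samples Number of samples to return.
#' @param seed Integer seed.
#' @param burn_in Samples generated and discarded before the output.
#' @return Numeric vector of length `n_samples`.
#' @export
simulate_ar_process <- function(spec, n_samples, seed, burn_in = 1000) {
  stopifnot(inherits(spec, "ar_spec"))
  if (!is.numeric(n_samples) || n_samples < 1L)
    stop("`n_samples` must be at least 1")
  ar_to_reflection(spec)  # errors if unstable
  withr::with_seed(as.integer(seed), {
    u <- stats::rnorm(n_samples + burn_in, mean = 0,
                      sd = sqrt(spec$noise_var))
    x <- stats::filter(u, filter = -spec$coeffs, method = "recursive")
    as.numeric(x)[burn_in + seq_len(n_samples)]
  })
}

#' Simulate a multichannel EEG recording
#'
#' Generates one session of synthetic scalp EEG: each channel is an
#' independent realization of its class model's AR process (independent
#' excitation streams, per-channel seeds derived deterministically from
#' `seed`), plus the model's optional common 60 Hz line component. Defaults
#' emulate the acquisition geometry this package targets: 6 channels at
#' 250 Hz for 10 s.
#'
#' @param model A [class_model()].
#' @param fs Sampling rate in Hz.
#' @param duration Session length in seconds.
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param session_id Identifier stored on the recording.
#' @return An [eeg_recording()] labeled with the model's task letter.
#' @export
simulate_recording <- function(model, fs = 250, duration = 10, seed = 1,
                               session_id = NULL) {
  stopifnot(inherits(model, "class_model"))
  ns <- as.integer(round(fs * duration))
  if (ns < 1L) stop("duration x fs must give at least one sample")
  nch <- length(model$specs)
  data <- matrix(NA_real_, nrow = nch, ncol = ns)
  for (c in seq_len(nch)) {
    ch_seed <- (as.integer(seed) * 131L + c * 7919L) %% 2147483629L
    data[c, ] <- simulate_ar_process(model$specs[[c]], ns, seed = ch_seed)
  }
  if (model$line_amp > 0) {
    t <- (seq_len(ns) - 1L) / fs
    line <- model$line_amp * sin(2 * pi * model$line_freq * t)
    data <- sweep(data, 2L, line, `+`)
  }
  eeg_recording(data, fs = fs, channel_labels = model$channel_labels,
                task_label = model$label, subject_id = session_id)
}

#' Simulate a labeled two-class session collection
#'
#' Produces `n_sessions_per_class` sessions from each of two class models,
#' with distinct session identifiers and deterministic per-session seeds
#' derived from `seed` — the synthetic stand-in for a two-task recording
#' campaign on which the whole pipeline (preprocess, features,
#' leave-one-out classification) can be exercised.
#'
#' @param model_a,model_b [class_model()] objects for the two tasks.
#' @param n_sessions_per_class Sessions per class (>= 1).
#' @param seed Integer master seed.
#' @param fs,duration Acquisition parameters per [simulate_recording()].
#' @return A list of `2 * n_sessions_per_class` labeled [eeg_recording()]s
#'   (class A sessions first).
#' @export
make_two_class_dataset <- function(model_a, model_b, n_sessions_per_class,
                                   seed = 1, fs = 250, duration = 10) {
  stopifnot(inherits(model_a, "class_model"), inherits(model_b, "class_model"))
  if (!is.numeric(n_sessions_per_class) || n_sessions_per_class < 1L)
    stop("`n_sessions_per_class` must be at least 1")
  n <- as.integer(n_sessions_per_class)
  recs <- vector("list", 2L * n)
  for (s in seq_len(n)) {
    recs[[s]] <- simulate_recording(
      model_a, fs = fs, duration = duration,
      seed = (as.integer(seed) * 977L + s * 104729L) %% 2147483629L,
      session_id = paste0(model_a$label, "_s", s))
    recs[[n + s]] <- simulate_recording(
      model_b, fs = fs, duration = duration,
      seed = (as.integer(seed) * 977L + (n + s) * 104729L) %% 2147483629L,
      session_id = paste0(model_b$label, "_s", s))
  }
  recs
}
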
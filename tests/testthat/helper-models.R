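# Shared fixtures: all synthetic, built in code at test time.

# Two task models with mirrored reflection signatures on every channel --
# strongly separable in reflection-coefficient space.
separable_model_pair <- function(line_amp = 0) {
  list(a = class_model("M", c(0.6, -0.4), line_amp = line_amp),
       b = class_model("C", c(-0.6, 0.4), line_amp = line_amp))
}

# Identical dynamics under two different labels: no class signal at all.
null_model_pair <- function() {
  list(a = class_model("A", c(0.2, -0.1)),
       b = class_model("B", c(0.2, -0.1)))
}

# A stable random reflection sequence (|k| <= 0.95 keeps models comfortably
# inside the unit-circle bound).
random_stable_k <- function(p, kmax = 0.95) stats::runif(p, -kmax, kmax)

# Independent framing oracle: enumerate window starts one by one.
naive_frame_count <- function(n_samples, frame_len, shift_len) {
  count <- 0L
  start <- 1L
  while (start + frame_len - 1L <= n_samples) {
    count <- count + 1L
    start <- start + shift_len
  }
  count
}

# One short recording with a deterministic signal, for I/O round trips.
toy_recording <- function(n = 500, fs = 250, nch = 6) {
  labels <- c("C3", "P3", "O1", "C4", "P4", "O2")[seq_len(nch)]
  t <- (seq_len(n) - 1) / fs
  data <- t(vapply(seq_len(nch), function(i)
    sin(2 * pi * (5 + i) * t) + 0.1 * cos(2 * pi * 40 * t + i),
    numeric(n)))
  eeg_recording(data, fs = fs, channel_labels = labels,
                task_label = "M", subject_id = "s1")
}
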
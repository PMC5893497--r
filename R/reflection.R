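#' Biased autocorrelation of a signal frame
#'
#' Computes the biased sample autocorrelation
#' \deqn{r_x(m) = \frac{1}{N}\sum_{n=0}^{N-1-m} x(n)\,x(n+m), \quad m \ge 0,}
#' with divisor `N` at every lag. The biased estimator is used deliberately:
#' it yields a positive-semidefinite autocorrelation sequence, which in turn
#' guarantees that all reflection coefficients derived from it are bounded
#' by one in magnitude.
#'
#' @param x Numeric vector, one frame of one channel.
#' @param max_lag Largest lag to compute (`1 <= max_lag < length(x)`).
#' @return An `acf_sequence`: list with `values` (lags `0..max_lag`) and
#'   `n_samples`.
#' @examples
#' autocorrelation(c(1, 2, 3, 4), max_lag = 2)$values  # 7.5 5.0 2.75
#' @export
autocorrelation <- function(x, max_lag) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1L) stop("empty frame")
  if (!is.numeric(max_lag) || length(max_lag) != 1L || max_lag < 1L ||
      max_lag != round(max_lag))
    stop("`max_lag` must be a positive integer")
  if (max_lag >= n)
    stop("`max_lag` (", max_lag, ") must be smaller than the frame length (",
         n, ")")
  vals <- vapply(0:max_lag, function(m)
    sum(x[seq_len(n - m)] * x[seq_len(n - m) + m]) / n, numeric(1))
  acf_sequence(vals, n)
}

#' @rdname autocorrelation
#' @param values Autocorrelation values at lags `0..max_lag`.
#' @param n_samples Number of samples the estimate is based on.
#' @export
acf_sequence <- function(values, n_samples = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty autocorrelation sequence")
  structure(list(values = values, n_samples = n_samples),
            class = "acf_sequence")
}

#' Reflection coefficients via the Levinson-Durbin recursion
#'
#' Solves the Yule-Walker system order-recursively, producing one reflection
#' coefficient per order increment without any matrix inversion:
#' \deqn{k_m = \frac{r_x(m) - \sum_{j=1}^{m-1} d_j^{(m-1)} r_x(m-j)}{E^{(m-1)}},}
#' with predictor update \eqn{d_j^{(m)} = d_j^{(m-1)} - k_m d_{m-j}^{(m-1)}},
#' \eqn{d_m^{(m)} = k_m}, and residual energy
#' \eqn{E^{(m)} = (1-k_m^2) E^{(m-1)}}, \eqn{E^{(0)} = r_x(0)}. The closed
#' forms for the first two orders are \eqn{k_1 = r_x(1)/r_x(0)} and
#' \eqn{k_2 = (r_x(2) - k_1 r_x(1)) / ((1-k_1^2) r_x(0))}.
#'
#' For a stable autoregressive signal every \eqn{|k_m| < 1} and the residual
#' energies are nonnegative and nonincreasing. Raising the order from p to
#' p+1 leaves \eqn{k_1..k_p} unchanged — only the newest coefficient is
#' added, which is what makes these features robust to the model-order
#' choice. The predictor sign convention is \eqn{d_j = -a_j} at full order
#' for the AR model \eqn{x(n) = -\sum a_k x(n-k) + u(n)}; `k[m]` equals the
#' lag-m partial autocorrelation of the signal.
#'
#' @param acf An `acf_sequence` (or bare numeric vector of lags `0..m`).
#' @param order Number of reflection coefficients p (`order <=` max lag).
#' @param eps Relative degeneracy threshold: the recursion aborts when the
#'   residual energy falls below `eps * r_x(0)`, which signals a perfectly
#'   predictable (degenerate) frame.
#' @return A `reflection_set`: list with `k` (length `order`),
#'   `residual_energies` (`E^(0)..E^(p)`, length `order + 1`) and
#'   `predictor` (final-stage coefficients `d^(p)`).
#' @examples
#' levinson_reflection(c(1, 0.5, 0.25), order = 2)$k  # 0.5 0
#' @export
levinson_reflection <- function(acf, order, eps = 1e-12) {
  r <- if (inherits(acf, "acf_sequence")) acf$values else as.numeric(acf)
  if (!is.numeric(order) || length(order) != 1L || order < 1L ||
      order != round(order))
    stop("`order` must be a positive integer")
  if (order > length(r) - 1L)
    stop("`order` (", order, ") exceeds the largest available lag (",
         length(r) - 1L, ")")
  r0 <- r[1]
  if (!is.finite(r0) || r0 <= 0)
    stop("r_x(0) must be positive; got ", r0)
  k <- numeric(order)
  E <- numeric(order + 1L)
  E[1] <- r0
  d <- numeric(0)
  for (m in seq_len(order)) {
    if (E[m] <= eps * r0)
      stop("degenerate frame: residual energy E^(", m - 1L,
           ") = ", E[m], " is below ", eps, " * r_x(0)")
    acc <- r[m + 1L]
    if (m > 1L)
      acc <- acc - sum(d * r[m + 1L - seq_len(m - 1L)])
    km <- acc / E[m]
    if (m > 1L)
      d <- d - km * rev(d)
    d <- c(d, km)
    k[m] <- km
    E[m + 1L] <- (1 - km^2) * E[m]
  }
  structure(list(k = k, residual_energies = E, predictor = d),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat("<reflection_set> order", length(x$k), "\n  k:",
      paste(signif(x$k, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Autoregressive model specification
#'
#' Coefficients follow the convention
#' \eqn{x(n) = -\sum_{k=1}^{p} a_k x(n-k) + u(n)} with white Gaussian
#' excitation `u` of variance `noise_var`.
#'
#' @param coeffs Numeric vector `a_1..a_p`.
#' @param noise_var Excitation variance \eqn{\sigma_u^2 > 0}.
#' @return An `ar_spec` object.
#' @export
ar_spec <- function(coeffs, noise_var = 1) {
  coeffs <- as.numeric(coeffs)
  if (!is.numeric(noise_var) || length(noise_var) != 1L || noise_var <= 0)
    stop("`noise_var` must be a positive scalar")
  structure(list(coeffs = coeffs, noise_var = noise_var), class = "ar_spec")
}

#' Convert between AR coefficients and reflection coefficients
#'
#' `ar_to_reflection()` runs the step-down (reverse Levinson) recursion,
#' recovering `k_1..k_p` from the coefficients of an [ar_spec()]; it rejects
#' any model whose reflection sequence leaves the open unit interval, since
#' such a model is not stable. `reflection_to_ar()` runs the exact inverse
#' step-up recursion. The two are mutual inverses to machine precision.
#'
#' @param spec An [ar_spec()].
#' @return `ar_to_reflection()`: a `reflection_set` (residual energies are
#'   relative to \eqn{E^{(0)} = 1}); `reflection_to_ar()`: an [ar_spec()].
#' @examples
#' ar_to_reflection(ar_spec(-0.5))$k            # 0.5
#' reflection_to_ar(c(0.6, -0.4))$coeffs
#' @export
ar_to_reflection <- function(spec) {
  stopifnot(inherits(spec, "ar_spec"))
  p <- length(spec$coeffs)
  if (p < 1L) stop("AR order must be at least 1")
  d <- -spec$coeffs
  k <- numeric(p)
  predictor <- d
  for (m in rev(seq_len(p))) {
    km <- d[m]
    if (!is.finite(km) || abs(km) >= 1)
      stop("unstable AR specification: |k_", m, "| = ", abs(km), " >= 1")
    k[m] <- km
    if (m > 1L) {
      dm1 <- d[seq_len(m - 1L)]
      d <- (dm1 + km * rev(dm1)) / (1 - km^2)
    }
  }
  E <- cumprod(c(1, 1 - k^2))
  structure(list(k = k, residual_energies = E, predictor = predictor),
            class = "reflection_set")
}

#' @rdname ar_to_reflection
#' @param k Numeric vector of reflection coefficients (all `|k| < 1`), or a
#'   `reflection_set`.
#' @param noise_var Excitation variance attached to the resulting spec.
#' @export
reflection_to_ar <- function(k, noise_var = 1) {
  if (inherits(k, "reflection_set")) k <- k$k
  k <- as.numeric(k)
  if (length(k) < 1L) stop("need at least one reflection coefficient")
  if (any(!is.finite(k)) || any(abs(k) >= 1))
    stop("all reflection coefficients must satisfy |k| < 1")
  d <- numeric(0)
  for (m in seq_along(k)) {
    if (m > 1L) d <- d - k[m] * rev(d)
    d <- c(d, k[m])
  }
  ar_spec(coeffs = -d, noise_var = noise_var)
}

#' Theoretical autocorrelation of a stable AR model
#'
#' Generates the exact stationary autocorrelation sequence implied by a
#' reflection-coefficient sequence and excitation variance, by inverting the
#' Levinson-Durbin recursion lag by lag (and extending beyond the model
#' order through the Yule-Walker extrapolation
#' \eqn{r(m) = \sum_j d_j^{(p)} r(m-j)}). Useful as an exact oracle and to
#' manufacture valid autocorrelation sequences from random stable models.
#'
#' @param k Reflection coefficients (all `|k| < 1`), or a `reflection_set`.
#' @param max_lag Largest lag wanted (`>= length(k)`).
#' @param noise_var Excitation variance; `r(0) = noise_var / prod(1 - k^2)`.
#' @return An `acf_sequence` of lags `0..max_lag`.
#' @export
reflection_to_acf <- function(k, max_lag = length(k), noise_var = 1) {
  if (inherits(k, "reflection_set")) k <- k$k
  k <- as.numeric(k)
  p <- length(k)
  if (any(abs(k) >= 1)) stop("all reflection coefficients must satisfy |k| < 1")
  if (max_lag < p) stop("`max_lag` must be at least the model order")
  r <- numeric(max_lag + 1L)
  r[1] <- noise_var / prod(1 - k^2)
  E <- r[1]
  d <- numeric(0)
  for (m in seq_len(p)) {
    acc <- k[m] * E
    if (m > 1L)
      acc <- acc + sum(d * r[m + 1L - seq_len(m - 1L)])
    r[m + 1L] <- acc
    if (m > 1L) d <- d - k[m] * rev(d)
    d <- c(d, k[m])
    E <- (1 - k[m]^2) * E
  }
  if (max_lag > p)
    for (m in (p + 1L):max_lag)
      r[m + 1L] <- sum(d * r[m + 1L - seq_len(p)])
  acf_sequence(r)
}

#' Reflection-coefficient feature matrix of a frameset
#'
#' For every frame and channel, computes the biased autocorrelation up to
#' lag `n_coeffs` and runs the Levinson-Durbin recursion, collecting the
#' first `n_coeffs` reflection coefficients. With the default two
#' coefficients per channel a six-channel montage yields a 12-dimensional
#' feature vector per frame — the proposed compact alternative to band-power
#' feature sets. Columns are ordered channel-major (`C3_k1, C3_k2, P3_k1,
#' ...`); all entries lie strictly inside (-1, 1).
#'
#' @param fset An `eeg_frameset`.
#' @param n_coeffs Reflection coefficients per channel (default 2).
#' @return A `feature_matrix`: numeric matrix `n_frames x
#'   (n_coeffs * n_channels)` with attributes `labels` (per-frame task
#'   labels), `sessions` (per-frame session ids) and `provenance`
#'   (data frame of column origin: channel, coefficient index).
#' @export
extract_reflection_features <- function(fset, n_coeffs = 2) {
  stopifnot(inherits(fset, "eeg_frameset"))
  if (!is.numeric(n_coeffs) || length(n_coeffs) != 1L || n_coeffs < 1L ||
      n_coeffs != round(n_coeffs))
    stop("`n_coeffs` must be a positive integer")
  d <- dim(fset$frames)
  if (d[3] <= n_coeffs)
    stop("frame length (", d[3], ") must exceed `n_coeffs` (", n_coeffs, ")")
  nf <- d[1]; nch <- d[2]
  X <- matrix(NA_real_, nrow = nf, ncol = n_coeffs * nch)
  for (f in seq_len(nf)) {
    for (c in seq_len(nch)) {
      refl <- tryCatch(
        levinson_reflection(autocorrelation(fset$frames[f, c, ], n_coeffs),
                            order = n_coeffs),
        error = function(e)
          stop("frame ", f, ", channel ", fset$channel_labels[c], ": ",
               conditionMessage(e), call. = FALSE)
      )
      X[f, (c - 1L) * n_coeffs + seq_len(n_coeffs)] <- refl$k
    }
  }
  prov <- data.frame(
    channel = rep(fset$channel_labels, each = n_coeffs),
    coefficient = rep(seq_len(n_coeffs), times = nch),
    stringsAsFactors = FALSE
  )
  colnames(X) <- paste0(prov$channel, "_k", prov$coefficient)
  feature_matrix(X, labels = fset$frame_labels, sessions = fset$session_ids,
                 provenance = prov)
}

#' Frame-by-feature matrix with class labels
#'
#' Thin wrapper tying a numeric matrix to per-frame task labels, session
#' ids and column provenance; the common currency between feature
#' extraction and classification.
#'
#' @param x Numeric matrix, frames in rows.
#' @param labels Per-frame class labels (length `nrow(x)`).
#' @param sessions Per-frame session identifiers.
#' @param provenance Optional data frame describing each column's origin.
#' @return A `feature_matrix` (a numeric matrix with extra attributes).
#' @export
feature_matrix <- function(x, labels, sessions = NULL, provenance = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("`labels` must have one entry per row")
  if (is.null(sessions)) sessions <- rep(NA_character_, nrow(x))
  structure(x, labels = labels, sessions = as.character(sessions),
            provenance = provenance,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x), " frame(s) x ", ncol(x), " feature(s); ",
      "classes: ", paste(unique(attr(x, "labels")), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a feature matrix as CSV
#'
#' One row per frame: all feature columns (named as extracted), then
#' `label` and `session`.
#'
#' @param features A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  tab <- as.data.frame(unclass(features))
  tab$label <- attr(features, "labels")
  tab$session <- attr(features, "sessions")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
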
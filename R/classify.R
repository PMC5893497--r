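#' Kernel specification for the SVM classifier
#'
#' Describes the kernel and soft-margin penalty handed to the underlying
#' support-vector-machine solver ([e1071::svm()]). Kernels: `linear`
#' \eqn{x \cdot x'}; `quadratic` \eqn{(x \cdot x' + 1)^2}; `polynomial`
#' \eqn{(x \cdot x' + 1)^d} with default degree 3; `rbf`
#' \eqn{\exp(-\gamma \|x - x'\|^2)} with \eqn{\gamma = 1 / (\mathrm{n\_features}
#' \times \mathrm{var}(X))} computed from the feature matrix at fit time
#' unless overridden. Features are used as given (no internal rescaling),
#' so the kernels act on the feature values the extraction stage defines.
#'
#' @param kind One of `"linear"`, `"quadratic"`, `"polynomial"`, `"rbf"`.
#' @param degree Polynomial degree (`polynomial` only; `quadratic` is
#'   degree 2 by definition).
#' @param gamma RBF scale; `NULL` means the data-dependent default above.
#' @param cost Soft-margin penalty C > 0. Default 1.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("linear", "quadratic", "polynomial", "rbf"),
                        degree = 3, gamma = NULL, cost = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0)
    stop("`cost` must be a positive scalar")
  if (kind == "polynomial" &&
      (!is.numeric(degree) || degree < 1 || degree != round(degree)))
    stop("polynomial degree must be an integer >= 1")
  if (kind == "quadratic") degree <- 2
  structure(list(kind = kind, degree = degree, gamma = gamma, cost = cost),
            class = "kernel_spec")
}

# Translate a kernel_spec into e1071::svm() arguments for a given matrix.
svm_args <- function(kernel, X) {
  gamma <- kernel$gamma
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }
  switch(kernel$kind,
    linear = list(kernel = "linear", cost = kernel$cost),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = 1, coef0 = 1,
                     cost = kernel$cost),
    polynomial = list(kernel = "polynomial", degree = kernel$degree,
                      gamma = 1, coef0 = 1, cost = kernel$cost),
    rbf = list(kernel = "radial", gamma = gamma, cost = kernel$cost))
}

#' Leave-one-out cross-validated SVM classification
#'
#' Frame-level leave-one-out protocol for a two-class feature matrix: each
#' frame in turn is held out, an SVM with the requested kernel is trained
#' on all remaining frames, and the held-out frame is predicted. Overall
#' accuracy is the percentage of frames predicted correctly. Note that with
#' 50%-overlapping frames this protocol lets frames from the same session
#' appear in both train and test folds (deliberately, to mirror common BCI
#' evaluation practice); set `group_by_session = TRUE` to hold out all
#' frames of a session together instead.
#'
#' Decision ties exactly at the margin are resolved toward the
#' lexicographically smaller class label, so results are deterministic.
#'
#' @param features A [feature_matrix()] carrying exactly two distinct
#'   labels, each with at least two frames.
#' @param kernel A [kernel_spec()]. Default quadratic, the configuration of
#'   record for reflection-coefficient features.
#' @param group_by_session Hold out whole sessions instead of single
#'   frames.
#' @return A `cv_result`: list with `accuracy` (percent), `predicted`,
#'   `truth`, `n_frames` and `kernel`.
#' @export
loocv_classify <- function(features, kernel = kernel_spec("quadratic"),
                           group_by_session = FALSE) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(kernel, "kernel_spec"))
  X <- unclass(features)
  labels <- attr(features, "labels")
  attr(X, "labels") <- NULL
  attr(X, "sessions") <- NULL
  attr(X, "provenance") <- NULL
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("leave-one-out classification needs exactly two classes; got ",
         length(classes))
  if (min(table(labels)) < 2L)
    stop("each class needs at least two frames")
  y <- factor(labels, levels = classes)
  args <- svm_args(kernel, X)

  folds <- if (group_by_session) {
    sess <- attr(features, "sessions")
    lapply(unique(sess), function(s) which(sess == s))
  } else {
    as.list(seq_len(nrow(X)))
  }
  predicted <- character(nrow(X))
  for (hold in folds) {
    if (length(unique(labels[-hold])) < 2L)
      stop("a training fold contains a single class; need >= 2 frames per class")
    fit <- do.call(e1071::svm, c(list(
      x = X[-hold, , drop = FALSE], y = y[-hold], scale = FALSE,
      type = "C-classification"), args))
    dv <- attr(stats::predict(fit, X[hold, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    # decision.values column name is "<levelA>/<levelB>": positive -> levelA
    pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
    predicted[hold] <- ifelse(dv[, 1] > 0, pair[1],
                       ifelse(dv[, 1] < 0, pair[2], min(pair)))
  }
  structure(list(
    accuracy = 100 * mean(predicted == labels),
    predicted = predicted, truth = labels, n_frames = nrow(X),
    kernel = kernel), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$kernel$kind, " kernel, ", x$n_frames,
      " frames, leave-one-out accuracy ", round(x$accuracy, 2), "%\n",
      sep = "")
  invisible(x)
}

#' Serialize a cross-validation result as JSON
#'
#' @param result A `cv_result` from [loocv_classify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  jsonlite::write_json(list(
    accuracy = result$accuracy, n_frames = result$n_frames,
    kernel = result$kernel$kind, predicted = result$predicted,
    truth = result$truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Principal-component reduction of a feature matrix
#'
#' Projects the mean-centered feature matrix onto its leading principal
#' components (via [stats::prcomp()], no rescaling), in decreasing
#' explained-variance order, preserving labels and session ids.
#'
#' @param features A [feature_matrix()].
#' @param n_components Number of components to keep
#'   (`1 <= n_components <= n_features`).
#' @return A [feature_matrix()] of component scores, with attribute
#'   `explained_variance` (per-component variance fractions).
#' @export
pca_reduce <- function(features, n_components) {
  stopifnot(inherits(features, "feature_matrix"))
  X <- unclass(features)
  if (!is.numeric(n_components) || length(n_components) != 1L ||
      n_components < 1L || n_components > ncol(X) ||
      n_components != round(n_components))
    stop("`n_components` must be an integer in 1..", ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- feature_matrix(scores, labels = attr(features, "labels"),
                        sessions = attr(features, "sessions"))
  attr(out, "explained_variance") <- (pc$sdev^2 / sum(pc$sdev^2))[
    seq_len(n_components)]
  out
}

#' Rank-sum class-separability screen
#'
#' Two-sided Wilcoxon rank-sum test of the equal-median null between one
#' feature's values in two classes — the nonparametric screen used to judge
#' which reflection coefficients carry discriminative information (small p:
#' the classes' medians differ; p near 1: no separability).
#'
#' @param values_a,values_b Numeric vectors of one feature's values in each
#'   class (both nonempty).
#' @return Two-sided p-value in \[0, 1\].
#' @export
ranksum_separability <- function(values_a, values_b) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) < 1L || length(values_b) < 1L)
    stop("both samples must be nonempty")
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = NULL)$p.value)
}
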
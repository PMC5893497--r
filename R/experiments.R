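#' Configuration for an ablation experiment
#'
#' Bundles the dataset source, the experiment kind and its sweep, the
#' kernel, and a seed, so every reported accuracy is reproducible from the
#' serialized configuration alone.
#'
#' Experiment kinds:
#' \describe{
#'   \item{`channels`}{Reflection features from channel subsets: left,
#'     right, central (C3, C4), parietal (P3, P4), occipital (O1, O2) and
#'     all.}
#'   \item{`pca`}{Principal-component count swept over `sweep`
#'     (default 2..6) on the full reflection feature matrix.}
#'   \item{`n_coeffs`}{Reflection coefficients per channel swept over
#'     `sweep` (default 1..6).}
#'   \item{`bands`}{Features extracted from band-limited signals: each
#'     conventional narrow band, the 4-37 Hz and 40-100 Hz wide bands, and
#'     the unfiltered full band.}
#'   \item{`kernels`}{Linear, quadratic, polynomial and RBF kernels on the
#'     same features.}
#'   \item{`par_comparison`}{Proposed reflection features vs PAR4/PAR5/PAR6
#'     band-power feature sets, with their feature dimensions.}
#' }
#'
#' @param kind Experiment kind (see Details).
#' @param dataset Either a list of labeled [eeg_recording()]s or a list
#'   `list(model_a =, model_b =, n_sessions_per_class =)` describing a
#'   synthetic pair to generate at run time.
#' @param sweep Sweep values where the kind admits them; sensible defaults
#'   otherwise.
#' @param kernel A [kernel_spec()] used by every kind except `kernels`.
#' @param seed Integer seed controlling dataset generation.
#' @param line_freq Notch frequency applied during preprocessing (`NULL`
#'   to skip).
#' @param n_coeffs Reflection coefficients per channel for kinds that do
#'   not sweep it.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(kind = c("channels", "pca", "n_coeffs",
                                       "bands", "kernels", "par_comparison"),
                              dataset, sweep = NULL,
                              kernel = kernel_spec("quadratic"), seed = 1,
                              line_freq = 60, n_coeffs = 2) {
  kind <- match.arg(kind)
  if (is.null(sweep)) {
    sweep <- switch(kind,
      pca = 2:6,
      n_coeffs = 1:6,
      kernels = c("linear", "quadratic", "polynomial", "rbf"),
      par_comparison = c("proposed", "PAR4", "PAR5", "PAR6"),
      NULL)
  }
  if (kind == "n_coeffs" &&
      (!all(sweep %in% 1:6)))
    stop("`n_coeffs` sweep values must lie in 1..6")
  if (kind %in% c("pca", "n_coeffs") && length(sweep) == 0L)
    stop("empty sweep")
  structure(list(kind = kind, dataset = dataset, sweep = sweep,
                 kernel = kernel, seed = as.integer(seed),
                 line_freq = line_freq, n_coeffs = n_coeffs),
            class = "experiment_config")
}

experiment_dataset <- function(cfg) {
  ds <- cfg$dataset
  if (length(ds) >= 1L && inherits(ds[[1]], "eeg_recording")) return(ds)
  if (is.list(ds) && all(c("model_a", "model_b") %in% names(ds))) {
    n <- if (is.null(ds$n_sessions_per_class)) 5L else
      as.integer(ds$n_sessions_per_class)
    return(make_two_class_dataset(ds$model_a, ds$model_b, n,
                                  seed = cfg$seed))
  }
  stop("`dataset` must be a list of recordings or a synthetic model pair")
}

channel_subsets <- function(labels, hemisphere_map) {
  side <- hemisphere_map[labels]
  subsets <- list(
    left = labels[side == "left"],
    right = labels[side == "right"],
    central = grep("^C", labels, value = TRUE),
    parietal = grep("^P", labels, value = TRUE),
    occipital = grep("^O", labels, value = TRUE),
    all = labels
  )
  subsets[vapply(subsets, length, integer(1)) > 0L]
}

#' Run an ablation experiment
#'
#' Generates (or takes) a labeled two-class dataset, preprocesses it
#' (notch, normalization, 1-s frames with 0.5-s shift), and evaluates
#' frame-level leave-one-out SVM accuracy across the sweep the experiment
#' kind defines. Deterministic for a fixed configuration and seed.
#'
#' @param cfg An [experiment_config()].
#' @return An `experiment_report`: list with `kind`, `table` (a data frame
#'   keyed by sweep value with `accuracy` (percent) and `n_features`),
#'   `seed` and the elapsed feature-extraction time in seconds (logged for
#'   interest only).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  recordings <- experiment_dataset(cfg)
  t0 <- proc.time()[["elapsed"]]
  fset <- preprocess_sessions(recordings, line_freq = cfg$line_freq)
  rows <- switch(cfg$kind,
    channels = {
      subsets <- channel_subsets(fset$channel_labels, fset$hemisphere_map)
      lapply(names(subsets), function(nm) {
        feats <- extract_reflection_features(
          select_channels(fset, subsets[[nm]]), n_coeffs = cfg$n_coeffs)
        res <- loocv_classify(feats, cfg$kernel)
        data.frame(sweep = nm, accuracy = res$accuracy,
                   n_features = ncol(feats))
      })
    },
    pca = {
      feats <- extract_reflection_features(fset, n_coeffs = cfg$n_coeffs)
      lapply(cfg$sweep, function(npc) {
        red <- pca_reduce(feats, npc)
        res <- loocv_classify(red, cfg$kernel)
        data.frame(sweep = paste0(npc, "pcs"), accuracy = res$accuracy,
                   n_features = npc)
      })
    },
    n_coeffs = {
      lapply(cfg$sweep, function(p) {
        feats <- extract_reflection_features(fset, n_coeffs = p)
        res <- loocv_classify(feats, cfg$kernel)
        data.frame(sweep = paste0(p, "cfs"), accuracy = res$accuracy,
                   n_features = ncol(feats))
      })
    },
    bands = {
      bands <- eeg_bands()
      variants <- c(as.list(bands),
                    list(wide_4_37 = band_definition("wide", 4, 37),
                         wide_40_100 = band_definition("wide", 40, 100),
                         full = NULL))
      lapply(names(variants), function(nm) {
        fs_b <- if (is.null(variants[[nm]])) fset else {
          filtered <- lapply(recordings, function(rec) {
            rec <- if (is.null(cfg$line_freq)) rec else
              notch_filter(rec, cfg$line_freq)
            rec <- normalize_recording(rec)
            bandpass(rec, variants[[nm]])
          })
          bind_framesets(lapply(filtered, frame_signal))
        }
        feats <- extract_reflection_features(fs_b, n_coeffs = cfg$n_coeffs)
        res <- loocv_classify(feats, cfg$kernel)
        data.frame(sweep = nm, accuracy = res$accuracy,
                   n_features = ncol(feats))
      })
    },
    kernels = {
      feats <- extract_reflection_features(fset, n_coeffs = cfg$n_coeffs)
      lapply(cfg$sweep, function(kk) {
        res <- loocv_classify(feats, kernel_spec(kk))
        data.frame(sweep = kk, accuracy = res$accuracy,
                   n_features = ncol(feats))
      })
    },
    par_comparison = {
      lapply(cfg$sweep, function(method) {
        feats <- if (method == "proposed")
          extract_reflection_features(fset, n_coeffs = cfg$n_coeffs)
        else assemble_par_features(fset, method)
        res <- loocv_classify(feats, cfg$kernel)
        data.frame(sweep = method, accuracy = res$accuracy,
                   n_features = ncol(feats))
      })
    })
  elapsed <- proc.time()[["elapsed"]] - t0
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(kind = cfg$kind, table = tab, seed = cfg$seed,
                 elapsed_s = elapsed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> kind:", x$kind, " (seed ", x$seed, ")\n", sep = "")
  tab <- x$table
  tab$accuracy <- sprintf("%6.2f", tab$accuracy)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize an experiment report as JSON
#'
#' @param report An `experiment_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_json <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  jsonlite::write_json(list(
    kind = report$kind, seed = report$seed, table = report$table),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
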
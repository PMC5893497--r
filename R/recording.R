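#' Construct an EEG recording
#'
#' An `eeg_recording` holds a multichannel scalp EEG session as a channels x
#' samples matrix together with its sampling rate, ordered channel labels, a
#' hemisphere assignment for every channel, and optional task label and
#' subject identifier. It is the unit of data every preprocessing step
#' operates on.
#'
#' Hemisphere assignment follows the 10-20 electrode naming convention when
#' `hemisphere_map` is not supplied: labels ending in an odd digit (C3, P3,
#' O1, ...) are left-hemisphere, even digits (C4, P4, O2, ...) right; labels
#' that do not end in a digit must be mapped explicitly.
#'
#' @param data Numeric matrix, channels in rows, samples in columns
#'   (amplitude, arbitrary units or microvolts).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `data`. Defaults to rownames of `data`.
#' @param hemisphere_map Named character vector mapping every channel label
#'   to `"left"` or `"right"`. Inferred from 10-20 names when `NULL`.
#' @param task_label Optional mental-task label, one of
#'   `"M"`, `"C"`, `"L"`, `"B"`, `"R"` (multiplication, counting, letter
#'   composing, baseline rest, figure rotation).
#' @param subject_id Optional subject/session identifier.
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' x <- matrix(rnorm(2 * 500), nrow = 2,
#'             dimnames = list(c("C3", "C4"), NULL))
#' rec <- eeg_recording(x, fs = 250)
#' rec$hemisphere_map
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          hemisphere_map = NULL, task_label = NULL,
                          subject_id = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (ncol(data) < 1L)
    stop("recording must contain at least one sample per channel")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("number of channel labels (", length(channel_labels),
         ") does not match number of data rows (", nrow(data), ")")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (is.null(hemisphere_map))
    hemisphere_map <- infer_hemispheres(channel_labels)
  hemisphere_map <- hemisphere_map[channel_labels]
  if (anyNA(hemisphere_map) || !all(hemisphere_map %in% c("left", "right")))
    stop("`hemisphere_map` must assign 'left' or 'right' to every channel")
  names(hemisphere_map) <- channel_labels
  if (!is.null(task_label)) {
    task_label <- as.character(task_label)
    stopifnot(length(task_label) == 1L)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         hemisphere_map = hemisphere_map, task_label = task_label,
         subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @noRd
infer_hemispheres <- function(labels) {
  last <- substr(labels, nchar(labels), nchar(labels))
  digit <- suppressWarnings(as.integer(last))
  if (anyNA(digit))
    stop("cannot infer hemisphere for label(s) ",
         paste(labels[is.na(digit)], collapse = ", "),
         "; supply `hemisphere_map`")
  side <- ifelse(digit %% 2L == 1L, "left", "right")
  stats::setNames(side, labels)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channel(s) x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 3), " s)\n",
      sep = "")
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$task_label)) cat("  task:", x$task_label, "\n")
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' Number of samples / channels of a recording
#' @param rec An `eeg_recording`.
#' @return Integer count.
#' @keywords internal
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
n_channels <- function(rec) nrow(rec$data)

#' Read a recording from CSV or EDF
#'
#' CSV files use the package's dialect: a comma-separated file whose header
#' row holds the channel labels and whose subsequent rows each hold one
#' sample per channel. CSV carries no sampling rate, so `fs_override` is
#' required. EDF files (European Data Format, 16-bit) carry the rate in
#' their header; `fs_override`, if given, replaces it.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"edf"`. Guessed from the file extension when
#'   missing.
#' @param fs_override Sampling rate in Hz. Mandatory for CSV.
#' @param task_label,subject_id Optional metadata attached to the result.
#' @return An [eeg_recording()].
#' @seealso [write_recording_csv()], [write_edf()] to produce such files.
#' @export
read_recording <- function(path, format = c("csv", "edf"),
                           fs_override = NULL, task_label = NULL,
                           subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(fs_override))
      stop("CSV carries no sampling rate; supply `fs_override` (Hz)")
    first_two <- readLines(path, n = 2L)
    header <- gsub('^"|"$', "",
                   trimws(strsplit(first_two[1], ",", fixed = TRUE)[[1]]))
    if (length(first_two) > 1L) {
      n_fields <- length(strsplit(first_two[2], ",", fixed = TRUE)[[1]])
      if (n_fields != length(header))
        stop("CSV header has ", length(header), " labels but rows have ",
             n_fields, " columns")
    }
    tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    if (!all(vapply(tab, is.numeric, logical(1))))
      stop("non-numeric sample values in ", path)
    eeg_recording(t(as.matrix(tab)), fs = fs_override,
                  channel_labels = header, task_label = task_label,
                  subject_id = subject_id)
  } else {
    rec <- read_edf(path)
    if (!is.null(fs_override)) rec$fs <- fs_override
    if (!is.null(task_label)) rec$task_label <- task_label
    if (!is.null(subject_id)) rec$subject_id <- subject_id
    rec
  }
}

#' Write a recording to the package's CSV dialect
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- as.data.frame(t(rec$data))
  names(tab) <- rec$channel_labels
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
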
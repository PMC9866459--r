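#' Triaxial accelerometer recordings
#'
#' An `accel_recording` holds one subject's triaxial acceleration time series
#' sampled at a fixed rate, together with per-sample activity labels
#' (`"walking"` or `"other"`) and optional subject metadata. It is the input
#' unit of the whole pipeline: recordings are windowed into segments, segments
#' into features, features into classifiers.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param x,y,z Equal-length numeric vectors of acceleration samples.
#'   Units are taken as-is; downstream standardization makes the pipeline
#'   insensitive to them.
#' @param labels Character vector of per-sample activity labels, one of
#'   `"walking"` or `"other"`; recycled from a single value. Defaults to
#'   all-`"other"`.
#' @param fs Sampling frequency in Hz (default 11, the rate of the
#'   back-mounted sensor this pipeline targets).
#' @param meta Optional named list of subject metadata (sex, age, walking
#'   aid, diagnosis).
#'
#' @return An object of class `accel_recording`: a list with elements
#'   `subject_id`, `fs`, `x`, `y`, `z`, `labels`, `meta`.
#' @examples
#' rec <- accel_recording("s1", x = rnorm(44), y = rnorm(44), z = rnorm(44),
#'                        labels = rep(c("other", "walking"), each = 22))
#' duration(rec)
#' @export
accel_recording <- function(subject_id, x, y, z,
                            labels = rep("other", length(x)),
                            fs = 11, meta = list()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (length(labels) == 1L) labels <- rep(labels, length(x))
  labels <- as.character(labels)
  n <- length(x)
  if (length(y) != n || length(z) != n || length(labels) != n) {
    stop("x, y, z and labels must have equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("acceleration values must be numeric and non-missing", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("walking", "other"))
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, fs = fs, x = x, y = y, z = z,
         labels = labels, meta = meta),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording> subject %s: %d samples @ %g Hz (%.1f s), %.1f%% walking\n",
    x$subject_id, length(x$x), x$fs, duration(x),
    100 * mean(x$labels == "walking")))
  invisible(x)
}

#' @export
length.accel_recording <- function(x) length(x$x)

#' Recording duration in seconds
#' @param rec An [accel_recording].
#' @return Numeric scalar, `length(rec) / rec$fs`.
#' @export
duration <- function(rec) length(rec$x) / rec$fs

#' Read a recording from delimited text
#'
#' Reads a CSV with header columns `x,y,z` and an optional `label` column,
#' one sample per row. A missing label column yields all-`"other"` labels
#' with a warning.
#'
#' @param path Path to the CSV file.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param fs Sampling frequency in Hz.
#' @return An [accel_recording].
#' @seealso [write_recording()]
#' @export
load_recording <- function(path, subject_id = NULL, fs = 11) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("recording file must have columns x, y, z: ", path, call. = FALSE)
  }
  for (col in need) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (!is.numeric(v) || anyNA(v)) {
      stop("non-numeric acceleration values in column ", col, call. = FALSE)
    }
    df[[col]] <- v
  }
  if ("label" %in% names(df)) {
    labels <- as.character(df$label)
  } else {
    warning("no label column in ", basename(path),
            "; assuming all samples are 'other'", call. = FALSE)
    labels <- rep("other", nrow(df))
  }
  accel_recording(subject_id, df$x, df$y, df$z, labels, fs = fs)
}

#' Write a recording to delimited text
#'
#' Writes the `x,y,z,label` CSV dialect read by [load_recording()]. Values
#' round-trip at full double precision.
#'
#' @param rec An [accel_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  df <- data.frame(x = rec$x, y = rec$y, z = rec$z, label = rec$labels)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Majority label of a window
#'
#' A window is labelled `"walking"` only if strictly more than half of its
#' samples are walking; exact ties go to `"other"`.
#'
#' @param sample_labels Non-empty character vector of per-sample labels.
#' @return `"walking"` or `"other"`.
#' @export
label_majority <- function(sample_labels) {
  n <- length(sample_labels)
  if (n == 0L) stop("cannot take majority of an empty label vector", call. = FALSE)
  if (sum(sample_labels == "walking") > n / 2) "walking" else "other"
}

#' Cut a recording into fixed-length overlapping segments
#'
#' Windows of `window_s` seconds with 50% overlap: the window length in
#' samples is `w = round(window_s * fs)` and the stride is `floor(w / 2)`,
#' so odd windows (e.g. 3 s at 11 Hz, w = 33) keep at least half overlap.
#' Trailing samples shorter than one window are dropped. Each segment gets a
#' single class by [label_majority()].
#'
#' @param rec An [accel_recording].
#' @param window_s Window length in seconds; the pipeline was designed around
#'   3, 6 and 9 s windows (6 s is the clinically preferred length for human
#'   walking analysis), but any length with at least two samples is accepted.
#' @return A list of `segment` objects, each a list with `subject_id`,
#'   `window_s`, `overlap_s`, `start_index` (0-based), `fs`, `data` (a w x 3
#'   matrix with columns x, y, z) and `label`. A recording shorter than one
#'   window yields an empty list with a warning.
#' @examples
#' rec <- accel_recording("s1", rnorm(132), rnorm(132), rnorm(132))
#' length(segment_recording(rec, 6))  # 3 segments: starts 0, 33, 66
#' @export
segment_recording <- function(rec, window_s) {
  stopifnot(inherits(rec, "accel_recording"))
  w <- as.integer(round(window_s * rec$fs))
  if (w < 2) stop("window_s * fs must be at least 2 samples", call. = FALSE)
  n <- length(rec$x)
  if (n < w) {
    warning(sprintf("recording %s (%d samples) is shorter than one %g s window",
                    rec$subject_id, n, window_s), call. = FALSE)
    return(list())
  }
  stride <- w %/% 2L
  starts <- seq.int(0L, n - w, by = stride)
  lapply(starts, function(s0) {
    idx <- (s0 + 1L):(s0 + w)
    structure(
      list(subject_id = rec$subject_id,
           window_s = window_s,
           overlap_s = window_s / 2,
           start_index = s0,
           fs = rec$fs,
           data = cbind(x = rec$x[idx], y = rec$y[idx], z = rec$z[idx]),
           label = label_majority(rec$labels[idx])),
      class = "segment"
    )
  })
}

#' Export segment metadata
#'
#' Summarises a list of segments as one row each:
#' `subject_id,window_s,start_index,label`.
#'
#' @param segments List of segments from [segment_recording()].
#' @param path Optional CSV path; when given the table is also written there.
#' @return A data frame, invisibly when `path` is given.
#' @export
segments_table <- function(segments, path = NULL) {
  df <- data.frame(
    subject_id = vapply(segments, `[[`, "", "subject_id"),
    window_s = vapply(segments, `[[`, 0, "window_s"),
    start_index = vapply(segments, `[[`, 0L, "start_index"),
    label = vapply(segments, `[[`, "", "label")
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
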
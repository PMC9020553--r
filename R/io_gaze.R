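#' Gaze recording container
#'
#' A data.frame of timestamped gaze samples in degrees of visual angle
#' with a validity flag, plus the declared sampling rate as an attribute.
#' Invalid samples carry `NA` coordinates.
#'
#' @param t Time in seconds from recording start; strictly increasing.
#' @param x,y Gaze position in degrees (screen centre = 0, x rightward,
#'   y downward positive).
#' @param valid Logical validity flag per sample.
#' @param rate Declared sampling rate in Hz.
#' @return An object of class `gaze_recording` (a data.frame).
#' @export
gaze_recording <- function(t, x, y, valid = rep(TRUE, length(t)), rate) {
  if (length(t) && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  out <- data.frame(t = t, x = x, y = y, valid = valid)
  attr(out, "rate") <- rate
  class(out) <- c("gaze_recording", "data.frame")
  out
}

#' Sampling rate of a recording
#' @param recording A [gaze_recording()].
#' @return Rate in Hz.
#' @export
sampling_rate <- function(recording) attr(recording, "rate")

#' Read a gaze sample table
#'
#' Reads a plain UTF-8 delimited gaze table (tab by default, comma
#' accepted) with columns `t`, `valid`, and either pixel coordinates
#' (`x_px`, `y_px`; requires `geometry`) or coordinates already in
#' degrees (`x_deg`, `y_deg`).  Pixel coordinates are converted to
#' degrees relative to the screen centre via [px_to_deg()].
#'
#' @param path File path.
#' @param geometry A [screen_geometry()]; required for pixel input.
#' @param sampling_rate Declared sampling rate, 60 or 120 Hz.
#' @return A [gaze_recording()].
#' @export
read_gaze_table <- function(path, geometry = NULL, sampling_rate) {
  if (!sampling_rate %in% c(60, 120)) {
    stop("sampling_rate must be 60 or 120 Hz")
  }
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE), error = function(e) character())
  if (length(first) == 0) stop("format error: empty gaze file: ", path)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("format error: gaze file has no samples: ", path)
  if (!all(c("t", "valid") %in% names(tab))) {
    stop("format error: gaze table must have columns 't' and 'valid'")
  }
  if (all(c("x_deg", "y_deg") %in% names(tab))) {
    x <- tab$x_deg; y <- tab$y_deg
  } else if (all(c("x_px", "y_px") %in% names(tab))) {
    if (is.null(geometry)) {
      stop("pixel coordinates require a screen geometry")
    }
    deg <- px_to_deg(tab$x_px, tab$y_px, geometry)
    x <- deg$x; y <- deg$y
  } else {
    stop("format error: gaze table needs x_px/y_px or x_deg/y_deg columns")
  }
  if (any(diff(tab$t) <= 0)) {
    stop("data error: timestamps are not strictly increasing")
  }
  gaze_recording(t = tab$t, x = x, y = y, valid = as.logical(tab$valid),
                 rate = sampling_rate)
}

#' Write a gaze recording as a delimited table
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @param sep Field separator (tab default).
#' @export
write_gaze_table <- function(recording, path, sep = "\t") {
  out <- data.frame(t = recording$t, x_deg = recording$x,
                    y_deg = recording$y, valid = recording$valid)
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read detected oculomotor events
#'
#' Events are stored as a comma-separated table whose leading columns are
#' `kind`, `onset`, `offset`, `amplitude`, `peak_velocity`; any further
#' event columns (positions, centroids) are preserved.  The round trip
#' `read_events(write_events(ev))` reproduces the events at full double
#' precision.
#'
#' @param events Event data.frame from [classify_ivt()].
#' @param path Output path.
#' @return `write_events()` returns the path invisibly; `read_events()`
#'   returns the event data.frame.
#' @export
write_events <- function(events, path) {
  need <- c("kind", "onset", "offset", "amplitude", "peak_velocity")
  if (!all(need %in% names(events))) {
    stop("events must have columns ", paste(need, collapse = ", "))
  }
  events <- events[, c(need, setdiff(names(events), need)), drop = FALSE]
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.csv(events, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(ev) <- c("oculomotor_events", "data.frame")
  ev
}
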
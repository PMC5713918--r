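#' Marker motion trace
#'
#' A `marker_trace` holds a timestamped multichannel position series in mm:
#' 9 channels for the three external surface markers (x, y, z per marker) or
#' 3 channels for the internal tumor/fiducial position. Timestamps are in
#' seconds and must be strictly increasing; external traces are nominally
#' sampled at ~25 Hz by the infrared tracking system.
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param values Numeric matrix, `length(timestamps)` rows by 9 (external) or
#'   3 (internal) columns, positions in mm.
#' @param sample_rate_hint Nominal sampling rate in Hz (default 25).
#' @return An object of class `marker_trace`.
#' @export
marker_trace <- function(timestamps, values, sample_rate_hint = 25) {
  values <- as.matrix(values)
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != nrow(values)) {
    stop("timestamps and values must have the same number of rows")
  }
  if (length(timestamps) == 0L) stop("trace must contain at least one sample")
  if (!all(is.finite(timestamps)) || !all(is.finite(values))) {
    stop("trace contains non-finite values")
  }
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (!ncol(values) %in% c(3L, 9L)) {
    stop("channel count must be 9 (external) or 3 (internal), got ", ncol(values))
  }
  structure(
    list(timestamps = timestamps, values = unname(values),
         sample_rate_hint = sample_rate_hint),
    class = "marker_trace"
  )
}

#' @export
print.marker_trace <- function(x, ...) {
  kind <- if (ncol(x$values) == 9L) "external (9-channel)" else "internal (3-channel)"
  cat(sprintf("marker_trace: %s, %d samples, %.2f-%.2f s\n",
              kind, length(x$timestamps),
              x$timestamps[1], x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' @export
length.marker_trace <- function(x) length(x$timestamps)

n_channels <- function(trace) ncol(trace$values)

#' Synchronized training set
#'
#' Pairs of external input (9-vector) and internal output (3-vector) observed
#' at the sparse imaging instants, time-ordered. These are the data from which
#' correlation models are built.
#'
#' @param X Numeric matrix, n x 9, external marker positions (mm).
#' @param Y Numeric matrix, n x 3, internal positions (mm).
#' @param timestamps Numeric vector of length n, seconds, strictly increasing.
#' @return An object of class `training_set`.
#' @export
training_set <- function(X, Y, timestamps) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  timestamps <- as.numeric(timestamps)
  if (nrow(X) != nrow(Y) || nrow(X) != length(timestamps)) {
    stop("X, Y and timestamps must agree in row count")
  }
  if (nrow(X) < 1L) stop("training set must contain at least one point")
  if (ncol(X) != 9L) stop("X must have 9 columns")
  if (ncol(Y) != 3L) stop("Y must have 3 columns")
  if (!all(is.finite(X)) || !all(is.finite(Y)) || !all(is.finite(timestamps))) {
    stop("training set contains non-finite values")
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("training set rows must be strictly time-ordered")
  }
  structure(list(X = unname(X), Y = unname(Y), timestamps = timestamps),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d synchronized imaging points over %.1f s\n",
              nrow(x$X), diff(range(x$timestamps))))
  invisible(x)
}

n_points <- function(train) nrow(train$X)

#' Synchronize an external trace with sparse internal observations
#'
#' For each internal timestamp the external trace is linearly interpolated at
#' that instant, provided the bracketing external samples are no more than
#' `tolerance` seconds apart; internal points that are not bracketed within
#' tolerance (including points outside the external time span) are dropped.
#'
#' @param external `marker_trace` with 9 channels.
#' @param internal `marker_trace` with 3 channels.
#' @param tolerance Maximum spacing (s) between the bracketing external
#'   samples for interpolation to be trusted. Default 0.2 s, about five
#'   external sample periods at 25 Hz.
#' @return A `training_set` of matched pairs.
#' @export
synchronize <- function(external, internal, tolerance = 0.2) {
  stopifnot(inherits(external, "marker_trace"), inherits(internal, "marker_trace"))
  if (n_channels(external) != 9L) stop("external trace must have 9 channels")
  if (n_channels(internal) != 3L) stop("internal trace must have 3 channels")
  if (tolerance <= 0) stop("tolerance must be positive")

  te <- external$timestamps
  keep <- logical(length(internal$timestamps))
  Xout <- matrix(NA_real_, length(internal$timestamps), 9L)
  for (i in seq_along(internal$timestamps)) {
    ti <- internal$timestamps[i]
    j <- findInterval(ti, te)
    if (j >= 1L && ti == te[j]) {          # exact knot: copy the row
      keep[i] <- TRUE
      Xout[i, ] <- external$values[j, ]
    } else if (j >= 1L && j < length(te) && (te[j + 1L] - te[j]) <= tolerance) {
      a <- (ti - te[j]) / (te[j + 1L] - te[j])
      keep[i] <- TRUE
      Xout[i, ] <- (1 - a) * external$values[j, ] + a * external$values[j + 1L, ]
    }
  }
  if (!any(keep)) stop("no synchronized points: no internal timestamp is bracketed by external samples within tolerance")
  training_set(Xout[keep, , drop = FALSE],
               internal$values[keep, , drop = FALSE],
               internal$timestamps[keep])
}

#' Fit a per-dimension [0,1] normalization from a training set
#'
#' Computes offset (minimum) and scale (range) per input and output dimension
#' so that model fitting operates on unit-width data, making the subtractive
#' clustering radius a fraction of data width uniformly across heterogeneous
#' dimensions. Constant (degenerate) dimensions get scale 1 and are flagged.
#'
#' @param train A `training_set` with at least 2 points.
#' @return An object of class `norm_spec` with components `x_offset`,
#'   `x_scale`, `y_offset`, `y_scale`, `x_degenerate`, `y_degenerate`.
#' @export
fit_normalization <- function(train) {
  stopifnot(inherits(train, "training_set"))
  if (n_points(train) < 2L) stop("normalization requires at least 2 points")
  fit_dim <- function(M) {
    off <- apply(M, 2L, min)
    rng <- apply(M, 2L, max) - off
    degen <- rng <= 0
    rng[degen] <- 1
    list(offset = off, scale = rng, degenerate = degen)
  }
  fx <- fit_dim(train$X); fy <- fit_dim(train$Y)
  structure(list(x_offset = fx$offset, x_scale = fx$scale, x_degenerate = fx$degenerate,
                 y_offset = fy$offset, y_scale = fy$scale, y_degenerate = fy$degenerate),
            class = "norm_spec")
}

# Map rows of M to [0,1] given offset/scale vectors.
norm_apply <- function(M, offset, scale) {
  sweep(sweep(M, 2L, offset, "-"), 2L, scale, "/")
}

norm_invert <- function(M, offset, scale) {
  sweep(sweep(M, 2L, scale, "*"), 2L, offset, "+")
}

normalize_inputs  <- function(spec, X) norm_apply(as.matrix(X), spec$x_offset, spec$x_scale)
normalize_outputs <- function(spec, Y) norm_apply(as.matrix(Y), spec$y_offset, spec$y_scale)
denormalize_outputs <- function(spec, Yn) norm_invert(as.matrix(Yn), spec$y_offset, spec$y_scale)

ext_header <- c("t", "m1x", "m1y", "m1z", "m2x", "m2y", "m2z", "m3x", "m3y", "m3z")
int_header <- c("t", "tx", "ty", "tz")

#' Read a motion trace from CSV
#'
#' External layout has header `t,m1x,m1y,m1z,m2x,m2y,m2z,m3x,m3y,m3z`;
#' internal layout has header `t,tx,ty,tz`. Units are seconds and mm.
#'
#' @param path File path.
#' @param layout `"external"` or `"internal"`.
#' @return A `marker_trace`.
#' @export
read_trace <- function(path, layout = c("external", "internal")) {
  layout <- match.arg(layout)
  want <- if (layout == "external") ext_header else int_header
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(hdr), want)) {
    stop("malformed header in ", path, ": expected '", paste(want, collapse = ","),
         "', got '", paste(hdr, collapse = ","), "'")
  }
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  M <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow = nrow(df)))
  bad <- which(!stats::complete.cases(M))
  if (length(bad)) stop("non-numeric cell in ", path, " at data row ", bad[1L])
  if (any(diff(M[, 1L]) <= 0)) {
    stop("non-monotone timestamps in ", path, " at data row ",
         which(diff(M[, 1L]) <= 0)[1L] + 1L)
  }
  marker_trace(M[, 1L], M[, -1L, drop = FALSE])
}

#' Write a motion trace to CSV
#'
#' @param trace A `marker_trace`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "marker_trace"))
  hdr <- if (n_channels(trace) == 9L) ext_header else int_header
  M <- cbind(trace$timestamps, trace$values)
  lines <- c(paste(hdr, collapse = ","),
             apply(M, 1L, function(r) paste(sprintf("%.12g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a training set to CSV (imaging log)
#'
#' Header is `t,tx,ty,tz,m1x,...,m3z`: timestamp, internal observation, then
#' the synchronized external row.
#'
#' @param train A `training_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_training_set <- function(train, path) {
  stopifnot(inherits(train, "training_set"))
  hdr <- c(int_header, ext_header[-1L])
  M <- cbind(train$timestamps, train$Y, train$X)
  lines <- c(paste(hdr, collapse = ","),
             apply(M, 1L, function(r) paste(sprintf("%.12g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a training set written by [write_training_set()]
#'
#' @param path File path.
#' @return A `training_set`.
#' @export
read_training_set <- function(path) {
  want <- c(int_header, ext_header[-1L])
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(hdr), want)) stop("malformed training-set header in ", path)
  df <- utils::read.csv(path, header = TRUE)
  M <- as.matrix(df)
  if (!all(is.finite(M))) stop("non-numeric cell in ", path)
  training_set(M[, 5:13, drop = FALSE], M[, 2:4, drop = FALSE], M[, 1L])
}
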
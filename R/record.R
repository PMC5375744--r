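#' One sEMG recording session (or one preprocessed trial)
#'
#' A `session_record` holds a frames x channels signal matrix with per-frame
#' gesture labels plus subject/session/trial identity, following the CapgMyo
#' record layout: raw records contain a whole session including rest frames
#' (gesture 0), while preprocessed per-trial records contain the middle 1000
#' frames of a single trial.
#'
#' @param signal Numeric matrix, frames x channels; normalized amplitudes in
#'   `[-1, 1]`.
#' @param gesture Integer vector of per-frame gesture labels (0 = rest), of
#'   length `nrow(signal)`, or a single scalar applied to every frame (the
#'   per-trial record convention).
#' @param subject Integer subject identifier.
#' @param session Integer session identifier (defaults to 1; CapgMyo DB-b
#'   encodes its two sessions as distinct subject IDs, but the generic record
#'   keeps them separate).
#' @param trial Optional integer trial identifier (present for preprocessed
#'   per-trial records).
#' @return An object of class `session_record`.
#' @export
session_record <- function(signal, gesture, subject, session = 1L, trial = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (nrow(signal) == 0L)
    stop("empty record: signal has 0 frames")
  if (length(gesture) == 1L)
    gesture <- rep(as.integer(gesture), nrow(signal))
  gesture <- as.integer(gesture)
  if (length(gesture) != nrow(signal))
    stop("gesture length (", length(gesture), ") does not match number of frames (",
         nrow(signal), ")")
  if (anyNA(signal) || max(abs(signal)) > 1 + 1e-9)
    stop("signal values must lie in [-1, 1]")
  structure(
    list(
      signal = signal,
      gesture = gesture,
      subject = as.integer(subject),
      session = as.integer(session),
      trial = if (is.null(trial)) NULL else as.integer(trial)
    ),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  g <- sort(unique(x$gesture))
  cat("<session_record> subject ", x$subject, ", session ", x$session,
      if (!is.null(x$trial)) paste0(", trial ", x$trial), ": ",
      nrow(x$signal), " frames x ", ncol(x$signal), " channels; gestures {",
      paste(g, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Number of frames / channels in a record
#' @param record A [session_record()].
#' @return Integer.
#' @export
n_frames <- function(record) nrow(record$signal)

#' @rdname n_frames
#' @export
n_channels <- function(record) ncol(record$signal)

# Table-2 field names used on disk.
.record_fields <- c("data", "gesture", "subject", "trial")

#' Read a record file
#'
#' Reads a record stored in the package's native container: an RDS-serialized
#' named list carrying the CapgMyo field names `data` (frames x channels
#' matrix), `gesture` (per-frame vector, or a scalar for per-trial records),
#' `subject`, and, for per-trial records, `trial`. An optional `session` field
#' is honoured when present.
#'
#' @param path Path to a record file written by [save_record()].
#' @return A [session_record()].
#' @seealso [save_record()]
#' @export
load_record <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj)) stop("format error: record container is not a field list")
  for (f in c("data", "gesture", "subject")) {
    if (is.null(obj[[f]]))
      stop("format error: missing field '", f, "' in ", path)
  }
  dat <- as.matrix(obj$data)
  if (nrow(dat) == 0L)
    stop("consistency error: empty record (0 frames) in ", path)
  if (length(obj$gesture) != 1L && length(obj$gesture) != nrow(dat))
    stop("consistency error: gesture length ", length(obj$gesture),
         " does not match ", nrow(dat), " frames in ", path)
  session_record(
    signal = dat,
    gesture = obj$gesture,
    subject = obj$subject,
    session = if (is.null(obj$session)) 1L else obj$session,
    trial = obj$trial
  )
}

#' Write a record file
#'
#' Serializes a [session_record()] to the native container with the CapgMyo
#' field names; [load_record()] reads it back bit-for-bit on `data` and
#' labels. Per-trial records (those with a `trial` id and a single gesture)
#' store `gesture` as a scalar, matching the per-trial file convention.
#'
#' @param record A valid [session_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_record <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  # re-validate: refuses to write records whose invariants were broken in place
  record <- session_record(record$signal, record$gesture, record$subject,
                           record$session, record$trial)
  g <- record$gesture
  if (!is.null(record$trial) && length(unique(g)) == 1L) g <- g[1L]
  obj <- list(data = record$signal, gesture = g, subject = record$subject,
              session = record$session)
  if (!is.null(record$trial)) obj$trial <- record$trial
  tryCatch(saveRDS(obj, path),
           error = function(e) stop("cannot write record to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Extract the centered window of each gesture segment
#'
#' CapgMyo preprocessing keeps only the static hold phase of each trial: the
#' middle one-second window (1000 frames at 1 kHz) of every contiguous
#' non-rest segment, so that movement transitions at segment edges are
#' excluded. Rest frames (gesture 0) delimit segments; labels are preserved.
#' When the leftover frame count is odd the extra frame is dropped at the end
#' of the segment (`floor((L - W) / 2)` leading frames are skipped).
#'
#' @param record A [session_record()].
#' @param window_frames Window length in frames (default 1000, one second at
#'   the CapgMyo sampling rate).
#' @return A [session_record()] containing the concatenated windows.
#' @export
segment_middle_window <- function(record, window_frames = 1000L) {
  stopifnot(inherits(record, "session_record"), window_frames >= 1L)
  g <- record$gesture
  act <- g != 0L
  if (!any(act)) stop("record contains no non-rest frames")
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- integer(0)
  seg_no <- 0L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    seg_no <- seg_no + 1L
    len <- r$lengths[j]
    if (len < window_frames)
      stop("segmentation error: segment ", seg_no,
           if (!is.null(record$trial)) paste0(" (trial ", record$trial, ")"),
           " has ", len, " frames < window of ", window_frames)
    lead <- (len - window_frames) %/% 2L
    from <- starts[j] + lead
    keep <- c(keep, seq.int(from, from + window_frames - 1L))
  }
  session_record(record$signal[keep, , drop = FALSE], g[keep],
                 record$subject, record$session, record$trial)
}
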
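#' Remove power-line interference with a Butterworth band-stop filter
#'
#' Applies a band-stop (notch band) Butterworth filter, by default 45-55 Hz
#' second order as used to clean 50 Hz mains interference from sEMG sampled
#' at 1 kHz. Filtering is zero-phase (forward-backward, [signal::filtfilt()])
#' so per-frame gesture labels stay time-aligned with the signal; the
#' effective order is therefore doubled, which is accepted.
#'
#' @param x Numeric vector (one channel) or frames x channels matrix.
#' @param low_hz,high_hz Stop-band edges in Hz.
#' @param order Butterworth order of the underlying design (per pass).
#' @param fs_hz Sampling rate in Hz.
#' @return Filtered signal, same shape as `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' x <- sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 150 * t)
#' y <- bandstop_filter(x, fs_hz = 1000)
#' @export
bandstop_filter <- function(x, low_hz = 45, high_hz = 55, order = 2, fs_hz = 1000) {
  if (!(0 < low_hz && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (fs_hz <= 2 * high_hz)
    stop("spec error: sampling rate ", fs_hz, " Hz cannot represent a ",
         high_hz, " Hz stop edge (need fs > 2*high_hz)")
  if (order < 1) stop("order must be >= 1")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "stop")
  run <- function(v) {
    if (length(v) <= 3 * order)
      stop("signal too short to filter (need length > ", 3 * order, ")")
    as.numeric(signal::filtfilt(bf, v))
  }
  if (is.matrix(x)) apply(x, 2L, run) else run(as.numeric(x))
}

#' Convert one instantaneous frame to a grayscale electrode-grid image
#'
#' Arranges the channel amplitudes of a single sampling instant on the
#' electrode grid and maps them linearly to grayscale intensity:
#' `pixel = 255 * clip((value - lo) / (hi - lo), 0, 1)`. Intensities are kept
#' as real numbers (no 8-bit quantization) so no information is lost before
#' the network input.
#'
#' @param frame Numeric vector of length `layout_size(layout)`.
#' @param layout A [grid_layout()].
#' @param in_range Length-2 numeric `(lo, hi)`, the amplitude range mapped to
#'   `[0, 255]`. Defaults to `c(-1, 1)`, the normalized amplitude range of
#'   CapgMyo signals, so that sign information is preserved.
#' @return An `emg_image`: a `n_rows x n_cols` numeric matrix with attribute
#'   `layout`.
#' @export
frame_to_image <- function(frame, layout, in_range = c(-1, 1)) {
  stopifnot(inherits(layout, "grid_layout"))
  lo <- in_range[1L]; hi <- in_range[2L]
  if (lo >= hi) stop("range error: in_range must satisfy lo < hi")
  if (length(frame) != layout_size(layout))
    stop("frame length ", length(frame), " does not match layout size ",
         layout_size(layout))
  v <- 255 * pmin(pmax((as.numeric(frame) - lo) / (hi - lo), 0), 1)
  px <- matrix(0, layout$n_rows, layout$n_cols)
  px[layout$channel_map] <- v
  structure(px, layout = layout, class = c("emg_image", "matrix", "array"))
}

#' 3 x 3 spatial median filter
#'
#' Replaces every pixel by the median of its 3 x 3 neighborhood, the spatial
#' denoising step applied to instantaneous sEMG images. Neighborhoods are
#' truncated at image borders (median of the available cells).
#'
#' @param image Numeric matrix (e.g. an `emg_image`).
#' @return Filtered matrix of the same shape, attributes preserved.
#' @export
spatial_median_filter <- function(image) {
  px <- unclass(image)
  nr <- nrow(px); nc <- ncol(px)
  out <- px
  for (i in seq_len(nr)) {
    ri <- max(1L, i - 1L):min(nr, i + 1L)
    for (j in seq_len(nc)) {
      cj <- max(1L, j - 1L):min(nc, j + 1L)
      out[i, j] <- stats::median(px[ri, cj])
    }
  }
  attributes(out) <- attributes(image)
  out
}

#' Convert every frame of a signal matrix to flattened image pixels
#'
#' Vectorized batch version of [frame_to_image()]: maps a frames x channels
#' matrix to a frames x pixels matrix in which column `p` is grid position
#' `(row, col)` with `p = (col - 1) * n_rows + row` (column-major). This is
#' the layout consumed by [emgnet()].
#'
#' @inheritParams frame_to_image
#' @param signal Frames x channels numeric matrix.
#' @return Frames x `layout_size(layout)` matrix of intensities in `[0, 255]`.
#' @export
frames_to_images <- function(signal, layout, in_range = c(-1, 1)) {
  stopifnot(inherits(layout, "grid_layout"))
  lo <- in_range[1L]; hi <- in_range[2L]
  if (lo >= hi) stop("range error: in_range must satisfy lo < hi")
  if (ncol(signal) != layout_size(layout))
    stop("signal has ", ncol(signal), " channels, layout expects ",
         layout_size(layout))
  v <- 255 * pmin(pmax((signal - lo) / (hi - lo), 0), 1)
  pos <- (layout$channel_map[, "col"] - 1L) * layout$n_rows +
    layout$channel_map[, "row"]
  out <- matrix(0, nrow(signal), layout_size(layout))
  out[, pos] <- v
  out
}
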
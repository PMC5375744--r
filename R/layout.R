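#' Electrode grid layout
#'
#' A `grid_layout` maps channel indices of a multi-channel sEMG recording onto
#' positions of a two-dimensional electrode array, and thereby defines the
#' shape of the instantaneous sEMG image. The CapgMyo armband is an 8 x 16
#' grid (128 channels), CSL-HDEMG a 7 x 24 grid, and NinaPro-style sparse
#' montages degenerate to a 1 x 10 "grid".
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param channel_map Optional integer matrix with `n_rows * n_cols` rows and
#'   columns `row`, `col` giving, for each channel index (row of the matrix),
#'   its electrode position. Defaults to column-major filling: channel 1 at
#'   (1, 1), channel 2 at (2, 1), ... This must be a bijection onto the grid.
#' @return An object of class `grid_layout`.
#' @examples
#' capgmyo_layout() # 8 x 16
#' grid_layout(1, 10) # sparse montage
#' @export
grid_layout <- function(n_rows, n_cols, channel_map = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  n <- n_rows * n_cols
  if (is.null(channel_map)) {
    channel_map <- cbind(
      row = rep(seq_len(n_rows), times = n_cols),
      col = rep(seq_len(n_cols), each = n_rows)
    )
  } else {
    channel_map <- as.matrix(channel_map)
    if (nrow(channel_map) != n || ncol(channel_map) != 2L)
      stop("channel_map must have ", n, " rows and 2 columns (row, col)")
    colnames(channel_map) <- c("row", "col")
  }
  pos <- (channel_map[, "col"] - 1L) * n_rows + channel_map[, "row"]
  if (anyDuplicated(pos) || any(channel_map[, "row"] < 1L) ||
      any(channel_map[, "row"] > n_rows) || any(channel_map[, "col"] < 1L) ||
      any(channel_map[, "col"] > n_cols))
    stop("channel_map is not a bijection onto the ", n_rows, " x ", n_cols, " grid")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, channel_map = channel_map),
    class = "grid_layout"
  )
}

#' @rdname grid_layout
#' @export
capgmyo_layout <- function() grid_layout(8L, 16L)

#' @rdname grid_layout
#' @export
csl_layout <- function() grid_layout(7L, 24L)

#' Number of channels covered by a layout
#' @param layout A [grid_layout()].
#' @return Integer, `n_rows * n_cols`.
#' @export
layout_size <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  layout$n_rows * layout$n_cols
}

#' @export
print.grid_layout <- function(x, ...) {
  cat("<grid_layout> ", x$n_rows, " x ", x$n_cols, " (",
      layout_size(x), " channels)\n", sep = "")
  invisible(x)
}
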
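#' Majority vote over a window of predicted labels
#'
#' Returns the modal label of a non-empty label sequence; ties are broken
#' deterministically toward the smallest label value.
#'
#' @param labels Vector of predicted labels (integer-valued).
#' @return The winning label (same type as `labels`).
#' @examples
#' majority_vote(c(1, 1, 2)) # 1
#' majority_vote(c(1, 2, 1, 2)) # tie -> 1
#' @export
majority_vote <- function(labels) {
  if (length(labels) == 0L) stop("contract error: empty label sequence")
  tab <- table(labels)
  # names(tab) sorts ascending, so which.max's first hit is the smallest label
  win <- names(tab)[which.max(tab)]
  if (is.numeric(labels)) as.integer(win) else win
}

# Voted label at every stride-1 window position of one trial's predictions.
# Returns integer vector of length len - w + 1 (codes in 1..G).
.windowed_votes <- function(codes, w, G) {
  len <- length(codes)
  onehot <- matrix(0L, len, G)
  onehot[cbind(seq_len(len), codes)] <- 1L
  cum <- rbind(0L, apply(onehot, 2L, cumsum))
  counts <- cum[(w + 1L):(len + 1L), , drop = FALSE] -
    cum[1L:(len - w + 1L), , drop = FALSE]
  max.col(counts, ties.method = "first")
}

#' Evaluate a fitted network under a protocol
#'
#' Computes per-frame recognition accuracy and sliding-window majority-voted
#' accuracy on the test units of an evaluation protocol. Voting windows move
#' one frame per step and never straddle trial (record) boundaries; a window
#' longer than a trial degenerates to one whole-trial vote (logged). The
#' special window `Inf` denotes per-trial voting. Voted accuracy averages
#' over all window positions of all test trials; a window's reference label
#' is the majority of its frames' true labels.
#'
#' @param object A fitted `emgnet`.
#' @param records List of per-trial [session_record()]s.
#' @param protocol An [make_protocol()] result (its `test_units` are used).
#' @param layout A [grid_layout()].
#' @param windows Integer vector of voting window sizes in frames (`Inf` =
#'   whole trial). Default `c(1, 150)`: single-frame and the 150 ms window.
#' @param in_range Amplitude range for image conversion.
#' @param ... Unused.
#' @return An `eval_report`: list with `per_frame_accuracy`,
#'   `voted_accuracy` (named by window), `confusion` (rows = true gesture),
#'   `per_unit` breakdown, and `n_frames`.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.emgnet <- function(object, records, protocol, layout,
                            windows = c(1, 150), in_range = c(-1, 1), ...) {
  stopifnot(inherits(protocol, "eval_protocol"))
  units <- protocol$test_units
  if (nrow(units) == 0L) stop("no test units")
  lev <- object$levels
  G <- length(lev)
  conf <- matrix(0L, G, G, dimnames = list(true = lev, predicted = lev))
  win_correct <- setNames(numeric(length(windows)), as.character(windows))
  win_total <- win_correct
  per_unit <- units
  per_unit$accuracy <- NA_real_
  n_correct <- 0L; n_total <- 0L

  for (i in seq_len(nrow(units))) {
    r <- records[[units$index[i]]]
    X <- frames_to_images(r$signal, layout, in_range)
    pr <- .nn_forward(object, X, mode = "eval")$probs
    pred_code <- max.col(pr, ties.method = "first")
    true_code <- match(r$gesture, lev)
    if (anyNA(true_code))
      stop("test unit contains gestures unknown to the model")
    len <- length(pred_code)
    ok <- pred_code == true_code
    n_correct <- n_correct + sum(ok)
    n_total <- n_total + len
    per_unit$accuracy[i] <- mean(ok)
    for (j in seq_len(len))
      conf[true_code[j], pred_code[j]] <- conf[true_code[j], pred_code[j]] + 1L
    for (wi in seq_along(windows)) {
      w <- windows[wi]
      if (!is.finite(w) || w > len) {
        if (is.finite(w) && w > len)
          message("window ", w, " exceeds trial of ", len,
                  " frames: whole-trial vote used")
        v <- which.max(tabulate(pred_code, G)) # ties -> smallest code
        tv <- which.max(tabulate(true_code, G))
        win_correct[wi] <- win_correct[wi] + (v == tv)
        win_total[wi] <- win_total[wi] + 1L
      } else {
        v <- .windowed_votes(pred_code, w, G)
        tv <- .windowed_votes(true_code, w, G)
        win_correct[wi] <- win_correct[wi] + sum(v == tv)
        win_total[wi] <- win_total[wi] + length(v)
      }
    }
  }
  structure(
    list(per_frame_accuracy = n_correct / n_total,
         voted_accuracy = win_correct / win_total,
         confusion = conf, per_unit = per_unit, n_frames = n_total),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> per-frame accuracy ",
      sprintf("%.1f%%", 100 * x$per_frame_accuracy), " over ",
      x$n_frames, " frames\n", sep = "")
  for (w in names(x$voted_accuracy))
    cat(sprintf("  voted accuracy (window %s): %.1f%%\n", w,
                100 * x$voted_accuracy[[w]]))
  invisible(x)
}
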
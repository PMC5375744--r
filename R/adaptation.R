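#' Calibration data from a target session
#'
#' Wraps target-session frames (as image matrices) for adaptation: unlabeled
#' calibration data drive [adapt()]; labeled calibration data additionally
#' allow [finetune()].
#'
#' @param frames Frames x pixels image matrix (see [frames_to_images()]).
#' @param labels Optional per-frame gesture labels.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(frames, labels = NULL) {
  frames <- as.matrix(frames)
  if (nrow(frames) == 0L) stop("calibration set is empty")
  if (!is.null(labels) && length(labels) != nrow(frames))
    stop("labels length does not match number of frames")
  structure(list(frames = frames, labels = labels,
                 labeled = !is.null(labels)),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("<calibration_set> ", nrow(x$frames), " frames (",
      if (x$labeled) "labeled" else "unlabeled", ")\n", sep = "")
  invisible(x)
}

#' Adapt a fitted network to a new session (AdaBN)
#'
#' Unsupervised domain adaptation by adaptive batch normalization: the
#' normalization statistics at every site are re-estimated from unlabeled
#' calibration frames of the target session while all learnable weights stay
#' fixed. The update runs bottom to top — each site's statistics are computed
#' from activations that have already been normalized by the updated
#' statistics of the lower sites — and accumulates over batches by moving
#' average, so adaptation can run incrementally for as long as the device is
#' worn.
#'
#' @param object A fitted `emgnet`.
#' @param calibration A [calibration_set()] (labels, if any, are ignored
#'   here) or a frames x pixels matrix.
#' @param batch_size Calibration frames per forward pass; the tail batch is
#'   processed as-is.
#' @param momentum `NULL` (default) accumulates batches with equal per-frame
#'   weight, so after any number of passes the first site's statistics equal
#'   the pooled calibration moments exactly and the result does not depend
#'   on how frames were split into batches; a numeric value in (0, 1] uses
#'   an exponential moving average with that weight per `adapt()` call
#'   instead (emphasizes recent data during never-ending use).
#' @param ... Unused.
#' @return The adapted `emgnet`; only normalization statistics differ from
#'   the input ([weight_digest()] is unchanged).
#' @export
adapt <- function(object, ...) UseMethod("adapt")

#' @rdname adapt
#' @export
adapt.emgnet <- function(object, calibration, batch_size = 1000L,
                         momentum = NULL, ...) {
  X <- if (inherits(calibration, "calibration_set")) calibration$frames
       else as.matrix(calibration)
  if (nrow(X) == 0L) stop("calibration set is empty")
  n <- nrow(X)
  starts <- seq.int(1L, n, by = batch_size)
  # bottom-to-top: each site's moments are pooled over the whole calibration
  # set, computed from activations normalized by the already-updated lower
  # sites; batches only bound the working-set size, not the result
  for (nm in names(object$sites)) {
    n_tot <- 0; s1 <- 0; s2 <- 0
    for (s in starts) {
      rows <- s:min(s + batch_size - 1L, n)
      U <- .nn_forward(object, X[rows, , drop = FALSE], mode = "eval",
                       stop_at = nm)$U
      k <- nrow(U)
      mo <- .col_moments(U)
      s1 <- s1 + k * mo$mu
      s2 <- s2 + k * (mo$var + mo$mu^2)
      n_tot <- n_tot + k
    }
    mu <- s1 / n_tot
    mo <- list(mu = mu, var = pmax(s2 / n_tot - mu^2, 0))
    object$sites[[nm]] <- .bn_adapt_update(object$sites[[nm]], mo, n_tot,
                                           momentum)
  }
  object$adapted <- TRUE
  object
}

#' Fine-tune a network on labeled calibration data
#'
#' Supervised follow-up to [adapt()]: all weights are trainable and updated
#' by SGD on the labeled calibration frames of the target session (a single
#' source domain, so the multi-stream pass runs with blocks drawn from that
#' one session). The adapted target statistics are updated from the
#' fine-tuning batches by moving average.
#'
#' @param object A fitted (typically already adapted) `emgnet`.
#' @param calibration A labeled [calibration_set()].
#' @param schedule An [emgnet_schedule()]; with `lr = 0` the weights are
#'   returned unchanged.
#' @param ... Unused.
#' @return The fine-tuned `emgnet`.
#' @export
finetune <- function(object, ...) UseMethod("finetune")

#' @rdname finetune
#' @export
finetune.emgnet <- function(object, calibration,
                            schedule = emgnet_schedule(epochs = 4L, lr = 0.01),
                            ...) {
  stopifnot(inherits(calibration, "calibration_set"))
  if (!calibration$labeled)
    stop("contract error: calibration set is unlabeled; use adapt() instead")
  X <- calibration$frames
  yi <- match(as.integer(calibration$labels), object$levels)
  if (anyNA(yi))
    stop("calibration labels outside the model's gesture set")
  bs <- min(schedule$batch_size, nrow(X))
  M <- object$spec$n_streams
  bs <- max(M, (bs %/% M) * M) # keep divisibility by M
  sched <- schedule
  sched$batch_size <- bs
  session <- rep(1L, nrow(X)) # one target session
  .nn_train(object, X, yi, session, sched, update = "target",
            pool_after = FALSE)
}
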
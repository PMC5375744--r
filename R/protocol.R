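#' Tabulate the identity of a set of records
#'
#' @param records A list of [session_record()]s (typically per-trial records).
#' @return A data.frame with one row per record: `index`, `subject`,
#'   `session`, `trial`, `gesture` (NA when a record mixes gestures), and
#'   `frames`.
#' @export
record_manifest <- function(records) {
  stopifnot(length(records) > 0L)
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    stopifnot(inherits(r, "session_record"))
    g <- unique(r$gesture)
    data.frame(
      index = i, subject = r$subject, session = r$session,
      trial = if (is.null(r$trial)) NA_integer_ else r$trial,
      gesture = if (length(g) == 1L) g else NA_integer_,
      frames = nrow(r$signal)
    )
  })
  do.call(rbind, rows)
}

#' Construct an evaluation protocol
#'
#' Builds the train/test/calibration partition for the three evaluation
#' scenarios used with session-structured sEMG data:
#'
#' * `intra_session` — within one session of one subject, odd-numbered trials
#'   (1, 3, 5, 7, 9, ...) train and even-numbered trials test (the 50/50
#'   split used for CapgMyo technical validation);
#' * `inter_session` — for one subject, all sessions except the held-out one
#'   train; the held-out session tests;
#' * `inter_subject` — leave-one-subject-out: all subjects except the held-out
#'   one train; every session of the held-out subject tests.
#'
#' Calibration units default to the test units with `calibration_labeled =
#' FALSE`: the unlabeled data of the target session, as consumed by
#' [adapt()].
#'
#' @param kind One of `"intra_session"`, `"inter_session"`, `"inter_subject"`.
#' @param records List of per-trial [session_record()]s.
#' @param held_out A named list selecting the evaluation target:
#'   `list(subject =, session =)` for `intra_session`; `list(session =)`
#'   (optionally plus `subject` to restrict to one subject) for
#'   `inter_session`; `list(subject =)` for `inter_subject`.
#' @return An object of class `eval_protocol` with elements `kind`,
#'   `train_units`, `test_units`, `calibration_units` (data.frames as from
#'   [record_manifest()]), `calibration_labeled`, and `manifest`.
#' @export
make_protocol <- function(kind = c("intra_session", "inter_session", "inter_subject"),
                          records, held_out) {
  kind <- match.arg(kind)
  man <- record_manifest(records)
  held_out <- as.list(held_out)

  pick <- function(cond) man[cond, , drop = FALSE]

  if (kind == "intra_session") {
    if (is.null(held_out$subject) || is.null(held_out$session))
      stop("selector error: intra_session needs held_out$subject and held_out$session")
    m <- pick(man$subject == held_out$subject & man$session == held_out$session)
    if (nrow(m) == 0L)
      stop("selector error: no records for subject ", held_out$subject,
           ", session ", held_out$session)
    if (anyNA(m$trial))
      stop("selector error: intra_session split needs per-trial records")
    train <- m[m$trial %% 2L == 1L, , drop = FALSE]
    test <- m[m$trial %% 2L == 0L, , drop = FALSE]
  } else if (kind == "inter_session") {
    if (is.null(held_out$session))
      stop("selector error: inter_session needs held_out$session")
    m <- if (is.null(held_out$subject)) man
         else pick(man$subject == held_out$subject)
    if (!held_out$session %in% m$session)
      stop("selector error: session ", held_out$session, " not present")
    train <- m[m$session != held_out$session, , drop = FALSE]
    test <- m[m$session == held_out$session, , drop = FALSE]
    if (nrow(train) == 0L)
      stop("selector error: no training sessions left after holding out session ",
           held_out$session)
  } else {
    if (is.null(held_out$subject))
      stop("selector error: inter_subject needs held_out$subject")
    if (!held_out$subject %in% man$subject)
      stop("selector error: subject ", held_out$subject, " not present")
    train <- man[man$subject != held_out$subject, , drop = FALSE]
    test <- man[man$subject == held_out$subject, , drop = FALSE]
    if (nrow(train) == 0L)
      stop("selector error: no training subjects left")
  }

  if (nrow(test) == 0L) stop("selector error: empty test set")
  structure(
    list(kind = kind, train_units = train, test_units = test,
         calibration_units = test, calibration_labeled = FALSE,
         manifest = man),
    class = "eval_protocol"
  )
}

#' @export
print.eval_protocol <- function(x, ...) {
  cat("<eval_protocol> ", x$kind, ": ", nrow(x$train_units), " train units, ",
      nrow(x$test_units), " test units (calibration ",
      if (x$calibration_labeled) "labeled" else "unlabeled", ")\n", sep = "")
  invisible(x)
}
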
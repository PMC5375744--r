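#' Reduced network / schedule presets for synthetic benchmarks
#'
#' The synthetic transfer experiments run a narrower variant of the
#' reference architecture (8 filters per convolutional and locally connected
#' layer, 32/32/16 fully connected units) and a shortened schedule (8
#' epochs, learning-rate drops after epochs 5 and 7, batch 200), so that a
#' full train/adapt/evaluate cycle completes in seconds on one CPU while
#' preserving every structural element: both convolution types, all eight
#' normalization sites, dropout and the multi-stream pass.
#'
#' @param layout A [grid_layout()].
#' @param n_gestures Number of gesture classes.
#' @param n_streams Statistic streams M.
#' @return An [emgnet_spec()] / [emgnet_schedule()].
#' @export
reduced_spec <- function(layout, n_gestures, n_streams = 1L) {
  emgnet_spec(input_shape = c(layout$n_rows, layout$n_cols),
              n_gestures = n_gestures, n_streams = n_streams,
              conv_filters = 8L, local_filters = 8L, fc_sizes = c(32L, 32L, 16L))
}

#' @rdname reduced_spec
#' @param epochs,seed Schedule parameters.
#' @param batch_size Total batch size; the default keeps at least 200 frames
#'   per batch and at least 50 frames per stream block, so block statistics
#'   stay usable as M grows.
#' @export
reduced_schedule <- function(n_streams = 1L, epochs = 8L, seed = NULL,
                             batch_size = NULL) {
  if (is.null(batch_size)) batch_size <- max(200L, 50L * n_streams)
  bs <- max(n_streams, (batch_size %/% n_streams) * n_streams)
  emgnet_schedule(batch_size = bs, epochs = epochs, lr = 0.1,
                  lr_drop_epochs = round(c(16, 24) / 28 * epochs),
                  lr_drop_factor = 10, weight_decay = 1e-4, seed = seed)
}

#' Reduced study conditions for the synthetic benchmarks
#'
#' The synthetic transfer benchmarks use the generator's default grid,
#' gesture count, subject/session structure, noise and shift parameters, but
#' fewer trials (4) and shorter hold phases (60 frames) than a real
#' recording so that experiments fit a desktop CPU budget; these sizes are
#' fixed once here and shared by all benchmark entry points.
#'
#' @param seed Master seed.
#' @param n_subjects,n_sessions Database structure.
#' @param trials_per_gesture,frames_per_trial,ramp_frames,rest_frames
#'   Benchmark-scale trial structure.
#' @param ... Further overrides passed to [generator_config()].
#' @return A [generator_config()].
#' @export
benchmark_config <- function(seed = 1L, n_subjects = 10L, n_sessions = 2L,
                             trials_per_gesture = 4L, frames_per_trial = 50L,
                             ramp_frames = 12L, rest_frames = 25L, ...) {
  generator_config(n_subjects = n_subjects, n_sessions = n_sessions,
                   trials_per_gesture = trials_per_gesture,
                   frames_per_trial = frames_per_trial,
                   ramp_frames = ramp_frames, rest_frames = rest_frames,
                   seed = seed, ...)
}

#' One synthetic inter-session transfer experiment
#'
#' For one subject of a synthetic database: (1) intra-session accuracy on
#' the last session (odd trials train, even trials test); (2) inter-session
#' accuracy training on all earlier sessions and testing on the last, with
#' and without unsupervised adaptation of the normalization statistics.
#'
#' @param db A [generate_database()] result.
#' @param config The [generator_config()] used to build `db`.
#' @param subject Subject to evaluate.
#' @param seed Seed for network initialization and batch composition.
#' @param epochs Training epochs.
#' @param window Voting window (frames) reported alongside per-frame
#'   accuracy.
#' @param calibration_fraction Fraction of the target-session frames used as
#'   unlabeled calibration data (default all).
#' @return A list with per-frame accuracies `intra`, `inter_no_adapt`,
#'   `inter_adapt`, the corresponding voted accuracies `*_voted`, and
#'   `adapt_gain = inter_adapt - inter_no_adapt`.
#' @export
run_transfer_experiment <- function(db, config, subject = 1L, seed = 1L,
                                    epochs = 10L, window = 15L,
                                    calibration_fraction = 1) {
  lay <- config$layout
  G <- config$n_gestures
  target <- config$n_sessions

  # intra-session: odd/even trial split within the target session
  p_intra <- make_protocol("intra_session", db$records,
                           list(subject = subject, session = target))
  p_inter <- make_protocol("inter_session", db$records,
                           list(subject = subject, session = target))
  # equalize the number of gradient updates between the two conditions: the
  # intra split trains on about half the frames of the inter split
  ep_intra <- max(epochs, round(epochs * sum(p_inter$train_units$frames) /
                                  sum(p_intra$train_units$frames)))
  m_intra <- train_model(db$records, p_intra, lay,
                         spec = reduced_spec(lay, G, n_streams = 1L),
                         schedule = reduced_schedule(1L, ep_intra, seed = .derive_seed(seed, 1L)),
                         init_seed = .derive_seed(seed, 11L))
  r_intra <- evaluate(m_intra, db$records, p_intra, lay, windows = window)

  # inter-session: earlier sessions train, target session tests
  M <- max(1L, config$n_sessions - 1L)
  m_inter <- train_model(db$records, p_inter, lay,
                         spec = reduced_spec(lay, G, n_streams = M),
                         schedule = reduced_schedule(M, epochs, seed = .derive_seed(seed, 2L)),
                         init_seed = .derive_seed(seed, 22L))
  r_before <- evaluate(m_inter, db$records, p_inter, lay, windows = window)

  calib <- .assemble_units(db$records, p_inter$calibration_units, lay)
  n_cal <- nrow(calib$x)
  take <- if (calibration_fraction >= 1) seq_len(n_cal) else {
    set.seed(.derive_seed(seed, 33L))
    sort(sample.int(n_cal, max(1L, round(calibration_fraction * n_cal))))
  }
  m_adapt <- adapt(m_inter, calibration_set(calib$x[take, , drop = FALSE]),
                   batch_size = 1000L)
  r_after <- evaluate(m_adapt, db$records, p_inter, lay, windows = window)

  list(intra = r_intra$per_frame_accuracy,
       inter_no_adapt = r_before$per_frame_accuracy,
       inter_adapt = r_after$per_frame_accuracy,
       intra_voted = unname(r_intra$voted_accuracy[1L]),
       inter_no_adapt_voted = unname(r_before$voted_accuracy[1L]),
       inter_adapt_voted = unname(r_after$voted_accuracy[1L]),
       adapt_gain = r_after$per_frame_accuracy - r_before$per_frame_accuracy,
       n_calibration = length(take))
}

#' Classical vs multi-stream adaptive normalization
#'
#' Trains the same reduced network on a many-session synthetic source (one
#' subject, `n_sessions - 1` source sessions, the last session held out)
#' twice: once with classical single-stream batch normalization (whole-batch
#' statistics; batches still session-homogeneous) and once with the
#' multi-stream pass (M = number of source sessions). Both are then adapted
#' on the unlabeled target session and evaluated there.
#'
#' @param config A [generator_config()] with `n_sessions >= 3`.
#' @param seed Seed.
#' @param epochs Training epochs.
#' @return A list with per-frame accuracies `classical`, `multistream`, and
#'   their difference `multistream_minus_classical`.
#' @export
run_stream_comparison <- function(config, seed = 1L, epochs = 5L) {
  db <- generate_database(config)
  lay <- config$layout
  G <- config$n_gestures
  target <- config$n_sessions
  p <- make_protocol("inter_session", db$records,
                     list(subject = 1L, session = target))
  M <- config$n_sessions - 1L
  calib <- .assemble_units(db$records, p$calibration_units, lay)

  # paired design: both normalization schemes start from identical weights
  # and share the batch-composition RNG stream, so the comparison isolates
  # the normalization scheme from initialization/sampling luck
  bs <- max(200L, 50L * M) # same total batch for both schemes
  one <- function(n_streams) {
    m <- train_model(db$records, p, lay,
                     spec = reduced_spec(lay, G, n_streams = n_streams),
                     schedule = reduced_schedule(n_streams, epochs,
                                                 seed = .derive_seed(seed, 1L),
                                                 batch_size = bs),
                     init_seed = .derive_seed(seed, 100L))
    m <- adapt(m, calibration_set(calib$x))
    evaluate(m, db$records, p, lay, windows = 1L)$per_frame_accuracy
  }
  classical <- one(1L)
  multistream <- one(M)
  list(classical = classical, multistream = multistream,
       multistream_minus_classical = multistream - classical)
}

#' Accuracy as a function of calibration-data volume
#'
#' Trains one inter-session network for a subject, then adapts it with
#' random subsets of the unlabeled target-session frames of increasing size
#' and evaluates each adapted model, tracing how quickly the adaptation
#' benefit saturates with calibration volume.
#'
#' @param db A [generate_database()] result.
#' @param config The [generator_config()] used to build `db`.
#' @param subject Subject to evaluate.
#' @param fractions Calibration fractions to test (of the target session's
#'   frames).
#' @param seed Seed.
#' @param epochs Training epochs.
#' @return A data.frame with columns `fraction`, `n_frames` and `accuracy`
#'   (per-frame, after adaptation); the no-adaptation accuracy is included
#'   as `fraction = 0`.
#' @export
run_calibration_curve <- function(db, config, subject = 1L,
                                  fractions = c(0.05, 0.25, 1), seed = 1L,
                                  epochs = 10L) {
  lay <- config$layout
  G <- config$n_gestures
  target <- config$n_sessions
  p <- make_protocol("inter_session", db$records,
                     list(subject = subject, session = target))
  M <- max(1L, config$n_sessions - 1L)
  m0 <- train_model(db$records, p, lay,
                    spec = reduced_spec(lay, G, n_streams = M),
                    schedule = reduced_schedule(M, epochs,
                                                seed = .derive_seed(seed, 2L)),
                    init_seed = .derive_seed(seed, 22L))
  calib <- .assemble_units(db$records, p$calibration_units, lay)
  n_cal <- nrow(calib$x)
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    set.seed(.derive_seed(seed, 33L, i))
    take <- sort(sample.int(n_cal, max(1L, round(f * n_cal))))
    m <- adapt(m0, calibration_set(calib$x[take, , drop = FALSE]))
    data.frame(fraction = f, n_frames = length(take),
               accuracy = evaluate(m, db$records, p, lay,
                                   windows = 1L)$per_frame_accuracy)
  })
  base <- data.frame(fraction = 0, n_frames = 0L,
                     accuracy = evaluate(m0, db$records, p, lay,
                                         windows = 1L)$per_frame_accuracy)
  rbind(base, do.call(rbind, rows))
}
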
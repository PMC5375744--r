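test_that("gesture patterns are smooth, distinct, separable and reproducible", {
  cfg <- generator_config(n_gestures = 8L, seed = 3L)
  pats <- make_gesture_patterns(cfg)
  expect_length(pats, 8L)
  for (p in pats) {
    expect_equal(dim(p), c(8L, 16L))
    expect_true(all(p >= 0 & p <= cfg$amplitude + 1e-12))
  }
  cors <- combn(8, 2, function(ij)
    cor(as.vector(pats[[ij[1]]]), as.vector(pats[[ij[2]]])))
  expect_true(all(cors < 0.9))
  expect_identical(make_gesture_patterns(cfg), pats) # same seed, same maps

  # separability oracle: a linear classifier on (slightly jittered) pattern
  # frames is perfect
  set.seed(60)
  X <- do.call(rbind, lapply(pats, function(p)
    matrix(rep(as.vector(p), 20), 20, 128, byrow = TRUE)))
  X <- X + matrix(rnorm(nrow(X) * 128, 0, 1e-3), nrow(X), 128)
  y <- factor(rep(1:8, each = 20))
  fit <- MASS::lda(X, grouping = y)
  expect_equal(mean(predict(fit, X)$class == y), 1.0)
  expect_error(make_gesture_patterns(generator_config(n_gestures = 1L)),
               "at least 2")
})

test_that("the noiseless, undistorted generator reproduces patterns exactly", {
  cfg <- generator_config(n_subjects = 1, n_sessions = 1, n_gestures = 3,
                          trials_per_gesture = 2, frames_per_trial = 20,
                          ramp_frames = 5, rest_frames = 10, noise_sd = 0,
                          powerline_amp = 0,
                          shift = shift_params(c(0, 0), 0, 0), seed = 5)
  pats <- make_gesture_patterns(cfg)
  raw <- generate_session(cfg, 1, 1, pats)
  seg <- segment_middle_window(raw, 20L)
  for (g in 1:3) {
    frames <- seg$signal[seg$gesture == g, , drop = FALSE]
    want <- pats[[g]][cfg$layout$channel_map]
    for (i in seq_len(nrow(frames)))
      expect_equal(unname(frames[i, ]), unname(want), tolerance = 1e-12)
  }
})

test_that("generated sessions are bounded, labeled by trial structure, and deterministic", {
  cfg <- mini_config()
  raw <- generate_session(cfg, 1, 1)
  expect_true(all(raw$signal >= -1 & raw$signal <= 1))
  expect_setequal(unique(raw$gesture), 0:cfg$n_gestures)
  # per-gesture frame count: trials x (hold + 2 ramps)
  expect_equal(sum(raw$gesture == 1),
               cfg$trials_per_gesture * (cfg$frames_per_trial + 2 * cfg$ramp_frames))
  expect_identical(generate_session(cfg, 1, 1)$signal, raw$signal)
  # a different session of the same subject differs (distortion is keyed)
  expect_false(identical(generate_session(cfg, 1, 2)$signal[1:10, ],
                         raw$signal[1:10, ]))
})

test_that("sessions of one subject differ by more than sampling noise", {
  cfg <- mini_config()
  db <- mini_db()
  man <- db$manifest
  chan_means <- function(ses) {
    idx <- man$index[man$session == ses]
    X <- do.call(rbind, lapply(idx, function(i) db$records[[i]]$signal))
    list(mu = colMeans(X), se = apply(X, 2, sd) / sqrt(nrow(X)), n = nrow(X))
  }
  s1 <- chan_means(1); s2 <- chan_means(2)
  z <- abs(s1$mu - s2$mu) / sqrt(s1$se^2 + s2$se^2)
  # a real domain gap: many channels shift by far more than their standard error
  expect_gt(max(z), 3)
  expect_gt(mean(z > 3), 0.25)
})

test_that("power-line contamination is present and removable by the band-stop filter", {
  cfg <- generator_config(n_subjects = 1, n_sessions = 1, n_gestures = 2,
                          trials_per_gesture = 1, frames_per_trial = 1000,
                          ramp_frames = 0, rest_frames = 0, noise_sd = 0.02,
                          powerline_amp = 0.1, seed = 8)
  raw <- generate_session(cfg, 1, 1)
  x <- raw$signal[raw$gesture == 1, 1]
  power_50 <- function(v) {
    n <- length(v)
    Mod(sum(v * exp(-2i * pi * 50 * seq_len(n) / cfg$fs_hz)))^2 / n
  }
  y <- bandstop_filter(x, fs_hz = cfg$fs_hz)
  drop_db <- 10 * log10(power_50(x) / power_50(y))
  expect_gt(drop_db, 20)
})

test_that("database generation yields the full per-trial record grid", {
  cfg <- benchmark_config(seed = 11, n_subjects = 3, n_sessions = 2,
                          n_gestures = 4, trials_per_gesture = 3,
                          frames_per_trial = 25, ramp_frames = 6,
                          rest_frames = 10)
  dir <- withr::local_tempdir()
  db <- generate_database(cfg, dir = dir)
  expect_length(db$records, 3 * 2 * 4 * 3) # subjects x sessions x gestures x trials
  man <- db$manifest
  expect_true(all(man$frames == cfg$frames_per_trial))
  expect_setequal(unique(man$gesture), 1:4)
  expect_setequal(unique(man$trial), 1:3)

  # records written to disk load back through the record reader, intact
  f <- file.path(dir, man$file[5])
  back <- load_record(f)
  expect_identical(back$signal, db$records[[5]]$signal)
  expect_identical(back$gesture, db$records[[5]]$gesture)

  # regeneration from the same master seed is identical
  db2 <- generate_database(cfg)
  expect_identical(db2$records[[17]]$signal, db$records[[17]]$signal)
})

test_that("without session shift there is no spurious inter-session gap", {
  # the generator must not create a domain gap on its own: one model trained
  # on part of session 1 must classify held-out session-1 trials and
  # session-2 trials equally well (within sampling noise) when the session
  # distortion is disabled, over five seeded replicates
  gaps <- numeric(5)
  for (s in 1:5) {
    cfg <- benchmark_config(seed = 200 + s, n_subjects = 1, n_sessions = 2,
                            n_gestures = 4, trials_per_gesture = 4,
                            frames_per_trial = 40, ramp_frames = 10,
                            rest_frames = 15,
                            shift = shift_params(c(0, 0), 0, 0))
    db <- generate_database(cfg)
    man <- db$manifest
    p <- make_protocol("inter_session", db$records,
                       list(subject = 1, session = 2))
    p$train_units <- man[man$session == 1 & man$trial <= 2, ]
    m <- train_model(db$records, p, cfg$layout,
                     spec = reduced_spec(cfg$layout, 4, 1L),
                     schedule = reduced_schedule(1L, 12L, seed = s),
                     init_seed = s)
    p_same <- p; p_same$test_units <- man[man$session == 1 & man$trial > 2, ]
    p_other <- p; p_other$test_units <- man[man$session == 2, ]
    a_same <- evaluate(m, db$records, p_same, cfg$layout,
                       windows = 1)$per_frame_accuracy
    a_other <- evaluate(m, db$records, p_other, cfg$layout,
                        windows = 1)$per_frame_accuracy
    gaps[s] <- a_same - a_other
  }
  expect_lt(abs(mean(gaps)), 0.02)
})
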
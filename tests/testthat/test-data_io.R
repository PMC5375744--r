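test_that("record files round-trip through the native container", {
  set.seed(1)
  rec <- session_record(matrix(runif(40 * 12, -1, 1), 40, 12),
                        gesture = 3L, subject = 4L, session = 1L, trial = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_record(rec, path)
  back <- load_record(path)
  expect_identical(back$signal, rec$signal)
  expect_identical(back$gesture, rec$gesture)
  expect_identical(back$subject, 4L)
  expect_identical(back$trial, 2L)
  # on-disk object carries exactly the per-trial field names
  obj <- readRDS(path)
  expect_true(all(c("data", "gesture", "subject", "trial") %in% names(obj)))
  expect_equal(dim(obj$data), c(40L, 12L))
  expect_length(obj$gesture, 1L) # per-trial files store the gesture as scalar
})

test_that("a per-trial container with 1000 frames loads as a constant-label record", {
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(data = matrix(0.1, 1000, 128), gesture = 3, subject = 4,
               trial = 2), path)
  rec <- load_record(path)
  expect_equal(n_frames(rec), 1000L)
  expect_equal(n_channels(rec), 128L)
  expect_true(all(rec$gesture == 3L))
})

test_that("malformed record files are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(data = matrix(0, 10, 4), subject = 1), p) # no gesture
  expect_error(load_record(p), "gesture")
  saveRDS(list(data = matrix(0, 0, 4), gesture = 1, subject = 1), p)
  expect_error(load_record(p), "empty")
  saveRDS(list(data = matrix(0, 10, 4), gesture = rep(1, 7), subject = 1), p)
  expect_error(load_record(p), "does not match")
  expect_error(load_record(file.path(tempdir(), "nope.rds")), "no such file")
})

test_that("invalid records cannot be constructed or written", {
  expect_error(session_record(matrix(0, 5, 4), gesture = rep(1, 4), subject = 1),
               "does not match")
  expect_error(session_record(matrix(2, 5, 4), gesture = 1L, subject = 1),
               "\\[-1, 1\\]")
  rec <- session_record(matrix(0, 5, 4), gesture = 1L, subject = 1)
  rec$gesture <- rec$gesture[-1] # break the invariant in place
  expect_error(save_record(rec, withr::local_tempfile()), "does not match")
})

test_that("middle-window segmentation is centered and label-preserving", {
  sig <- matrix(seq_len(3000) / 3000, 3000, 2)
  rec <- session_record(sig, gesture = rep(5L, 3000), subject = 1)
  out <- segment_middle_window(rec, 1000L)
  expect_equal(n_frames(out), 1000L)
  expect_equal(out$signal[, 1], sig[1001:2000, 1]) # centered 1-based slice
  expect_true(all(out$gesture == 5L))

  # window equal to the segment is the identity
  rec1 <- session_record(sig[1:1000, ], gesture = rep(2L, 1000), subject = 1)
  expect_identical(segment_middle_window(rec1, 1000L)$signal, rec1$signal)

  # too-short segment errors
  rec2 <- session_record(sig[1:999, ], gesture = rep(2L, 999), subject = 1)
  expect_error(segment_middle_window(rec2, 1000L), "segmentation error")

  # multiple gesture segments separated by rest, odd leftover drops at the end
  g <- c(rep(0L, 5), rep(1L, 11), rep(0L, 4), rep(2L, 10))
  rec3 <- session_record(matrix(seq_along(g) / 100, length(g), 1), g, subject = 1)
  out3 <- segment_middle_window(rec3, 10L)
  expect_equal(out3$gesture, c(rep(1L, 10), rep(2L, 10)))
  # 11-frame segment starts at frame 6; floor((11-10)/2)=0 leading skipped
  expect_equal(out3$signal[1:10, 1], rec3$signal[6:15, 1])
})

test_that("evaluation protocols partition units as specified", {
  set.seed(2)
  recs <- list()
  for (sub in 1:3) for (ses in 1:2) for (tr in 1:10)
    recs[[length(recs) + 1]] <- session_record(matrix(0, 5, 4), gesture = 1L,
                                               subject = sub, session = ses,
                                               trial = tr)
  p <- make_protocol("intra_session", recs, list(subject = 2, session = 1))
  expect_setequal(p$train_units$trial, c(1, 3, 5, 7, 9))
  expect_setequal(p$test_units$trial, c(2, 4, 6, 8, 10))

  p2 <- make_protocol("inter_session", recs, list(subject = 1, session = 2))
  expect_true(all(p2$train_units$session == 1))
  expect_true(all(p2$test_units$session == 2))

  p3 <- make_protocol("inter_subject", recs, list(subject = 3))
  expect_setequal(unique(p3$train_units$subject), c(1, 2))
  expect_true(all(p3$test_units$subject == 3))
  expect_false(p3$calibration_labeled)

  # degenerate selectors
  one_ses <- Filter(function(r) r$session == 1, recs)
  expect_error(make_protocol("inter_session", one_ses,
                             list(subject = 1, session = 1)),
               "selector error")
  expect_error(make_protocol("inter_subject", recs, list(subject = 99)),
               "selector error")
})

test_that("train and test units are disjoint for every protocol kind", {
  recs <- list()
  for (sub in 1:4) for (ses in 1:3) for (tr in 1:6)
    recs[[length(recs) + 1]] <- session_record(matrix(0, 3, 4), gesture = 1L,
                                               subject = sub, session = ses,
                                               trial = tr)
  cases <- list(
    make_protocol("intra_session", recs, list(subject = 1, session = 2)),
    make_protocol("inter_session", recs, list(subject = 3, session = 1)),
    make_protocol("inter_subject", recs, list(subject = 2))
  )
  for (p in cases) {
    expect_length(intersect(p$train_units$index, p$test_units$index), 0)
    expect_gt(nrow(p$train_units), 0)
    expect_gt(nrow(p$test_units), 0)
  }
})
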
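test_that("adaptation never touches learnable weights and hits exact moments", {
  m <- mini_model()
  cfg <- mini_config()
  db <- mini_db()
  calib <- emgadapt:::.assemble_units(db$records, mini_protocol()$calibration_units,
                                      cfg$layout)
  before <- weight_digest(m)
  m2 <- adapt(m, calibration_set(calib$x))
  expect_identical(weight_digest(m2), before)

  # first-site statistics equal the calibration set's moments exactly
  U0 <- as.vector(calib$x)
  expect_equal(m2$sites$input$mu_t, mean(U0), tolerance = 1e-3)
  expect_equal(m2$sites$input$var_t, mean(U0^2) - mean(U0)^2, tolerance = 1e-3)

  # batch partitioning does not change the result (order-invariant pooling)
  m3 <- adapt(m, calibration_set(calib$x), batch_size = 64L)
  for (nm in names(m2$sites)) {
    expect_equal(m3$sites[[nm]]$mu_t, m2$sites[[nm]]$mu_t, tolerance = 1e-8)
    expect_equal(m3$sites[[nm]]$var_t, m2$sites[[nm]]$var_t, tolerance = 1e-8)
  }
})

test_that("re-adapting on the same data is a fixed point and calls accumulate", {
  m <- mini_model()
  cfg <- mini_config()
  calib <- emgadapt:::.assemble_units(mini_db()$records,
                                      mini_protocol()$calibration_units,
                                      cfg$layout)
  m1 <- adapt(m, calibration_set(calib$x))
  m2 <- adapt(m1, calibration_set(calib$x))
  # same data again: pooled moments unchanged, eval outputs unchanged
  for (nm in names(m1$sites)) {
    expect_equal(m2$sites[[nm]]$mu_t, m1$sites[[nm]]$mu_t, tolerance = 1e-8)
    expect_equal(m2$sites[[nm]]$var_t, m1$sites[[nm]]$var_t, tolerance = 1e-8)
  }
  X <- calib$x[1:20, , drop = FALSE]
  expect_equal(predict(m2, X, type = "prob"), predict(m1, X, type = "prob"),
               tolerance = 1e-10)
  # two calls over the same data equal one call over the doubled data
  m4 <- adapt(m, calibration_set(rbind(calib$x, calib$x)))
  expect_equal(m4$sites$fc3$mu_t, m2$sites$fc3$mu_t, tolerance = 1e-8)
  expect_equal(m4$sites$fc3$var_t, m2$sites$fc3$var_t, tolerance = 1e-8)
})

test_that("a single calibration frame is legal", {
  m <- mini_model()
  cfg <- mini_config()
  calib <- emgadapt:::.assemble_units(mini_db()$records,
                                      mini_protocol()$calibration_units,
                                      cfg$layout)
  m1 <- adapt(m, calibration_set(calib$x[1, , drop = FALSE]))
  expect_true(all(is.finite(m1$sites$fc1$var_t)))
  expect_true(all(m1$sites$fc1$var_t >= 0))
  p <- predict(m1, calib$x[1:5, , drop = FALSE], type = "prob")
  expect_true(all(is.finite(p)))
})

test_that("adaptation recovers accuracy lost to session shift, and labels help further", {
  # five independently seeded mini experiments: an affine + displacement
  # session shift degrades transfer; re-estimating the statistics recovers
  # part of it, and supervised fine-tuning on the same frames (with labels)
  # does at least as well on average
  gains <- numeric(5)
  ft_delta <- numeric(5)
  for (s in 1:5) {
    cfg <- benchmark_config(seed = 100 + s, n_subjects = 1, n_sessions = 2,
                            n_gestures = 4, trials_per_gesture = 3,
                            frames_per_trial = 30, ramp_frames = 8,
                            rest_frames = 15)
    db <- generate_database(cfg)
    p <- make_protocol("inter_session", db$records,
                       list(subject = 1, session = 2))
    m0 <- train_model(db$records, p, cfg$layout,
                      spec = reduced_spec(cfg$layout, 4, 1L),
                      schedule = reduced_schedule(1L, 10L, seed = s),
                      init_seed = s + 50)
    calib <- emgadapt:::.assemble_units(db$records, p$calibration_units,
                                        cfg$layout)
    acc0 <- evaluate(m0, db$records, p, cfg$layout, windows = 1)$per_frame_accuracy
    ma <- adapt(m0, calibration_set(calib$x))
    acc1 <- evaluate(ma, db$records, p, cfg$layout, windows = 1)$per_frame_accuracy
    mf <- finetune(ma, calibration_set(calib$x, labels = calib$y),
                   schedule = reduced_schedule(1L, 2L, seed = s + 9))
    acc2 <- evaluate(mf, db$records, p, cfg$layout, windows = 1)$per_frame_accuracy
    gains[s] <- acc1 - acc0
    ft_delta[s] <- acc2 - acc1
  }
  expect_gt(mean(gains), 0) # unsupervised adaptation helps on average
  expect_gte(mean(gains >= 0), 0.8) # and in (almost) every replicate
  expect_gte(mean(ft_delta), -0.02) # labels do not hurt
})

test_that("fine-tuning contracts: labels required, zero rate is a no-op", {
  m <- mini_model()
  cfg <- mini_config()
  calib <- emgadapt:::.assemble_units(mini_db()$records,
                                      mini_protocol()$calibration_units,
                                      cfg$layout)
  expect_error(finetune(m, calibration_set(calib$x)), "unlabeled")

  zero <- emgnet_schedule(batch_size = 64L, epochs = 1L, lr = 0,
                          weight_decay = 0, seed = 1L)
  mf <- finetune(m, calibration_set(calib$x, labels = calib$y), schedule = zero)
  expect_identical(weight_digest(mf), weight_digest(m))

  # one frame per class completes without error
  idx <- match(sort(unique(calib$y)), calib$y)
  small <- calibration_set(calib$x[idx, , drop = FALSE], labels = calib$y[idx])
  sched <- emgnet_schedule(batch_size = 4L, epochs = 1L, lr = 0.01, seed = 2L)
  expect_s3_class(finetune(m, small, schedule = sched), "emgnet")
})
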
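# shared fixtures, built in code once per run

.cache <- new.env(parent = emptyenv())

tiny_layout <- function() grid_layout(4L, 6L)

tiny_spec <- function(G = 3L, M = 1L) {
  emgnet_spec(c(4L, 6L), n_gestures = G, n_streams = M,
              conv_filters = 4L, local_filters = 4L, fc_sizes = c(8L, 8L, 6L))
}

# linearly separable image data: one bright band per gesture plus mild noise
separable_images <- function(G = 2L, n_per_class = 60L, noise = 10,
                             seed = 42L) {
  set.seed(seed)
  n_px <- layout_size(tiny_layout())
  width <- n_px %/% G
  x <- do.call(rbind, lapply(seq_len(G), function(g) {
    v <- numeric(n_px)
    v[((g - 1L) * width + 1L):(g * width)] <- 200
    matrix(rep(v, n_per_class), n_per_class, n_px, byrow = TRUE)
  }))
  x <- x + matrix(stats::rnorm(nrow(x) * n_px, 0, noise), nrow(x), n_px)
  list(x = x, y = rep(seq_len(G), each = n_per_class))
}

# a small two-session database shared by slower tests (built once)
mini_config <- function(seed = 7L) {
  benchmark_config(seed = seed, n_subjects = 1L, n_sessions = 2L,
                   n_gestures = 4L, trials_per_gesture = 4L,
                   frames_per_trial = 30L, ramp_frames = 8L, rest_frames = 15L)
}

mini_db <- function() {
  if (is.null(.cache$db)) .cache$db <- generate_database(mini_config())
  .cache$db
}

# a fitted mini model on session 1 of the mini database (built once)
mini_model <- function() {
  if (is.null(.cache$model)) {
    cfg <- mini_config()
    db <- mini_db()
    p <- make_protocol("inter_session", db$records,
                       list(subject = 1, session = 2))
    .cache$protocol <- p
    .cache$model <- train_model(
      db$records, p, cfg$layout,
      spec = reduced_spec(cfg$layout, cfg$n_gestures, n_streams = 1L),
      schedule = reduced_schedule(1L, epochs = 8L, seed = 99L),
      init_seed = 98L)
  }
  .cache$model
}

mini_protocol <- function() {
  mini_model()
  .cache$protocol
}
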
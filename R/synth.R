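#' Inter-session distortion parameters
#'
#' Describes how the synthetic generator perturbs a recording session
#' relative to the gesture's canonical activation pattern, emulating the
#' three dominant sources of inter-session variability: electrode-array
#' displacement, per-channel gain changes (electrode-skin impedance) and
#' per-channel baseline offsets.
#'
#' @param grid_shift Integer `(rows, cols)`: maximum circular displacement of
#'   the activation pattern on the grid; the session's displacement is drawn
#'   uniformly from `-grid_shift .. grid_shift` per axis. The default shifts
#'   only along the column axis, matching a band-type electrode array worn
#'   around the forearm (wraparound ring of modules).
#' @param channel_gain_sd Standard deviation of per-channel log-gains
#'   (gains are `exp(N(0, sd))`, hence positive).
#' @param channel_offset_sd Standard deviation of per-channel additive
#'   baseline offsets (normalized amplitude units).
#' @return An object of class `shift_params`.
#' @export
shift_params <- function(grid_shift = c(0L, 1L), channel_gain_sd = 0.2,
                         channel_offset_sd = 0.05) {
  stopifnot(length(grid_shift) == 2L, all(grid_shift >= 0L),
            channel_gain_sd >= 0, channel_offset_sd >= 0)
  structure(list(grid_shift = as.integer(grid_shift),
                 channel_gain_sd = channel_gain_sd,
                 channel_offset_sd = channel_offset_sd),
            class = "shift_params")
}

#' Synthetic database configuration
#'
#' Study conditions for the synthetic HD-sEMG generator: a session-structured
#' database of gesture trials on an electrode grid, with gesture-dependent
#' smooth spatial activation patterns, a raised-cosine per-trial envelope
#' (ramp up, hold, ramp down, mimicking the guided hold phase), additive
#' Gaussian noise, 50 Hz power-line contamination, and session-keyed
#' distortions from [shift_params()]. Every quantity is deterministic given
#' `seed` and the (subject, session) identity.
#'
#' @param layout A [grid_layout()] (default the 8 x 16 CapgMyo grid).
#' @param n_gestures Number of gesture classes (default 8).
#' @param n_subjects Number of subjects (default 10).
#' @param n_sessions Recording sessions per subject (default 2).
#' @param trials_per_gesture Trials of each gesture per session (default 10).
#' @param frames_per_trial Hold-phase frames kept per trial (default 1000,
#'   one second at `fs_hz`).
#' @param ramp_frames Transition frames on each side of the hold phase.
#' @param rest_frames Rest (gesture 0) frames between trials in a raw
#'   session.
#' @param fs_hz Sampling rate (default 1000).
#' @param amplitude Peak pattern amplitude in normalized units.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param powerline_amp Amplitude of the common-mode 50 Hz sinusoid.
#' @param shift A [shift_params()].
#' @param seed Master seed; all per-session randomness is keyed by
#'   `(seed, subject, session)`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(layout = capgmyo_layout(), n_gestures = 8L,
                             n_subjects = 10L, n_sessions = 2L,
                             trials_per_gesture = 10L, frames_per_trial = 1000L,
                             ramp_frames = 250L, rest_frames = 500L,
                             fs_hz = 1000, amplitude = 0.6, noise_sd = 0.1,
                             powerline_amp = 0.05, shift = shift_params(),
                             seed = 1L) {
  stopifnot(inherits(layout, "grid_layout"), inherits(shift, "shift_params"),
            n_gestures >= 1L, n_subjects >= 1L, n_sessions >= 1L,
            trials_per_gesture >= 1L, frames_per_trial >= 1L, noise_sd >= 0)
  if (any(shift$grid_shift >= c(layout$n_rows, layout$n_cols)))
    stop("grid_shift exceeds grid bounds")
  structure(
    list(layout = layout, n_gestures = as.integer(n_gestures),
         n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
         trials_per_gesture = as.integer(trials_per_gesture),
         frames_per_trial = as.integer(frames_per_trial),
         ramp_frames = as.integer(ramp_frames),
         rest_frames = as.integer(rest_frames), fs_hz = fs_hz,
         amplitude = amplitude, noise_sd = noise_sd,
         powerline_amp = powerline_amp, shift = shift, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# deterministic sub-seed below 2^31, keyed by the master seed and identity
.derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  s <- 0
  for (v in ids) s <- (s * 7919 + as.numeric(v) + 1) %% 2147483629
  as.integer(s)
}

# Gaussian blur with border truncation (kernel renormalized in-window).
.smooth2d <- function(mat, sigma = 1.5) {
  h <- ceiling(2 * sigma)
  w <- exp(-(-h:h)^2 / (2 * sigma^2))
  K <- outer(w, w)
  R <- nrow(mat); C <- ncol(mat)
  out <- mat
  for (i in seq_len(R)) for (j in seq_len(C)) {
    ri <- max(1L, i - h):min(R, i + h)
    cj <- max(1L, j - h):min(C, j + h)
    Ksub <- K[ri - i + h + 1L, cj - j + h + 1L, drop = FALSE]
    out[i, j] <- sum(mat[ri, cj] * Ksub) / sum(Ksub)
  }
  out
}

#' Generate per-gesture spatial activation patterns
#'
#' Draws one smooth non-negative activation map per gesture on the electrode
#' grid (Gaussian-smoothed noise fields rescaled to `[0, amplitude]`),
#' resampling until all pairwise pattern correlations are below 0.9 so
#' gestures are separable. Patterns are shared across subjects and sessions;
#' all inter-session/inter-subject differences come from [shift_params()]
#' distortions.
#'
#' @param config A [generator_config()].
#' @param seed Seed (defaults to the config's master seed).
#' @return A list of `n_gestures` matrices of dim `n_rows x n_cols`.
#' @export
make_gesture_patterns <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  G <- config$n_gestures
  if (G < 2L) stop("config error: need at least 2 gestures")
  R <- config$layout$n_rows; C <- config$layout$n_cols
  set.seed(.derive_seed(seed, 0L, 0L))
  draw <- function() {
    f <- .smooth2d(matrix(stats::rnorm(R * C), R, C),
                   sigma = max(1, min(R, C) / 5))
    rng <- range(f)
    (f - rng[1L]) / max(rng[2L] - rng[1L], 1e-12) * config$amplitude
  }
  pats <- replicate(G, draw(), simplify = FALSE)
  for (attempt in 1:100) {
    cors <- outer(seq_len(G), seq_len(G), Vectorize(function(a, b)
      if (a >= b) 0 else stats::cor(as.vector(pats[[a]]), as.vector(pats[[b]]))))
    bad <- which(cors >= 0.9, arr.ind = TRUE)
    if (nrow(bad) == 0L) return(pats)
    for (b in unique(bad[, 2L])) pats[[b]] <- draw()
  }
  stop("config error: grid too small to hold ", G,
       " distinct patterns at the requested smoothness")
}

# circular 2D shift of a pattern matrix by (dr, dc)
.shift_pattern <- function(mat, dr, dc) {
  R <- nrow(mat); C <- ncol(mat)
  ri <- ((seq_len(R) - 1L - dr) %% R) + 1L
  ci <- ((seq_len(C) - 1L - dc) %% C) + 1L
  mat[ri, ci, drop = FALSE]
}

# session distortion draw, keyed by (seed, subject, session)
.session_distortion <- function(config, subject, session) {
  set.seed(.derive_seed(config$seed, subject, session))
  gs <- config$shift$grid_shift
  nch <- layout_size(config$layout)
  list(
    dr = if (gs[1L] > 0L) sample(seq(-gs[1L], gs[1L]), 1L) else 0L,
    dc = if (gs[2L] > 0L) sample(seq(-gs[2L], gs[2L]), 1L) else 0L,
    gain = exp(stats::rnorm(nch, 0, config$shift$channel_gain_sd)),
    offset = stats::rnorm(nch, 0, config$shift$channel_offset_sd)
  )
}

#' Generate one synthetic recording session
#'
#' Produces a raw-style [session_record()]: for every gesture and trial, a
#' raised-cosine envelope ramps the gesture's activation pattern up over
#' `ramp_frames`, holds it for `frames_per_trial` frames and ramps it down,
#' with Gaussian channel noise and a common-mode 50 Hz sinusoid added;
#' trials are separated by `rest_frames` rest frames (label 0). The whole
#' session is then distorted by its session-keyed per-channel affine
#' transform and circular grid displacement, and clipped to `[-1, 1]`.
#' Frames are labeled by the guiding trial structure (transition frames
#' carry the gesture's label), so [segment_middle_window()] recovers exactly
#' the hold phase.
#'
#' @param config A [generator_config()].
#' @param subject,session Identity of the session to generate.
#' @param patterns Optional precomputed [make_gesture_patterns()] output.
#' @return A [session_record()].
#' @export
generate_session <- function(config, subject = 1L, session = 1L,
                             patterns = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(patterns)) patterns <- make_gesture_patterns(config)
  lay <- config$layout
  nch <- layout_size(lay)
  dist <- .session_distortion(config, subject, session)
  # pattern value seen by channel ch after grid displacement
  pat_vec <- lapply(patterns, function(p)
    .shift_pattern(p, dist$dr, dist$dc)[lay$channel_map])

  hold <- config$frames_per_trial
  ramp <- config$ramp_frames
  rest <- config$rest_frames
  Ltr <- hold + 2L * ramp
  env <- c(if (ramp > 0L) 0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1L))),
           rep(1, hold),
           if (ramp > 0L) rev(0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1L)))))

  set.seed(.derive_seed(config$seed, subject, session, 777L))
  blocks <- list(); labels <- list(); bi <- 0L
  tglob <- 0L # running sample index for the power-line phase
  add_block <- function(sig, lab, n) {
    bi <<- bi + 1L
    if (config$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(n * nch, 0, config$noise_sd), n, nch)
    if (config$powerline_amp > 0) {
      ph <- 2 * pi * 50 * (tglob + seq_len(n)) / config$fs_hz
      sig <- sig + config$powerline_amp * sin(ph)
    }
    tglob <<- tglob + n
    blocks[[bi]] <<- sig
    labels[[bi]] <<- rep(lab, n)
  }
  for (g in seq_len(config$n_gestures)) {
    for (tr in seq_len(config$trials_per_gesture)) {
      if (rest > 0L) add_block(matrix(0, rest, nch), 0L, rest)
      add_block(outer(env, pat_vec[[g]]), g, Ltr)
    }
  }
  sig <- do.call(rbind, blocks)
  sig <- sweep(sweep(sig, 2L, dist$gain, "*"), 2L, dist$offset, "+")
  sig <- pmin(pmax(sig, -1), 1)
  session_record(sig, unlist(labels), subject, session)
}

#' Generate a full synthetic database of per-trial records
#'
#' Generates every (subject, session), segments each trial's hold phase with
#' [segment_middle_window()], and returns per-trial records of exactly
#' `frames_per_trial` frames together with a manifest. With `dir` given, the
#' records are written as native container files named
#' `sss_ggg_ttt_kN.rds` (subject, gesture, trial, session).
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory (created if needed).
#' @return A list with `records` (list of [session_record()]s), `manifest`
#'   (data.frame), and `patterns`.
#' @export
generate_database <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  patterns <- make_gesture_patterns(config)
  records <- list(); ri <- 0L
  for (sub in seq_len(config$n_subjects)) {
    for (ses in seq_len(config$n_sessions)) {
      raw <- generate_session(config, sub, ses, patterns)
      seg <- segment_middle_window(raw, config$frames_per_trial)
      # split the concatenated hold windows back into per-trial records
      per_trial <- config$frames_per_trial
      n_seg <- nrow(seg$signal) %/% per_trial
      trial_counter <- integer(config$n_gestures)
      for (i in seq_len(n_seg)) {
        rows <- ((i - 1L) * per_trial + 1L):(i * per_trial)
        g <- seg$gesture[rows[1L]]
        trial_counter[g] <- trial_counter[g] + 1L
        ri <- ri + 1L
        records[[ri]] <- session_record(seg$signal[rows, , drop = FALSE],
                                        g, sub, ses, trial_counter[g])
      }
    }
  }
  manifest <- record_manifest(records)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$file <- sprintf("%03d_%03d_%03d_k%d.rds", manifest$subject,
                             manifest$gesture, manifest$trial, manifest$session)
    if (anyDuplicated(manifest$file))
      stop("output path collision in ", dir)
    for (i in seq_along(records))
      save_record(records[[i]], file.path(dir, manifest$file[i]))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(records = records, manifest = manifest, patterns = patterns)
}
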
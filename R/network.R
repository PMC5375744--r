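#' Network topology specification
#'
#' Describes the 8-layer convolutional classifier for instantaneous sEMG
#' images: two 3 x 3 convolutional layers (stride 1, padding 1), two locally
#' connected layers of per-position 1 x 1 filters with untied weights, three
#' fully connected layers, and a final G-way fully connected layer with
#' softmax. Batch normalization is applied to the input (a single statistic
#' over all pixels, since the input is an image) and before every ReLU;
#' dropout follows the fourth, fifth and sixth layers. Every normalization
#' site carries `n_streams` independent statistic sets (one per
#' session-homogeneous block of a training batch) plus shared learnable
#' scale/shift.
#'
#' The reference topology uses 64 filters per convolutional/locally connected
#' layer and 512/512/128 fully connected units; narrower variants (for small
#' synthetic benchmarks) are obtained by lowering `conv_filters`,
#' `local_filters` and `fc_sizes`.
#'
#' @param input_shape Integer `(n_rows, n_cols)` of the input image.
#' @param n_gestures Number of gesture classes G (>= 2).
#' @param n_streams Number of statistic streams M (default 10).
#' @param conv_filters Filters in each of the two convolutional layers.
#' @param local_filters Filters in each of the two locally connected layers.
#' @param fc_sizes Sizes of the three hidden fully connected layers.
#' @param dropout_p Dropout probability after layers 4, 5, 6.
#' @param eps Batch-normalization variance guard.
#' @return An object of class `emgnet_spec`.
#' @export
emgnet_spec <- function(input_shape = c(8L, 16L), n_gestures, n_streams = 10L,
                        conv_filters = c(64L, 64L), local_filters = c(64L, 64L),
                        fc_sizes = c(512L, 512L, 128L), dropout_p = 0.5,
                        eps = 1e-5) {
  if (n_gestures < 2L) stop("spec error: need at least 2 gesture classes")
  conv_filters <- rep_len(as.integer(conv_filters), 2L)
  local_filters <- rep_len(as.integer(local_filters), 2L)
  fc_sizes <- rep_len(as.integer(fc_sizes), 3L)
  structure(
    list(input_shape = as.integer(input_shape), n_gestures = as.integer(n_gestures),
         n_streams = as.integer(n_streams), conv_filters = conv_filters,
         local_filters = local_filters, fc_sizes = fc_sizes,
         dropout_p = dropout_p, eps = eps),
    class = "emgnet_spec"
  )
}

#' Training schedule
#'
#' Stochastic gradient descent hyper-parameters. The reference schedule is a
#' batch size of 1000, 28 epochs, weight decay 1e-4, and a learning rate
#' starting at 0.1 divided by 10 after the 16th and 24th epochs.
#'
#' @param batch_size Frames per batch (must be divisible by the number of
#'   streams M).
#' @param epochs Number of passes over the training set.
#' @param lr Initial learning rate.
#' @param lr_drop_epochs Epochs after which the rate is divided by
#'   `lr_drop_factor`.
#' @param lr_drop_factor Division factor at each drop.
#' @param weight_decay L2 penalty coefficient on the weight matrices.
#' @param stat_momentum Moving-average momentum for the per-stream running
#'   statistics.
#' @param seed Integer seed for batch composition, dropout and (when no
#'   pretrained model is given) weight initialization.
#' @return An object of class `emgnet_schedule`.
#' @export
emgnet_schedule <- function(batch_size = 1000L, epochs = 28L, lr = 0.1,
                            lr_drop_epochs = c(16L, 24L), lr_drop_factor = 10,
                            weight_decay = 1e-4, stat_momentum = 0.1,
                            seed = NULL) {
  structure(
    list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         lr = lr, lr_drop_epochs = as.integer(lr_drop_epochs),
         lr_drop_factor = lr_drop_factor, weight_decay = weight_decay,
         stat_momentum = stat_momentum, seed = seed),
    class = "emgnet_schedule"
  )
}

# --- geometry helpers -------------------------------------------------------

# 3x3 neighbor table for an R x C grid in column-major position order:
# NB[p, k] is the position index of neighbor k (dr, dc in -1..1), 0 = padding.
.neighbor_table <- function(R, C) {
  P <- R * C
  pr <- rep(seq_len(R), times = C)
  pc <- rep(seq_len(C), each = R)
  NB <- matrix(0L, P, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    r2 <- pr + dr; c2 <- pc + dc
    ok <- r2 >= 1L & r2 <= R & c2 >= 1L & c2 <= C
    NB[ok, k] <- (c2[ok] - 1L) * R + r2[ok]
  }
  NB
}

# Gather 3x3 patches: A is (m*P) x Fin with sample s of position p in row
# (p-1)*m + s; returns (m*P) x (9*Fin).
.im2col <- function(A, m, NB) {
  Fin <- ncol(A)
  P <- nrow(NB)
  out <- matrix(0, m * P, 9L * Fin)
  sseq <- seq_len(m)
  for (k in 1:9) {
    pv <- which(NB[, k] > 0L)
    if (!length(pv)) next
    tgt <- rep((pv - 1L) * m, each = m) + sseq
    src <- rep((NB[pv, k] - 1L) * m, each = m) + sseq
    out[tgt, ((k - 1L) * Fin + 1L):(k * Fin)] <- A[src, , drop = FALSE]
  }
  out
}

# Scatter-add transpose of .im2col.
.col2im <- function(dAcol, m, NB, Fin) {
  P <- nrow(NB)
  dA <- matrix(0, m * P, Fin)
  sseq <- seq_len(m)
  for (k in 1:9) {
    pv <- which(NB[, k] > 0L)
    if (!length(pv)) next
    tgt <- rep((pv - 1L) * m, each = m) + sseq
    src <- rep((NB[pv, k] - 1L) * m, each = m) + sseq
    dA[src, ] <- dA[src, , drop = FALSE] +
      dAcol[tgt, ((k - 1L) * Fin + 1L):(k * Fin), drop = FALSE]
  }
  dA
}

# --- initialization ---------------------------------------------------------

.he_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Build an (untrained) network
#'
#' Allocates all learnable parameters with He (fan-in scaled) initialization
#' and every statistic set at mean 0 / variance 1.
#'
#' @param spec An [emgnet_spec()].
#' @param init_seed Integer seed; identical seeds give identical weights.
#' @return An object of class `emgnet` (untrained: `$epochs_trained == 0`).
#' @export
build_network <- function(spec, init_seed = 1L) {
  stopifnot(inherits(spec, "emgnet_spec"))
  R <- spec$input_shape[1L]; C <- spec$input_shape[2L]
  P <- R * C
  F1 <- spec$conv_filters[1L]; F2 <- spec$conv_filters[2L]
  F3 <- spec$local_filters[1L]; F4 <- spec$local_filters[2L]
  H <- spec$fc_sizes; G <- spec$n_gestures
  set.seed(as.integer(init_seed))
  params <- list(
    conv1 = list(W = .he_mat(9L, F1), b = numeric(F1)),
    conv2 = list(W = .he_mat(9L * F1, F2), b = numeric(F2)),
    local1 = list(W = array(stats::rnorm(F2 * F3 * P, sd = sqrt(2 / F2)),
                            dim = c(F2, F3, P)),
                  b = matrix(0, P, F3)),
    local2 = list(W = array(stats::rnorm(F3 * F4 * P, sd = sqrt(2 / F3)),
                            dim = c(F3, F4, P)),
                  b = matrix(0, P, F4)),
    fc1 = list(W = .he_mat(P * F4, H[1L]), b = numeric(H[1L])),
    fc2 = list(W = .he_mat(H[1L], H[2L]), b = numeric(H[2L])),
    fc3 = list(W = .he_mat(H[2L], H[3L]), b = numeric(H[3L])),
    out = list(W = .he_mat(H[3L], G), b = numeric(G))
  )
  M <- spec$n_streams
  sites <- list(
    input = .bn_site(1L, M),
    conv1 = .bn_site(F1, M), conv2 = .bn_site(F2, M),
    local1 = .bn_site(F3, M), local2 = .bn_site(F4, M),
    fc1 = .bn_site(H[1L], M), fc2 = .bn_site(H[2L], M), fc3 = .bn_site(H[3L], M)
  )
  structure(
    list(spec = spec, params = params, sites = sites,
         NB = .neighbor_table(R, C), levels = seq_len(G),
         epochs_trained = 0L, adapted = FALSE, loss_history = numeric(0)),
    class = "emgnet"
  )
}

#' Number of learnable parameters
#' @param model An `emgnet`.
#' @return Integer count of weights, biases and normalization scale/shift
#'   parameters.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "emgnet"))
  np <- sum(vapply(model$params, function(l) length(l$W) + length(l$b), 0))
  nb <- sum(vapply(model$sites, function(s) 2L * s$n, 0L))
  as.integer(np + nb)
}

# --- forward / backward -----------------------------------------------------

.softmax <- function(Z) {
  Z <- Z - Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z)
  E / rowSums(E)
}

# Locally connected 1x1 layer: per-position dense map with untied weights.
# A is (m*P) x Fin with sample s of position p in row (p-1)*m + s; W is
# (Fin, Fout, P); b is P x Fout.
.local_forward <- function(A, m, W, b) {
  P <- dim(W)[3L]; Fout <- dim(W)[2L]
  Z <- matrix(0, m * P, Fout)
  for (p in seq_len(P)) {
    rows <- ((p - 1L) * m + 1L):(p * m)
    Z[rows, ] <- A[rows, , drop = FALSE] %*% W[, , p] +
      rep(b[p, ], each = m)
  }
  Z
}

.local_backward <- function(dZ, A, m, W) {
  P <- dim(W)[3L]
  dW <- array(0, dim = dim(W))
  db <- matrix(0, P, dim(W)[2L])
  dA <- matrix(0, m * P, dim(W)[1L])
  for (p in seq_len(P)) {
    rows <- ((p - 1L) * m + 1L):(p * m)
    dZp <- dZ[rows, , drop = FALSE]
    dW[, , p] <- crossprod(A[rows, , drop = FALSE], dZp)
    db[p, ] <- colSums(dZp)
    dA[rows, ] <- dZp %*% t(W[, , p])
  }
  list(dA = dA, dW = dW, db = db)
}

# Normalization dispatcher shared by the forward modes. In "train" the batch
# is block-partitioned and block moments are used (the multi-stream pass); in
# "eval" the stored target statistics are used unchanged.
.bn_step <- function(model, name, U, mode, block_of, rows_per_sample,
                     momentum, update) {
  site <- model$sites[[name]]
  eps <- model$spec$eps
  if (mode == "train") {
    r <- .bn_forward_train(U, site, block_of, rows_per_sample, momentum, eps,
                           update = update)
    model$sites[[name]] <- r$site
    list(model = model, V = r$V, cache = r$cache)
  } else {
    list(model = model, V = .bn_forward_eval(U, site, eps), cache = NULL)
  }
}

# Full forward pass. X: m x P image-pixel matrix. Returns probabilities and,
# in train mode, the caches needed by .nn_backward.
.nn_forward <- function(model, X, mode = c("eval", "train"),
                        block_of = NULL, momentum = 0.1,
                        update = "stream", keep_cache = FALSE,
                        stop_at = NULL) {
  mode <- match.arg(mode)
  spec <- model$spec
  m <- nrow(X)
  P <- prod(spec$input_shape)
  if (ncol(X) != P)
    stop("input has ", ncol(X), " pixels, spec expects ", P)
  if (mode == "train") {
    if (is.null(block_of)) block_of <- rep(1L, m)
    if (length(block_of) != m)
      stop("batch-composition error: block_of length ", length(block_of),
           " does not match batch of ", m)
  }
  train <- mode == "train"
  cache <- list(m = m, block_of = block_of)

  # input normalization: one feature over all pixels
  U0 <- matrix(as.vector(X), ncol = 1L) # row (p-1)*m + s
  if (identical(stop_at, "input")) return(list(U = U0))
  s0 <- .bn_step(model, "input", U0, mode, block_of, P, momentum, update)
  model <- s0$model
  A <- matrix(s0$V, m * P, 1L) # (m*P) x 1, 1 input channel
  if (keep_cache) cache$input <- list(U = U0, bn = s0$cache)

  conv_names <- c("conv1", "conv2")
  for (nm in conv_names) {
    Acol <- .im2col(A, m, model$NB)
    Z <- Acol %*% model$params[[nm]]$W
    Z <- Z + rep(model$params[[nm]]$b, each = nrow(Z))
    if (identical(stop_at, nm)) return(list(U = Z))
    s <- .bn_step(model, nm, Z, mode, block_of, P, momentum, update)
    model <- s$model
    V <- s$V
    Anew <- V * (V > 0)
    if (keep_cache) cache[[nm]] <- list(Acol = Acol, bn = s$cache, V = V)
    A <- Anew
  }

  for (nm in c("local1", "local2")) {
    Ain <- A
    Z <- .local_forward(A, m, model$params[[nm]]$W, model$params[[nm]]$b)
    if (identical(stop_at, nm)) return(list(U = Z))
    s <- .bn_step(model, nm, Z, mode, block_of, P, momentum, update)
    model <- s$model
    V <- s$V
    A <- V * (V > 0)
    drop_mask <- NULL
    if (nm == "local2" && train && spec$dropout_p > 0) {
      drop_mask <- matrix(stats::rbinom(length(A), 1L, 1 - spec$dropout_p) /
                            (1 - spec$dropout_p), nrow(A), ncol(A))
      A <- A * drop_mask
    }
    if (keep_cache) cache[[nm]] <- list(Ain = Ain, bn = s$cache, V = V,
                                        drop = drop_mask)
  }

  # flatten (m*P) x F4 -> m x (F4*P); feature f occupies columns (f-1)*P+1..f*P
  F4 <- spec$local_filters[2L]
  Xf <- matrix(A, m * P * F4, 1L)
  dim(Xf) <- c(m, P * F4)
  A <- Xf

  for (nm in c("fc1", "fc2", "fc3")) {
    Ain <- A
    Z <- A %*% model$params[[nm]]$W
    Z <- Z + rep(model$params[[nm]]$b, each = m)
    if (identical(stop_at, nm)) return(list(U = Z))
    s <- .bn_step(model, nm, Z, mode, block_of, 1L, momentum, update)
    model <- s$model
    V <- s$V
    A <- V * (V > 0)
    drop_mask <- NULL
    if (nm %in% c("fc1", "fc2") && train && spec$dropout_p > 0) {
      drop_mask <- matrix(stats::rbinom(length(A), 1L, 1 - spec$dropout_p) /
                            (1 - spec$dropout_p), nrow(A), ncol(A))
      A <- A * drop_mask
    }
    if (keep_cache) cache[[nm]] <- list(Ain = Ain, bn = s$cache, V = V,
                                        drop = drop_mask)
  }

  Z <- A %*% model$params$out$W +
    matrix(model$params$out$b, m, spec$n_gestures, byrow = TRUE)
  probs <- .softmax(Z)
  if (keep_cache) cache$out <- list(Ain = A)
  list(probs = probs, cache = if (keep_cache) cache else NULL, model = model)
}

# Backward pass from dZ_out (m x G gradient at the pre-softmax output).
.nn_backward <- function(model, cache, dZ) {
  m <- cache$m
  spec <- model$spec
  P <- prod(spec$input_shape)
  grads <- list()

  grads$out <- list(W = crossprod(cache$out$Ain, dZ), b = colSums(dZ))
  dA <- dZ %*% t(model$params$out$W)

  for (nm in c("fc3", "fc2", "fc1")) {
    cc <- cache[[nm]]
    if (!is.null(cc$drop)) dA <- dA * cc$drop
    dV <- dA * (cc$V > 0)
    bb <- .bn_backward(dV, model$sites[[nm]], cc$bn)
    grads[[nm]] <- list(W = crossprod(cc$Ain, bb$dU), b = colSums(bb$dU),
                        gamma = bb$dgamma, beta = bb$dbeta)
    dA <- bb$dU %*% t(model$params[[nm]]$W)
  }

  # unflatten m x (F4*P) -> (m*P) x F4
  F4 <- spec$local_filters[2L]
  dA <- matrix(as.vector(dA), m * P, F4)

  for (nm in c("local2", "local1")) {
    cc <- cache[[nm]]
    if (!is.null(cc$drop)) dA <- dA * cc$drop
    dV <- dA * (cc$V > 0)
    bb <- .bn_backward(dV, model$sites[[nm]], cc$bn)
    lb <- .local_backward(bb$dU, cc$Ain, m, model$params[[nm]]$W)
    grads[[nm]] <- list(W = lb$dW, b = lb$db,
                        gamma = bb$dgamma, beta = bb$dbeta)
    dA <- lb$dA
  }

  for (nm in c("conv2", "conv1")) {
    cc <- cache[[nm]]
    dV <- dA * (cc$V > 0)
    bb <- .bn_backward(dV, model$sites[[nm]], cc$bn)
    grads[[nm]] <- list(W = crossprod(cc$Acol, bb$dU), b = colSums(bb$dU),
                        gamma = bb$dgamma, beta = bb$dbeta)
    Fin <- if (nm == "conv1") 1L else spec$conv_filters[1L]
    dA <- .col2im(bb$dU %*% t(model$params[[nm]]$W), m, model$NB, Fin)
  }

  cc <- cache$input
  bb <- .bn_backward(matrix(dA, ncol = 1L), model$sites$input, cc$bn)
  grads$input <- list(gamma = bb$dgamma, beta = bb$dbeta)
  grads
}

#' Run a forward pass through the network
#'
#' In `eval` mode the pass is a pure function of the weights, the adapted
#' statistics and the input (dropout disabled). In `train` mode the batch
#' must be partitioned into M session-homogeneous blocks given by `block_of`
#' and each block is normalized with its own block statistics (the
#' multi-stream pass); the updated running statistics are discarded here —
#' use [emgnet()] / [finetune()] to train.
#'
#' @param model An `emgnet`.
#' @param images Frames x pixels matrix (see [frames_to_images()]).
#' @param mode `"eval"` or `"train"`.
#' @param block_of Integer vector assigning each row to a stream (train mode).
#' @return Matrix of class probabilities, one row per frame, rows summing
#'   to 1.
#' @export
emgnet_forward <- function(model, images, mode = c("eval", "train"),
                           block_of = NULL) {
  mode <- match.arg(mode)
  if (mode == "train" && !is.null(block_of)) {
    m <- nrow(images)
    M <- max(block_of)
    if (m %% M != 0L || !all(tabulate(block_of, M) == m %/% M))
      stop("batch-composition error: batch of ", m,
           " rows not divisible into ", M, " equal blocks")
  }
  .nn_forward(model, images, mode = mode, block_of = block_of)$probs
}

# --- training ---------------------------------------------------------------

.sgd_update <- function(model, grads, lr, weight_decay) {
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    model$params[[nm]]$W <- model$params[[nm]]$W -
      lr * (g$W + weight_decay * model$params[[nm]]$W)
    model$params[[nm]]$b <- model$params[[nm]]$b - lr * g$b
  }
  for (nm in names(model$sites)) {
    g <- grads[[nm]]
    if (is.null(g) || is.null(g$gamma)) next
    model$sites[[nm]]$gamma <- model$sites[[nm]]$gamma - lr * g$gamma
    model$sites[[nm]]$beta <- model$sites[[nm]]$beta - lr * g$beta
  }
  model
}

# Core SGD loop over session-structured data. update = "stream" maintains the
# per-stream running statistics (initial training); update = "target" updates
# the adapted target statistics instead (fine-tuning on calibration data).
.nn_train <- function(model, X, y, session, schedule, update = "stream",
                      pool_after = identical(update, "stream")) {
  spec <- model$spec
  m_all <- nrow(X)
  stopifnot(length(y) == m_all, length(session) == m_all)
  if (!is.null(schedule$seed)) set.seed(as.integer(schedule$seed))
  M <- spec$n_streams
  bs <- schedule$batch_size
  if (bs %% M != 0L)
    stop("schedule error: batch_size ", bs, " not divisible by n_streams ", M)
  Pblk <- bs %/% M
  sess_idx <- split(seq_len(m_all), session)
  n_sess <- length(sess_idx)
  if (n_sess < M)
    message("fewer sessions (", n_sess, ") than streams (", M,
            "): sessions are reused within batches")
  n_batches <- max(1L, ceiling(m_all / bs))
  epoch_loss <- numeric(schedule$epochs)
  if (schedule$epochs == 0L) return(model)
  for (ep in seq_len(schedule$epochs)) {
    lr <- schedule$lr / schedule$lr_drop_factor^sum(ep > schedule$lr_drop_epochs)
    losses <- numeric(n_batches)
    for (bt in seq_len(n_batches)) {
      slots <- if (n_sess >= M) sample.int(n_sess, M)
               else sample.int(n_sess, M, replace = TRUE)
      rows <- unlist(lapply(slots, function(s) {
        pool <- sess_idx[[s]]
        pool[sample.int(length(pool), Pblk, replace = length(pool) < Pblk)]
      }), use.names = FALSE)
      block_of <- rep(seq_len(M), each = Pblk)
      fw <- .nn_forward(model, X[rows, , drop = FALSE], mode = "train",
                        block_of = block_of,
                        momentum = schedule$stat_momentum,
                        update = update, keep_cache = TRUE)
      model <- fw$model
      yb <- y[rows]
      pr <- fw$probs[cbind(seq_along(rows), yb)]
      losses[bt] <- -mean(log(pmax(pr, 1e-12)))
      if (lr > 0) {
        dZ <- fw$probs
        dZ[cbind(seq_along(rows), yb)] <- dZ[cbind(seq_along(rows), yb)] - 1
        dZ <- dZ / length(rows)
        grads <- .nn_backward(model, fw$cache, dZ)
        model <- .sgd_update(model, grads, lr, schedule$weight_decay)
      }
    }
    epoch_loss[ep] <- mean(losses)
  }
  model$loss_history <- c(model$loss_history, epoch_loss)
  model$epochs_trained <- model$epochs_trained + schedule$epochs
  if (pool_after)
    model$sites <- lapply(model$sites, .bn_pool_streams)
  model
}

#' Fit the instantaneous-image gesture classifier
#'
#' Trains the 8-layer convolutional network on instantaneous sEMG images
#' with multi-stream batch normalization: every training batch is divided
#' into M session-homogeneous blocks and each block is normalized with its
#' own statistics, so that session-specific signal statistics are kept out of
#' the learned weights. After training, the per-stream statistics are pooled
#' (law of total variance) into the target statistics used at prediction
#' time; [adapt()] replaces these with statistics estimated from unlabeled
#' data of a new session.
#'
#' @param x Frames x pixels numeric matrix of image intensities (from
#'   [frames_to_images()]).
#' @param y Per-frame gesture labels (integer or factor).
#' @param session Integer vector of session identifiers per frame (one
#'   recording session = one source domain). Defaults to a single session.
#' @param spec An [emgnet_spec()]. `n_gestures` is deduced from `y` when the
#'   spec is built here from `input_shape`.
#' @param schedule An [emgnet_schedule()].
#' @param pretrained Optional fitted `emgnet` used to initialize weights and
#'   statistics (pre-training / warm start).
#' @param init_seed Seed for weight initialization when `pretrained` is NULL.
#' @return A fitted object of class `emgnet`.
#' @seealso [predict.emgnet()], [adapt()], [finetune()], [evaluate()]
#' @export
emgnet <- function(x, y, session = NULL, spec, schedule = emgnet_schedule(),
                   pretrained = NULL, init_seed = 1L) {
  x <- as.matrix(x)
  lev <- sort(unique(as.integer(y)))
  yi <- match(as.integer(y), lev)
  if (is.null(session)) session <- rep(1L, nrow(x))
  stopifnot(inherits(spec, "emgnet_spec"))
  if (spec$n_gestures != length(lev))
    stop("spec declares ", spec$n_gestures, " gestures but y has ",
         length(lev), " distinct labels")
  model <- if (is.null(pretrained)) build_network(spec, init_seed)
           else pretrained
  model$levels <- lev
  .nn_train(model, x, yi, session, schedule, update = "stream")
}

#' Train a network on the training units of an evaluation protocol
#'
#' Convenience wrapper assembling the image matrix, labels and session ids
#' from the per-trial records selected by a protocol's `train_units` and
#' fitting [emgnet()] on them. Sessions are identified by (subject, session)
#' pairs so that inter-subject training treats every subject-session as one
#' source domain.
#'
#' @param records List of per-trial [session_record()]s.
#' @param protocol An [make_protocol()] result.
#' @param layout A [grid_layout()].
#' @param spec,schedule,pretrained,init_seed Passed to [emgnet()].
#' @param in_range Amplitude range mapped to image intensity.
#' @return A fitted `emgnet`.
#' @export
train_model <- function(records, protocol, layout, spec,
                        schedule = emgnet_schedule(), pretrained = NULL,
                        init_seed = 1L, in_range = c(-1, 1)) {
  stopifnot(inherits(protocol, "eval_protocol"))
  if (nrow(protocol$train_units) == 0L) stop("no training units")
  asm <- .assemble_units(records, protocol$train_units, layout, in_range)
  emgnet(asm$x, asm$y, asm$session, spec = spec, schedule = schedule,
         pretrained = pretrained, init_seed = init_seed)
}

# Stack the frames of the selected units into (x, y, session, trial).
.assemble_units <- function(records, units, layout, in_range = c(-1, 1)) {
  xs <- vector("list", nrow(units))
  ys <- vector("list", nrow(units))
  ss <- vector("list", nrow(units))
  tr <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    r <- records[[units$index[i]]]
    xs[[i]] <- frames_to_images(r$signal, layout, in_range)
    ys[[i]] <- r$gesture
    key <- r$subject * 1000L + r$session # one domain per (subject, session)
    ss[[i]] <- rep(key, nrow(r$signal))
    tr[[i]] <- rep(i, nrow(r$signal))
  }
  list(x = do.call(rbind, xs), y = unlist(ys), session = unlist(ss),
       unit = unlist(tr))
}

# --- methods ----------------------------------------------------------------

#' Predict gesture labels or class probabilities
#'
#' Runs the eval-mode forward pass (dropout off, adapted statistics).
#' Label ties in the argmax are broken toward the smallest class label.
#'
#' @param object A fitted `emgnet`.
#' @param newdata Frames x pixels image matrix.
#' @param type `"class"` for per-frame labels, `"prob"` for the probability
#'   matrix.
#' @param ... Unused.
#' @return Integer labels (original coding) or a matrix of probabilities.
#' @export
predict.emgnet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  pr <- .nn_forward(object, as.matrix(newdata), mode = "eval")$probs
  colnames(pr) <- object$levels
  if (type == "prob") return(pr)
  object$levels[max.col(pr, ties.method = "first")]
}

#' @export
print.emgnet <- function(x, ...) {
  s <- x$spec
  cat("<emgnet> ", s$input_shape[1L], "x", s$input_shape[2L], " input, ",
      s$n_gestures, " gestures, M=", s$n_streams, " streams\n", sep = "")
  cat("  conv ", paste(s$conv_filters, collapse = "/"), " | local ",
      paste(s$local_filters, collapse = "/"), " | fc ",
      paste(s$fc_sizes, collapse = "/"), " | ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  cat("  trained ", x$epochs_trained, " epochs",
      if (length(x$loss_history))
        paste0(" (final loss ", signif(utils::tail(x$loss_history, 1L), 4), ")"),
      if (x$adapted) "; statistics adapted to target session", "\n", sep = "")
  invisible(x)
}

#' @export
summary.emgnet <- function(object, ...) {
  structure(list(model = object), class = "summary.emgnet")
}

#' @export
print.summary.emgnet <- function(x, ...) {
  print(x$model)
  lh <- x$model$loss_history
  if (length(lh)) {
    cat("  loss by epoch: ", paste(signif(lh, 3), collapse = " "), "\n", sep = "")
  }
  cat("  normalization sites:\n")
  for (nm in names(x$model$sites)) {
    s <- x$model$sites[[nm]]
    cat(sprintf("    %-7s %4d features, target mean in [%.3g, %.3g]\n",
                nm, s$n, min(s$mu_t), max(s$mu_t)))
  }
  invisible(x)
}

#' @export
coef.emgnet <- function(object, ...) {
  c(lapply(object$params, function(l) l["W"]),
    list(batchnorm = lapply(object$sites, function(s)
      list(gamma = s$gamma, beta = s$beta))))
}

#' Digest of all learnable parameters
#'
#' Serialization-based fingerprint of every weight, bias and normalization
#' scale/shift (statistics excluded). Two models have equal digests iff their
#' learnable parameters are identical; [adapt()] must leave the digest
#' unchanged.
#'
#' @param model An `emgnet`.
#' @return A character scalar.
#' @export
weight_digest <- function(model) {
  w <- list(params = model$params,
            gb = lapply(model$sites, function(s) list(s$gamma, s$beta)))
  raw <- serialize(w, NULL, xdr = TRUE)[-(1:14)] # drop format-version header
  tf <- tempfile(); on.exit(unlink(tf))
  writeBin(raw, tf)
  unname(tools::md5sum(tf))
}
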
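#' Batch normalization transform
#'
#' Applies the batch normalization affine transform to an activations matrix,
#' feature by feature (column by column):
#' `v_i = (u_i - mu_i) / sqrt(sigma2_i + eps) * gamma_i + beta_i`.
#' `mu` and `sigma2` are the normalization statistics (in training these are
#' the batch moments; after adaptation, the target-session moments), while
#' `gamma`/`beta` are the learnable scale and shift shared across streams.
#'
#' @param U Numeric matrix, batch x features.
#' @param mu,sigma2 Per-feature means and variances (length `ncol(U)` or
#'   scalar).
#' @param gamma,beta Per-feature scale and shift (length `ncol(U)` or
#'   scalar). Default to the identity transform.
#' @param eps Numerical guard added to the variance before the square root.
#' @return Matrix of the same shape as `U`.
#' @export
batchnorm_transform <- function(U, mu, sigma2, gamma = 1, beta = 0, eps = 1e-5) {
  U <- as.matrix(U)
  n <- ncol(U)
  chk <- function(v, nm) {
    if (!length(v) %in% c(1L, n))
      stop("contract error: length(", nm, ") = ", length(v),
           " does not conform to ", n, " features")
    rep_len(as.numeric(v), n)
  }
  mu <- chk(mu, "mu"); sigma2 <- chk(sigma2, "sigma2")
  gamma <- chk(gamma, "gamma"); beta <- chk(beta, "beta")
  if (any(sigma2 < 0)) stop("contract error: negative variance")
  m <- nrow(U)
  scale <- gamma / sqrt(sigma2 + eps)
  (U - rep(mu, each = m)) * rep(scale, each = m) + rep(beta, each = m)
}

# Population (biased) per-column moments, the estimator used at every
# normalization site.
.col_moments <- function(U) {
  m <- colMeans(U)
  v <- colMeans(U * U) - m * m
  v[v < 0] <- 0 # guard tiny negative round-off
  list(mu = m, var = v)
}

#' Multi-stream batch-normalization training pass
#'
#' Forward pass of multi-stream adaptive batch normalization on one batch:
#' the batch is divided into `M` session-homogeneous blocks of equal size
#' `P = m / M`; each block `k` is normalized with its own block moments
#' `mu_k = E[U[k]]`, `sigma2_k = Var[U[k]]` (population variance) and then
#' transformed with the shared learnable `gamma`/`beta`. With `M = 1` this
#' reduces exactly to classical single-stream batch normalization of the
#' whole batch.
#'
#' @param U Numeric matrix, batch x features; rows ordered so that block `k`
#'   occupies rows `(k-1)*P + 1 .. k*P`, or an arbitrary order described by
#'   `block_of`.
#' @param M Number of streams (blocks).
#' @param block_of Optional integer vector of length `nrow(U)` assigning each
#'   row to a block in `1..M`; defaults to contiguous equal blocks.
#' @param gamma,beta Shared scale and shift (per feature or scalar).
#' @param eps Variance guard.
#' @return A list with `V` (transformed activations, same shape as `U`),
#'   `mu` (`M x n` block means) and `var` (`M x n` block variances).
#' @export
multistream_train_pass <- function(U, M, block_of = NULL, gamma = 1, beta = 0,
                                   eps = 1e-5) {
  U <- as.matrix(U)
  m <- nrow(U); n <- ncol(U)
  M <- as.integer(M)
  if (is.null(block_of)) {
    if (m %% M != 0L)
      stop("batch-composition error: batch of ", m,
           " rows not divisible into ", M, " equal blocks")
    block_of <- rep(seq_len(M), each = m %/% M)
  }
  if (length(block_of) != m)
    stop("batch-composition error: block_of length does not match batch")
  gamma <- rep_len(as.numeric(gamma), n)
  beta <- rep_len(as.numeric(beta), n)
  V <- U
  mu <- matrix(0, M, n)
  va <- matrix(0, M, n)
  for (k in seq_len(M)) {
    rows <- which(block_of == k)
    if (length(rows) == 0L)
      stop("batch-composition error: block ", k, " is empty")
    mo <- .col_moments(U[rows, , drop = FALSE])
    mu[k, ] <- mo$mu
    va[k, ] <- mo$var
    sd_ <- sqrt(mo$var + eps)
    V[rows, ] <- sweep(sweep(U[rows, , drop = FALSE], 2L, mo$mu, "-"),
                       2L, gamma / sd_, "*") +
      matrix(beta, length(rows), n, byrow = TRUE)
  }
  list(V = V, mu = mu, var = va)
}

# --- internal: per-site state -----------------------------------------------

# One normalization site: per-stream running moments (mu, var: M x n) plus the
# adapted target-session moments (mu_t, var_t) used in eval mode.
.bn_site <- function(n, M) {
  list(n = n, M = M,
       mu = matrix(0, M, n), var = matrix(1, M, n),
       mu_t = rep(0, n), var_t = rep(1, n),
       gamma = rep(1, n), beta = rep(0, n),
       count = 0L, count_t = 0)
}

# Pool the M per-stream moments into a single statistic set by the law of
# total variance: pooled var = mean within-stream var + between-stream
# variance of means. Used as the pre-adaptation ("no adaptation") baseline.
.bn_pool_streams <- function(site) {
  mu_t <- colMeans(site$mu)
  var_t <- colMeans(site$var) + colMeans(site$mu^2) - mu_t^2
  var_t[var_t < 0] <- 0
  site$mu_t <- mu_t
  site$var_t <- var_t
  site$count_t <- 0 # adaptation restarts from this pooled baseline
  site
}

# Fold one calibration batch's moments into the adapted target statistics.
# momentum = NULL: equally-weighted accumulation (pooled moments over all
# frames seen so far, exact and order-invariant); numeric momentum:
# exponential moving average with that per-batch weight.
.bn_adapt_update <- function(site, mo, n_new, momentum = NULL) {
  if (is.null(momentum)) {
    n_old <- site$count_t
    if (n_old <= 0) {
      site$mu_t <- mo$mu
      site$var_t <- mo$var
    } else {
      n_tot <- n_old + n_new
      mu <- (n_old * site$mu_t + n_new * mo$mu) / n_tot
      ex2 <- (n_old * (site$var_t + site$mu_t^2) +
                n_new * (mo$var + mo$mu^2)) / n_tot
      site$mu_t <- mu
      site$var_t <- pmax(ex2 - mu^2, 0)
    }
    site$count_t <- site$count_t + n_new
  } else {
    site$mu_t <- (1 - momentum) * site$mu_t + momentum * mo$mu
    site$var_t <- (1 - momentum) * site$var_t + momentum * mo$var
    site$count_t <- site$count_t + n_new
  }
  site
}

# Train-mode forward at one site. Returns transformed activations, cache for
# the backward pass, and the site with running stream stats updated.
# block_of gives the stream of each *sample*; rows_per_sample > 1 for
# convolutional/locally-connected sites where each sample spans spatial rows
# (sample s of a batch of m occupies rows (p-1)*m + s for positions p).
.bn_forward_train <- function(U, site, block_of, rows_per_sample = 1L,
                              momentum = 0.1, eps = 1e-5,
                              update = c("stream", "target", "none")) {
  update <- match.arg(update)
  m <- length(block_of)
  M <- max(block_of)
  row_block <- if (rows_per_sample == 1L) block_of else rep.int(block_of, rows_per_sample)
  V <- U
  cache <- vector("list", M)
  for (k in seq_len(M)) {
    rows <- which(row_block == k)
    Uk <- U[rows, , drop = FALSE]
    mo <- .col_moments(Uk)
    sd_ <- sqrt(mo$var + eps)
    mk <- length(rows)
    xhat <- (Uk - rep(mo$mu, each = mk)) * rep(1 / sd_, each = mk)
    V[rows, ] <- xhat * rep(site$gamma, each = mk) +
      rep(site$beta, each = mk)
    cache[[k]] <- list(rows = rows, xhat = xhat, sd = sd_)
    if (update == "stream") {
      site$mu[k, ] <- (1 - momentum) * site$mu[k, ] + momentum * mo$mu
      site$var[k, ] <- (1 - momentum) * site$var[k, ] + momentum * mo$var
    } else if (update == "target") {
      site$mu_t <- (1 - momentum) * site$mu_t + momentum * mo$mu
      site$var_t <- (1 - momentum) * site$var_t + momentum * mo$var
    }
  }
  if (update == "stream") site$count <- site$count + 1L
  list(V = V, cache = cache, site = site)
}

# Backward through a train-mode normalization site (population variance).
.bn_backward <- function(dV, site, cache) {
  dU <- dV
  dgamma <- numeric(site$n)
  dbeta <- numeric(site$n)
  for (k in seq_along(cache)) {
    cc <- cache[[k]]
    rows <- cc$rows
    dVk <- dV[rows, , drop = FALSE]
    dbeta <- dbeta + colSums(dVk)
    dgamma <- dgamma + colSums(dVk * cc$xhat)
    mk <- length(rows)
    dxhat <- dVk * rep(site$gamma, each = mk)
    mdx <- colMeans(dxhat)
    mdxx <- colMeans(dxhat * cc$xhat)
    dU[rows, ] <- (dxhat - rep(mdx, each = mk) -
                     cc$xhat * rep(mdxx, each = mk)) *
      rep(1 / cc$sd, each = mk)
  }
  list(dU = dU, dgamma = dgamma, dbeta = dbeta)
}

# Eval-mode forward: pure function of adapted target statistics.
.bn_forward_eval <- function(U, site, eps = 1e-5) {
  batchnorm_transform(U, site$mu_t, site$var_t, site$gamma, site$beta, eps)
}
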
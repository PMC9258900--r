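#' Draw i.i.d. uniform sequences
#'
#' Every symbol (including the gap) at every position with equal probability
#' \code{1/q}.
#'
#' @param N sequence length
#' @param q alphabet size
#' @param n number of sequences
#' @param seed RNG seed
#' @return integer code matrix \code{(n, N)}
#' @export
sample_uniform <- function(N, q, n, seed = NULL) {
  local_rng(seed)
  matrix(sample.int(q, n * N, replace = TRUE), n, N)
}

#' Bundle sequences with their original-model energies
#'
#' The regression data for distillation: sequences drawn from a distribution
#' D together with the original model's energies on them.
#'
#' @param seqs integer code matrix
#' @param energies numeric vector, one per sequence
#' @param source \code{"U"} (uniform), \code{"M"} (original-model samples)
#'   or \code{"explicit"}
#' @param estimator list describing how energies were computed (e.g.
#'   \code{list(exact = TRUE)} or \code{list(exact = FALSE, K = 5000,
#'   seed = 1)})
#' @return object of class \code{energy_sample_set}
#' @export
energy_sample_set <- function(seqs, energies, source = "explicit",
                              estimator = list(exact = TRUE)) {
  seqs <- as_code_matrix(seqs)
  if (nrow(seqs) != length(energies))
    stop("one energy per sequence required")
  if (any(!is.finite(energies))) stop("energies must be finite")
  structure(list(seqs = seqs, energies = as.numeric(energies),
                 source = source, estimator = estimator),
            class = "energy_sample_set")
}

#' Prepare distillation samples and energies from an original model
#'
#' @param model the original model (energy contract)
#' @param distribution \code{"M"} (the model's own distribution) or
#'   \code{"U"} (uniform)
#' @param n_samples number of sequences
#' @param seed RNG seed (sampling and, for estimated energies, the
#'   estimator)
#' @param K_target importance samples per energy when the original model's
#'   energies are estimates (VAE); ignored for exact models
#' @return an \code{energy_sample_set}
#' @export
prepare_sample_set <- function(model, distribution = c("M", "U"),
                               n_samples, seed = 1L, K_target = 5000) {
  distribution <- match.arg(distribution)
  N <- n_sites(model); q <- n_states(model)
  S <- if (distribution == "M") model_sample(model, n_samples, seed = seed)
       else sample_uniform(N, q, n_samples, seed = seed)
  if (is_estimated_energy(model)) {
    E <- energy(model, S, K = K_target, seed = seed + 1L)
    est <- list(exact = FALSE, K = K_target, seed = seed + 1L)
  } else {
    E <- energy(model, S)
    est <- list(exact = TRUE)
  }
  energy_sample_set(S, E, source = distribution, estimator = est)
}

#' Mean squared error in energies of a candidate model on a sample set
#'
#' @param sample_set an \code{energy_sample_set}
#' @param candidate a \code{pairwise_model} or \code{independent_model}
#' @return mean over samples of the squared energy difference
#' @export
mse_loss <- function(sample_set, candidate) {
  mean((sample_set$energies - energy(candidate, sample_set$seqs))^2)
}

# ---- feature bookkeeping for the linear least-squares view ------------------
# E_pw(s) = -(x(s) . theta) with binary features: constant, one field
# indicator per position, one coupling indicator per position pair.

pair_table <- function(N) {
  if (N < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(N, 2))
}

n_features <- function(N, q, family) {
  if (family == "pairwise") 1L + N * q + nrow(pair_table(N)) * q * q
  else 1L + N * q
}

# Sparse design matrix of active features for each row of S.
design_matrix <- function(S, q, family) {
  n <- nrow(S); N <- ncol(S)
  P <- n_features(N, q, family)
  rows <- rep(seq_len(n), 1L + N)
  cols <- c(rep(1L, n),
            unlist(lapply(seq_len(N),   # column-major h layout: (a-1)*N + i
                          function(i) 1L + (S[, i] - 1L) * N + i)))
  if (family == "pairwise" && N >= 2) {
    pt <- pair_table(N)
    off <- 1L + N * q
    for (p in seq_len(nrow(pt))) {
      i <- pt[p, 1]; j <- pt[p, 2]
      rows <- c(rows, seq_len(n))
      cols <- c(cols, off + (p - 1L) * q * q + (S[, j] - 1L) * q + S[, i])
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(n, P))
}

theta_to_model <- function(theta, N, q, family, alphabet) {
  C <- theta[1]
  h <- matrix(theta[1L + seq_len(N * q)], N, q)
  if (family == "independent")
    return(independent_model(h, C, alphabet = alphabet))
  J <- array(0, dim = c(N, N, q, q))
  pt <- pair_table(N)
  off <- 1L + N * q
  for (p in seq_len(nrow(pt))) {
    blk <- theta[off + (p - 1L) * q * q + seq_len(q * q)]
    J[pt[p, 1], pt[p, 2], , ] <- matrix(blk, q, q)  # rows s_i, cols s_j
  }
  pairwise_model(J, h, C, alphabet = alphabet)
}

#' Exact minimizer of the energy MSE over a weighted enumeration (oracle)
#'
#' Solves the weighted least-squares problem
#' \eqn{\min_{J,h,C} \sum_s w(s) (E^M(s) - E^{pw}(s))^2} over the full
#' enumeration of sequence space.  Because gauge transformations leave the
#' fitted energies unchanged, the design matrix is rank-deficient; the
#' minimum-norm solution is taken (eigendecomposition pseudo-inverse) and
#' the returned model is re-expressed in the zero-sum gauge.  With uniform
#' weights this reproduces the order-2 truncation of the zero-sum
#' interaction expansion of the original energy.
#'
#' @param model the original model (exact energies required)
#' @param weights nonnegative weights over all \code{q^N} sequences in
#'   lexicographic order (default uniform); normalized internally
#' @param family \code{"pairwise"} or \code{"independent"}
#' @param cap enumeration cap
#' @return fitted model with attributes \code{"achieved_loss"} (weighted
#'   MSE at the minimizer) and \code{"route"}
#' @export
extract_exact <- function(model, weights = NULL,
                          family = c("pairwise", "independent"),
                          cap = 1e6) {
  family <- match.arg(family)
  N <- n_sites(model); q <- n_states(model)
  S <- enumerate_sequences(N, q, cap = cap)
  E <- energy(model, S)
  w <- weights %||% rep(1, nrow(S))
  if (length(w) != nrow(S) || any(w < 0))
    stop("weights must be nonnegative, one per enumerated sequence")
  w <- w / sum(w)
  X <- design_matrix(S, q, family)
  y <- -E
  A <- as.matrix(Matrix::crossprod(X, X * w))
  b <- as.numeric(Matrix::crossprod(X, w * y))
  eig <- eigen(A, symmetric = TRUE)
  tol <- max(eig$values) * 1e-10
  keep <- eig$values > tol
  theta <- eig$vectors[, keep, drop = FALSE] %*%
    ((t(eig$vectors[, keep, drop = FALSE]) %*% b) / eig$values[keep])
  fitted <- theta_to_model(as.numeric(theta), N, q, family,
                           alphabet_of(model))
  fitted <- to_zero_sum_gauge(fitted)
  attr(fitted, "achieved_loss") <- sum(w * (E - energy(fitted, S))^2)
  attr(fitted, "route") <- "exact"
  fitted
}

alphabet_of <- function(model) model$alphabet %||% default_alphabet(n_states(model))

#' Closed-form uniform-distribution extraction by conditional averages
#'
#' Monte-Carlo version of the uniform-distribution minimizer: draws
#' \code{n_samples} uniform sequences, evaluates the original energies, and
#' forms the conditional-mean estimators of the zero-sum expansion (grand
#' mean for the constant, single-site conditional means for fields, pair
#' conditional means with lower-order terms subtracted for couplings).
#' Conditional cells never observed fall back to the grand-mean estimate
#' (zero coefficient).  The output is re-expressed in the zero-sum gauge.
#'
#' @param model the original model
#' @param n_samples number of uniform samples
#' @param seed RNG seed
#' @param family \code{"pairwise"} or \code{"independent"}
#' @param K_target importance samples per energy for estimated-energy models
#' @return fitted model with attribute \code{"route"}
#' @export
extract_uniform_closed_form <- function(model, n_samples, seed = 1L,
                                        family = c("pairwise", "independent"),
                                        K_target = 5000) {
  family <- match.arg(family)
  N <- n_sites(model); q <- n_states(model)
  S <- sample_uniform(N, q, n_samples, seed = seed)
  E <- if (is_estimated_energy(model))
    energy(model, S, K = K_target, seed = seed + 1L) else energy(model, S)
  f0 <- mean(E)
  cond1 <- matrix(f0, N, q)  # empty cells keep the grand mean
  for (i in seq_len(N)) {
    cnt <- tabulate(S[, i], nbins = q)
    sums <- numeric(q)
    R <- rowsum(E, S[, i])
    sums[as.integer(rownames(R))] <- R
    cond1[i, cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  }
  f1 <- cond1 - f0
  h <- -f1
  if (family == "independent") {
    fit <- independent_model(h, C = -f0, alphabet = alphabet_of(model))
    fit <- to_zero_sum_gauge(fit)
    attr(fit, "route") <- "uniform_closed_form"
    return(fit)
  }
  J <- array(0, dim = c(N, N, q, q))
  if (N >= 2) {
    pt <- pair_table(N)
    for (p in seq_len(nrow(pt))) {
      i <- pt[p, 1]; j <- pt[p, 2]
      g <- (S[, j] - 1L) * q + S[, i]
      cnt <- tabulate(g, nbins = q * q)
      sums <- numeric(q * q)
      R <- rowsum(E, g)
      sums[as.integer(rownames(R))] <- R
      cond2 <- matrix(f0, q, q)  # rows s_i, cols s_j
      nz <- cnt > 0
      cond2[nz] <- sums[nz] / cnt[nz]
      f2 <- cond2 - outer(f1[i, ], rep(1, q)) - outer(rep(1, q), f1[j, ]) - f0
      f2[!nz] <- 0
      J[i, j, , ] <- -f2
    }
  }
  fit <- pairwise_model(J, h, C = -f0, alphabet = alphabet_of(model))
  fit <- to_zero_sum_gauge(fit)
  attr(fit, "route") <- "uniform_closed_form"
  fit
}

#' Extraction protocol configuration
#'
#' Defaults follow the reference stochastic-gradient protocol: 1e7 prepared
#' samples, Adam with batch size 10000, every in-batch sample independently
#' replaced by a fresh uniform sequence with probability 1\%, an exponential
#' moving average of batch losses with smoothing factor 0.9, stopping when
#' the EMA has not reached a new minimum within 1000 steps, and all
#' parameters initialized to 0.  \code{n_samples} and \code{max_steps} are
#' routinely reduced for small problems.
#'
#' @param distribution \code{"M"}, \code{"U"} or \code{"explicit"}
#' @param family \code{"pairwise"} or \code{"independent"}
#' @param n_samples prepared sample count
#' @param batch_size Adam batch size
#' @param uniform_mix_prob per-sample uniform replacement probability
#' @param ema_factor smoothing factor of the batch-loss EMA
#' @param patience_steps stop after this many steps without a new EMA
#'   minimum
#' @param step_size,beta1,beta2,epsilon Adam hyperparameters
#' @param max_steps hard cap on gradient steps
#' @param seed RNG seed (sample preparation, batching, mixing)
#' @param K_target importance samples per energy for estimated-energy
#'   originals
#' @param sample_set optional precomputed \code{energy_sample_set}
#'   (\code{distribution = "explicit"})
#' @return list of class \code{extraction_config}
#' @export
extraction_config <- function(distribution = c("M", "U", "explicit"),
                              family = c("pairwise", "independent"),
                              n_samples = 1e7, batch_size = 10000,
                              uniform_mix_prob = 0.01, ema_factor = 0.9,
                              patience_steps = 1000, step_size = 1e-3,
                              beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                              max_steps = Inf, seed = 1L, K_target = 5000,
                              sample_set = NULL) {
  distribution <- match.arg(distribution)
  family <- match.arg(family)
  stopifnot(uniform_mix_prob >= 0, uniform_mix_prob <= 1,
            ema_factor >= 0, ema_factor < 1,
            n_samples >= 1, batch_size >= 1, patience_steps >= 1)
  structure(list(distribution = distribution, family = family,
                 n_samples = n_samples, batch_size = batch_size,
                 uniform_mix_prob = uniform_mix_prob,
                 ema_factor = ema_factor, patience_steps = patience_steps,
                 step_size = step_size, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, max_steps = max_steps,
                 seed = as.integer(seed), K_target = K_target,
                 sample_set = sample_set),
            class = "extraction_config")
}

#' Stochastic-gradient extraction of a pairwise or independent model
#'
#' Prepares \code{n_samples} sequences from the chosen distribution with
#' their original-model energies, then minimizes the energy MSE by Adam:
#' each step draws \code{batch_size} samples individually (with
#' replacement) from the prepared pool, independently replaces each with a
#' fresh uniform sequence with probability \code{uniform_mix_prob}
#' (computing the original energy of the replacement on the fly, so rare
#' symbol combinations stay identifiable), and updates the parameters.  An
#' exponential moving average of batch losses governs early stopping; the
#' returned parameters are the checkpoint at the minimal EMA.  For the
#' independent family the coupling gradient is discarded (couplings stay at
#' their zero initialization).
#'
#' @param model the original model (energy contract with a sampler)
#' @param config an \code{\link{extraction_config}}
#' @return fitted model (zero-sum gauge) with attributes
#'   \code{"training_log"} (data.frame of step, batch loss, EMA),
#'   \code{"route"} and \code{"achieved_ema"}
#' @export
extract_sgd <- function(model, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  N <- n_sites(model); q <- n_states(model)
  pairwise <- config$family == "pairwise"
  if (config$distribution == "explicit") {
    ss <- config$sample_set
    if (is.null(ss)) stop("explicit distribution requires a sample_set")
  } else {
    ss <- prepare_sample_set(model, config$distribution, config$n_samples,
                             seed = config$seed, K_target = config$K_target)
  }
  S <- ss$seqs; E <- ss$energies
  n <- nrow(S)
  local_rng(config$seed + 1L)

  model_energy <- function(Srep) {
    if (is_estimated_energy(model))
      energy(model, Srep, K = config$K_target,
             seed = sample.int(.Machine$integer.max, 1))
    else energy(model, Srep)
  }

  pt <- pair_table(N)
  npair <- nrow(pt)
  C <- 0
  h <- matrix(0, N, q)
  J3 <- if (pairwise) array(0, dim = c(q, q, npair))
  # Adam moment buffers
  mC <- vC <- 0
  mh <- vh <- matrix(0, N, q)
  if (pairwise) { mJ <- vJ <- array(0, dim = c(q, q, npair)) }
  b1 <- config$beta1; b2 <- config$beta2; lr <- config$step_size
  eps <- config$epsilon
  ema <- NA_real_; best_ema <- Inf; best <- NULL; since_best <- 0L
  steps <- batch_losses <- emas <- numeric(0)
  step <- 0L
  B <- config$batch_size

  while (step < config$max_steps && since_best < config$patience_steps) {
    step <- step + 1L
    idx <- sample.int(n, B, replace = TRUE)
    Sb <- S[idx, , drop = FALSE]
    Eb <- E[idx]
    if (config$uniform_mix_prob > 0) {
      repl <- which(stats::runif(B) < config$uniform_mix_prob)
      if (length(repl)) {
        Sb[repl, ] <- matrix(sample.int(q, length(repl) * N, replace = TRUE),
                             length(repl), N)
        Eb[repl] <- model_energy(Sb[repl, , drop = FALSE])
      }
    }
    # candidate energies and residuals
    acc <- rep(C, B)
    for (i in seq_len(N)) acc <- acc + h[i, Sb[, i]]
    if (pairwise && npair > 0) {
      for (p in seq_len(npair)) {
        acc <- acc + J3[, , p][cbind(Sb[, pt[p, 1]], Sb[, pt[p, 2]])]
      }
    }
    r <- Eb + acc            # = Eb - (-acc) = residual E^M - E_pw
    loss <- mean(r^2)
    if (!is.finite(loss)) stop("non-finite extraction loss at step ", step)
    # gradients of the batch MSE (E_pw is linear in the parameters)
    gC <- 2 * mean(r)
    gh <- matrix(0, N, q)
    for (i in seq_len(N)) {
      R <- rowsum(r, Sb[, i])
      gh[i, as.integer(rownames(R))] <- 2 * R / B
    }
    if (pairwise && npair > 0) {
      gJ <- array(0, dim = c(q, q, npair))
      for (p in seq_len(npair)) {
        g <- (Sb[, pt[p, 2]] - 1L) * q + Sb[, pt[p, 1]]
        R <- rowsum(r, g)
        Gp <- numeric(q * q)
        Gp[as.integer(rownames(R))] <- 2 * R / B
        gJ[, , p] <- matrix(Gp, q, q)
      }
    }
    # Adam
    t_ <- step
    corr <- sqrt(1 - b2^t_) / (1 - b1^t_)
    mC <- b1 * mC + (1 - b1) * gC; vC <- b2 * vC + (1 - b2) * gC^2
    C <- C - lr * corr * mC / (sqrt(vC) + eps)
    mh <- b1 * mh + (1 - b1) * gh; vh <- b2 * vh + (1 - b2) * gh^2
    h <- h - lr * corr * mh / (sqrt(vh) + eps)
    if (pairwise && npair > 0) {
      mJ <- b1 * mJ + (1 - b1) * gJ; vJ <- b2 * vJ + (1 - b2) * gJ^2
      J3 <- J3 - lr * corr * mJ / (sqrt(vJ) + eps)
    }
    ema <- if (is.na(ema)) loss
           else config$ema_factor * ema + (1 - config$ema_factor) * loss
    steps <- c(steps, step); batch_losses <- c(batch_losses, loss)
    emas <- c(emas, ema)
    if (ema < best_ema) {
      best_ema <- ema
      best <- list(C = C, h = h, J3 = if (pairwise) J3)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
  }

  C <- best$C; h <- best$h
  if (pairwise) {
    J <- array(0, dim = c(N, N, q, q))
    for (p in seq_len(npair)) J[pt[p, 1], pt[p, 2], , ] <- best$J3[, , p]
    fit <- pairwise_model(J, h, C, alphabet = alphabet_of(model))
  } else {
    fit <- independent_model(h, C, alphabet = alphabet_of(model))
  }
  fit <- to_zero_sum_gauge(fit)
  attr(fit, "training_log") <- data.frame(step = steps,
                                          batch_loss = batch_losses,
                                          ema = emas)
  attr(fit, "achieved_ema") <- best_ema
  attr(fit, "route") <- "sgd"
  attr(fit, "sample_set_source") <- ss$source
  fit
}
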
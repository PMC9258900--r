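#' Construct a one-hidden-layer variational autoencoder over sequences
#'
#' The encoder maps the one-hot sequence (length \code{N*q}) through a
#' single tanh layer to the mean and log variance of a diagonal Gaussian
#' over a d-dimensional latent \code{z}; the decoder maps \code{z} through
#' a single tanh layer to per-position softmax distributions over the q
#' symbols.  The prior on \code{z} is standard normal.  The marginal
#' likelihood \eqn{p(s) = \int p(s|z) N(z; 0, I) dz} is intractable, so the
#' energy \eqn{-\log p(s)} is an importance-sampling estimate
#' (\code{\link{vae_energy_importance}}) and the model's energies are
#' flagged as estimated.
#'
#' @param params named list of parameter matrices/vectors:
#'   \code{W_enc (H x Nq)}, \code{b_enc (H)}, \code{W_mu}, \code{b_mu},
#'   \code{W_sigma}, \code{b_sigma} (latent d rows), \code{W_dec (H x d)},
#'   \code{b_dec (H)}, \code{W_s (Nq x H)}, \code{b_s (Nq)}
#' @param N sequence length
#' @param q alphabet size
#' @param alphabet symbol ordering
#' @return object of class \code{vae_model}
#' @export
vae_model <- function(params, N, q, alphabet = default_alphabet(q)) {
  H <- length(params$b_enc)
  d <- length(params$b_mu)
  stopifnot(all(dim(params$W_enc) == c(H, N * q)),
            all(dim(params$W_mu) == c(d, H)),
            all(dim(params$W_sigma) == c(d, H)),
            length(params$b_sigma) == d,
            all(dim(params$W_dec) == c(H, d)),
            length(params$b_dec) == H,
            all(dim(params$W_s) == c(N * q, H)),
            length(params$b_s) == N * q)
  structure(list(params = params, N = N, q = q, hidden = H, latent = d,
                 alphabet = alphabet),
            class = "vae_model")
}

#' @export
n_sites.vae_model <- function(model) model$N
#' @export
n_states.vae_model <- function(model) model$q
#' @export
is_estimated_energy.vae_model <- function(model) TRUE

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("VAE: N = %d, q = %d, hidden = %d, latent = %d\n",
              x$N, x$q, x$hidden, x$latent))
  invisible(x)
}

#' Zero-initialized or randomly initialized VAE
#'
#' @param N,q sequence length and alphabet size
#' @param hidden,latent layer widths
#' @param init_sd standard deviation of the Gaussian weight initialization
#'   (biases start at 0); \code{0} gives the all-zero model whose decoder is
#'   uniform over symbols
#' @param seed seed for the initialization draw
#' @param alphabet symbol ordering
#' @return a \code{vae_model}
#' @export
vae_init <- function(N, q, hidden = 40, latent = 5, init_sd = 0.05,
                     seed = NULL, alphabet = default_alphabet(q)) {
  local_rng(seed)
  rmat <- function(r, c) matrix(stats::rnorm(r * c, sd = init_sd), r, c)
  params <- list(
    W_enc = rmat(hidden, N * q), b_enc = numeric(hidden),
    W_mu = rmat(latent, hidden), b_mu = numeric(latent),
    W_sigma = rmat(latent, hidden), b_sigma = numeric(latent),
    W_dec = rmat(hidden, latent), b_dec = numeric(hidden),
    W_s = rmat(N * q, hidden), b_s = numeric(N * q))
  vae_model(params, N, q, alphabet)
}

# One-hot encode a code matrix: n x (N*q), position i in columns
# (i-1)*q + 1 .. i*q.
one_hot <- function(S, q) {
  n <- nrow(S); N <- ncol(S)
  X <- matrix(0, n, N * q)
  for (i in seq_len(N)) X[cbind(seq_len(n), (i - 1L) * q + S[, i])] <- 1
  X
}

add_bias <- function(A, b) sweep(A, 2, b, `+`)

# Encoder forward pass for a batch (rows = sequences).
vae_encode_batch <- function(m, X) {
  p <- m$params
  He <- tanh(add_bias(X %*% t(p$W_enc), p$b_enc))
  list(He = He,
       mu = add_bias(He %*% t(p$W_mu), p$b_mu),
       log_var = add_bias(He %*% t(p$W_sigma), p$b_sigma))
}

# Decoder forward pass: Z (rows = latent points) -> per-position log
# probabilities (n x N*q) and hidden activations.
vae_decode_batch <- function(m, Z) {
  p <- m$params
  Hd <- tanh(add_bias(Z %*% t(p$W_dec), p$b_dec))
  G <- add_bias(Hd %*% t(p$W_s), p$b_s)
  logP <- G
  for (i in seq_len(m$N)) {
    cols <- (i - 1L) * m$q + seq_len(m$q)
    L <- G[, cols, drop = FALSE]
    mx <- apply(L, 1, max)
    logP[, cols] <- L - (mx + log(rowSums(exp(L - mx))))
  }
  list(Hd = Hd, logits = G, logP = logP)
}

#' Encode a sequence to its posterior mean and log variance
#'
#' @param m a \code{vae_model}
#' @param s integer code vector
#' @return list with numeric vectors \code{mu} and \code{log_var} of length
#'   \code{latent}
#' @export
vae_encode <- function(m, s) {
  X <- one_hot(check_codes(as_code_matrix(s), m$N, m$q), m$q)
  enc <- vae_encode_batch(m, X)
  list(mu = drop(enc$mu), log_var = drop(enc$log_var))
}

#' Decode a latent point to per-position symbol distributions
#'
#' @param m a \code{vae_model}
#' @param z numeric vector of length \code{latent}
#' @return \code{N x q} matrix of probabilities; each row sums to 1
#' @export
vae_decode <- function(m, z) {
  if (length(z) != m$latent) stop("z must have length ", m$latent)
  dec <- vae_decode_batch(m, matrix(z, nrow = 1))
  matrix(exp(dec$logP[1, ]), m$N, m$q, byrow = TRUE)
}

# log p(s | z) for paired rows of S and Z.
vae_log_cond <- function(m, S, Z) {
  dec <- vae_decode_batch(m, Z)
  n <- nrow(S)
  lp <- numeric(n)
  for (i in seq_len(m$N))
    lp <- lp + dec$logP[cbind(seq_len(n), (i - 1L) * m$q + S[, i])]
  lp
}

#' Monte-Carlo ELBO of sequences under a VAE
#'
#' Reparameterized estimate of
#' \eqn{E_{q(z|s)}[\log p(s|z)] - KL(q(z|s) \| N(0, I))} with the KL term in
#' closed form.  Deterministic given the seed.
#'
#' @param m a \code{vae_model}
#' @param seqs code matrix or vector
#' @param n_mc number of Monte-Carlo draws per sequence
#' @param seed RNG seed
#' @return numeric vector, one ELBO value per sequence
#' @export
vae_elbo <- function(m, seqs, n_mc = 1, seed = NULL) {
  S <- check_codes(as_code_matrix(seqs), m$N, m$q)
  local_rng(seed)
  X <- one_hot(S, m$q)
  enc <- vae_encode_batch(m, X)
  n <- nrow(S)
  kl <- 0.5 * rowSums(enc$mu^2 + exp(enc$log_var) - 1 - enc$log_var)
  recon <- numeric(n)
  sig <- exp(enc$log_var / 2)
  for (k in seq_len(n_mc)) {
    Eps <- matrix(stats::rnorm(n * m$latent), n, m$latent)
    Z <- enc$mu + sig * Eps
    recon <- recon + vae_log_cond(m, S, Z)
  }
  recon / n_mc - kl
}

#' Train a VAE by full-batch gradient descent on the weighted ELBO
#'
#' Maximizes the weighted ELBO (weights normalized to sum to one) minus a
#' weight-decay penalty on the weight matrices (biases are not decayed).
#' One fresh reparameterization draw per sequence per step.  Deterministic
#' given the seed.
#'
#' @param aln training \code{encoded_alignment}
#' @param weights per-sequence weights (default: alignment weights or uniform)
#' @param hidden,latent layer widths (defaults 40 and 5)
#' @param weight_decay L2 penalty on weight matrices
#' @param steps number of gradient steps
#' @param lr learning rate
#' @param seed RNG seed for initialization and reparameterization draws
#' @param init_sd weight initialization scale
#' @return a trained \code{vae_model} with attribute \code{"loss_trace"}
#'   (the per-step training loss)
#' @export
train_vae <- function(aln, weights = NULL, hidden = 40, latent = 5,
                      weight_decay = 0.01, steps = 300, lr = 0.05,
                      seed = 1L, init_sd = 0.05) {
  S <- aln$seqs
  n <- nrow(S); N <- ncol(S); q <- length(aln$alphabet)
  if (n < 2) stop("need at least 2 sequences to train")
  w <- weights %||% aln$weights %||% rep(1, n)
  w <- w / sum(w)
  local_rng(seed)
  m <- vae_init(N, q, hidden, latent, init_sd = init_sd, seed = NULL,
                alphabet = aln$alphabet)
  X <- one_hot(S, q)
  decayed <- c("W_enc", "W_mu", "W_sigma", "W_dec", "W_s")
  trace <- numeric(steps)
  for (step in seq_len(steps)) {
    p <- m$params
    He <- tanh(add_bias(X %*% t(p$W_enc), p$b_enc))
    Mu <- add_bias(He %*% t(p$W_mu), p$b_mu)
    Lv <- add_bias(He %*% t(p$W_sigma), p$b_sigma)
    sig <- exp(Lv / 2)
    Eps <- matrix(stats::rnorm(n * latent), n, latent)
    Z <- Mu + sig * Eps
    Hd <- tanh(add_bias(Z %*% t(p$W_dec), p$b_dec))
    G <- add_bias(Hd %*% t(p$W_s), p$b_s)
    # per-position softmax probabilities and reconstruction log-likelihood
    P <- G; recon <- numeric(n)
    for (i in seq_len(N)) {
      cols <- (i - 1L) * q + seq_len(q)
      L <- G[, cols, drop = FALSE]
      mx <- apply(L, 1, max)
      logp <- L - (mx + log(rowSums(exp(L - mx))))
      P[, cols] <- exp(logp)
      recon <- recon + logp[cbind(seq_len(n), S[, i])]
    }
    kl <- 0.5 * rowSums(Mu^2 + exp(Lv) - 1 - Lv)
    loss <- -sum(w * (recon - kl)) +
      weight_decay * sum(vapply(decayed, function(nm) sum(p[[nm]]^2),
                                numeric(1)))
    if (!is.finite(loss)) stop("non-finite VAE training loss at step ", step)
    trace[step] <- loss

    dG <- (P - X) * w
    gWs <- t(dG) %*% Hd + 2 * weight_decay * p$W_s
    gbs <- colSums(dG)
    dHd <- dG %*% p$W_s
    dAd <- dHd * (1 - Hd^2)
    gWdec <- t(dAd) %*% Z + 2 * weight_decay * p$W_dec
    gbdec <- colSums(dAd)
    dZ <- dAd %*% p$W_dec
    dMu <- dZ + Mu * w
    dLv <- dZ * Eps * sig * 0.5 + 0.5 * (exp(Lv) - 1) * w
    gWmu <- t(dMu) %*% He + 2 * weight_decay * p$W_mu
    gbmu <- colSums(dMu)
    gWsig <- t(dLv) %*% He + 2 * weight_decay * p$W_sigma
    gbsig <- colSums(dLv)
    dHe <- dMu %*% p$W_mu + dLv %*% p$W_sigma
    dAe <- dHe * (1 - He^2)
    gWenc <- t(dAe) %*% X + 2 * weight_decay * p$W_enc
    gbenc <- colSums(dAe)

    m$params <- list(
      W_enc = p$W_enc - lr * gWenc, b_enc = p$b_enc - lr * gbenc,
      W_mu = p$W_mu - lr * gWmu, b_mu = p$b_mu - lr * gbmu,
      W_sigma = p$W_sigma - lr * gWsig, b_sigma = p$b_sigma - lr * gbsig,
      W_dec = p$W_dec - lr * gWdec, b_dec = p$b_dec - lr * gbdec,
      W_s = p$W_s - lr * gWs, b_s = p$b_s - lr * gbs)
  }
  attr(m, "loss_trace") <- trace
  m
}

#' @export
model_sample.vae_model <- function(model, n, seed = NULL, ...) {
  local_rng(seed)
  Z <- matrix(stats::rnorm(n * model$latent), n, model$latent)
  dec <- vae_decode_batch(model, Z)
  S <- matrix(1L, n, model$N)
  for (i in seq_len(model$N)) {
    cols <- (i - 1L) * model$q + seq_len(model$q)
    P <- exp(dec$logP[, cols, drop = FALSE])
    cum <- P
    if (model$q > 1)
      for (cc in 2:model$q) cum[, cc] <- cum[, cc - 1] + P[, cc]
    u <- stats::runif(n)
    S[, i] <- 1L + as.integer(rowSums(cum < u))
  }
  S
}

#' Importance-sampling estimate of a VAE sequence energy
#'
#' Estimates \eqn{-\log p(s)} with
#' \eqn{\hat p(s) = K^{-1} \sum_k p(s|z_k) N(z_k; 0, I) / q(z_k|s)},
#' \eqn{z_k \sim q(z|s)}, computed in log space via log-sum-exp.
#' Deterministic given the seed.
#'
#' @param m a \code{vae_model}
#' @param s integer code vector (one sequence)
#' @param K number of importance samples (default 5000)
#' @param seed RNG seed
#' @return estimated energy (a single number)
#' @export
vae_energy_importance <- function(m, s, K = 5000, seed = NULL) {
  local_rng(seed)
  vae_energy_importance_once(m, as.integer(s), K)
}

vae_energy_importance_once <- function(m, s, K) {
  enc <- vae_encode(m, s)
  sig <- exp(enc$log_var / 2)
  d <- m$latent
  Eps <- matrix(stats::rnorm(K * d), K, d)
  Z <- matrix(enc$mu, K, d, byrow = TRUE) + matrix(sig, K, d, byrow = TRUE) * Eps
  S <- matrix(rep(s, each = K), K, m$N)
  log_cond <- vae_log_cond(m, S, Z)
  log_prior <- rowSums(stats::dnorm(Z, log = TRUE))
  log_q <- rowSums(stats::dnorm(Z, mean = matrix(enc$mu, K, d, byrow = TRUE),
                                sd = matrix(sig, K, d, byrow = TRUE),
                                log = TRUE))
  -(logsumexp(log_cond + log_prior - log_q) - log(K))
}

#' @rdname energy
#' @param K importance samples per sequence (VAE energies only)
#' @param seed RNG seed for the estimator (VAE energies only)
#' @export
energy.vae_model <- function(model, seqs, K = 5000, seed = 1L, ...) {
  S <- check_codes(as_code_matrix(seqs), model$N, model$q)
  local_rng(seed)
  vapply(seq_len(nrow(S)),
         function(r) vae_energy_importance_once(model, S[r, ], K),
         numeric(1))
}
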
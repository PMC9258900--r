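# Small model builders shared across tests.

toy_alphabet <- function(q) default_alphabet(q)

# Deterministic tiny pairwise model used in hand-worked examples:
# N = 2, q = 2, h = ((1, 0), (0, 2)), J[1,2](1,1) = 3, C = 0.
hand_pairwise <- function() {
  h <- rbind(c(1, 0), c(0, 2))
  J <- array(0, dim = c(2, 2, 2, 2))
  J[1, 2, 1, 1] <- 3
  pairwise_model(J, h, C = 0, alphabet = toy_alphabet(2))
}

# Parity energy on q = 2, N = 3: E(s) = (-1)^(s1 + s2 + s3), a pure
# three-body interaction (zero-sum along every axis).
parity_model <- function() {
  T3 <- array(0, dim = c(2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2)
    T3[a, b, cc] <- (-1)^(a + b + cc)
  base <- pairwise_model(h = matrix(0, 3, 2), alphabet = toy_alphabet(2))
  planted_model(base, matrix(1:3, 1), list(T3))
}

# A VAE whose encoder sits exactly at the prior (all encoder parameters 0)
# and whose decoder ignores z; only the decoder output bias is nonzero, so
# p(s|z) = p(s) factorizes and the marginal likelihood is available in
# closed form.
prior_encoder_vae <- function(N = 4, q = 3, latent = 2, seed = 1) {
  m <- vae_init(N, q, hidden = 5, latent = latent, init_sd = 0)
  set.seed(seed)
  m$params$b_s <- rnorm(N * q)
  m
}

random_ardca <- function(N, q, sd = 0.5, seed = 1) {
  set.seed(seed)
  h <- matrix(rnorm(N * q, sd = sd), N, q)
  J <- vector("list", N)
  for (o in seq_len(N)) if (o > 1)
    J[[o]] <- array(rnorm(q * q * (o - 1), sd = sd), dim = c(q, q, o - 1))
  ardca_model(h, J, alphabet = toy_alphabet(q))
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

empirical_dist <- function(S, q) {
  N <- ncol(S)
  g <- rep(1L, nrow(S))
  mult <- 1L
  for (i in N:1) {  # lexicographic, position 1 most significant
    g <- g + (S[, i] - 1L) * mult
    mult <- mult * q
  }
  tabulate(g, nbins = q^N) / nrow(S)
}
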
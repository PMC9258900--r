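#' Construct an autoregressive (ArDCA-style) sequence model
#'
#' The probability of a sequence factorizes along a site ordering as
#' \deqn{p(s) = \prod_i p(s_i | s_{<i}), \quad
#'   p(s_i | s_{<i}) \propto \exp\big(h_i(s_i) + \sum_{j<i} J_{ij}(s_i, s_j)\big),}
#' where "<" refers to the site ordering.  Each conditional is a softmax, so
#' the likelihood and ancestral sampling are exact; the model implements the
#' energy contract with \eqn{E(s) = -\log p(s)} computed without any
#' estimation.  Despite the shared names, these fields and couplings do not
#' map directly onto the parameters of a pairwise energy model: the
#' per-position normalizations make the log probability a genuinely
#' higher-order function of the sequence.
#'
#' @param h numeric matrix \code{(N, q)}: autoregressive fields, indexed by
#'   sequence position
#' @param J list of length N; \code{J[[o]]} is an array
#'   \code{(q, q, o - 1)} coupling the symbol at the o-th ordered position
#'   (first index) to the symbol at each preceding ordered position (third
#'   index); \code{J[[1]]} is ignored and may be \code{NULL}
#' @param site_order permutation of \code{1:N} giving the autoregressive
#'   order (default natural left-to-right)
#' @param alphabet symbol ordering
#' @return object of class \code{ardca_model}
#' @export
ardca_model <- function(h, J = NULL, site_order = NULL,
                        alphabet = default_alphabet(ncol(h))) {
  h <- as.matrix(h)
  N <- nrow(h); q <- ncol(h)
  site_order <- site_order %||% seq_len(N)
  if (!identical(sort(site_order), seq_len(N)))
    stop("site_order must be a permutation of 1:N")
  if (is.null(J)) {
    J <- vector("list", N)
    for (o in seq_len(N)) if (o > 1) J[[o]] <- array(0, dim = c(q, q, o - 1))
  }
  for (o in seq_len(N)) {
    if (o == 1) next
    if (!all(dim(J[[o]]) == c(q, q, o - 1)))
      stop("J[[", o, "]] must have dim (q, q, ", o - 1, ")")
  }
  structure(list(h = h, J = J, site_order = as.integer(site_order),
                 N = N, q = q, alphabet = alphabet),
            class = "ardca_model")
}

#' @export
n_sites.ardca_model <- function(model) model$N
#' @export
n_states.ardca_model <- function(model) model$q

#' @export
print.ardca_model <- function(x, ...) {
  cat(sprintf("autoregressive model: N = %d, q = %d\n", x$N, x$q))
  invisible(x)
}

# Conditional logits for the o-th ordered position, for all rows of S at
# once.  Positions earlier in the ordering must already be filled in S.
ardca_logits <- function(m, S, o) {
  n <- nrow(S)
  pos <- m$site_order[o]
  L <- matrix(m$h[pos, ], n, m$q, byrow = TRUE)
  if (o > 1) {
    for (k in seq_len(o - 1)) {
      prev <- m$site_order[k]
      L <- L + t(m$J[[o]][, S[, prev], k])
    }
  }
  L
}

#' Conditional distribution of one position given its predecessors
#'
#' @param m an \code{ardca_model}
#' @param s integer code vector with the predecessor positions (in site
#'   order) filled
#' @param o index into the site ordering (equals the position for the
#'   default natural order)
#' @return probability vector of length q summing to 1
#' @export
conditional_distribution <- function(m, s, o) {
  L <- ardca_logits(m, matrix(as.integer(s), nrow = 1), o)
  drop(row_softmax(L))
}

#' Exact log probability of sequences under an autoregressive model
#'
#' @param m an \code{ardca_model}
#' @param seqs code matrix or vector
#' @return numeric vector of log probabilities (no estimation involved)
#' @export
log_prob <- function(m, seqs) {
  S <- check_codes(as_code_matrix(seqs), m$N, m$q)
  n <- nrow(S)
  lp <- numeric(n)
  for (o in seq_len(m$N)) {
    L <- ardca_logits(m, S, o)
    mx <- apply(L, 1, max)
    lse <- mx + log(rowSums(exp(L - mx)))
    lp <- lp + L[cbind(seq_len(n), S[, m$site_order[o]])] - lse
  }
  lp
}

#' @rdname energy
#' @export
energy.ardca_model <- function(model, seqs, ...) -log_prob(model, seqs)

#' @export
model_sample.ardca_model <- function(model, n, seed = NULL, ...) {
  local_rng(seed)
  S <- matrix(1L, n, model$N)
  for (o in seq_len(model$N)) {
    P <- row_softmax(ardca_logits(model, S, o))
    cum <- P
    if (model$q > 1)
      for (cc in 2:model$q) cum[, cc] <- cum[, cc - 1] + P[, cc]
    u <- stats::runif(n)
    S[, model$site_order[o]] <- 1L + as.integer(rowSums(cum < u))
  }
  S
}

# ---- training ---------------------------------------------------------------

ardca_n_par <- function(N, q) N * q + q^2 * N * (N - 1) / 2

ardca_unflatten <- function(theta, N, q, site_order, alphabet) {
  h <- matrix(theta[seq_len(N * q)], N, q)
  J <- vector("list", N)
  off <- N * q
  for (o in seq_len(N)) {
    if (o == 1) next
    len <- q * q * (o - 1)
    J[[o]] <- array(theta[off + seq_len(len)], dim = c(q, q, o - 1))
    off <- off + len
  }
  ardca_model(h, J, site_order, alphabet)
}

ardca_flatten <- function(m) {
  c(as.vector(m$h),
    unlist(lapply(seq_len(m$N)[-1], function(o) as.vector(m$J[[o]]))))
}

#' Train an autoregressive model by regularized weighted maximum likelihood
#'
#' Maximizes \eqn{\sum_m w_m \log p(s_m) - \lambda_J \|J\|^2 -
#' \lambda_h \|h\|^2} with sequence weights normalized to sum to one and
#' unnormalized squared-norm penalties at the stated strengths.  Full-batch
#' quasi-Newton (L-BFGS) optimization from a zero initialization, so the
#' result is deterministic.
#'
#' @param aln training \code{encoded_alignment} (at least 2 sequences)
#' @param weights positive per-sequence weights (default: the alignment's
#'   own weights, or uniform)
#' @param lambda_J,lambda_h L2 regularization strengths for couplings and
#'   fields (defaults 0.01 and 0.0001)
#' @param site_order \code{"natural"}, \code{"entropic"} (ascending
#'   single-site entropy) or an explicit permutation
#' @param maxit maximum L-BFGS iterations
#' @return a trained \code{ardca_model}
#' @export
train_ardca <- function(aln, weights = NULL, lambda_J = 0.01,
                        lambda_h = 0.0001, site_order = "natural",
                        maxit = 500) {
  S <- aln$seqs
  n <- nrow(S); N <- ncol(S); q <- length(aln$alphabet)
  if (n < 2) stop("need at least 2 sequences to train")
  w <- weights %||% aln$weights %||% rep(1, n)
  if (any(w <= 0)) stop("weights must be positive")
  w <- w / sum(w)
  ord <- resolve_site_order(site_order, S, q)

  X_onehot <- lapply(seq_len(N), function(i) {
    M <- matrix(0, n, q); M[cbind(seq_len(n), S[, i])] <- 1; M
  })

  obj_env <- new.env()
  obj_and_grad <- function(theta) {
    m <- ardca_unflatten(theta, N, q, ord, aln$alphabet)
    nll <- 0
    gh <- matrix(0, N, q)
    gJ <- vector("list", N)
    for (o in seq_len(N)) {
      pos <- ord[o]
      L <- ardca_logits(m, S, o)
      mx <- apply(L, 1, max)
      lse <- mx + log(rowSums(exp(L - mx)))
      nll <- nll - sum(w * (L[cbind(seq_len(n), S[, pos])] - lse))
      P <- exp(L - lse)               # n x q softmax probabilities
      D <- (P - X_onehot[[pos]]) * w  # d(nll)/d(logits)
      gh[pos, ] <- colSums(D)
      if (o > 1) {
        gJ[[o]] <- array(0, dim = c(q, q, o - 1))
        for (k in seq_len(o - 1)) {
          prev <- ord[k]
          R <- rowsum(D, S[, prev])   # rows: predecessor symbol b
          gJ[[o]][, as.integer(rownames(R)), k] <- t(R)
        }
      }
    }
    if (!is.finite(nll))
      stop("non-finite training loss; check inputs and regularization")
    pen_h <- lambda_h * sum(m$h^2)
    Jvec <- theta[-seq_len(N * q)]
    pen_J <- lambda_J * sum(Jvec^2)
    grad <- c(as.vector(gh + 2 * lambda_h * m$h),
              if (N > 1)
                unlist(lapply(seq_len(N)[-1],
                              function(o) as.vector(gJ[[o]]))) + 2 * lambda_J * Jvec)
    list(value = nll + pen_h + pen_J, grad = grad)
  }
  fn <- function(theta) {
    res <- obj_and_grad(theta)
    obj_env$last <- list(theta = theta, grad = res$grad)
    res$value
  }
  gr <- function(theta) {
    if (!is.null(obj_env$last) && identical(obj_env$last$theta, theta))
      return(obj_env$last$grad)
    obj_and_grad(theta)$grad
  }
  theta0 <- numeric(ardca_n_par(N, q))
  fit <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  ardca_unflatten(fit$par, N, q, ord, aln$alphabet)
}

resolve_site_order <- function(site_order, S, q) {
  N <- ncol(S)
  if (is.numeric(site_order)) return(as.integer(site_order))
  switch(site_order,
         natural = seq_len(N),
         entropic = {
           ent <- vapply(seq_len(N), function(i) {
             p <- tabulate(S[, i], nbins = q) / nrow(S)
             p <- p[p > 0]
             -sum(p * log(p))
           }, numeric(1))
           order(ent)
         },
         stop("unknown site_order '", site_order, "'"))
}
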
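#' Energy of sequences under a model
#'
#' Every model in the package (pairwise, independent, autoregressive, VAE,
#' planted toy models) implements the energy-based-model contract: it
#' assigns each sequence an energy \eqn{E(s) = -\log p(s) + const} and can
#' draw samples.  For models whose marginal likelihood is intractable (the
#' VAE) the energy is an importance-sampling estimate, flagged by
#' \code{\link{is_estimated_energy}} and deterministic given a seed.
#'
#' @param model a model object
#' @param seqs integer code matrix (sequences x positions) or a single code
#'   vector, or an \code{encoded_alignment}
#' @param ... method-specific arguments (e.g. estimator settings)
#' @return numeric vector of energies, one per sequence
#' @export
energy <- function(model, seqs, ...) UseMethod("energy")

#' Draw sequences from a model's distribution
#'
#' @param model a model object
#' @param n number of sequences
#' @param seed integer seed; samples are deterministic given the seed
#' @param ... method-specific arguments
#' @return integer code matrix with \code{n} rows
#' @export
model_sample <- function(model, n, seed = NULL, ...) UseMethod("model_sample")

#' Sequence length of a model
#' @param model a model object
#' @return integer number of aligned positions
#' @export
n_sites <- function(model) UseMethod("n_sites")

#' Alphabet size of a model
#' @param model a model object
#' @return integer number of states per position
#' @export
n_states <- function(model) UseMethod("n_states")

#' Does the model return estimated (rather than exact) energies?
#' @param model a model object
#' @return logical
#' @export
is_estimated_energy <- function(model) UseMethod("is_estimated_energy")

#' @export
is_estimated_energy.default <- function(model) FALSE

as_code_matrix <- function(seqs) {
  if (inherits(seqs, "encoded_alignment")) return(seqs$seqs)
  if (is.null(dim(seqs))) seqs <- matrix(seqs, nrow = 1)
  storage.mode(seqs) <- "integer"
  seqs
}

check_codes <- function(S, N, q) {
  if (ncol(S) != N) stop("sequence length ", ncol(S), " does not match model length ", N)
  if (nrow(S) > 0 && (min(S) < 1L || max(S) > q))
    stop("sequence codes out of range 1..", q)
  S
}

#' Construct a pairwise (Potts) energy model
#'
#' The energy is
#' \deqn{E(s) = -\sum_{i<j} J_{ij}(s_i, s_j) - \sum_i h_i(s_i) - C,}
#' with couplings \eqn{J}, fields \eqn{h} and an additive constant \eqn{C}.
#' Couplings are stored only in the \eqn{i<j} slots of a 4-way array; the
#' symmetrized entry \eqn{J_{ji}(b,a)} is available via
#' \code{\link{coupling_block}}.
#'
#' @param J numeric array of dim \code{(N, N, q, q)}; only slots with
#'   \code{i < j} are used (others are zeroed on construction), or
#'   \code{NULL} for a coupling-free model
#' @param h numeric matrix \code{(N, q)} of fields
#' @param C additive constant (kept explicit so extracted models reproduce
#'   energies, not just probabilities)
#' @param alphabet symbol ordering of the \code{q} states
#' @param gauge gauge tag, \code{"none"} or \code{"zero_sum"}
#' @return object of class \code{pairwise_model}
#' @export
pairwise_model <- function(J = NULL, h, C = 0,
                           alphabet = default_alphabet(ncol(h)),
                           gauge = "none") {
  h <- as.matrix(h)
  N <- nrow(h); q <- ncol(h)
  if (is.null(J)) J <- array(0, dim = c(N, N, q, q))
  if (!all(dim(J) == c(N, N, q, q))) stop("J must have dim (N, N, q, q)")
  if (!all(is.finite(J)) || !all(is.finite(h)) || !is.finite(C))
    stop("model parameters must be finite")
  # zero out the redundant lower-triangle and diagonal slots
  for (i in seq_len(N)) J[i, seq_len(i), , ] <- 0
  structure(list(J = J, h = h, C = C, N = N, q = q, alphabet = alphabet,
                 gauge = gauge),
            class = "pairwise_model")
}

#' Construct an independent (profile) energy model
#'
#' A pairwise model with all couplings fixed to zero:
#' \eqn{E(s) = -\sum_i h_i(s_i) - C}; its probability factorizes over
#' positions.
#'
#' @inheritParams pairwise_model
#' @return object of class \code{independent_model}
#' @export
independent_model <- function(h, C = 0, alphabet = default_alphabet(ncol(h)),
                              gauge = "none") {
  h <- as.matrix(h)
  if (!all(is.finite(h)) || !is.finite(C)) stop("model parameters must be finite")
  structure(list(h = h, C = C, N = nrow(h), q = ncol(h), alphabet = alphabet,
                 gauge = gauge),
            class = "independent_model")
}

#' Symmetrized coupling block of a pairwise model
#' @param m a \code{pairwise_model}
#' @param i,j positions (any order)
#' @return \code{q x q} matrix \code{J[i, j, , ]} with
#'   \code{J[j, i, b, a] == J[i, j, a, b]}
#' @export
coupling_block <- function(m, i, j) {
  if (i == j) stop("coupling blocks are defined for i != j")
  if (i < j) m$J[i, j, , ] else t(m$J[j, i, , ])
}

#' @export
n_sites.pairwise_model <- function(model) model$N
#' @export
n_sites.independent_model <- function(model) model$N
#' @export
n_states.pairwise_model <- function(model) model$q
#' @export
n_states.independent_model <- function(model) model$q

#' @export
print.pairwise_model <- function(x, ...) {
  cat(sprintf("pairwise model: N = %d, q = %d, gauge = %s (%d parameters)\n",
              x$N, x$q, x$gauge, parameter_count(x$N, x$q, "pairwise")))
  invisible(x)
}

#' @export
print.independent_model <- function(x, ...) {
  cat(sprintf("independent model: N = %d, q = %d, gauge = %s (%d parameters)\n",
              x$N, x$q, x$gauge, parameter_count(x$N, x$q, "independent")))
  invisible(x)
}

#' @rdname energy
#' @export
energy.pairwise_model <- function(model, seqs, ...) {
  S <- check_codes(as_code_matrix(seqs), model$N, model$q)
  n <- nrow(S)
  acc <- rep(model$C, n)
  for (i in seq_len(model$N)) acc <- acc + model$h[i, S[, i]]
  if (model$N >= 2) {
    for (i in seq_len(model$N - 1)) for (j in (i + 1):model$N) {
      acc <- acc + model$J[i, j, , ][cbind(S[, i], S[, j])]
    }
  }
  -acc
}

#' @rdname energy
#' @export
energy.independent_model <- function(model, seqs, ...) {
  S <- check_codes(as_code_matrix(seqs), model$N, model$q)
  acc <- rep(model$C, nrow(S))
  for (i in seq_len(model$N)) acc <- acc + model$h[i, S[, i]]
  -acc
}

#' Embed an independent model as a pairwise model with zero couplings
#' @param m an \code{independent_model}
#' @return an energy-equivalent \code{pairwise_model}
#' @export
as_pairwise <- function(m) {
  stopifnot(inherits(m, "independent_model"))
  pairwise_model(J = NULL, h = m$h, C = m$C, alphabet = m$alphabet,
                 gauge = m$gauge)
}

#' @export
model_sample.pairwise_model <- function(model, n, seed = NULL, ...) {
  sample_model(model, n, seed = seed, ...)
}

#' @export
model_sample.independent_model <- function(model, n, seed = NULL, ...) {
  local_rng(seed)
  P <- row_softmax(model$h)  # per-position marginals p_i(a) ~ exp(h_i(a))
  S <- matrix(0L, n, model$N)
  for (i in seq_len(model$N))
    S[, i] <- sample.int(model$q, n, replace = TRUE, prob = P[i, ])
  S
}

#' Number of parameters of a pairwise or independent parameterization
#'
#' Pairwise: \eqn{Nq + N(N-1)/2\,q^2 + 1}; independent: \eqn{Nq + 1}
#' (fields, couplings and the constant).  At protein scale (N = 77, q = 21)
#' the pairwise family has 1,291,984 parameters.
#'
#' @param N sequence length
#' @param q alphabet size
#' @param family \code{"pairwise"} or \code{"independent"}
#' @return integer parameter count
#' @export
parameter_count <- function(N, q, family = c("pairwise", "independent")) {
  family <- match.arg(family)
  stopifnot(N >= 1, q >= 2)
  if (family == "pairwise") N * q + N * (N - 1) / 2 * q^2 + 1 else N * q + 1
}

#' Transform a model to the zero-sum gauge
#'
#' Re-expresses the same energy function with every coupling block summing
#' to zero along each amino-acid index and every field vector summing to
#' zero, shifting as much coefficient mass as possible to lower orders:
#' coupling row/column means are folded into the fields, field means into
#' the constant.  Energies of all sequences are unchanged.
#'
#' @param m a \code{pairwise_model} or \code{independent_model}
#' @return the gauge-fixed model (tagged \code{gauge = "zero_sum"})
#' @export
to_zero_sum_gauge <- function(m) UseMethod("to_zero_sum_gauge")

#' @export
to_zero_sum_gauge.pairwise_model <- function(m) {
  J <- m$J; h <- m$h; C <- m$C
  N <- m$N; q <- m$q
  if (N >= 2) {
    for (i in seq_len(N - 1)) for (j in (i + 1):N) {
      A <- J[i, j, , ]
      rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
      J[i, j, , ] <- A - outer(rm_, rep(1, q)) - outer(rep(1, q), cm_) + gm
      h[i, ] <- h[i, ] + rm_
      h[j, ] <- h[j, ] + cm_
      C <- C - gm
    }
  }
  hm <- rowMeans(h)
  h <- h - hm
  C <- C + sum(hm)
  pairwise_model(J, h, C, alphabet = m$alphabet, gauge = "zero_sum")
}

#' @export
to_zero_sum_gauge.independent_model <- function(m) {
  hm <- rowMeans(m$h)
  independent_model(m$h - hm, m$C + sum(hm), alphabet = m$alphabet,
                    gauge = "zero_sum")
}

#' Enumerate all sequences of length N over q states
#'
#' Lexicographic order with position 1 most significant.  Refuses to
#' enumerate more than \code{cap} sequences.
#'
#' @param N sequence length
#' @param q alphabet size
#' @param cap enumeration cap (default \code{1e6} sequences)
#' @return integer matrix \code{(q^N, N)}
#' @export
enumerate_sequences <- function(N, q, cap = 1e6) {
  M <- q^N
  if (M > cap) stop("enumeration of q^N = ", M, " sequences exceeds cap ", cap)
  idx <- seq_len(M) - 1L
  S <- matrix(0L, M, N)
  for (i in seq_len(N))
    S[, i] <- as.integer((idx %/% q^(N - i)) %% q) + 1L
  S
}

#' Enumerate the energies of every sequence under a model
#'
#' Brute-force oracle; only feasible for small \code{q^N}.
#'
#' @param model any model implementing the energy contract
#' @param cap enumeration cap
#' @param ... passed to \code{\link{energy}}
#' @return numeric vector of length \code{q^N} in lexicographic order
#' @export
enumerate_energies <- function(model, cap = 1e6, ...) {
  S <- enumerate_sequences(n_sites(model), n_states(model), cap = cap)
  energy(model, S, ...)
}
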
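#' Random pairwise model with Gaussian parameters
#'
#' Couplings and fields are i.i.d. zero-mean Gaussian at the stated scales,
#' the constant is 0.  Deterministic given the seed.
#'
#' @param N sequence length (>= 2)
#' @param q alphabet size
#' @param coupling_scale standard deviation of coupling entries
#' @param field_scale standard deviation of field entries
#' @param seed RNG seed
#' @return a \code{pairwise_model}
#' @export
random_pairwise_model <- function(N, q, coupling_scale = 0.5,
                                  field_scale = 0.5, seed = NULL) {
  stopifnot(N >= 2)
  local_rng(seed)
  h <- matrix(stats::rnorm(N * q, sd = field_scale), N, q)
  J <- array(0, dim = c(N, N, q, q))
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    J[i, j, , ] <- matrix(stats::rnorm(q * q, sd = coupling_scale), q, q)
  pairwise_model(J, h, C = 0, alphabet = default_alphabet(q))
}

# Center a 3-way tensor to zero sum along every axis (sequential centering;
# each later centering preserves the earlier zero sums).
center_threebody <- function(T3) {
  q <- dim(T3)[1]
  for (ax in 1:3) {
    mns <- apply(T3, setdiff(1:3, ax), mean)
    T3 <- T3 - switch(ax,
                      aperm(array(mns, dim = dim(T3)[c(2, 3, 1)]), c(3, 1, 2)),
                      aperm(array(mns, dim = dim(T3)[c(1, 3, 2)]), c(1, 3, 2)),
                      array(mns, dim = dim(T3)))
  }
  T3
}

#' Planted model with pure three-body interactions
#'
#' A random pairwise base plus sparse three-body tensors on random position
#' triplets.  Each tensor is centered to zero sum along every amino-acid
#' axis, so under uniform weighting it contributes nothing to the constant,
#' field or coupling coefficients of the interaction expansion: the planted
#' part is exactly invisible to uniform-weighted pairwise extraction, and
#' the residual extraction loss equals its uniform variance.
#'
#' @param N sequence length (>= 3)
#' @param q alphabet size
#' @param n_triplets number of interacting triplets
#' @param strength scale multiplying each centered tensor
#' @param seed RNG seed
#' @param base optional \code{pairwise_model} to plant on (default: random)
#' @param coupling_scale,field_scale scales of the random base
#' @return object of class \code{planted_model}
#' @export
planted_threebody_model <- function(N, q, n_triplets = 1, strength = 1,
                                    seed = NULL, base = NULL,
                                    coupling_scale = 0.3, field_scale = 0.3) {
  stopifnot(N >= 3, n_triplets >= 1)
  local_rng(seed)
  base <- base %||% random_pairwise_model(N, q, coupling_scale, field_scale,
                                          seed = NULL)
  triplets <- matrix(0L, n_triplets, 3)
  tensors <- vector("list", n_triplets)
  for (t in seq_len(n_triplets)) {
    triplets[t, ] <- sort(sample.int(N, 3))
    T3 <- array(stats::rnorm(q^3), dim = c(q, q, q))
    tensors[[t]] <- strength * center_threebody(T3)
  }
  planted_model(base, triplets, tensors)
}

#' Assemble a planted model from explicit parts
#'
#' @param base a \code{pairwise_model}
#' @param triplets integer matrix \code{(n_t, 3)} of position triplets
#' @param tensors list of \code{q x q x q} arrays added to the energy at
#'   the corresponding triplets
#' @return object of class \code{planted_model}
#' @export
planted_model <- function(base, triplets, tensors) {
  stopifnot(inherits(base, "pairwise_model"),
            nrow(triplets) == length(tensors))
  structure(list(base = base, triplets = triplets, tensors = tensors,
                 N = base$N, q = base$q, alphabet = base$alphabet),
            class = "planted_model")
}

#' @export
n_sites.planted_model <- function(model) model$N
#' @export
n_states.planted_model <- function(model) model$q

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("planted model: N = %d, q = %d, %d three-body triplet(s)\n",
              x$N, x$q, nrow(x$triplets)))
  invisible(x)
}

#' @rdname energy
#' @export
energy.planted_model <- function(model, seqs, ...) {
  S <- check_codes(as_code_matrix(seqs), model$N, model$q)
  E <- energy(model$base, S)
  for (t in seq_len(nrow(model$triplets))) {
    tr <- model$triplets[t, ]
    E <- E + model$tensors[[t]][cbind(S[, tr[1]], S[, tr[2]], S[, tr[3]])]
  }
  E
}

#' @export
model_sample.planted_model <- function(model, n, seed = NULL, ...) {
  sample_model(model, n, seed = seed, ...)
}

#' Sample sequences from an arbitrary exact-energy model
#'
#' \code{method = "enumerate"} draws exactly from \eqn{e^{-E}/Z} over the
#' full enumeration (small \code{q^N} only).  \code{method = "gibbs"} runs
#' parallel single-site heat-bath chains: each site update draws from the
#' exact conditional obtained by evaluating the full energy at all q states
#' of that site, so the sampler applies to any model with exact energies
#' (including planted higher-order models).  One independent chain per
#' requested sequence, recorded after \code{burn_in_sweeps} full sweeps.
#'
#' @param model a model with exact energies
#' @param n number of sequences
#' @param seed RNG seed
#' @param method \code{"auto"} (enumerate when feasible), \code{"enumerate"}
#'   or \code{"gibbs"}
#' @param cap enumeration cap for \code{"enumerate"}
#' @param burn_in_sweeps Gibbs burn-in, in full sweeps over all sites
#' @return integer code matrix \code{(n, N)}
#' @export
sample_model <- function(model, n, seed = NULL,
                         method = c("auto", "enumerate", "gibbs"),
                         cap = 1e6, burn_in_sweeps = NULL) {
  method <- match.arg(method)
  N <- n_sites(model); q <- n_states(model)
  if (method == "auto") method <- if (q^N <= cap) "enumerate" else "gibbs"
  local_rng(seed)
  if (method == "enumerate") {
    S <- enumerate_sequences(N, q, cap = cap)
    E <- energy(model, S)
    lw <- -E - max(-E)
    idx <- sample.int(nrow(S), n, replace = TRUE, prob = exp(lw))
    S[idx, , drop = FALSE]
  } else {
    burn_in_sweeps <- burn_in_sweeps %||% (100L * N)
    S <- matrix(sample.int(q, n * N, replace = TRUE), n, N)
    for (sweep in seq_len(burn_in_sweeps)) {
      for (i in seq_len(N)) {
        logits <- matrix(0, n, q)
        for (a in seq_len(q)) {
          Sa <- S; Sa[, i] <- a
          logits[, a] <- -energy(model, Sa)
        }
        P <- row_softmax(logits)
        cum <- P
        if (q > 1) for (cc in 2:q) cum[, cc] <- cum[, cc - 1] + P[, cc]
        S[, i] <- 1L + as.integer(rowSums(cum < stats::runif(n)))
      }
    }
    S
  }
}

#' Synthetic single-mutant fitness table from a model
#'
#' Draws distinct single substitutions of the wild type and assigns fitness
#' \eqn{-E(\mathrm{mutant}) + \epsilon}, \eqn{\epsilon \sim N(0,
#' \mathrm{noise\_sd}^2)}: low energy means high fitness, mirroring the
#' convention used for benchmarking mutational-effect prediction.
#'
#' @param model a model implementing the energy contract
#' @param wildtype integer code vector (defaults to a sample from the model)
#' @param n_single_mutants number of mutants, at most \code{N * (q - 1)}
#' @param noise_sd standard deviation of the additive Gaussian noise
#' @param seed RNG seed
#' @return a \code{\link{mutational_dataset}}
#' @export
synthetic_mutational_dataset <- function(model, wildtype = NULL,
                                         n_single_mutants, noise_sd = 0,
                                         seed = NULL) {
  N <- n_sites(model); q <- n_states(model)
  local_rng(seed)
  wildtype <- wildtype %||% drop(model_sample(model, 1))
  all_subs <- expand.grid(pos = seq_len(N), to = seq_len(q))
  all_subs <- all_subs[wildtype[all_subs$pos] != all_subs$to, ]
  if (n_single_mutants > nrow(all_subs))
    stop("requested ", n_single_mutants, " mutants but only ",
         nrow(all_subs), " distinct single mutants exist")
  pick <- all_subs[sample.int(nrow(all_subs), n_single_mutants), ]
  subs <- lapply(seq_len(nrow(pick)), function(r) {
    matrix(c(pick$pos[r], wildtype[pick$pos[r]], pick$to[r]), 1, 3,
           dimnames = list(NULL, c("pos", "from", "to")))
  })
  data <- mutational_dataset(wildtype, subs, fitness = numeric(length(subs)),
                             alphabet = alphabet_of(model))
  E <- energy(model, mutant_matrix(data))
  data$fitness <- -E + stats::rnorm(length(E), sd = noise_sd)
  data
}
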
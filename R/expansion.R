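#' Brute-force zero-sum interaction expansion of an energy function
#'
#' Expands an arbitrary energy over sequences of length N as
#' \deqn{E(s) = \sum_{L \subseteq \{1..N\}} f_L(s_L),}
#' in the unique orthogonal (zero-sum) form where every coefficient tensor
#' sums to zero along each of its amino-acid axes: \eqn{f_\emptyset} is the
#' grand mean energy under the uniform distribution, \eqn{f_{\{i\}}(a)} the
#' conditional mean given \eqn{s_i = a} minus the grand mean, pair and
#' higher tensors subtract all lower-order terms recursively.  Truncating at
#' order 2 yields exactly the pairwise part of the energy in the zero-sum
#' gauge.  Requires full enumeration, so it is an oracle for small
#' \code{q^N} only.
#'
#' @param model any model implementing the energy contract (exact energies)
#' @param max_order highest interaction order to compute (default \code{N})
#' @param cap enumeration cap
#' @return object of class \code{expansion_coefficients}: a list with
#'   \code{f} (named list of coefficient vectors keyed by comma-separated
#'   position subsets, element order: first listed position varies fastest),
#'   \code{N}, \code{q}, \code{max_order}
#' @export
mobius_zero_sum_expansion <- function(model, max_order = NULL, cap = 1e6) {
  N <- n_sites(model); q <- n_states(model)
  max_order <- max_order %||% N
  S <- enumerate_sequences(N, q, cap = cap)
  E <- energy(model, S)
  expansion_from_energies(E, S, N, q, max_order)
}

# Shared worker: expansion from a full enumeration (S, E).
expansion_from_energies <- function(E, S, N, q, max_order) {
  f <- list()
  f[["0"]] <- mean(E)
  if (max_order >= 1) {
    for (ord in seq_len(max_order)) {
      subsets <- utils::combn(N, ord, simplify = FALSE)
      for (L in subsets) {
        # linear group index over the assignment of positions in L,
        # first position in L varying fastest
        g <- rep(1L, nrow(S))
        mult <- 1L
        for (k in seq_along(L)) {
          g <- g + (S[, L[k]] - 1L) * mult
          mult <- mult * q
        }
        cond <- as.vector(rowsum(E, g) / tabulate(g, nbins = q^ord))
        # subtract all lower-order contributions
        vals <- cond - f[["0"]]
        grid <- assignment_grid(ord, q)
        if (ord >= 2) {
          for (sub_ord in seq_len(ord - 1)) {
            for (sub in utils::combn(seq_along(L), sub_ord, simplify = FALSE)) {
              key <- paste(L[sub], collapse = ",")
              lin <- rep(1L, nrow(grid))
              mult <- 1L
              for (k in seq_along(sub)) {
                lin <- lin + (grid[, sub[k]] - 1L) * mult
                mult <- mult * q
              }
              vals <- vals - f[[key]][lin]
            }
          }
        }
        f[[paste(L, collapse = ",")]] <- vals
      }
    }
  }
  structure(list(f = f, N = N, q = q, max_order = max_order),
            class = "expansion_coefficients")
}

# All assignments of `ord` positions over q states, first column fastest.
assignment_grid <- function(ord, q) {
  as.matrix(expand.grid(rep(list(seq_len(q)), ord)))
}

#' Evaluate a (possibly truncated) interaction expansion on sequences
#'
#' @param expansion an \code{expansion_coefficients} object
#' @param seqs integer code matrix
#' @param max_order truncation order (default: all stored orders)
#' @return numeric vector of reconstructed energies
#' @export
reconstruct_energy <- function(expansion, seqs, max_order = NULL) {
  S <- as_code_matrix(seqs)
  q <- expansion$q
  max_order <- max_order %||% expansion$max_order
  out <- rep(expansion$f[["0"]], nrow(S))
  for (key in names(expansion$f)) {
    if (key == "0") next
    L <- as.integer(strsplit(key, ",")[[1]])
    if (length(L) > max_order) next
    lin <- rep(1L, nrow(S))
    mult <- 1L
    for (k in seq_along(L)) {
      lin <- lin + (S[, L[k]] - 1L) * mult
      mult <- mult * q
    }
    out <- out + expansion$f[[key]][lin]
  }
  out
}

#' Pairwise model matching the order-2 truncation of an expansion
#'
#' Converts the constant, single-position and pair coefficients of a
#' zero-sum expansion into a \code{pairwise_model} (sign-flipped, since the
#' model energy carries minus signs in front of J, h and C).
#'
#' @param expansion an \code{expansion_coefficients} object with
#'   \code{max_order >= 2}
#' @param alphabet symbol ordering for the resulting model
#' @return a \code{pairwise_model} in the zero-sum gauge
#' @export
expansion_to_pairwise <- function(expansion,
                                  alphabet = default_alphabet(expansion$q)) {
  N <- expansion$N; q <- expansion$q
  h <- matrix(0, N, q)
  J <- array(0, dim = c(N, N, q, q))
  for (i in seq_len(N)) {
    fi <- expansion$f[[as.character(i)]]
    if (!is.null(fi)) h[i, ] <- -fi
  }
  if (N >= 2) for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    fij <- expansion$f[[paste(i, j, sep = ",")]]
    if (!is.null(fij)) J[i, j, , ] <- -matrix(fij, q, q)  # rows: s_i, cols: s_j
  }
  pairwise_model(J, h, C = -expansion$f[["0"]], alphabet = alphabet,
                 gauge = "zero_sum")
}

#' Degenerate top-order rewrite of an energy function
#'
#' Builds the trivial (non-zero-sum) expansion that stores the whole energy
#' in the order-N coefficient \eqn{f_I(s) = E(s)} with all other
#' coefficients zero.  Demonstrates the gauge freedom of the interaction
#' expansion: it reconstructs the same energies as the zero-sum form.
#'
#' @param model any model with exact energies
#' @param cap enumeration cap
#' @return an \code{expansion_coefficients} object
#' @export
degenerate_expansion <- function(model, cap = 1e6) {
  N <- n_sites(model); q <- n_states(model)
  S <- enumerate_sequences(N, q, cap = cap)
  E <- energy(model, S)
  f <- list()
  f[["0"]] <- 0
  # enumerate_sequences has position 1 most significant; f_I storage has
  # position 1 (first in L) varying fastest, so re-index
  lin <- rep(1L, nrow(S))
  mult <- 1L
  for (k in seq_len(N)) {
    lin <- lin + (S[, k] - 1L) * mult
    mult <- mult * q
  }
  vals <- numeric(q^N)
  vals[lin] <- E
  f[[paste(seq_len(N), collapse = ",")]] <- vals
  structure(list(f = f, N = N, q = q, max_order = N),
            class = "expansion_coefficients")
}
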
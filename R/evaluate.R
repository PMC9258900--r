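#' Range-normalized root-mean-squared energy error
#'
#' \deqn{\mathrm{NRMSE} = \frac{\sqrt{\frac1M \sum_m (E^M(s_m) -
#'   E^{ext}(s_m))^2}}{\max_m E^M(s_m) - \min_m E^M(s_m)},}
#' i.e. the RMSE between original and extracted energies divided by the
#' range of the original energies on the evaluation set.  Invariant to
#' shifting both energy vectors by a constant or scaling both by a positive
#' factor.
#'
#' @param E_orig original-model energies
#' @param E_ext extracted-model energies (same sequences, same order)
#' @return the normalized RMSE (>= 0)
#' @export
nrmse <- function(E_orig, E_ext) {
  if (length(E_orig) != length(E_ext) || length(E_orig) == 0)
    stop("energy vectors must have equal nonzero length")
  rng <- max(E_orig) - min(E_orig)
  if (rng <= 0)
    stop("degenerate range: original energies are constant")
  sqrt(mean((E_orig - E_ext)^2)) / rng
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive mean ranks).
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return correlation in \code{[-1, 1]}
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with at least 3 entries")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input vector")
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation between model energies and mutational fitness
#'
#' Builds each mutant by applying its substitutions to the wild type,
#' computes the model energies, and correlates \emph{minus} energy with the
#' fitness values: models that rank fit mutants at low energy score
#' positively.
#'
#' @param model a model implementing the energy contract
#' @param data a \code{\link{mutational_dataset}}
#' @param ... passed to \code{\link{energy}} (e.g. estimator settings)
#' @return Spearman correlation
#' @export
mutational_spearman <- function(model, data, ...) {
  E <- energy(model, mutant_matrix(data), ...)
  spearman(-E, data$fitness)
}

#' Stratified energy-error report for extracted models
#'
#' Compares one or more extracted models against the original on three
#' strata: the test sequences close to the training set, the test
#' sequences distant from it (per the split labels), and the mutant
#' sequences of a mutational dataset.  Also returns per-test-sequence
#' diagnostics in dependence of the minimum Hamming distance to the
#' training set: the original energies, the absolute error of each
#' extracted model, and per-distance standard deviations / RMSEs (one bin
#' per distinct observed distance).
#'
#' @param original the original model
#' @param extracted named list of extracted models
#' @param split a split result from \code{\link{split_train_test}}
#' @param mutdata optional \code{mutational_dataset}; the mutational
#'   stratum is recorded as missing when absent
#' @param ... passed to \code{\link{energy}} for the original model
#' @return object of class \code{evaluation_report}: list with
#'   \code{nrmse} (data.frame model x stratum), \code{spearman}
#'   (data.frame, present when \code{mutdata} given), \code{distance_table}
#'   (per-test-sequence diagnostics) and \code{distance_profile}
#'   (per-distance-bin sd of original energies and RMSE per model)
#' @export
stratified_energy_report <- function(original, extracted, split,
                                     mutdata = NULL, ...) {
  stopifnot(is.list(extracted))
  if (is.null(names(extracted)) && length(extracted) > 0)
    names(extracted) <- paste0("model", seq_along(extracted))
  test <- split$test
  labels <- split$test_labels
  d <- vapply(seq_len(n_sequences(test)),
              function(i) min_hamming_to_set(test$seqs[i, ], split$train),
              numeric(1))
  E_orig_test <- energy(original, test$seqs, ...)
  strata <- list(test_close = which(labels == "close"),
                 test_distant = which(labels == "distant"))

  nrmse_rows <- list()
  spearman_rows <- list()
  dist_tab <- data.frame(index = seq_along(d), min_hamming = d,
                         label = labels, E_original = E_orig_test)
  if (!is.null(mutdata)) {
    E_orig_mut <- energy(original, mutant_matrix(mutdata), ...)
    spearman_rows[["original"]] <-
      data.frame(model = "original",
                 spearman = spearman(-E_orig_mut, mutdata$fitness))
  }
  for (nm in names(extracted)) {
    E_ext_test <- energy(extracted[[nm]], test$seqs)
    dist_tab[[paste0("abs_error_", nm)]] <- abs(E_orig_test - E_ext_test)
    for (st in names(strata)) {
      idx <- strata[[st]]
      val <- if (length(idx) >= 2 && max(E_orig_test[idx]) > min(E_orig_test[idx]))
        nrmse(E_orig_test[idx], E_ext_test[idx]) else NA_real_
      nrmse_rows[[paste(nm, st)]] <-
        data.frame(model = nm, stratum = st, nrmse = val,
                   n = length(idx))
    }
    if (!is.null(mutdata)) {
      E_ext_mut <- energy(extracted[[nm]], mutant_matrix(mutdata))
      val <- if (max(E_orig_mut) > min(E_orig_mut))
        nrmse(E_orig_mut, E_ext_mut) else NA_real_
      nrmse_rows[[paste(nm, "mutational")]] <-
        data.frame(model = nm, stratum = "mutational", nrmse = val,
                   n = length(E_orig_mut))
      spearman_rows[[nm]] <-
        data.frame(model = nm,
                   spearman = spearman(-E_ext_mut, mutdata$fitness))
    } else {
      nrmse_rows[[paste(nm, "mutational")]] <-
        data.frame(model = nm, stratum = "mutational", nrmse = NA_real_,
                   n = 0L)
    }
  }

  # per-distance-bin profile: sd of original energies, RMSE per model
  bins <- sort(unique(d))
  prof <- data.frame(min_hamming = bins,
                     n = vapply(bins, function(b) sum(d == b), integer(1)),
                     sd_E_original = vapply(bins, function(b) {
                       if (sum(d == b) >= 2) stats::sd(E_orig_test[d == b])
                       else NA_real_
                     }, numeric(1)))
  for (nm in names(extracted)) {
    ae <- dist_tab[[paste0("abs_error_", nm)]]
    prof[[paste0("rmse_", nm)]] <-
      vapply(bins, function(b) sqrt(mean(ae[d == b]^2)), numeric(1))
  }

  structure(list(nrmse = do.call(rbind, unname(nrmse_rows)),
                 spearman = if (length(spearman_rows))
                   do.call(rbind, unname(spearman_rows)),
                 distance_table = dist_tab,
                 distance_profile = prof),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation report\n\nNRMSE by stratum:\n")
  print(x$nrmse, row.names = FALSE)
  if (!is.null(x$spearman)) {
    cat("\nmutational-effect Spearman:\n")
    print(x$spearman, row.names = FALSE)
  }
  invisible(x)
}

#' APC-corrected contact scores from a pairwise model
#'
#' Standard coupling-based contact prediction: transform the model to the
#' zero-sum gauge, score each position pair by the Frobenius norm of its
#' coupling block (restricted to the 20 non-gap symbols for the protein
#' alphabet), and apply the average product correction
#' \eqn{S'_{ij} = S_{ij} - S_{i\cdot} S_{\cdot j} / S_{\cdot\cdot}}.  The
#' diagonal is zero; the APC of an all-zero score matrix is defined as 0.
#'
#' @param m a \code{pairwise_model}
#' @param drop_gap exclude the gap state (the last symbol, protein alphabet
#'   only) from the Frobenius norm
#' @param apc apply the average product correction
#' @return symmetric \code{N x N} score matrix
#' @export
contact_scores <- function(m, drop_gap = TRUE, apc = TRUE) {
  m <- to_zero_sum_gauge(m)
  N <- m$N; q <- m$q
  states <- if (drop_gap && q == 21) seq_len(20) else seq_len(q)
  S <- matrix(0, N, N)
  if (N >= 2) for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    S[i, j] <- S[j, i] <- sqrt(sum(m$J[i, j, states, states]^2))
  }
  if (apc) {
    gm <- mean(S[upper.tri(S)])
    if (gm > 0) {
      rm_ <- rowSums(S) / (N - 1)
      grand <- sum(S) / (N * (N - 1))
      S <- S - outer(rm_, rm_) / grand
      diag(S) <- 0
    }
  }
  S
}

#' Positive-predictive-value curve of ranked contact predictions
#'
#' Ranks all position pairs with \code{|i - j| >= min_separation} by score
#' (descending; ties broken lexicographically by (i, j)) and returns, for
#' each k up to \code{top_n}, the fraction of true contacts among the top k
#' pairs.
#'
#' @param scores symmetric score matrix
#' @param truth two-column integer matrix of true contact pairs (any order)
#' @param top_n curve length
#' @param min_separation minimum sequence separation of eligible pairs
#' @return numeric vector of precisions; shorter than \code{top_n} (with a
#'   warning) when fewer eligible pairs exist
#' @export
ppv_curve <- function(scores, truth, top_n = 200, min_separation = 5) {
  N <- nrow(scores)
  pairs <- pair_table(N)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= min_separation, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no pairs at the requested separation")
  sc <- scores[pairs]
  ord <- order(-sc, pairs[, 1], pairs[, 2])
  k <- min(top_n, nrow(pairs))
  if (k < top_n)
    warning("only ", k, " eligible pairs; returning a truncated curve")
  top <- pairs[ord[seq_len(k)], , drop = FALSE]
  truth_keys <- paste(pmin(truth[, 1], truth[, 2]),
                      pmax(truth[, 1], truth[, 2]))
  hits <- paste(top[, 1], top[, 2]) %in% truth_keys
  cumsum(hits) / seq_len(k)
}

#' Paired coupling values of two pairwise models in the zero-sum gauge
#'
#' Transforms both models to the zero-sum gauge and pairs a random subset
#' of coupling entries (the same entries in both models), reporting the
#' Pearson correlation — the numerical counterpart of a coupling scatter
#' plot.
#'
#' @param extracted,reference \code{pairwise_model}s of identical shape
#' @param n_points number of coupling entries to pair (capped at the total)
#' @param seed RNG seed for the subset draw
#' @return data.frame with columns \code{extracted}, \code{reference} and
#'   attribute \code{"pearson"}
#' @export
coupling_scatter <- function(extracted, reference, n_points = 5000,
                             seed = 1L) {
  stopifnot(extracted$N == reference$N, extracted$q == reference$q)
  e <- to_zero_sum_gauge(extracted)
  r <- to_zero_sum_gauge(reference)
  N <- e$N; q <- e$q
  pt <- pair_table(N)
  total <- nrow(pt) * q * q
  local_rng(seed)
  pick <- sample.int(total, min(n_points, total))
  p_idx <- (pick - 1L) %/% (q * q) + 1L
  ab <- (pick - 1L) %% (q * q)
  a <- ab %% q + 1L
  b <- ab %/% q + 1L
  ev <- e$J[cbind(pt[p_idx, 1], pt[p_idx, 2], a, b)]
  rv <- r$J[cbind(pt[p_idx, 1], pt[p_idx, 2], a, b)]
  out <- data.frame(extracted = ev, reference = rv)
  attr(out, "pearson") <- if (stats::sd(ev) > 0 && stats::sd(rv) > 0)
    stats::cor(ev, rv) else NA_real_
  out
}

#' Read a contact map from a plain-text pair list
#'
#' Expects whitespace- or comma-delimited columns \code{i j label} with a
#' header line declaring the position base via a \code{#} comment
#' (\code{# base=1} or \code{# base=0}); rows with label 1 are contacts.
#' A two-column file treats every row as a contact.
#'
#' @param path file path
#' @return integer matrix of 1-based contact pairs
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  base <- 1L
  hdr <- grep("^#", lines, value = TRUE)
  bm <- regmatches(hdr, regexpr("base=[01]", hdr))
  if (length(bm)) base <- as.integer(sub("base=", "", bm[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.table(text = body, sep = "", header = FALSE)
  if (ncol(tab) >= 3) tab <- tab[tab[[3]] == 1, , drop = FALSE]
  as.matrix(tab[, 1:2]) + (1L - base)
}
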
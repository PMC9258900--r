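#' Protein alphabet used throughout the package
#'
#' The 20 standard amino acids in alphabetical one-letter order followed by
#' the alignment gap character \code{"-"}.  Sequences are encoded as integer
#' codes \code{1..q} against this ordering, so the gap is always code
#' \code{q} (21 for proteins).  All parameter tensors (fields, couplings)
#' index amino acids by these codes, which keeps parameter layouts
#' comparable across models.
#'
#' @param q alphabet size; \code{q = 21} gives the protein alphabet, smaller
#'   values give toy alphabets using the first \code{q - 1} amino-acid
#'   letters followed by the gap.
#' @return character vector of length \code{q}
#' @export
default_alphabet <- function(q = 21L) {
  stopifnot(q >= 2, q <= 21)
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][seq_len(q - 1L)], "-")
}

#' Construct an encoded alignment
#'
#' An encoded alignment is the package's container for a multiple sequence
#' alignment: an integer matrix with one row per sequence and one column per
#' aligned position, codes in \code{1..q}, plus optional sequence identifiers
#' and positive per-sequence weights.
#'
#' @param seqs integer matrix (sequences x positions), codes in \code{1..q}
#' @param alphabet ordered character vector of the \code{q} symbols
#' @param ids optional character vector of sequence labels
#' @param weights optional positive per-sequence weights
#' @return object of class \code{encoded_alignment}
#' @export
encoded_alignment <- function(seqs, alphabet = default_alphabet(), ids = NULL,
                              weights = NULL) {
  seqs <- as.matrix(seqs)
  storage.mode(seqs) <- "integer"
  q <- length(alphabet)
  if (nrow(seqs) > 0 && (min(seqs) < 1L || max(seqs) > q))
    stop("sequence codes must lie in 1..q")
  if (!is.null(weights)) {
    if (length(weights) != nrow(seqs) || any(!is.finite(weights)) ||
        any(weights <= 0))
      stop("weights must be finite, positive, one per sequence")
  }
  if (!is.null(ids) && length(ids) != nrow(seqs))
    stop("ids must have one entry per sequence")
  structure(list(seqs = seqs, alphabet = alphabet, ids = ids,
                 weights = weights),
            class = "encoded_alignment")
}

#' @export
print.encoded_alignment <- function(x, ...) {
  cat(sprintf("encoded alignment: %d sequences x %d positions (q = %d)\n",
              nrow(x$seqs), ncol(x$seqs), length(x$alphabet)))
  if (!is.null(x$weights))
    cat(sprintf("  effective sequences (sum of weights): %.2f\n",
                sum(x$weights)))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln an \code{encoded_alignment}
#' @return integer
#' @export
n_sequences <- function(aln) nrow(aln$seqs)

#' Encode character sequences against an alphabet
#'
#' Case-insensitive; \code{"."} and any character outside the alphabet
#' (e.g. non-standard amino acids such as \code{"X"} or \code{"B"}) are
#' mapped to the gap code \code{q}.
#'
#' @param strings character vector of equal-length sequences
#' @param alphabet ordered symbol vector, gap last
#' @return integer matrix of codes
#' @export
encode_sequences <- function(strings, alphabet = default_alphabet()) {
  if (length(strings) == 0) stop("empty input: no sequences to encode")
  lens <- nchar(strings)
  if (length(unique(lens)) != 1)
    stop("alignment shape error: sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  q <- length(alphabet)
  chars <- matrix(unlist(strsplit(toupper(strings), "")), nrow = length(strings),
                  byrow = TRUE)
  codes <- match(chars, toupper(alphabet))
  codes[is.na(codes)] <- q  # unknown symbols and '.' become the gap
  matrix(as.integer(codes), nrow = length(strings))
}

#' Decode an integer code matrix back to character strings
#' @param seqs integer matrix of codes
#' @param alphabet ordered symbol vector
#' @return character vector
#' @export
decode_sequences <- function(seqs, alphabet = default_alphabet()) {
  apply(seqs, 1, function(row) paste(alphabet[row], collapse = ""))
}

#' Read an aligned FASTA file into an encoded alignment
#'
#' All records must have the same length.  Characters outside the 20
#' standard amino acids and \code{"-"} are encoded as gaps.
#'
#' @param path path to an aligned FASTA file
#' @param alphabet symbol ordering to encode against
#' @return an \code{encoded_alignment}
#' @export
read_fasta_alignment <- function(path, alphabet = default_alphabet()) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty input: no FASTA records in ", path)
  strings <- as.character(ss)
  seqs <- encode_sequences(unname(strings), alphabet)
  encoded_alignment(seqs, alphabet = alphabet, ids = names(ss))
}

#' Write an encoded alignment to FASTA
#' @param aln an \code{encoded_alignment}
#' @param path output path
#' @export
write_fasta_alignment <- function(aln, path) {
  strings <- decode_sequences(aln$seqs, aln$alphabet)
  ids <- aln$ids
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(aln$seqs)))
  ss <- Biostrings::BStringSet(stats::setNames(strings, ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Remove duplicated sequences, keeping the first occurrence
#'
#' @param aln an \code{encoded_alignment}
#' @return deduplicated \code{encoded_alignment}, input order preserved
#' @export
deduplicate <- function(aln) {
  keep <- !duplicated(asplit(aln$seqs, 1))
  encoded_alignment(aln$seqs[keep, , drop = FALSE], aln$alphabet,
                    ids = aln$ids[keep],
                    weights = if (!is.null(aln$weights)) aln$weights[keep])
}

subset_alignment <- function(aln, idx) {
  encoded_alignment(aln$seqs[idx, , drop = FALSE], aln$alphabet,
                    ids = aln$ids[idx],
                    weights = if (!is.null(aln$weights)) aln$weights[idx])
}

#' Minimum normalized Hamming distance from a sequence to a reference set
#'
#' The normalized Hamming distance between two aligned sequences is the
#' fraction of positions at which they differ.
#'
#' @param s integer code vector (one sequence)
#' @param ref an \code{encoded_alignment} used as the reference set
#' @return minimum over the reference sequences, in \code{[0, 1]}
#' @export
min_hamming_to_set <- function(s, ref) {
  if (n_sequences(ref) == 0) stop("empty reference set")
  if (length(s) != ncol(ref$seqs)) stop("sequence length mismatch")
  diffs <- ref$seqs != matrix(s, nrow = nrow(ref$seqs), ncol = length(s),
                              byrow = TRUE)
  min(rowMeans(diffs))
}

#' Label test sequences as close or distant from the training set
#'
#' The \code{distant_fraction} of test sequences with the largest minimum
#' normalized Hamming distance to the training set are labeled
#' \code{"distant"}, the rest \code{"close"}.  The distant count is the
#' nearest integer (half-up) to \code{distant_fraction * n_test}; ties in
#' distance are resolved by input order, earlier sequences winning the
#' distant slot.
#'
#' @param test,train \code{encoded_alignment}s
#' @param distant_fraction fraction of the test set labeled distant
#' @return character vector of labels, one per test sequence
#' @export
partition_test_by_distance <- function(test, train, distant_fraction = 0.1) {
  n_test <- n_sequences(test)
  if (n_test == 0 || n_sequences(train) == 0)
    stop("test and train sets must be non-empty")
  d <- vapply(seq_len(n_test),
              function(i) min_hamming_to_set(test$seqs[i, ], train),
              numeric(1))
  k <- floor(distant_fraction * n_test + 0.5)
  labels <- rep("close", n_test)
  if (k > 0) {
    ord <- order(-d, seq_len(n_test))  # stable: earlier index wins ties
    labels[ord[seq_len(k)]] <- "distant"
  }
  labels
}

#' Randomly split an alignment into train and test sets
#'
#' Draws a uniformly random partition at the given test fraction (nearest
#' integer, at least one test sequence), then labels test sequences close or
#' distant by their minimum Hamming distance to the training set.
#'
#' @param aln a deduplicated \code{encoded_alignment} with at least 2 rows
#' @param test_fraction fraction of sequences assigned to the test set
#' @param seed integer seed making the split reproducible
#' @param distant_fraction passed to \code{\link{partition_test_by_distance}}
#' @return list with elements \code{train}, \code{test} (alignments),
#'   \code{test_labels} and \code{split_seed}
#' @export
split_train_test <- function(aln, test_fraction = 0.1, seed = 1L,
                             distant_fraction = 0.1) {
  n <- n_sequences(aln)
  if (n < 2) stop("need at least 2 sequences to split")
  n_test <- max(1L, as.integer(floor(test_fraction * n + 0.5)))
  rng <- local_rng(seed)
  test_idx <- sort(sample.int(n, n_test))
  train <- subset_alignment(aln, setdiff(seq_len(n), test_idx))
  test <- subset_alignment(aln, test_idx)
  structure(list(train = train, test = test,
                 test_labels = partition_test_by_distance(test, train,
                                                          distant_fraction),
                 split_seed = as.integer(seed)),
            class = "split_result")
}

#' Phylogenetic reweighting of an alignment
#'
#' Standard neighborhood-counting scheme: the weight of sequence m is
#' 1 / (number of sequences, m included, whose fraction of identical
#' positions with m is at least \code{similarity_threshold}).  Gaps count as
#' an ordinary 21st symbol in the identity computation.  Down-weights dense
#' clusters of near-identical sequences that would otherwise dominate
#' training objectives.
#'
#' @param aln a deduplicated \code{encoded_alignment}
#' @param similarity_threshold fractional identity defining a neighbor
#' @return numeric weights in \code{(0, 1]}, one per sequence
#' @export
compute_weights <- function(aln, similarity_threshold = 0.8) {
  S <- aln$seqs
  n <- nrow(S); N <- ncol(S)
  counts <- integer(n)
  for (i in seq_len(n)) {
    ident <- rowMeans(S == matrix(S[i, ], n, N, byrow = TRUE))
    counts[i] <- sum(ident >= similarity_threshold)
  }
  1 / counts
}

#' Attach weights to an alignment
#' @param aln an \code{encoded_alignment}
#' @param similarity_threshold see \code{\link{compute_weights}}
#' @return the alignment with its \code{weights} field populated
#' @export
reweight_alignment <- function(aln, similarity_threshold = 0.8) {
  aln$weights <- compute_weights(aln, similarity_threshold)
  aln
}
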
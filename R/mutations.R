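#' Construct a mutational dataset
#'
#' Pairs a wild-type sequence with a table of substitution records and
#' experimental (or synthetic) fitness values, the input for
#' mutational-effect benchmarking.  Each record holds one or more single
#' substitutions; the originating residue of every substitution must match
#' the wild type at that position.
#'
#' @param wildtype integer code vector (the wild-type sequence)
#' @param subs list of integer matrices, one per record, with columns
#'   \code{pos}, \code{from}, \code{to} (1-based positions, codes in 1..q)
#' @param fitness numeric fitness value per record
#' @param alphabet symbol ordering the codes refer to
#' @return object of class \code{mutational_dataset}
#' @export
mutational_dataset <- function(wildtype, subs, fitness,
                               alphabet = default_alphabet()) {
  if (length(subs) != length(fitness))
    stop("one fitness value per mutation record required")
  N <- length(wildtype)
  for (r in seq_along(subs)) {
    m <- subs[[r]]
    if (any(m[, "pos"] < 1 | m[, "pos"] > N))
      stop("record ", r, ": position out of range 1..", N)
    bad <- which(wildtype[m[, "pos"]] != m[, "from"])
    if (length(bad))
      stop("record ", r, ": wild-type residue mismatch at position ",
           m[bad[1], "pos"])
  }
  structure(list(wildtype = as.integer(wildtype), subs = subs,
                 fitness = as.numeric(fitness), alphabet = alphabet),
            class = "mutational_dataset")
}

#' @export
print.mutational_dataset <- function(x, ...) {
  cat(sprintf("mutational dataset: %d records on a length-%d wild type\n",
              length(x$fitness), length(x$wildtype)))
  invisible(x)
}

# Parse a colon-separated mutation spec like "A42G" or "A1C:G2A" into an
# integer matrix with columns pos/from/to.  File positions are 1-based.
parse_mutation_spec <- function(spec, alphabet) {
  parts <- strsplit(trimws(spec), ":")[[1]]
  out <- matrix(0L, nrow = length(parts), ncol = 3,
                dimnames = list(NULL, c("pos", "from", "to")))
  for (k in seq_along(parts)) {
    p <- parts[k]
    m <- regmatches(p, regexec("^([A-Za-z.-])([0-9]+)([A-Za-z.-])$", p))[[1]]
    if (length(m) != 4) stop("cannot parse mutation spec '", p, "'")
    codes <- match(toupper(c(m[2], m[4])), toupper(alphabet))
    codes[is.na(codes)] <- length(alphabet)
    out[k, ] <- c(as.integer(m[3]), codes[1], codes[2])
  }
  out
}

#' Read a mutational fitness table
#'
#' Expects a delimited text file with a header \code{mutant,fitness};
#' \code{mutant} entries are colon-separated substitution specs such as
#' \code{"A42G"} (1-based positions), \code{fitness} a single numeric
#' column.  Every record is validated against the wild type.
#'
#' @param path path to the CSV file
#' @param wildtype integer code vector of the wild-type sequence
#' @param alphabet symbol ordering for en/decoding residues
#' @return a \code{\link{mutational_dataset}}
#' @export
read_mutational_csv <- function(path, wildtype,
                                alphabet = default_alphabet()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty mutational table: ", path)
  subs <- lapply(seq_len(nrow(tab)), function(r) {
    tryCatch(parse_mutation_spec(tab$mutant[r], alphabet),
             error = function(e) stop("row ", r, ": ", conditionMessage(e)))
  })
  tryCatch(mutational_dataset(wildtype, subs, tab$fitness, alphabet),
           error = function(e) stop("validation failed in ", path, ": ",
                                    conditionMessage(e)))
}

#' Write a mutational dataset to CSV
#' @param data a \code{mutational_dataset}
#' @param path output path
#' @export
write_mutational_csv <- function(data, path) {
  specs <- vapply(data$subs, function(m) {
    paste(sprintf("%s%d%s", data$alphabet[m[, "from"]], m[, "pos"],
                  data$alphabet[m[, "to"]]), collapse = ":")
  }, character(1))
  utils::write.csv(data.frame(mutant = specs, fitness = data$fitness),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Materialize mutant sequences as a code matrix
#'
#' Applies each record's substitutions to the wild type.
#'
#' @param data a \code{mutational_dataset}
#' @return integer matrix with one mutant per row
#' @export
mutant_matrix <- function(data) {
  n <- length(data$subs)
  out <- matrix(rep(data$wildtype, each = n), nrow = n)
  for (r in seq_len(n)) {
    m <- data$subs[[r]]
    out[r, m[, "pos"]] <- m[, "to"]
  }
  storage.mode(out) <- "integer"
  out
}
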
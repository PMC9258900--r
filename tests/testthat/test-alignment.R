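test_that("encoding maps standard residues, gaps and unknowns correctly", {
  codes <- encode_sequences(c("AC-", "ACA"))
  expect_equal(codes[1, ], c(1L, 2L, 21L))
  expect_equal(codes[2, ], c(1L, 2L, 1L))
  # non-standard residues and '.' become the gap code, case-insensitively
  codes2 <- encode_sequences(c("aXc", "B.U"))
  expect_equal(codes2[1, ], c(1L, 21L, 2L))
  expect_equal(codes2[2, ], c(21L, 21L, 21L))
  expect_error(encode_sequences(c("ACD", "ACDE")), "unequal lengths")
  expect_error(encode_sequences(character(0)), "empty")
})

test_that("encoding round-trips over the standard alphabet", {
  set.seed(1)
  ab <- default_alphabet()
  strings <- replicate(20, paste(sample(ab, 15, replace = TRUE), collapse = ""))
  expect_identical(decode_sequences(encode_sequences(strings), ab), strings)
})

test_that("FASTA round trip preserves sequences and ids", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDE-", ">s2", "acdXg"), tmp)
  aln <- read_fasta_alignment(tmp)
  expect_equal(nrow(aln$seqs), 2)
  expect_equal(ncol(aln$seqs), 5)
  expect_equal(aln$seqs[1, 5], 21L)          # gap
  expect_equal(aln$seqs[2, 4], 21L)          # 'X' -> gap
  expect_equal(aln$ids, c("s1", "s2"))
  tmp2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, tmp2)
  expect_equal(read_fasta_alignment(tmp2)$seqs, aln$seqs)
})

test_that("deduplicate keeps first occurrences and is idempotent", {
  s1 <- c(1L, 2L, 3L); s2 <- c(3L, 2L, 1L)
  aln <- encoded_alignment(rbind(s1, s2, s1, s1), alphabet = toy_alphabet(3),
                           ids = c("a", "b", "c", "d"))
  dd <- deduplicate(aln)
  expect_equal(nrow(dd$seqs), 2)
  expect_equal(dd$ids, c("a", "b"))
  expect_equal(deduplicate(dd)$seqs, dd$seqs)
  # all-distinct input unchanged
  aln2 <- encoded_alignment(rbind(s1, s2), alphabet = toy_alphabet(3))
  expect_equal(deduplicate(aln2)$seqs, aln2$seqs)
})

test_that("train/test split is a disjoint 9:1 cover, deterministic by seed", {
  set.seed(42)
  aln <- encoded_alignment(matrix(sample.int(4, 100 * 8, replace = TRUE),
                                  100, 8), alphabet = toy_alphabet(4))
  aln <- deduplicate(aln)
  n <- n_sequences(aln)
  sp <- split_train_test(aln, 0.1, seed = 7)
  expect_equal(n_sequences(sp$test), max(1, floor(0.1 * n + 0.5)))
  expect_equal(n_sequences(sp$train) + n_sequences(sp$test), n)
  key <- function(a) apply(a$seqs, 1, paste, collapse = ",")
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  sp2 <- split_train_test(aln, 0.1, seed = 7)
  expect_identical(sp$test$seqs, sp2$test$seqs)
  expect_error(split_train_test(encoded_alignment(matrix(1L, 1, 3),
                                                  alphabet = toy_alphabet(2))),
               "at least 2")
  # 10 sequences -> 9/1
  small <- encoded_alignment(aln$seqs[1:10, ], alphabet = toy_alphabet(4))
  sp3 <- split_train_test(small, 0.1, seed = 1)
  expect_equal(n_sequences(sp3$test), 1)
})

test_that("min Hamming distance to a set behaves on the boundary cases", {
  ref <- encoded_alignment(rbind(c(1L, 1L, 2L), c(2L, 2L, 2L)),
                           alphabet = toy_alphabet(2))
  expect_equal(min_hamming_to_set(c(1L, 1L, 2L), ref), 0)
  expect_equal(min_hamming_to_set(c(1L, 1L, 1L), ref), 1 / 3)
  ref2 <- encoded_alignment(matrix(c(2L, 2L, 2L), 1), alphabet = toy_alphabet(2))
  expect_equal(min_hamming_to_set(c(1L, 1L, 1L), ref2), 1)
  expect_error(min_hamming_to_set(c(1L, 1L),
                                  encoded_alignment(matrix(integer(0), 0, 2),
                                                    alphabet = toy_alphabet(2))),
               "empty")
})

test_that("distance partition labels the farthest 10%, ties by index", {
  # construct test sequences at controlled distances from one train sequence
  N <- 10
  train <- encoded_alignment(matrix(1L, 1, N), alphabet = toy_alphabet(3))
  mk <- function(k) { s <- rep(1L, N); if (k > 0) s[seq_len(k)] <- 2L; s }
  test <- encoded_alignment(do.call(rbind, lapply(1:10, mk)),
                            alphabet = toy_alphabet(3))
  lab <- partition_test_by_distance(test, train)
  expect_equal(sum(lab == "distant"), 1)
  expect_equal(which(lab == "distant"), 10)   # the farthest one
  test20 <- encoded_alignment(do.call(rbind, lapply(rep(1:10, 2), mk)),
                              alphabet = toy_alphabet(3))
  expect_equal(sum(partition_test_by_distance(test20, train) == "distant"), 2)
  # all-equal distances: first index wins
  testeq <- encoded_alignment(do.call(rbind, lapply(rep(3, 10), mk)),
                              alphabet = toy_alphabet(3))
  labeq <- partition_test_by_distance(testeq, train)
  expect_equal(which(labeq == "distant"), 1)
})

test_that("reweighting counts 80% identity neighborhoods, gaps included", {
  N <- 10
  base <- rep(1L, N)
  near <- base; near[1] <- 2L                      # 90% identical to base
  far <- rep(3L, N)                                # 0% identical
  aln <- encoded_alignment(rbind(base, near, far), alphabet = toy_alphabet(3))
  w <- compute_weights(aln)
  expect_equal(w, c(1 / 2, 1 / 2, 1))
  # three mutually similar -> 1/3 each; group weights sum to 1
  near2 <- base; near2[2] <- 2L
  aln3 <- encoded_alignment(rbind(base, near, near2), alphabet = toy_alphabet(3))
  expect_equal(compute_weights(aln3), rep(1 / 3, 3))
  expect_equal(sum(compute_weights(aln3)), 1)
  # all mutually dissimilar -> all 1
  aln_far <- encoded_alignment(rbind(base, far, rep(2L, N)),
                               alphabet = toy_alphabet(3))
  expect_equal(compute_weights(aln_far), rep(1, 3))
})

test_that("mutational CSV parsing validates against the wild type", {
  wt <- encode_sequences("ACDEF")[1, ]
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mutant,fitness", "A1C,0.5", "A1C:C2A,-1.2"), tmp)
  md <- read_mutational_csv(tmp, wt)
  expect_equal(length(md$fitness), 2)
  expect_equal(md$subs[[1]][1, "pos"], c(pos = 1))
  expect_equal(md$fitness, c(0.5, -1.2))
  expect_equal(nrow(md$subs[[2]]), 2)
  # mutant matrix applies substitutions
  mm <- mutant_matrix(md)
  expect_equal(mm[1, 1], 2L)                       # A -> C
  expect_equal(mm[2, 1:2], c(2L, 1L))
  # wild-type mismatch and out-of-range position are errors
  writeLines(c("mutant,fitness", "C1A,0.5"), tmp)
  expect_error(read_mutational_csv(tmp, wt), "mismatch")
  writeLines(c("mutant,fitness", "A9C,0.5"), tmp)
  expect_error(read_mutational_csv(tmp, wt), "out of range")
  # round trip
  md2 <- mutational_dataset(wt, md$subs, md$fitness)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_mutational_csv(md2, tmp2)
  md3 <- read_mutational_csv(tmp2, wt)
  expect_equal(md3$fitness, md2$fitness)
  expect_equal(md3$subs, md2$subs)
})
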
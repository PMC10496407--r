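test_that("homopolymer compression collapses maximal runs with an exact map", {
  h <- hpc_compress("AAACCG")
  expect_equal(h$compressed, "ACG")
  expect_equal(h$start, c(0L, 3L, 5L))
  expect_equal(h$end, c(3L, 5L, 6L))

  expect_equal(hpc_compress("")$compressed, "")
  expect_length(hpc_compress("")$start, 0L)

  h2 <- hpc_compress("ATAT")
  expect_equal(h2$compressed, "ATAT")
  expect_equal(h2$end - h2$start, rep(1L, 4L))
})

test_that("homopolymer compression round-trips and is idempotent", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_dna(sample(1:120, 1))
    h <- hpc_compress(s)
    expect_identical(hpc_expand(h), s)
    expect_identical(hpc_compress(h$compressed)$compressed, h$compressed)
    # runs tile the original exactly
    expect_equal(h$start[1], 0L)
    expect_equal(h$end[length(h$end)], nchar(s))
    if (length(h$start) > 1L) {
      expect_equal(h$start[-1], h$end[-length(h$end)])
    }
  }
})

test_that("edit_align reproduces classic and identity cases", {
  expect_equal(edit_align("kitten", "sitting")$edit_distance, 3L)
  a <- edit_align("ACGTACGT", "ACGTACGT")
  expect_equal(a$edit_distance, 0L)
  expect_equal(a$identity, 1)
  expect_error(edit_align("", "ACGT"), "non-empty")
})

test_that("edit_align matches the full-matrix oracle on random pairs", {
  set.seed(7)
  for (i in 1:60) {
    m <- sample(1:300, 1); n <- sample(1:300, 1)
    a <- random_dna(m); b <- random_dna(n)
    expect_equal(edit_align(a, b, "global")$edit_distance, lev_oracle(a, b))
  }
})

test_that("infix mode finds the best-matching substring", {
  set.seed(8)
  for (i in 1:20) {
    q <- random_dna(sample(3:8, 1))
    t <- random_dna(sample(8:25, 1))
    expect_equal(edit_align(q, t, "infix")$edit_distance, infix_oracle(q, t))
  }
  # a planted infix is found exactly
  t <- paste0(random_dna(500), "ACGTACGTTTGCA", random_dna(500))
  a <- edit_align("ACGTACGTTTGCA", t, "infix")
  expect_equal(a$edit_distance, 0L)
})

test_that("edit distance equals the sum of non-match cigar op lengths", {
  set.seed(9)
  for (i in 1:25) {
    a <- random_dna(200); b <- errify(a, 0.1)
    al <- edit_align(a, b, "global")
    cg <- al$cigar
    expect_equal(sum(cg$len[cg$op != "="]), al$edit_distance)
    expect_equal(sum(cg$len), al$alignment_length)
    expect_gte(al$identity, 0); expect_lte(al$identity, 1)
  }
})

test_that("phred conversion follows -10 log10(1 - identity) with a cap", {
  expect_equal(phred_from_identity(0.9), 10)
  expect_equal(phred_from_identity(0.99874), 29, tolerance = 0.02 / 29)
  expect_equal(phred_from_identity(1), 60)
  expect_equal(phred_from_identity(1, cap = 45), 45)
  expect_error(phred_from_identity(1.2), "identity")
  expect_error(phred_from_identity(-0.1), "identity")
  # monotone increasing on [0, 1)
  ids <- seq(0, 0.999, length.out = 200)
  expect_true(all(diff(phred_from_identity(ids)) > 0))
})

test_that("column consensus takes per-column majorities over non-gap symbols", {
  expect_equal(column_consensus(c("ACGT", "ACGT")), "ACGT")
  expect_equal(column_consensus(c("ACGT", "ACCT", "ACCT")), "ACCT")
  expect_equal(column_consensus(c("A-", "AT")), "AT")
  expect_equal(column_consensus(c("A-", "A-")), "A")  # all-gap column dropped
  expect_equal(column_consensus(c("AN", "AN", "AC")), "AC")  # N is missing
  expect_equal(column_consensus(c("AC", "AG")), "AC")  # tie: lexicographic
  expect_error(column_consensus(c("AC", "A")), "equal length")
  expect_error(column_consensus(character(0)), "at least one")
})

test_that("fasta/fastq round-trip through files", {
  tmp <- tempfile(fileext = ".fa")
  seqs <- c(a = "ACGTACGT", b = "TTTTGGGG")
  write_fasta(seqs, tmp)
  expect_identical(read_seqs(tmp), seqs)
  tmpq <- tempfile(fileext = ".fastq")
  write_fastq(seqs, tmpq)
  expect_identical(read_seqs(tmpq), seqs)
})
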
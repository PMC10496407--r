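test_that("read truncation clips to the aligned interval plus flank", {
  reads <- c(strrep("A", 3000), strrep("C", 20000))
  # read fully inside the window: unchanged
  out <- truncate_reads(reads[1], 500L, 2500L, 9000L)
  expect_equal(nchar(out), 3000L)
  # 12 kb past the alignment end, flank 9 kb: 9 kb retained beyond the end
  out <- truncate_reads(reads[2], 0L, 8000L, 9000L)
  expect_equal(nchar(out), 8000L + 9000L)
  # flank 0: reads end at the alignment boundary
  out <- truncate_reads(reads[2], 1000L, 8000L, 0L)
  expect_equal(nchar(out), 7000L)
  expect_equal(attr(out, "offsets"), 1000L)
})

test_that("error-free tiling reads assemble the window exactly", {
  set.seed(41)
  window <- random_dna(8000)
  starts <- as.integer(seq(0, 6000, by = 300))
  reads <- substring(window, starts + 1L, pmin(starts + 2000L, 8000L))
  res <- assemble_cluster(reads, starts)
  expect_identical(res$contig, window)
})

test_that("undersized or discontiguous clusters signal assembly failure", {
  set.seed(42)
  window <- random_dna(3000)
  expect_error(assemble_cluster(substring(window, c(1, 500, 1000), 2500),
                                c(0L, 499L, 999L), min_reads = 5L),
               class = "sdweaver_assembly_error")
  # a coverage gap would split the assembly into two contigs
  starts <- c(0L, 200L, 2200L, 2400L, 2600L)
  reads <- substring(window, starts + 1L, starts + 400L)
  expect_error(assemble_cluster(reads, starts, min_reads = 3L),
               class = "sdweaver_assembly_error")
})

test_that("noisy reads polish to a near-perfect window consensus", {
  set.seed(43)
  window <- random_dna(5000)
  starts <- as.integer(seq(0, 3000, by = 75))
  reads <- errify(substring(window, starts + 1L, pmin(starts + 2000L, 5000L)),
                  0.15)
  res <- assemble_cluster(reads, starts, rounds = 4L)
  # score the evenly covered core of the window: coverage ramps up over the
  # first read length and decays past the last read start
  a <- edit_align(substr(res$contig, 2001, 4500),
                  substr(window, 1800, 4700), "infix")
  expect_gte(phred_from_identity(a$identity), 20)
})

test_that("anchor extension follows the contig suffix with a step cap", {
  set.seed(44)
  anchor <- random_dna(1000)
  st <- new_anchor_state(anchor)
  suffix <- random_dna(800)
  r <- extend_anchor(st, paste0(anchor, suffix), step_cap = 1000L,
                     anchor_len = 1000L)
  expect_equal(r$status, "extended")
  expect_equal(r$extension, 800L)
  expect_identical(r$state$assembled, paste0(anchor, suffix))
  expect_identical(r$state$anchor,
                   substr(paste0(anchor, suffix), 801L, 1800L))
  # contig identical to the anchor: no extension
  r <- extend_anchor(st, anchor, 1000L, 1000L)
  expect_equal(r$status, "terminated_no_extension")
  expect_equal(r$extension, 0L)
  # a 2.5 kb suffix is capped at step_cap
  r <- extend_anchor(st, paste0(anchor, random_dna(2500)), 1000L, 1000L)
  expect_equal(r$extension, 1000L)
  # an unrelated contig means the anchor lost its locus
  r <- extend_anchor(st, random_dna(3000), 1000L, 1000L)
  expect_equal(r$status, "terminated_lost_track")
})

test_that("a single-copy region assembles exactly from error-free reads", {
  set.seed(45)
  region <- random_dna(9000)
  starts <- sample(0:7200, 120, replace = TRUE)
  reads <- setNames(substring(region, starts + 1L, starts + 1800L),
                    sprintf("r%03d", 1:120))
  cfg <- run_config(seed = 9, anchor_len = 600L, coverage = 24,
                    error_rate = 0, read_mean = 1800, read_sd = 1,
                    step_cap = 500L, flank = 800L, max_length = 8600L,
                    min_cov_frac = 0.4)
  # the anchor must sit inside the read cloud so that reads span it
  run <- sd_assemble(reads, substr(region, 501, 1100), cfg)
  expect_gte(nchar(run$contig), 6500L)
  a <- edit_align(run$contig, substr(region, 501, 9000), "semiglobal")
  expect_equal(a$edit_distance, 0L)
  expect_equal(phred_from_identity(a$identity), 60)
})

test_that("the driver is deterministic given a fixed seed", {
  set.seed(46)
  region <- random_dna(6000)
  starts <- sample(0:4800, 150, replace = TRUE)
  reads <- setNames(errify(substring(region, starts + 1L, starts + 1200L), 0.1),
                    sprintf("r%03d", 1:150))
  cfg <- run_config(seed = 33, anchor_len = 500L, coverage = 30,
                    error_rate = 0.1, read_mean = 1200, read_sd = 1,
                    step_cap = 400L, flank = 600L, max_length = 5200L)
  r1 <- sd_assemble(reads, substr(region, 101, 600), cfg)
  r2 <- sd_assemble(reads, substr(region, 101, 600), cfg)
  expect_identical(r1$contig, r2$contig)
  expect_identical(r1$history, r2$history)
  # invariants: per-iteration extension bounded, assembly non-decreasing
  expect_true(all(r1$history$extension <= 400L))
  expect_true(all(diff(r1$history$assembled_len) >= 0))
})

test_that("running out of reads terminates gracefully", {
  set.seed(47)
  region <- random_dna(9000)
  starts <- sample(0:2400, 60, replace = TRUE)  # reads only over [0, 3.6 kb]
  reads <- setNames(substring(region, starts + 1L, starts + 1200L),
                    sprintf("r%03d", 1:60))
  cfg <- run_config(seed = 3, anchor_len = 500L, coverage = 20,
                    error_rate = 0, read_mean = 1200, read_sd = 1,
                    step_cap = 400L, flank = 600L, max_length = 8000L)
  run <- sd_assemble(reads, substr(region, 1, 500), cfg)
  expect_equal(run$status, "terminated_no_reads")
  expect_lt(nchar(run$assembled), 4500L)
  # an anchor with no reads at all is a hard error at iteration 1
  expect_error(sd_assemble(reads, substr(region, 6001, 6600), cfg),
               "no reads recruited")
})

test_that("bidirectional assembly stitches the two directions at the anchor", {
  set.seed(48)
  region <- random_dna(7000)
  starts <- sample(0:5800, 140, replace = TRUE)
  reads <- setNames(substring(region, starts + 1L, starts + 1200L),
                    sprintf("r%03d", 1:140))
  cfg <- run_config(seed = 12, anchor_len = 500L, coverage = 24,
                    error_rate = 0, read_mean = 1200, read_sd = 1,
                    step_cap = 400L, flank = 600L, max_length = 6500L,
                    trim_tail = 0L)
  anchor <- substr(region, 3001, 3500)
  res <- sd_assemble_bidirectional(reads, anchor, cfg)
  a <- chained_alignment(res$contig, region)
  expect_gte(a$coverage, 0.95)
  expect_equal(a$edit_distance, 0L)
  expect_gte(nchar(res$contig), nchar(res$forward$contig))
})
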
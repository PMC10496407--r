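test_that("tree topologies have the promised shapes", {
  flat <- topology_tree("flat", 5)
  expect_equal(length(flat$tip.label), 5L)
  expect_equal(flat$Nnode, 1L)  # star: one internal node

  bif <- topology_tree("bifurcating", 8)
  expect_equal(length(bif$tip.label), 8L)
  # balanced binary: every tip at depth 3
  depths <- ape::node.depth.edgelength(ape::compute.brlen(bif, 1))
  expect_true(all(depths[1:8] == 3))

  casc <- topology_tree("cascading", 6)
  depths <- ape::node.depth.edgelength(ape::compute.brlen(casc, 1))
  expect_equal(max(depths[1:6]), 5)  # caterpillar: deepest tip at n - 1

  set.seed(3)
  rnd <- topology_tree("random", 10)
  expect_equal(length(rnd$tip.label), 10L)
  expect_true(ape::is.binary(rnd))
})

test_that("zero mutation rate copies the root to every leaf", {
  set.seed(11)
  root <- random_dna(800)
  tr <- evolve_units(root, topology_tree("bifurcating", 4), 0)
  expect_true(all(tr$units == root))
})

test_that("per-edge substitutions match the binomial expectation", {
  set.seed(12)
  L <- 500; r <- 0.02; n_rep <- 100
  ham <- replicate(n_rep, {
    root <- random_dna(L)
    tr <- evolve_units(root, topology_tree("flat", 2), r)
    mean(strsplit(tr$units[[1]], "")[[1]] != strsplit(root, "")[[1]])
  })
  se <- sqrt(r * (1 - r) / (L * n_rep))
  expect_lt(abs(mean(ham) - r), 3 * se)
})

test_that("leaf-vs-root identity hits the configured 99.5% target", {
  set.seed(13)
  L <- 4000
  root <- random_dna(L)
  tr <- evolve_units(root, topology_tree("flat", 2), 1 - 0.995)
  div <- vapply(tr$units, function(u)
    mean(strsplit(u, "")[[1]] != strsplit(root, "")[[1]]), 0)
  se <- sqrt(0.005 * 0.995 / L)
  expect_true(all(abs(div - 0.005) < 3 * se + 1e-9))
  # leaf-vs-leaf divergence doubles (independent edges)
  d12 <- mean(strsplit(tr$units[[1]], "")[[1]] != strsplit(tr$units[[2]], "")[[1]])
  expect_lt(abs(d12 - 2 * 0.005 * 0.995), 3 * sqrt(0.01 / L) + 2e-3)
})

test_that("collapsed contig layout arithmetic and flank uniqueness hold", {
  set.seed(14)
  root <- random_dna(3000)
  tr <- evolve_units(root, topology_tree("flat", 2), 0.005)
  tr <- build_collapsed_contig(tr, flank_len = 1000)
  expect_equal(nchar(tr$contig), 1000L + 2L * 3000L + 1000L)
  expect_equal(tr$unit_intervals$start, c(1000L, 4000L))
  expect_equal(tr$unit_intervals$end, c(4000L, 7000L))
  # spacers add unique flanks between units
  tr2 <- build_collapsed_contig(tr, flank_len = 1000, spacer_len = 500)
  expect_equal(nchar(tr2$contig), 1000L + 3000L + 500L + 3000L + 1000L)
  # no flank 21-mer occurs in any unit
  k <- 21L
  unit_kmers <- unique(unlist(lapply(tr2$units, function(u)
    substring(u, 1:(nchar(u) - k + 1L), k:nchar(u)))))
  for (i in seq_len(nrow(tr2$flanks))) {
    f <- substr(tr2$contig, tr2$flanks$start[i] + 1L, tr2$flanks$end[i])
    if (nchar(f) < k) next
    fk <- substring(f, 1:(nchar(f) - k + 1L), k:nchar(f))
    expect_false(any(fk %in% unit_kmers))
  }
  # anchors come from the flank preceding each unit
  a <- anchor_for_leaf(tr2, "L2", 400)
  expect_identical(a, substr(tr2$contig, 4500 - 400 + 1L, 4500))
})

test_that("identical seeds give byte-identical truth sets and reads", {
  gen <- function() {
    set.seed(77)
    tr <- evolve_units(random_dna(2000), topology_tree("flat", 2), 0.005)
    tr <- build_collapsed_contig(tr, 800)
    list(tr = tr, reads = sample_reads(tr, coverage = 3, mean_len = 900,
                                       sd_len = 150, error_rate = 0.1))
  }
  x <- gen(); y <- gen()
  expect_identical(x$tr$contig, y$tr$contig)
  expect_identical(x$reads, y$reads)
})

test_that("error-free reads are exact substrings of the contig", {
  set.seed(15)
  tr <- evolve_units(random_dna(2500), topology_tree("flat", 2), 0.005)
  tr <- build_collapsed_contig(tr, 800)
  reads <- sample_reads(tr, coverage = 2, mean_len = 700, sd_len = 100,
                        error_rate = 0)
  for (i in seq_len(nrow(reads))) {
    origin <- substr(tr$contig, reads$start[i] + 1L, reads$end[i])
    if (reads$strand[i] == "-") origin <- revcomp_dna(origin)
    expect_identical(reads$seq[i], origin)
  }
  expect_true(all(reads$n_errors == 0L))
})

test_that("sampling meets the coverage target and the error calibration", {
  set.seed(16)
  ctg <- random_dna(60000)
  reads <- sample_reads(ctg, coverage = 10, mean_len = 1200, sd_len = 200,
                        error_rate = 0.15)
  expect_gte(sum(reads$end - reads$start), 10 * nchar(ctg))
  expect_true(all(reads$end - reads$start >= 200))
  # observed per-read error fraction within 3 sigma of the configured rate
  n <- min(500L, nrow(reads))
  frac <- reads$n_errors[1:n] / (reads$end - reads$start)[1:n]
  p <- 0.15
  se <- sqrt(p * (1 - p) / sum((reads$end - reads$start)[1:n]))
  expect_lt(abs(mean(frac) - p), 3 * se * 2)
  expect_error(sample_reads(ctg, coverage = 1, error_rate = 0.6), "error_rate")
  expect_error(sample_reads(ctg, coverage = 1, mean_len = 100), "mean_len")
})

test_that("the benchmark suite has the ten stated scenarios", {
  suite <- benchmark_suite(5, unit_len = 1200, flank_len = 500,
                           coverage = 2, read_mean = 400, read_sd = 60)
  expect_length(suite, 10L)
  n_leaves <- vapply(suite, function(s) nrow(s$truth$unit_intervals), 0L)
  expect_equal(unname(n_leaves[c("flat2", "flat4", "flat8")]), c(2L, 4L, 8L))
  expect_equal(unname(n_leaves[c("random10a", "random10b")]), c(10L, 10L))
  expect_equal(unname(n_leaves[c("cascading4", "cascading8")]), c(4L, 8L))
  expect_true(all(vapply(suite, function(s) !is.null(s$truth$contig), TRUE)))
})
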
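test_that("a contig identical to a unit is assigned with capped quality", {
  set.seed(51)
  units <- c(U1 = random_dna(6000), U2 = random_dna(6000))
  res <- assign_contigs(c(c1 = units[["U1"]]), units)
  a <- res$assignments
  expect_equal(a$unit, "U1")
  expect_gte(a$coverage, 0.99)
  expect_equal(a$q, 60)
  expect_equal(unname(res$resolved), c(TRUE, FALSE))
})

test_that("a contig covered below 95% of its length stays unassigned", {
  set.seed(52)
  unit <- random_dna(6000)
  contig <- paste0(unit, random_dna(450))  # ~93% of the contig aligns
  res <- assign_contigs(c(c1 = contig), c(U1 = unit))
  expect_true(is.na(res$assignments$unit))
  expect_false(res$resolved[["U1"]])
})

test_that("ties between equally good units break by order and are flagged", {
  set.seed(53)
  unit <- random_dna(5000)
  res <- assign_contigs(c(c1 = unit), c(U1 = unit, U2 = unit))
  expect_equal(res$assignments$unit, "U1")
  expect_true(res$assignments$ambiguous)
})

test_that("the alignment Q matches phred_from_identity of its identity", {
  set.seed(54)
  unit <- random_dna(8000)
  contig <- errify(unit, 0.003)
  res <- assign_contigs(c(c1 = contig), c(U1 = unit))
  a <- res$assignments
  expect_equal(a$q, phred_from_identity(a$identity))
  expect_false(is.na(a$identity))
})

test_that("BAC-style resolution applies the 99.5% clone-coverage rule", {
  set.seed(55)
  clone <- random_dna(10000)
  contig <- paste0(random_dna(2000), clone, random_dna(2000))
  r <- bac_style_resolution(contig, clone)
  expect_true(r$resolved)
  expect_equal(r$q, 60)
  # an alignment covering ~99% of the clone misses the threshold
  contig2 <- paste0(random_dna(2000), substr(clone, 1, 9900))
  r2 <- bac_style_resolution(contig2, clone)
  expect_false(r2$resolved)
  # 0.2% substitutions: resolved near Q 27
  clone3 <- errify(clone, 0) # copy
  v <- strsplit(clone3, "")[[1]]
  idx <- seq(17, 10000, by = 500)  # exactly 20 substitutions = 0.2%
  v[idx] <- vapply(v[idx], function(b) setdiff(c("A","C","G","T"), b)[1], "")
  r3 <- bac_style_resolution(paste0(random_dna(1000), paste(v, collapse = ""),
                                    random_dna(1000)), clone)
  expect_true(r3$resolved)
  expect_equal(r3$q, 26.99, tolerance = 1 / 27)
})

test_that("summaries compute resolution percentages and Q statistics", {
  asg <- data.frame(
    contig = c("a", "b", "c"),
    unit = c("U1", "U2", NA),
    coverage = c(0.99, 0.99, 0.5),
    identity = c(0.999, 0.998, NA),
    q = c(30, 27, NA),
    edit_distance = c(10, 20, NA),
    ambiguous = FALSE,
    scenario = c("s1", "s1", "s2"))
  sm <- summarize_assignments(asg, n_units = c(s1 = 2, s2 = 8))
  expect_equal(sm$resolved_pct[sm$scenario == "s1"], 100)
  expect_equal(sm$q_min[sm$scenario == "s1"], 27)
  expect_equal(sm$q_median[sm$scenario == "s1"], 28.5)
  expect_equal(sm$resolved_pct[sm$scenario == "s2"], 0)
  expect_true(is.na(sm$q_min[sm$scenario == "s2"]))
  # 1 of 8 resolved prints 12.5%
  asg$unit[3] <- "U3"; asg$q[3] <- 25
  sm <- summarize_assignments(asg, n_units = c(s1 = 2, s2 = 8))
  expect_equal(sm$resolved_pct[sm$scenario == "s2"], 12.5)
})

test_that("a single qualifying unit is never spuriously rejected", {
  set.seed(56)
  for (i in 1:5) {
    unit <- random_dna(4000)
    contig <- errify(unit, 0.002)
    res <- assign_contigs(setNames(contig, "c"), setNames(unit, "U"))
    expect_equal(res$assignments$unit, "U")
  }
})

test_that("resolution percent is invariant under contig relabeling", {
  set.seed(57)
  units <- setNames(c(random_dna(4000), random_dna(4000)), c("U1", "U2"))
  contigs <- setNames(c(units[[2]], units[[1]]), c("x", "y"))
  r1 <- assign_contigs(contigs, units)
  r2 <- assign_contigs(rev(contigs), units)
  expect_equal(sum(r1$resolved), sum(r2$resolved))
})
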
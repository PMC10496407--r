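# helper: pileup from constructed reads that all span the anchor
span_pileup <- function(anchor, reads, ...) {
  build_pileup(anchor, reads, ...)
}

# a sequence with n isolated substitution sites that survive homopolymer
# compression: the new base differs from both neighbours and the original
planted_variant <- function(seq, n_sites, seed) {
  set.seed(seed)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  picked <- integer(0)
  pos <- sample(3:(L - 2))
  for (p in pos) {
    if (length(picked) == n_sites) break
    if (any(abs(picked - p) < 10)) next
    nb <- setdiff(c("A", "C", "G", "T"), c(v[p - 1], v[p], v[p + 1]))
    if (length(nb) == 0 || v[p - 1] == v[p] || v[p + 1] == v[p]) next
    picked <- c(picked, p)
    v[p] <- nb[1]
  }
  list(seq = paste(v, collapse = ""), sites = sort(picked))
}

test_that("identical error-free copies give a unanimous pileup", {
  set.seed(31)
  anchor <- random_dna(1500)
  pu <- span_pileup(anchor, setNames(rep(anchor, 10), paste0("r", 1:10)))
  expect_equal(pu$n_reads, 10L)
  top <- apply(pu$counts, 2, max)
  expect_true(all(top == 10L))
  expect_equal(nrow(call_cismorphisms(pu, min_f2 = 0.05)), 0L)
})

test_that("reads from two units expose exactly the planted variant columns", {
  set.seed(32)
  u1 <- random_dna(1500)
  pv <- planted_variant(u1, 5, seed = 33)
  u2 <- pv$seq
  reads <- c(setNames(rep(u1, 8), paste0("a", 1:8)),
             setNames(rep(u2, 8), paste0("b", 1:8)))
  pu <- span_pileup(u1, reads)
  cis <- call_cismorphisms(pu, min_f2 = 0.2)
  expect_equal(nrow(cis), 5L)
  # called columns map back to the planted original positions
  amap <- hpc_compress(u1)
  called_orig <- amap$start[cis$pos] + 1L
  expect_setequal(called_orig, pv$sites)
  expect_true(all(cis$f2 == 0.5))
})

test_that("a read covering half the anchor is excluded from the pileup", {
  set.seed(34)
  anchor <- random_dna(1200)
  reads <- c(full = anchor, half = substr(anchor, 1, 600))
  pu <- span_pileup(anchor, reads)
  expect_equal(pu$read_ids, "full")
})

test_that("cis-morphism calling applies the f2 threshold and the site cap", {
  mk_pileup <- function(counts) {
    structure(list(counts = counts, n_reads = max(colSums(counts))),
              class = "sd_pileup")
  }
  cn <- matrix(0L, 5, 3, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  cn[, 1] <- c(18L, 12L, 0L, 0L, 0L)   # f2 = 0.4: retained
  cn[, 2] <- c(29L, 1L, 0L, 0L, 0L)    # f2 = 1/30: not retained
  cn[, 3] <- c(30L, 0L, 0L, 0L, 0L)
  cis <- call_cismorphisms(mk_pileup(cn), min_f2 = 0.2)
  expect_equal(cis$pos, 1L)
  expect_equal(cis$f2, 0.4)
  expect_equal(cis$major, "A"); expect_equal(cis$second, "C")

  # 250 qualifying loci with a cap of 200 keep the largest-f2 ones
  n <- 260L
  cn <- matrix(0L, 5, n, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  cn[1, ] <- 60L
  minor <- c(rep(0L, 10L), 15L + (seq_len(250L) %% 25L))
  cn[2, ] <- minor
  cis <- call_cismorphisms(mk_pileup(cn), min_f2 = 0.2, max_sites = 200L)
  expect_equal(nrow(cis), 200L)
  f2_all <- minor / (60L + minor)
  kept_thresh <- sort(f2_all[f2_all > 0.2], decreasing = TRUE)[200L]
  expect_true(all(cis$f2 >= kept_thresh))
})

test_that("similarity graph blocks follow the normalized Hamming rule", {
  g <- rbind(a = c(0L, 0L, 0L, 0L), b = c(0L, 0L, 0L, 0L))
  expect_equal(similarity_graph(g), c(1L, 1L))
  # AAAA vs TTTT: distance 1.0 over 4 shared loci -> different blocks
  g <- rbind(a = rep(0L, 4), b = rep(3L, 4))
  expect_equal(length(unique(similarity_graph(g))), 2L)
  # three mutually close reads plus one distant read -> blocks {3, 1}
  g <- rbind(a = c(0L, 0L, 0L, 0L), b = c(0L, 0L, 0L, 1L),
             c = c(0L, 0L, 1L, 0L), d = c(3L, 3L, 3L, 3L))
  memb <- similarity_graph(g, max_dist = 0.4)
  expect_equal(sort(as.vector(table(memb))), c(1L, 3L))
  expect_true(memb[1] == memb[2] && memb[2] == memb[3])
  expect_true(memb[4] != memb[1])
})

test_that("the cluster-size floor controls random partition splits", {
  set.seed(35)
  # two perfectly separated haplotype groups of 20 reads each over 6 loci
  g <- rbind(matrix(0L, 20, 6), matrix(1L, 20, 6))
  rownames(g) <- sprintf("r%02d", 1:40)
  # floor = 0.8 * 40 = 32: children of 20 are forbidden -> a single cluster
  p1 <- random_partition(g, coverage = 40, min_frac = 0.8, n_sim = 20, seed = 1)
  expect_equal(p1$n_clusters, 1L)
  expect_equal(length(p1$clusters[[1]]), 40L)
  # floor = 0.4 * 40 = 16: the split is allowed and is perfectly pure
  p2 <- random_partition(g, coverage = 40, min_frac = 0.4, n_sim = 20, seed = 1)
  expect_equal(p2$n_clusters, 2L)
  expect_equal(p2$score, 0)
  sizes <- sort(vapply(p2$clusters, length, 0L))
  expect_equal(sizes, c(20L, 20L))
  pur <- vapply(p2$clusters, function(cl)
    max(table(substr(cl, 1, 3) <= "r20")), 0L)
  expect_true(all(pur == 20L))
})

test_that("a block with zero loci stays one cluster with score zero", {
  g <- matrix(integer(0), nrow = 12, ncol = 0)
  rownames(g) <- paste0("r", 1:12)
  p <- random_partition(g, coverage = 10, min_frac = 0.8, n_sim = 5, seed = 2)
  expect_equal(p$n_clusters, 1L)
  expect_equal(p$score, 0)
  expect_error(random_partition(g[0, , drop = FALSE], 10), "empty")
})

test_that("clusters always partition the block", {
  set.seed(36)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    g <- matrix(sample(c(-1L, 0L, 1L, 2L), n * 8, replace = TRUE,
                       prob = c(0.1, 0.5, 0.3, 0.1)), n, 8)
    rownames(g) <- paste0("r", seq_len(n))
    p <- random_partition(g, coverage = 10, min_frac = 0.5, n_sim = 10,
                          seed = rep)
    ids <- sort(unlist(p$clusters))
    expect_identical(ids, sort(rownames(g)))
  }
})

test_that("cluster selection follows shared reads, then documented tie-breaks", {
  mk <- function(ids) list(ids = ids, consensus = c(0L, 1L))
  cl <- list(mk(c(paste0("r", 1:8), "r20")), mk(paste0("s", 1:10)))
  sel <- select_cluster(cl, prev_reads = paste0("r", 1:10))
  expect_equal(sel$index, 1L)
  expect_equal(sel$status, "ok")
  # equal overlap: the larger cluster wins
  cl <- list(mk(c("p1", "p2", "p3", "p4", "p5", "x1")),
             mk(c("p6", "p7", "p8", "p9", "p10", "y1", "y2")))
  sel <- select_cluster(cl, prev_reads = paste0("p", 1:10))
  expect_equal(sel$index, 2L)
  # no previous selection: pick by consensus similarity to the anchor
  cl <- list(list(ids = "a", consensus = c(0L, 0L, 0L)),
             list(ids = "b", consensus = c(1L, 1L, 1L)))
  sel <- select_cluster(cl, anchor_geno = c(1L, 1L, 1L))
  expect_equal(sel$index, 2L)
  # empty intersections without an anchor genotype: lost track
  sel <- select_cluster(cl, prev_reads = "zz")
  expect_equal(sel$status, "lost_track")
})

test_that("clustering separates simulated copies with high purity", {
  set.seed(37)
  root <- random_dna(2000)
  tr <- evolve_units(root, topology_tree("flat", 4), 0.005)
  reads <- unlist(lapply(names(tr$units), function(l) {
    setNames(errify(rep(tr$units[[l]], 36), 0.15), paste0(l, "_", 1:36))
  }))
  pu <- build_pileup(tr$units[[1]], reads, max_div = 0.32)
  cis <- sdweaver:::call_loci_z(pu, 36, 0.15)
  geno <- read_genotypes(pu, cis)
  memb <- similarity_graph(geno)
  blocks <- split(seq_len(nrow(geno)), memb)
  labs <- sub("_.*", "", pu$read_ids)
  purities <- c()
  for (rows in blocks) {
    if (length(rows) < 5) next
    p <- random_partition(geno[rows, , drop = FALSE], coverage = 36,
                          min_frac = 0.8, n_sim = 30, seed = 5,
                          per_cluster_penalty = 36,
                          state_rate = sdweaver:::pileup_state_rates(0.15))
    for (cl in p$clusters) {
      if (length(cl) < 5) next
      purities <- c(purities, max(table(labs[match(cl, pu$read_ids)])) /
                      length(cl))
    }
  }
  expect_true(all(purities >= 0.95))
})
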
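# Clustering phase: cis-morphism calling from a homopolymer-compressed pileup
# of anchor-spanning reads, similarity-graph blocking, randomized recursive
# partitioning, and selection of the cluster continuing the previous iteration.

GENO_MISSING <- -1L
GENO_STATES <- c("A", "C", "G", "T", "-")

#' Pileup of anchor-spanning reads on the homopolymer-compressed anchor
#'
#' Both anchor and reads are homopolymer-compressed; each read is aligned to
#' the HPC anchor with free read ends, and its base at every HPC anchor
#' position is recorded (insertions are ignored, deletions count as missing).
#' Only reads whose alignment spans the full HPC anchor at acceptable
#' divergence are retained — reads covering part of the anchor fail the
#' divergence filter because the unmatched anchor suffix/prefix is charged to
#' the edit distance.
#'
#' @param anchor anchor sequence (original space).
#' @param reads named character vector of oriented reads (or read segments
#'   covering the anchor).
#' @param band alignment band half-width (default scales with anchor length).
#' @param max_div maximum edit distance / alignment length for a read to count
#'   as spanning the anchor.
#' @param require_flanked require the read to extend beyond both anchor ends
#'   (used by the driver, whose read segments are padded); reads starting or
#'   ending exactly at an anchor boundary are then excluded.
#' @return an `sd_pileup`: `anchor_hpc` (string), `hpc_map`, `read_ids`,
#'   `calls` (reads x positions integer matrix: bases 0..3, 4 = deletion,
#'   -1 missing/unaligned), `counts` (5 x positions over `{A,C,G,T,-}`),
#'   `coverage`, `read_div`, and per-read original
#'   coordinates of the anchor span on the read (`r_as`, `r_ae`). `n_reads`
#'   is 0 when nothing spans the anchor (the caller then cannot cluster).
#' @export
build_pileup <- function(anchor, reads, band = NULL, max_div = 0.45,
                         require_flanked = FALSE) {
  stopifnot(is.character(anchor), length(anchor) == 1L, nchar(anchor) > 0L)
  amap <- hpc_compress(anchor)
  ah <- amap$compressed
  m <- nchar(ah)
  if (is.null(band)) band <- max(80L, ceiling(0.06 * m))
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  keep <- character(0)
  calls <- list(); r_as <- integer(0); r_ae <- integer(0); divs <- numeric(0)
  for (i in seq_along(reads)) {
    rmap <- hpc_compress(reads[[i]])
    th <- rmap$compressed
    n <- nchar(th)
    if (n < 0.5 * m) next
    d_lo <- -band
    d_hi <- max(n - m, 0L) + band
    a <- cpp_align(ah, th, d_lo, d_hi, TRUE, TRUE, FALSE, TRUE, TRUE)
    if (is.na(a$dist) || a$alnlen == 0L) next
    if (require_flanked && (a$t_start < 1L || a$t_end > n - 1L)) next
    div <- a$dist / a$alnlen
    if (div > max_div) next
    keep <- c(keep, ids[i])
    calls[[length(calls) + 1L]] <- a$calls
    divs <- c(divs, div)
    r_as <- c(r_as, hpc_lift(rmap, a$t_start, "start"))
    r_ae <- c(r_ae, hpc_lift(rmap, a$t_end, "end"))
  }
  n_reads <- length(keep)
  cm <- if (n_reads) do.call(rbind, calls) else
    matrix(integer(0), nrow = 0, ncol = m)
  rownames(cm) <- keep
  counts <- matrix(0L, nrow = 5L, ncol = m, dimnames = list(GENO_STATES, NULL))
  if (n_reads) {
    for (b in 0:4) counts[b + 1L, ] <- colSums(cm == b)
  }
  structure(list(anchor_hpc = ah, hpc_map = amap, read_ids = keep,
                 calls = cm, counts = counts,
                 coverage = colSums(counts),
                 read_div = divs, r_as = r_as, r_ae = r_ae,
                 n_reads = n_reads),
            class = "sd_pileup")
}

#' @export
print.sd_pileup <- function(x, ...) {
  cat(sprintf("<sd_pileup> %d reads spanning %d HPC positions\n",
              x$n_reads, nchar(x$anchor_hpc)))
  invisible(x)
}

#' Call cis-morphisms from a pileup
#'
#' A locus is a cis-morphism candidate when the frequency of its second most
#' common nucleotide exceeds `min_f2`. When more than `max_sites` loci
#' qualify, the `max_sites` loci with the largest second-base fraction are
#' retained (ties break to the leftmost position). Deletion columns count as a
#' fifth state: in homopolymer-compressed space most single-nucleotide
#' differences between SD copies surface as single-base indels (the new base
#' merges with or splits an adjacent run), so the minority copy shows a
#' systematic deletion against the anchor. Insertions are never called.
#'
#' @param pileup `sd_pileup` from [build_pileup()].
#' @param min_f2 second-base frequency threshold (strictly greater-than).
#' @param max_sites upper bound on retained loci (default 200).
#' @return data.frame sorted by position: `pos` (1-based HPC anchor
#'   position), `major`, `second`, `f2`, `depth`.
#' @export
call_cismorphisms <- function(pileup, min_f2 = 0.25, max_sites = 200L) {
  stopifnot(inherits(pileup, "sd_pileup"))
  cn <- pileup$counts
  depth <- colSums(cn)
  ord <- apply(cn, 2, order, decreasing = TRUE)
  top1 <- cn[cbind(ord[1L, ], seq_len(ncol(cn)))]
  top2 <- cn[cbind(ord[2L, ], seq_len(ncol(cn)))]
  f2 <- ifelse(depth > 0, top2 / depth, 0)
  sel <- which(f2 > min_f2)
  if (length(sel) > max_sites) {
    sel <- sel[order(-f2[sel], sel)][seq_len(max_sites)]
  }
  sel <- sort(sel)
  data.frame(pos = sel,
             major = GENO_STATES[ord[1L, sel]],
             second = GENO_STATES[ord[2L, sel]],
             f2 = f2[sel],
             depth = depth[sel])
}

#' Read genotypes over the retained cis-morphism loci
#'
#' @param pileup `sd_pileup`.
#' @param cis data.frame from [call_cismorphisms()].
#' @return integer matrix (reads x loci; 0..3 bases, -1 missing) with read ids
#'   as row names.
#' @export
read_genotypes <- function(pileup, cis) {
  g <- pileup$calls[, cis$pos, drop = FALSE]
  rownames(g) <- pileup$read_ids
  g
}

#' Similarity-graph blocks of reads
#'
#' Connects two reads when their Hamming distance over jointly covered loci,
#' normalized by the number of shared loci, is at most `max_dist` and they
#' share at least `min_shared` loci. Each read is additionally connected to
#' its most similar neighbour when that distance is below `nn_cap`: genotype
#' noise occasionally pushes same-copy pairs past `max_dist`, and the
#' nearest-neighbour edge keeps a copy's reads in one block without linking
#' clearly distinct genotypes. Blocks are the connected components; reads
#' sharing fewer than `min_shared` loci with everyone (or whose nearest
#' neighbour is farther than `nn_cap`) form singleton blocks.
#'
#' @param geno genotype matrix from [read_genotypes()].
#' @param max_dist normalized Hamming distance threshold (default 0.4).
#' @param min_shared minimum jointly covered loci per edge (default 3).
#' @param nn_cap distance cap for the nearest-neighbour edge.
#' @return integer block membership vector (one entry per read).
#' @export
similarity_graph <- function(geno, max_dist = 0.4, min_shared = 3L,
                             nn_cap = 0.75) {
  n <- nrow(geno)
  if (n < 1L) stop("need at least one genotype")
  if (n == 1L) return(1L)
  if (ncol(geno) < min_shared) return(rep(1L, n))  # too few loci to compare
  pw <- cpp_pairwise_geno(geno)
  d <- pw$dist
  d[pw$shared < min_shared] <- NA
  adj <- !is.na(d) & d <= max_dist
  nn <- apply(d, 1, function(row) {
    row[is.na(row)] <- Inf
    j <- which.min(row)
    if (is.finite(row[j]) && row[j] <= nn_cap) j else NA_integer_
  })
  for (i in seq_len(n)) if (!is.na(nn[i])) adj[i, nn[i]] <- adj[nn[i], i] <- TRUE
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(gr)$membership)
}

#' Consensus genotype of a read set
#'
#' Per-locus majority base over non-missing calls; ties break to the
#' lexicographically smallest base; all-missing loci stay missing.
#'
#' @param geno genotype matrix (rows = reads).
#' @return integer vector of consensus calls.
#' @export
genotype_consensus <- function(geno) {
  apply(geno, 2, function(col) {
    col <- col[col >= 0]
    if (length(col) == 0L) return(GENO_MISSING)
    tab <- tabulate(col + 1L, nbins = 5L)
    which.max(tab) - 1L
  })
}

#' Randomized recursive clustering of a block
#'
#' Runs `n_sim` random simulations. Each simulation recursively partitions the
#' reads by a uniformly chosen informative cis-morphism locus (reads grouped
#' by their base; missing and sub-threshold bases join the majority branch),
#' stopping when no locus can split the set into groups of at least
#' `min_frac * coverage` reads. After splitting, reads are re-assigned to the
#' nearest cluster consensus. The best clustering minimizes the summed
#' Hamming distance of every read to its nearest cluster consensus (ties:
#' fewer clusters, then first found).
#'
#' @param geno genotype matrix of the block (rows = reads, with row names).
#' @param coverage expected number of anchor-spanning reads per SD copy.
#' @param min_frac cluster-size floor as a fraction of `coverage`.
#' @param n_sim number of random simulations.
#' @param seed optional seed for this block's simulations.
#' @param per_cluster_penalty complexity penalty added per cluster when
#'   comparing clusterings (default 0: the best clustering is the one with
#'   the minimal raw distance sum). The iteration driver passes the per-copy
#'   read coverage, so that an additional cluster must reduce the summed
#'   distance by at least one copy's worth of reads.
#' @param state_rate per-state noise rates (fraction of reads showing each of
#'   `A,C,G,T,-` at a locus by error alone); a state only forms a branch when
#'   its count exceeds the noise expected at the node's depth.
#' @param z_gate z-score gate applied to `state_rate` noise.
#' @return an `sd_clustering`: `clusters` (list of read-id vectors), `assign`,
#'   `consensus` (clusters x loci matrix), `score`, `n_clusters`.
#' @export
random_partition <- function(geno, coverage, min_frac = 0.8, n_sim = 100L,
                             seed = NULL, per_cluster_penalty = 0,
                             state_rate = rep(0, 5), z_gate = 2.5) {
  if (nrow(geno) == 0L) stop("empty block")
  if (n_sim < 1L) stop("n_sim must be >= 1")
  if (coverage <= 0) stop("coverage must be positive")
  if (!is.null(seed)) set.seed(seed)
  r <- cpp_random_partition(geno, min_frac * coverage, as.integer(n_sim),
                            per_cluster_penalty, state_rate, z_gate)
  ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
  clusters <- split(ids, r$assign)
  structure(list(clusters = unname(clusters), assign = r$assign,
                 consensus = r$consensus, score = r$score,
                 n_clusters = r$k),
            class = "sd_clustering")
}

#' @export
print.sd_clustering <- function(x, ...) {
  cat(sprintf("<sd_clustering> %d clusters (%s), score %.1f\n",
              x$n_clusters,
              paste(vapply(x$clusters, length, 0L), collapse = "+"),
              x$score))
  invisible(x)
}

#' Select the cluster continuing the previous iteration
#'
#' With a previous selection, picks the cluster sharing the most reads with it
#' (ties: larger cluster, then lexicographically smallest member id). Without
#' one (first iteration), picks the cluster whose consensus genotype is
#' closest in Hamming distance to the anchor's own bases at the cis-morphism
#' loci. When every intersection is empty and no anchor genotype is supplied,
#' the iteration has lost track of its locus.
#'
#' @param clusters list of clusters, each `list(ids, consensus)` where
#'   `consensus` is an integer genotype vector.
#' @param prev_reads read ids selected in the previous iteration, or `NULL`.
#' @param anchor_geno anchor genotype at the cis-morphism loci, or `NULL`.
#' @return `list(index, status)` with status `"ok"` or `"lost_track"`.
#' @export
select_cluster <- function(clusters, prev_reads = NULL, anchor_geno = NULL) {
  stopifnot(length(clusters) >= 1L)
  sizes <- vapply(clusters, function(cl) length(cl$ids), 0L)
  first_id <- vapply(clusters, function(cl) min(cl$ids), "")
  if (!is.null(prev_reads)) {
    ov <- vapply(clusters, function(cl) length(intersect(cl$ids, prev_reads)), 0L)
    if (any(ov > 0L)) {
      ord <- order(-ov, -sizes, first_id)
      return(list(index = ord[1L], status = "ok"))
    }
    if (is.null(anchor_geno)) return(list(index = NA_integer_,
                                          status = "lost_track"))
  }
  if (is.null(anchor_geno)) return(list(index = NA_integer_,
                                        status = "lost_track"))
  dist <- vapply(clusters, function(cl) {
    cons <- cl$consensus
    ok <- cons >= 0 & anchor_geno >= 0
    if (!any(ok)) return(0)  # no comparable loci: fall through to tie-breaks
    sum(cons[ok] != anchor_geno[ok])
  }, 0)
  ord <- order(dist, -sizes, first_id)
  list(index = ord[1L], status = "ok")
}

# per-state noise rates of pileup columns under the configured read error
# rate: the substitution rate spreads over three alternative bases plus
# alignment wobble; HPC deletions are dominated by lost singleton runs and
# wobble around run boundaries (rates calibrated on simulated single-copy
# pileups at 15% error; they scale roughly linearly with the error rate)
pileup_state_rates <- function(error_rate) {
  f <- error_rate / 0.15
  c(rep(0.042 * f, 4), 0.065 * f)
}

# driver-side cis-morphism call: per-state z-scored thresholds admit loci
# whose second state exceeds its noise expectation, while a copy-fraction
# term keeps the call meaningful for shallow stacks; ranked by z, capped,
# and thinned so artifact neighbourhoods contribute one locus. The gate is
# deliberately permissive (z > 1): a deep stack dilutes a private site's
# frequency below the top-level noise, and such loci only become decisive
# inside partition nodes after other copies have been split off, where the
# recursion re-tests them against the node-level noise
call_loci_z <- function(pileup, lambda, error_rate, max_sites = 200L,
                        z = 2.0, min_gap = 3L) {
  call_loci_z_counts(pileup$counts, pileup$n_reads, lambda, error_rate,
                     max_sites = max_sites, z = z, min_gap = min_gap)
}

call_loci_z_counts <- function(cn, N, lambda, error_rate, max_sites = 200L,
                               z = 2.0, min_gap = 3L) {
  depth <- pmax(colSums(cn), 1L)
  # per column: state index of the largest and second-largest count, ties
  # broken towards the lower state index (max.col "first" == stable order)
  idx <- cbind(seq_len(ncol(cn)), 0L)
  tcn <- t(cn)
  major <- max.col(tcn, ties.method = "first")
  idx[, 2L] <- major
  tcn[idx] <- -1L
  second <- max.col(tcn, ties.method = "first")
  idx[, 2L] <- second
  c2 <- tcn[idx]
  rates <- pileup_state_rates(error_rate)[second]
  zsc <- (c2 - depth * rates) / sqrt(pmax(depth * rates * (1 - rates), 1e-9))
  f2 <- c2 / depth
  sel <- which(zsc > z & f2 > 0.25 * lambda / N)
  if (length(sel) > 1L) {  # thin artifact neighbourhoods, keep strongest
    keep <- logical(length(sel))
    for (i in order(-zsc[sel], sel)) {
      if (!any(keep & abs(sel - sel[i]) <= min_gap)) keep[i] <- TRUE
    }
    sel <- sel[keep]
  }
  if (length(sel) > max_sites) {
    sel <- sel[order(-zsc[sel], sel)][seq_len(max_sites)]
  }
  sel <- sort(sel)
  data.frame(pos = sel, major = GENO_STATES[major[sel]],
             second = GENO_STATES[second[sel]], f2 = f2[sel],
             z = zsc[sel], depth = depth[sel])
}

# counts of the five states over a subset of pileup reads
subset_counts <- function(calls, rows) {
  cm <- calls[rows, , drop = FALSE]
  out <- matrix(0L, nrow = 5L, ncol = ncol(cm),
                dimnames = list(GENO_STATES, NULL))
  for (b in 0:4) out[b + 1L, ] <- colSums(cm == b)
  out
}

# recursive block refinement: within every unresolved read set, cis-morphism
# loci are re-derived from just those reads (a site private to one copy rises
# above the noise floor once unrelated copies are split away), the set is
# re-partitioned, and oversized children are refined further
refine_block <- function(pu, rows, cov_fs, cfg, iter, block, depth = 0L,
                         floor_cov = NULL, penalty = NULL) {
  floor_cov <- floor_cov %||% max(cfg$min_reads, cov_fs - 2 * sqrt(cov_fs))
  penalty <- penalty %||% cov_fs
  if (depth > 4L || length(rows) < 2 * cfg$min_frac * floor_cov) {
    return(list(rows))
  }
  cn <- subset_counts(pu$calls, rows)
  cis_b <- call_loci_z_counts(cn, length(rows), cov_fs, cfg$error_rate,
                              cfg$max_sites)
  if (nrow(cis_b) == 0L) return(list(rows))
  geno_b <- pu$calls[rows, cis_b$pos, drop = FALSE]
  rownames(geno_b) <- as.character(rows)
  part <- random_partition(geno_b, coverage = floor_cov,
                           min_frac = cfg$min_frac, n_sim = cfg$n_sim,
                           seed = derive_seed(cfg$seed, iter,
                                              block * 131L + depth),
                           per_cluster_penalty = penalty,
                           state_rate = pileup_state_rates(cfg$error_rate),
                           z_gate = 2.5)
  if (part$n_clusters == 1L) return(list(rows))
  out <- list()
  for (cl in part$clusters) {
    rws <- as.integer(cl)
    if (length(rws) > 1.7 * cov_fs) {
      out <- c(out, refine_block(pu, rws, cov_fs, cfg, iter, block,
                                 depth + 1L, floor_cov = floor_cov,
                                 penalty = penalty))
    } else {
      out <- c(out, list(rws))
    }
  }
  out
}

# clusters below the assembly minimum cannot stand alone; attach their reads
# to the nearest sizeable cluster by consensus-genotype distance
attach_small_clusters <- function(id_lists, geno, min_reads) {
  sizes <- lengths(id_lists)
  big <- which(sizes >= min_reads)
  if (length(big) == 0L || length(big) == length(id_lists)) return(id_lists)
  cons <- lapply(id_lists[big], function(ids)
    genotype_consensus(geno[ids, , drop = FALSE]))
  out <- id_lists[big]
  for (sm in which(sizes < min_reads)) {
    for (id in id_lists[[sm]]) {
      g <- geno[id, ]
      d <- vapply(cons, function(cc) {
        ok <- g >= 0L & cc >= 0L
        if (!any(ok)) return(Inf)
        sum(g[ok] != cc[ok]) / sum(ok)
      }, 0)
      j <- which.min(d)
      out[[j]] <- c(out[[j]], id)
    }
  }
  out
}

# drop pileup reads whose divergence is far above the bulk: they are
# chimeric junctions, mis-oriented segments or otherwise poorly aligned
# reads whose noisy genotypes seed spurious cluster shards
prune_pileup <- function(pu, slack = 0.06) {
  if (pu$n_reads < 8L) return(pu)
  cap <- stats::median(pu$read_div) + slack
  keep <- pu$read_div <= cap
  if (all(keep)) return(pu)
  pu$read_ids <- pu$read_ids[keep]
  pu$calls <- pu$calls[keep, , drop = FALSE]
  pu$r_as <- pu$r_as[keep]
  pu$r_ae <- pu$r_ae[keep]
  pu$read_div <- pu$read_div[keep]
  pu$n_reads <- sum(keep)
  for (b in 0:4) pu$counts[b + 1L, ] <- colSums(pu$calls == b)
  pu$coverage <- colSums(pu$counts)
  pu
}

# align a read segment against a slice of the HPC anchor (chained interval
# [a_lo, a_hi) in original anchor coordinates) and return its calls over the
# full anchor column range (-1 outside the covered slice), plus the original
# read coordinates of the aligned span and its divergence. Lets reads that
# cover only part of the anchor contribute genotypes and consensus support.
partial_calls <- function(amap, seg, a_lo, a_hi, band = 96L, max_div = 0.32) {
  m_all <- nchar(amap$compressed)
  c0 <- findInterval(a_lo, amap$start)            # 1-based column of a_lo
  c1 <- findInterval(max(a_lo + 1L, a_hi - 1L), amap$start)
  c0 <- max(1L, c0); c1 <- min(m_all, c1)
  if (c1 - c0 + 1L < 30L) return(NULL)
  qh <- substr(amap$compressed, c0, c1)
  rmap <- hpc_compress(seg)
  th <- rmap$compressed
  n <- nchar(th)
  m <- nchar(qh)
  if (n < 0.5 * m) return(NULL)
  B <- max(band, ceiling(0.15 * m))
  a <- cpp_align(qh, th, -B, max(n - m, 0L) + B, TRUE, TRUE, FALSE, TRUE, TRUE)
  if (is.na(a$dist) || a$alnlen == 0L) return(NULL)
  if (a$dist / a$alnlen > max_div) return(NULL)
  calls <- rep(-1L, m_all)
  calls[c0:c1] <- a$calls
  list(calls = calls,
       r_as = hpc_lift(rmap, a$t_start, "start"),
       r_ae = hpc_lift(rmap, a$t_end, "end"),
       col_range = c(c0, c1),
       div = a$dist / a$alnlen)
}

# genotype of the anchor itself at the cis loci (the pileup reference)
anchor_genotype <- function(pileup, cis) {
  bases <- strsplit(pileup$anchor_hpc, "", fixed = TRUE)[[1]][cis$pos]
  out <- match(bases, DNA_BASES) - 1L
  out[is.na(out)] <- GENO_MISSING
  out
}

# diagnostics dumps: the data surface a viewer would consume
write_cis_table <- function(cis, path) {
  write.table(cis, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_cluster_assignments <- function(ids, block, cluster, selected, path) {
  write.table(data.frame(read_id = ids, block = block, cluster = cluster,
                         selected = selected),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
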